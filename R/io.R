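# Readers and writers for the standard formats every stage consumes:
# FASTA genomes, GFF3 CDS annotations with an RBP flag, VCF variant calls
# with per-sample allele frequencies, and headed TSV assay/coverage tables.
# All coordinates are 1-based inclusive.

#' Default product keywords that mark a CDS as a receptor-binding protein
#'
#' Case-insensitive substrings matched against the GFF3 `product` attribute.
#' The curated-alignment RBP refinement used on the real community is not
#' reconstructed here; the keyword/attribute rule is an explicit proxy.
#' @export
RBP_KEYWORDS <- c("tail fiber", "tail spike", "receptor-binding")

#' Read phage genomes from a FASTA file
#'
#' Sequences are uppercased and `U` is mapped to `T`; only `A`, `C`, `G`,
#' `T`, `N` are accepted. Record ids are the first whitespace-delimited token
#' of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by genome id.
#' @export
read_genomes <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate genome id(s): ", paste(dup, collapse = ", "))
  }
  s <- chartr("U", "T", toupper(as.character(x)))
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) {
    stop("non-ACGTN characters in genome(s): ", paste(ids[bad], collapse = ", "))
  }
  if (any(nchar(s) == 0L)) {
    stop("zero-length genome(s): ", paste(ids[nchar(s) == 0L], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(s)
  names(out) <- ids
  out
}

#' Write genomes to FASTA
#'
#' @param genomes a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(genomes, path) {
  Biostrings::writeXStringSet(genomes, path)
  invisible(path)
}

#' Read CDS annotations from a GFF3 file
#'
#' Keeps `CDS` features and flags receptor-binding proteins: a CDS is an RBP
#' iff it carries an `rbp=true` attribute or its `product` attribute contains
#' any of `rbp_keywords` (case-insensitive substring).
#'
#' @param path path to a GFF3 file.
#' @param genomes optional [Biostrings::DNAStringSet]; when supplied, CDS
#'   referencing unknown genome ids or exceeding genome bounds are an error.
#' @param rbp_keywords character vector of product keywords ([RBP_KEYWORDS]).
#' @return a data.frame with columns `genome_id`, `feature_id`, `start`,
#'   `end`, `strand`, `product`, `is_rbp` (1-based inclusive coordinates).
#' @export
read_annotations <- function(path, genomes = NULL, rbp_keywords = RBP_KEYWORDS) {
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[S4Vectors::mcols(g)$type == "CDS"]
  if (length(g) == 0L) stop("no CDS features in ", path)
  mc <- S4Vectors::mcols(g)
  product <- if ("product" %in% names(mc)) as.character(mc$product) else rep(NA_character_, length(g))
  rbp_attr <- if ("rbp" %in% names(mc)) tolower(as.character(mc$rbp)) else rep(NA_character_, length(g))
  fid <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(g))
  fid[is.na(fid)] <- paste0(as.character(GenomicRanges::seqnames(g))[is.na(fid)],
                            "_cds", which(is.na(fid)))
  kw_hit <- rep(FALSE, length(g))
  for (kw in rbp_keywords) {
    kw_hit <- kw_hit | grepl(kw, tolower(product), fixed = TRUE)
  }
  kw_hit[is.na(product)] <- FALSE
  ann <- data.frame(
    genome_id = as.character(GenomicRanges::seqnames(g)),
    feature_id = fid,
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    product = product,
    is_rbp = (!is.na(rbp_attr) & rbp_attr == "true") | kw_hit,
    stringsAsFactors = FALSE
  )
  ann$strand[ann$strand == "*"] <- "+"
  if (!is.null(genomes)) {
    unknown <- setdiff(unique(ann$genome_id), names(genomes))
    if (length(unknown) > 0L) {
      stop("CDS reference unknown genome id(s): ", paste(unknown, collapse = ", "))
    }
    glen <- Biostrings::width(genomes)[match(ann$genome_id, names(genomes))]
    bad <- ann$start < 1L | ann$end > glen | ann$start > ann$end
    if (any(bad)) {
      stop("CDS outside genome bounds: ", paste(ann$feature_id[bad], collapse = ", "))
    }
  }
  ann
}

#' Write CDS annotations to GFF3
#'
#' @param annotations a CDS data.frame as returned by [read_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$genome_id,
    ranges = IRanges::IRanges(annotations$start, annotations$end),
    strand = annotations$strand
  )
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- annotations$feature_id
  S4Vectors::mcols(gr)$product <- annotations$product
  S4Vectors::mcols(gr)$rbp <- ifelse(annotations$is_rbp, "true", "false")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

parse_sample_key <- function(meta, path) {
  key_line <- grep("^##sample_key=", meta, value = TRUE)
  if (length(key_line) >= 1L) {
    kv <- key_line[1]
    line <- as.integer(sub(".*line=([0-9]+).*", "\\1", kv))
    passage <- as.integer(sub(".*passage=([0-9]+).*", "\\1", kv))
    if (!is.na(line) && !is.na(passage)) return(list(line = line, passage = passage))
  }
  fn <- basename(path)
  m <- regmatches(fn, regexec("L([0-9]+)_P([0-9]+)", fn))[[1]]
  if (length(m) == 3L) {
    return(list(line = as.integer(m[2]), passage = as.integer(m[3])))
  }
  list(line = NA_integer_, passage = NA_integer_)
}

#' Read variant calls from a VCF file
#'
#' Allele frequency comes from the `AF` INFO field; when absent it is
#' computed from `DP4` counts as alt/(ref+alt). A record with neither is an
#' error. Multi-allelic records are split into one row per alternate allele.
#' Sample identity (evolution line, passage) is taken from `sample`, else a
#' `##sample_key=line=<i>;passage=<j>` header line, else an `L<i>_P<j>`
#' pattern in the filename.
#'
#' @param path path to a VCF file.
#' @param sample optional `list(line =, passage =)` overriding header/filename.
#' @return a data.frame with columns `genome_id`, `pos`, `ref`, `alt`,
#'   `vtype` (`SNP`/`INS`/`DEL`), `af`, `depth`, `line`, `passage`.
#' @export
read_variants <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  key <- if (!is.null(sample)) sample else parse_sample_key(v@meta, path)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(data.frame(
      genome_id = character(0), pos = integer(0), ref = character(0),
      alt = character(0), vtype = character(0), af = numeric(0),
      depth = integer(0), line = integer(0), passage = integer(0)
    ))
  }
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    info <- fix[i, "INFO"]
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    af_m <- regmatches(info, regexec("(?:^|;)AF=([^;]+)", info))[[1]]
    dp_m <- regmatches(info, regexec("(?:^|;)DP=([0-9]+)", info))[[1]]
    depth <- if (length(dp_m) == 2L) as.integer(dp_m[2]) else NA_integer_
    if (length(af_m) == 2L) {
      af <- as.numeric(strsplit(af_m[2], ",", fixed = TRUE)[[1]])
    } else {
      dp4_m <- regmatches(info, regexec("(?:^|;)DP4=([0-9,]+)", info))[[1]]
      if (length(dp4_m) != 2L) {
        stop("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
             " has neither AF nor DP4; cannot derive allele frequency")
      }
      dp4 <- as.integer(strsplit(dp4_m[2], ",", fixed = TRUE)[[1]])
      af <- rep(sum(dp4[3:4]) / sum(dp4), length(alts))
    }
    if (length(af) != length(alts)) af <- rep_len(af, length(alts))
    vtype <- ifelse(nchar(alts) > nchar(ref), "INS",
                    ifelse(nchar(alts) < nchar(ref), "DEL", "SNP"))
    out[[i]] <- data.frame(
      genome_id = unname(fix[i, "CHROM"]), pos = as.integer(fix[i, "POS"]),
      ref = unname(ref), alt = alts, vtype = vtype, af = af, depth = depth,
      line = key$line, passage = key$passage, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write variant calls to a minimal VCF
#'
#' Writes a site-only VCF v4.2 with `AF` (4 decimals) and `DP` in INFO and a
#' `##sample_key` header line carrying line/passage identity.
#'
#' @param variants data.frame as returned by [read_variants()].
#' @param path output path.
#' @param line,passage sample identity; defaults to the values in `variants`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path,
                           line = variants$line[1], passage = variants$passage[1]) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##sample_key=line=%d;passage=%d", as.integer(line), as.integer(passage)),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(variants) > 0L) {
    o <- order(variants$genome_id, variants$pos)
    v <- variants[o, ]
    dp <- if ("depth" %in% names(v)) v$depth else rep(NA_integer_, nrow(v))
    info <- sprintf("AF=%.4f", v$af)
    info <- ifelse(is.na(dp), info, paste0(info, ";DP=", dp))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       v$genome_id, v$pos, v$ref, v$alt, info), con)
  }
  invisible(path)
}

table_schemas <- list(
  coverage = list(required = c("line", "passage", "phage", "mapped_reads"),
                  numeric = c("line", "passage", "mapped_reads")),
  spots = list(required = c("phage", "strain", "replicate", "outcome"),
               numeric = c("replicate")),
  titers = list(required = c("phage", "strain", "replicate", "titer"),
                numeric = c("replicate")),
  alignment_variant = list(required = c("genome_id", "pos", "ref", "alt",
                                        "line", "passage", "isolate"),
                           numeric = c("pos", "line", "passage"))
)

strip_tag <- function(x, tag) {
  # accepts "L1"/"P40" style values as well as bare integers
  sub(paste0("^", tag), "", x, ignore.case = TRUE)
}

#' Read a typed TSV table (coverage, spots, titers, alignment-variant)
#'
#' Validates the header against the named schema and coerces numeric fields.
#' Coverage `line`/`passage` values may be written `L1`/`P40` or bare.
#' In titer tables the sentinel `ND` (no spot detected) yields
#' `below_detection = TRUE` with `titer = NA`; the detection-limit substitute
#' is applied downstream by [compute_eop()].
#'
#' @param path path to a tab-separated file with a header row.
#' @param schema one of `"coverage"`, `"spots"`, `"titers"`,
#'   `"alignment_variant"`.
#' @return a typed data.frame.
#' @export
read_table <- function(path, schema = c("coverage", "spots", "titers", "alignment_variant")) {
  schema <- match.arg(schema)
  sch <- table_schemas[[schema]]
  x <- read.delim(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(sch$required, names(x))
  if (length(missing) > 0L) {
    stop("table ", path, " lacks required column(s) for schema '", schema,
         "': ", paste(missing, collapse = ", "))
  }
  if (schema == "coverage") {
    x$line <- strip_tag(x$line, "L")
    x$passage <- strip_tag(x$passage, "P")
  }
  if (schema == "titers") {
    nd <- toupper(trimws(x$titer)) %in% c("ND", "NA")
    x$below_detection <- nd
    x$titer[nd] <- NA_character_
    tt <- suppressWarnings(as.numeric(x$titer))
    if (any(is.na(tt) & !nd)) {
      stop("non-numeric titer value(s) in ", path)
    }
    x$titer <- tt
  }
  for (col in sch$numeric) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    if (any(is.na(v) & !is.na(x[[col]]) & x[[col]] != "")) {
      stop("non-numeric value in column '", col, "' of ", path)
    }
    x[[col]] <- if (col %in% c("line", "passage", "replicate", "pos")) as.integer(v) else v
  }
  if (schema == "spots") {
    ok <- c("PLAQUES", "TURBID_FIRST_ONLY", "NONE")
    if (!all(x$outcome %in% ok)) {
      stop("unknown spot outcome(s): ",
           paste(unique(setdiff(x$outcome, ok)), collapse = ", "))
    }
    if ("limiting_dilution" %in% names(x)) {
      x$limiting_dilution <- suppressWarnings(as.integer(x$limiting_dilution))
    } else {
      x$limiting_dilution <- NA_integer_
    }
  }
  x
}

#' Write a data.frame as a TSV table
#'
#' Inverse of [read_table()]; `NA` titers with `below_detection = TRUE` are
#' written back as the `ND` sentinel.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  if ("below_detection" %in% names(x) && "titer" %in% names(x)) {
    x$titer <- ifelse(x$below_detection, "ND", format(x$titer, scientific = FALSE, trim = TRUE))
    x$below_detection <- NULL
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
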