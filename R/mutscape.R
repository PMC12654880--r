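# Mutational landscape: variant effect classification against CDS
# annotations, sliding-window mutation profiles, exact region-vs-genome
# rate enrichment (comparison of Poisson rates), cross-line parallelism,
# and a Nei-Gojobori counting dN/dS screen.

GENETIC_CODE_11 <- Biostrings::GENETIC_CODE  # table 11 translates identically

complement_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chars <- function(chars) rev(unname(complement_base[chars]))

translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return(NA_character_)
  unname(GENETIC_CODE_11[codon])
}

#' Classify variants by coding effect
#'
#' Each variant is located against the CDS annotations: SNPs inside a CDS
#' are classified by their codon change under the standard bacterial genetic
#' code (SYNONYMOUS / NONSYNONYMOUS / NONSENSE); codons containing `N` are
#' flagged `AMBIGUOUS_N`. Indels inside a CDS are `FRAMESHIFT` when the
#' length change is not a multiple of 3, else `INFRAME_INDEL`. Variants in
#' no CDS are `INTERGENIC`. Minus-strand CDS are classified on the
#' reverse-complemented reading frame.
#'
#' @param variants variant data.frame ([read_variants()]).
#' @param features CDS data.frame ([read_annotations()]); lengths must be
#'   multiples of 3.
#' @param genomes named [Biostrings::DNAStringSet].
#' @return the input with added columns `effect`, `cds_id`, `ref_aa`,
#'   `alt_aa`, `codon_index`.
#' @export
classify_variants <- function(variants, features, genomes) {
  bad <- (features$end - features$start + 1L) %% 3L != 0L
  if (any(bad)) {
    stop("CDS length not divisible by 3: ",
         paste(features$feature_id[bad], collapse = ", "))
  }
  seqs <- setNames(as.character(genomes), names(genomes))
  n <- nrow(variants)
  effect <- character(n)
  cds_id <- rep(NA_character_, n)
  ref_aa <- rep(NA_character_, n)
  alt_aa <- rep(NA_character_, n)
  codon_index <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    g <- variants$genome_id[i]
    pos <- variants$pos[i]
    if (!g %in% names(seqs)) stop("variant references unknown genome '", g, "'")
    if (pos < 1L || pos > nchar(seqs[[g]])) {
      stop("variant position ", pos, " outside genome ", g)
    }
    f <- features[features$genome_id == g & features$start <= pos &
                    features$end >= pos, , drop = FALSE]
    if (nrow(f) == 0L) {
      effect[i] <- "INTERGENIC"
      next
    }
    f <- f[1L, ]  # overlapping CDS are rare; classify against the first
    cds_id[i] <- f$feature_id
    ref <- variants$ref[i]
    alt <- variants$alt[i]
    if (nchar(ref) != nchar(alt)) {
      effect[i] <- if ((abs(nchar(ref) - nchar(alt)) %% 3L) != 0L)
        "FRAMESHIFT" else "INFRAME_INDEL"
      next
    }
    # SNP (or same-length substitution, classified on its first base)
    if (f$strand == "+") {
      off <- pos - f$start
      ci <- off %/% 3L
      cstart <- f$start + 3L * ci
      codon <- strsplit(substring(seqs[[g]], cstart, cstart + 2L), "")[[1]]
      k <- off %% 3L + 1L
      mut <- codon
      mut[k] <- substr(alt, 1L, 1L)
    } else {
      off <- f$end - pos
      ci <- off %/% 3L
      cend <- f$end - 3L * ci
      codon <- revcomp_chars(strsplit(substring(seqs[[g]], cend - 2L, cend), "")[[1]])
      k <- off %% 3L + 1L
      mut <- codon
      mut[k] <- complement_base[[substr(alt, 1L, 1L)]]
    }
    codon_index[i] <- ci + 1L
    aa1 <- translate_codon(paste(codon, collapse = ""))
    aa2 <- translate_codon(paste(mut, collapse = ""))
    if (is.na(aa1) || is.na(aa2)) {
      effect[i] <- "AMBIGUOUS_N"
      next
    }
    ref_aa[i] <- aa1
    alt_aa[i] <- aa2
    effect[i] <- if (aa1 == aa2) "SYNONYMOUS"
                 else if (aa2 == "*") "NONSENSE"
                 else "NONSYNONYMOUS"
  }
  cbind(variants, data.frame(effect = effect, cds_id = cds_id,
                             ref_aa = ref_aa, alt_aa = alt_aa,
                             codon_index = codon_index,
                             stringsAsFactors = FALSE))
}

#' Sliding-window mutation profile along a genome
#'
#' Windows of `window` bases advance by `step` (default half a window) from
#' position 1; the final partial window is included. Two metrics per window:
#' the number of distinct mutated positions and the sum of allele
#' frequencies over variant records.
#'
#' @param variants variants of one genome (typically one evolution line).
#' @param genome_length genome length in bases.
#' @param window window size in bases (the display convention is 500).
#' @param step step between window starts.
#' @return data.frame with `window_start`, `window_end`, `n_positions`,
#'   `af_sum`.
#' @export
window_profile <- function(variants, genome_length, window = 500L, step = window / 2) {
  stopifnot(window > 0, step > 0, step <= window)
  starts <- seq.int(1L, genome_length, by = as.integer(step))
  ends <- pmin(starts + as.integer(window) - 1L, genome_length)
  n_pos <- integer(length(starts))
  af_sum <- numeric(length(starts))
  for (i in seq_along(starts)) {
    hit <- variants$pos >= starts[i] & variants$pos <= ends[i]
    n_pos[i] <- length(unique(variants$pos[hit]))
    af_sum[i] <- sum(variants$af[hit])
  }
  data.frame(window_start = starts, window_end = ends,
             n_positions = n_pos, af_sum = af_sum)
}

#' Distinct mutated positions inside vs outside a region, per line
#'
#' Counts distinct genomic positions (not variant records: a position
#' mutated at both sampled passages, or with two alternate alleles, counts
#' once) carrying at least one variant in the stated passages, separately
#' per evolution line, split by a region given as intervals (overlaps are
#' unioned).
#'
#' @param variants variant data.frame for one genome.
#' @param region data.frame of intervals with `start`, `end` (1-based
#'   inclusive).
#' @param passages passages considered (default 40 and 69).
#' @param lines lines to tabulate (default: those present).
#' @return data.frame with `line`, `k_region`, `k_rest`; the unioned region
#'   length is attached as attribute `L_region`.
#' @export
count_region_positions <- function(variants, region, passages = c(40L, 69L),
                                   lines = sort(unique(variants$line))) {
  u <- interval_union(region)
  out <- data.frame(line = lines, k_region = 0L, k_rest = 0L)
  for (j in seq_along(lines)) {
    v <- variants[variants$line == lines[j] & variants$passage %in% passages, , drop = FALSE]
    pos <- unique(v$pos)
    inside <- positions_in_intervals(pos, u)
    out$k_region[j] <- sum(inside)
    out$k_rest[j] <- sum(!inside)
  }
  attr(out, "L_region") <- sum(u$end - u$start + 1L)
  out
}

#' Exact comparison of two Poisson rates (conditional binomial test)
#'
#' Tests whether mutations accumulate at a higher per-base rate in a region
#' than in the rest of the genome. Conditional on the total count
#' `K = k_region + k_rest`, the region count is Binomial(K, L_region /
#' (L_region + L_rest)) under equal rates; the two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed one
#' (minimum-likelihood convention). One-sided alternatives are exact
#' binomial tails.
#'
#' @param k_region,k_rest distinct mutated positions inside / outside the
#'   region.
#' @param L_region,L_rest region / remaining genome lengths in bases.
#' @param alternative `"two.sided"` (default), `"greater"` (region rate
#'   higher) or `"less"`.
#' @return an object of classes `poisson_rate_test` and `htest` with
#'   `p.value` and the rate ratio `(k_region/L_region)/(k_rest/L_rest)` as
#'   `estimate` (`NA` when no mutations at all).
#' @export
#' @examples
#' poisson_rate_test(10, 2000, 20, 40000)
poisson_rate_test <- function(k_region, L_region, k_rest, L_rest,
                              alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(L_region > 0, L_rest > 0, k_region >= 0, k_rest >= 0)
  K <- k_region + k_rest
  p0 <- L_region / (L_region + L_rest)
  if (K == 0L) {
    p <- 1
    rr <- NA_real_
  } else {
    rr <- (k_region / L_region) / (k_rest / L_rest)
    p <- switch(alternative,
      two.sided = {
        d <- dbinom(0:K, K, p0)
        sum(d[d <= d[k_region + 1L] * (1 + 1e-7)])
      },
      greater = pbinom(k_region - 1L, K, p0, lower.tail = FALSE),
      less = pbinom(k_region, K, p0)
    )
    p <- min(p, 1)
  }
  structure(list(
    statistic = c(`k region` = k_region),
    parameter = c(`K` = K, `L region` = L_region, `L rest` = L_rest),
    p.value = p,
    estimate = c(`rate ratio` = rr),
    alternative = alternative,
    method = "Exact conditional comparison of two Poisson rates",
    data.name = sprintf("%d of %d mutated positions in %g of %g bases",
                        k_region, K, L_region, L_region + L_rest)
  ), class = c("poisson_rate_test", "htest"))
}

#' Region-vs-genome mutation-rate enrichment per line
#'
#' Convenience wrapper: counts distinct mutated positions inside and outside
#' `region` per line ([count_region_positions()]) and applies
#' [poisson_rate_test()] to each. Benjamini-Hochberg adjusted p-values are
#' added only on request (`adjust = TRUE`); raw p-values are always
#' reported.
#'
#' @param variants variant data.frame for one genome.
#' @param region region intervals (`start`/`end`), e.g. the RBP CDS spans.
#' @param genome_length total genome length.
#' @param passages passages considered (default 40 and 69).
#' @param adjust add a BH-adjusted column across lines.
#' @inheritParams poisson_rate_test
#' @return data.frame with per-line counts, lengths, rate ratio and exact
#'   p-value.
#' @export
region_enrichment <- function(variants, region, genome_length,
                              passages = c(40L, 69L),
                              alternative = "two.sided", adjust = FALSE) {
  counts <- count_region_positions(variants, region, passages)
  L_region <- attr(counts, "L_region")
  L_rest <- genome_length - L_region
  counts$L_region <- L_region
  counts$L_rest <- L_rest
  res <- lapply(seq_len(nrow(counts)), function(i) {
    poisson_rate_test(counts$k_region[i], L_region, counts$k_rest[i], L_rest,
                      alternative = alternative)
  })
  counts$rate_ratio <- vapply(res, function(r) unname(r$estimate), numeric(1))
  counts$p_value <- vapply(res, function(r) r$p.value, numeric(1))
  if (adjust) counts$p_adjusted <- p.adjust(counts$p_value, "BH")
  counts
}

#' Positions mutated in two or more evolution lines
#'
#' @param variants variant data.frame (several lines, one genome or many).
#' @return data.frame with `genome_id`, `pos`, `n_lines`, `lines`
#'   (comma-separated), `max_af`, and `effects` when the input carries an
#'   `effect` column; zero rows when nothing is shared.
#' @export
parallelism <- function(variants) {
  if (length(unique(variants$line)) < 2L) {
    stop("parallelism requires variants from at least 2 lines")
  }
  key <- paste(variants$genome_id, variants$pos, sep = ":")
  out <- list()
  for (k in unique(key)) {
    v <- variants[key == k, , drop = FALSE]
    lines <- sort(unique(v$line))
    if (length(lines) < 2L) next
    out[[length(out) + 1L]] <- data.frame(
      genome_id = v$genome_id[1], pos = v$pos[1],
      n_lines = length(lines), lines = paste(lines, collapse = ","),
      max_af = max(v$af),
      effects = if ("effect" %in% names(v))
        paste(sort(unique(v$effect)), collapse = ",") else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(genome_id = character(0), pos = integer(0),
                      n_lines = integer(0), lines = character(0),
                      max_af = numeric(0), effects = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$genome_id, res$pos), , drop = FALSE]
}

codon_table <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Fraction of the three possible changes at each codon position that are
# synonymous; changes to stop codons count as non-synonymous.
codon_syn_sites <- function(codon) {
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  aa <- translate_codon(codon)
  s <- 0
  for (k in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[k])) {
      mut <- chars
      mut[k] <- b
      if (identical(translate_codon(paste(mut, collapse = "")), aa)) s <- s + 1 / 3
    }
  }
  s
}

# All orderings of the differing positions; paths through premature stop
# codons are discarded (unless every path is blocked, then all are used).
codon_path_diffs <- function(ca, cb) {
  a <- strsplit(ca, "", fixed = TRUE)[[1]]
  b <- strsplit(cb, "", fixed = TRUE)[[1]]
  dpos <- which(a != b)
  nd <- length(dpos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(dpos) else {
    if (nd == 2L) list(dpos, rev(dpos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) dpos[o])
    }
  }
  tally <- function(order) {
    cur <- a
    sd <- 0
    nd_ <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- translate_codon(paste(cur, collapse = ""))
      aa2 <- translate_codon(paste(nxt, collapse = ""))
      if (aa2 == "*" && !identical(nxt, b)) return(NULL)  # premature stop
      if (aa1 == aa2) sd <- sd + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd_)
  }
  res <- lapply(perms, tally)
  ok <- res[!vapply(res, is.null, logical(1))]
  if (length(ok) == 0L) {
    ok <- lapply(perms, function(o) {
      cur <- a; sd <- 0; nd_ <- 0
      for (p in o) {
        nxt <- cur; nxt[p] <- b[p]
        if (identical(translate_codon(paste(cur, collapse = "")),
                      translate_codon(paste(nxt, collapse = "")))) sd <- sd + 1
        else nd_ <- nd_ + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd_)
    })
  }
  colMeans(do.call(rbind, ok))
}

#' Counting dN/dS between two aligned coding sequences (Nei-Gojobori 1986)
#'
#' Synonymous and non-synonymous site counts come from the per-position
#' fraction of synonymous changes among the three possible substitutions
#' (averaged over the two sequences); observed differences in multi-hit
#' codons are averaged over all shortest mutational pathways, discarding
#' pathways through premature stop codons. Proportions are Jukes-Cantor
#' corrected, `d = -(3/4) ln(1 - (4/3) p)`. This is an explicitly simplified
#' counting screen, not a codon-model likelihood method. Codons containing
#' `N` or gaps in either sequence are excluded and counted in `n_excluded`.
#'
#' @param cds_seq_a,cds_seq_b coding sequences (character or
#'   [Biostrings::DNAString]); equal length, multiple of 3, no internal
#'   stops.
#' @return an object of class `dnds_result`: `S_sites`, `N_sites`, `Sd`,
#'   `Nd`, `pS`, `pN`, `dS`, `dN`, `ratio` (`NA` when `dS` is 0), `status`
#'   (`"OK"` or `"SATURATED"` when a proportion reaches 3/4), `n_codons`,
#'   `n_excluded`.
#' @export
#' @examples
#' ng86_dnds("GGGGGG", "GGAGGG")  # one synonymous change: ratio 0
ng86_dnds <- function(cds_seq_a, cds_seq_b) {
  a <- toupper(as.character(cds_seq_a))
  b <- toupper(as.character(cds_seq_b))
  if (nchar(a) != nchar(b)) stop("sequences must be equal length")
  if (nchar(a) %% 3L != 0L) stop("sequence length must be a multiple of 3")
  ca <- codon_table(a)
  cb <- codon_table(b)
  usable <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  n_excluded <- sum(!usable)
  ca <- ca[usable]
  cb <- cb[usable]
  internal <- seq_along(ca) < length(ca)
  if (any(vapply(ca[internal], translate_codon, character(1)) == "*") ||
      any(vapply(cb[internal], translate_codon, character(1)) == "*")) {
    stop("internal stop codon in input")
  }
  S <- (sum(vapply(ca, codon_syn_sites, numeric(1))) +
        sum(vapply(cb, codon_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca), function(i) codon_path_diffs(ca[i], cb[i]),
                  numeric(2))
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  saturated <- pS >= 3 / 4 || pN >= 3 / 4
  jc <- function(p) if (p == 0) 0 else -3 / 4 * log(1 - 4 / 3 * p)
  dS <- if (saturated) NA_real_ else jc(pS)
  dN <- if (saturated) NA_real_ else jc(pN)
  ratio <- if (saturated || is.na(dS) || dS == 0) NA_real_ else dN / dS
  if (!saturated && !is.na(dS) && dS > 0 && dN == 0) ratio <- 0
  structure(list(
    S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    dS = dS, dN = dN, ratio = ratio,
    status = if (saturated) "SATURATED" else "OK",
    n_codons = length(ca), n_excluded = n_excluded
  ), class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("Nei-Gojobori dN/dS over %d codons (%d excluded)\n",
              x$n_codons, x$n_excluded))
  cat(sprintf("  S = %.2f, N = %.2f; Sd = %.2f, Nd = %.2f\n",
              x$S_sites, x$N_sites, x$Sd, x$Nd))
  if (x$status == "SATURATED") {
    cat("  SATURATED: proportion of differences >= 3/4, no distance\n")
  } else {
    cat(sprintf("  dS = %.4f, dN = %.4f, dN/dS = %s\n", x$dS, x$dN,
                ifelse(is.na(x$ratio), "NA (dS = 0)", sprintf("%.4f", x$ratio))))
  }
  invisible(x)
}
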