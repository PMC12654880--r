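# Synthetic experiment generator: random phage genomes with annotated CDS and
# a designated close-relative pair, serial-passage community dynamics with
# bottleneck drift and RBP-weighted mutation, recombinant mosaics with planted
# breakpoints, and plating assays with a detection limit. Every stage records
# its ground truth so downstream estimators have parameter-recovery tests.

#' Configuration for a synthetic phage-community evolution experiment
#'
#' Defaults mirror the evolution protocol the generator emulates: a 12-phage
#' community passaged 69 times in 3 independent lines, sequenced at passages
#' 0/40/69, one pair of close relatives distinguished by diagnostic sites,
#' a plating detection limit of 10^2 PFU/mL and an inoculum of 10^6 PFU/mL
#' per phage.
#'
#' @param seed master integer seed; all stages derive deterministic
#'   substreams from it via [substream_seed()].
#' @param n_phages,n_hosts community sizes (phages, bacterial strains).
#' @param n_lines,n_passages evolution lines and serial passages.
#' @param sequencing_passages passages at which variant calls and coverage
#'   are emitted.
#' @param pair_identity nucleotide identity of the designated close pair,
#'   in (0.9, 1); substituted positions become the diagnostic sites.
#' @param genome_length_range genome lengths (bases), sampled uniformly.
#' @param gc GC content of the random genomes.
#' @param n_cds_range CDS count per genome (placement is gene-dense tiling;
#'   the upper bound caps the count).
#' @param mu per-base per-passage mutation probability.
#' @param rho mutation-placement enrichment multiplier for RBP-coding bases
#'   (`rho = 1` is uniform placement).
#' @param sel_coeff per-passage logistic growth rate of beneficial alleles.
#' @param beneficial_frac fraction of RBP mutations that are beneficial.
#' @param Ne resampling depth for allele-frequency drift (`Inf` disables
#'   drift).
#' @param bottleneck phage particles sampled per passage.
#' @param fitness_scale coefficient `c` in the replicator fitness
#'   `w_i = 1 + c * sum_h matrix[i, h]`.
#' @param indel_rate per-phage per-passage probability of a short (1-30 bp)
#'   deletion.
#' @param min_emit_af smallest allele frequency written to VCF (variant
#'   caller sensitivity floor).
#' @param reads_per_sample sequencing reads per (line, passage) sample.
#' @param diag_depth per-site read depth used to draw noisy diagnostic-site
#'   allele frequencies for the close pair.
#' @param detection_limit plating detection limit (PFU/mL).
#' @param inoculum_titer per-phage inoculum titer (PFU/mL).
#' @param n_recombinants,k_breakpoints,min_gap recombinant mosaic defaults
#'   passed to [generate_recombinants()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_phages = 12L, n_hosts = 39L,
                       n_lines = 3L, n_passages = 69L,
                       sequencing_passages = c(0L, 40L, 69L),
                       pair_identity = 0.98,
                       genome_length_range = c(40000L, 170000L),
                       gc = 0.5,
                       n_cds_range = c(10L, 60L),
                       mu = 2e-7, rho = 10,
                       sel_coeff = 0.25, beneficial_frac = 0.1,
                       Ne = 1000, bottleneck = 1000,
                       fitness_scale = 0.05,
                       indel_rate = 0.02,
                       min_emit_af = 0.01,
                       reads_per_sample = 1e5,
                       diag_depth = 100L,
                       detection_limit = 1e2,
                       inoculum_titer = 1e6,
                       n_recombinants = 27L,
                       k_breakpoints = 1:3,
                       min_gap = 2000L) {
  cfg <- list(
    seed = as.integer(seed), n_phages = as.integer(n_phages),
    n_hosts = as.integer(n_hosts), n_lines = as.integer(n_lines),
    n_passages = as.integer(n_passages),
    sequencing_passages = sort(unique(as.integer(sequencing_passages))),
    pair_identity = pair_identity,
    genome_length_range = as.integer(genome_length_range), gc = gc,
    n_cds_range = as.integer(n_cds_range),
    mu = mu, rho = rho, sel_coeff = sel_coeff,
    beneficial_frac = beneficial_frac, Ne = Ne,
    bottleneck = as.integer(bottleneck), fitness_scale = fitness_scale,
    indel_rate = indel_rate, min_emit_af = min_emit_af,
    reads_per_sample = reads_per_sample, diag_depth = as.integer(diag_depth),
    detection_limit = detection_limit, inoculum_titer = inoculum_titer,
    n_recombinants = as.integer(n_recombinants),
    k_breakpoints = as.integer(k_breakpoints), min_gap = as.integer(min_gap)
  )
  with(cfg, {
    stopifnot(n_phages >= 2L, n_hosts >= 1L, n_lines >= 1L, n_passages >= 1L,
              mu > 0, mu < 1, rho >= 1, bottleneck > 0,
              gc > 0, gc < 1, Ne > 0,
              genome_length_range[1] >= 3000L,
              all(sequencing_passages >= 0L),
              all(sequencing_passages <= n_passages))
  })
  if (!(cfg$pair_identity > 0.9 && cfg$pair_identity < 1)) {
    stop("pair_identity must lie strictly in (0.9, 1); identical pair members ",
         "carry no diagnostic sites")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic phage-community experiment configuration\n")
  cat(sprintf("  %d phages (pair identity %.3f), %d hosts, %d lines x %d passages\n",
              x$n_phages, x$pair_identity, x$n_hosts, x$n_lines, x$n_passages))
  cat(sprintf("  mu = %.2g /base/passage, rho = %.3g, s = %.3g, Ne = %.3g, bottleneck = %d\n",
              x$mu, x$rho, x$sel_coeff, x$Ne, x$bottleneck))
  cat(sprintf("  sequencing at passages %s; %g reads/sample\n",
              paste(x$sequencing_passages, collapse = "/"), x$reads_per_sample))
  invisible(x)
}

phage_ids <- function(n) {
  if (n <= 26L) paste0("phage", LETTERS[seq_len(n)]) else sprintf("phage%02d", seq_len(n))
}

random_genome <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

other_bases <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")

substitute_base <- function(base) {
  vapply(base, function(b) {
    k <- sample.int(3L, 1L)
    substr(other_bases[[b]], k, k)
  }, character(1), USE.NAMES = FALSE)
}

named_products <- c("terminase large subunit", "portal protein",
                    "major capsid protein", "DNA polymerase", "endolysin",
                    "holin", "tail sheath protein", "baseplate protein")

# Gene-dense tiling: alternate short intergenic gaps and CDS until the genome
# (or the CDS cap) is exhausted. Phage genomes are ~90% coding, so placement
# is deterministic-feasible rather than rejection-sampled.
place_cds <- function(genome_id, len, n_cds_range) {
  starts <- integer(0)
  ends <- integer(0)
  pos <- 1L + sample.int(100L, 1L)
  while (length(starts) < n_cds_range[2] && pos + 299L <= len) {
    cds_len <- 3L * sample(100:600, 1L)
    if (pos + cds_len - 1L > len) {
      cds_len <- 3L * ((len - pos + 1L) %/% 3L)
      if (cds_len < 300L) break
    }
    starts <- c(starts, pos)
    ends <- c(ends, pos + cds_len - 1L)
    pos <- pos + cds_len + sample(0:150, 1L)
  }
  n <- length(starts)
  if (n < n_cds_range[1]) {
    stop("could not place at least ", n_cds_range[1], " CDS on genome ",
         genome_id, " (", len, " bp); use longer genomes")
  }
  n_rbp <- min(n, sample(1:3, 1L))
  rbp_idx <- sample.int(n, n_rbp)
  product <- ifelse(runif(n) < 0.25,
                    sample(named_products, n, replace = TRUE),
                    "hypothetical protein")
  product[rbp_idx] <- sample(c("tail fiber protein", "tail spike protein"),
                             n_rbp, replace = TRUE)
  data.frame(
    genome_id = genome_id,
    feature_id = sprintf("%s_cds%03d", genome_id, seq_len(n)),
    start = starts, end = ends,
    strand = sample(c("+", "-"), n, replace = TRUE),
    product = product,
    is_rbp = seq_len(n) %in% rbp_idx,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic phage community: genomes, annotations, diagnostic sites
#'
#' Draws `n_phages` random genomes with gene-dense CDS annotations (each with
#' at least one flagged RBP). Exactly one designated close-relative pair is
#' created by copying one genome and substituting bases at i.i.d. positions
#' so the pair reaches `pair_identity`; the substituted positions are the
#' returned diagnostic sites. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `phage_genome_set`: list with `genomes`
#'   ([Biostrings::DNAStringSet]), `features` (CDS data.frame), `pair`
#'   (ids of the close pair, reference member first), `diagnostic_sites`
#'   (positions where the pair differs) and `config`.
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "genomes"), {
    ids <- phage_ids(config$n_phages)
    pair_idx <- if (config$n_phages >= 3L) c(2L, 3L) else c(1L, 2L)
    rng <- config$genome_length_range
    lens <- rng[1] + sample.int(rng[2] - rng[1] + 1L, config$n_phages,
                                replace = TRUE) - 1L
    lens[pair_idx[2]] <- lens[pair_idx[1]]
    seqs <- character(config$n_phages)
    feats <- vector("list", config$n_phages)
    for (i in seq_len(config$n_phages)) {
      if (i == pair_idx[2]) next
      seqs[i] <- random_genome(lens[i], config$gc)
      feats[[i]] <- place_cds(ids[i], lens[i], config$n_cds_range)
    }
    # the minor pair member: copy + i.i.d. substitutions
    ref <- seqs[pair_idx[1]]
    n_ref <- lens[pair_idx[1]]
    diag_sites <- which(runif(n_ref) < (1 - config$pair_identity))
    chars <- strsplit(ref, "", fixed = TRUE)[[1]]
    chars[diag_sites] <- substitute_base(chars[diag_sites])
    seqs[pair_idx[2]] <- paste(chars, collapse = "")
    f2 <- feats[[pair_idx[1]]]
    f2$genome_id <- ids[pair_idx[2]]
    f2$feature_id <- sub(ids[pair_idx[1]], ids[pair_idx[2]], f2$feature_id, fixed = TRUE)
    feats[[pair_idx[2]]] <- f2
    genomes <- Biostrings::DNAStringSet(seqs)
    names(genomes) <- ids
    structure(list(
      genomes = genomes,
      features = do.call(rbind, feats),
      pair = ids[pair_idx],
      diagnostic_sites = diag_sites,
      config = config
    ), class = "phage_genome_set")
  })
}

#' Generate a host susceptibility matrix
#'
#' Rows are phages, columns bacterial strains, entries 0 (resistant),
#' 1 (partially susceptible), 2 (susceptible). Roughly a third of phages are
#' generalists (3-7 susceptible strains); the rest are specialists with a
#' single susceptible strain and up to two partials.
#'
#' @param config a [sim_config()].
#' @param phage_ids optional row names (defaults to the generator's ids).
#' @return an integer matrix.
#' @export
make_host_matrix <- function(config, phage_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ids <- phage_ids %||% phage_ids_default(config)
  with_seed(substream_seed(config$seed, "hosts"), {
    m <- matrix(0L, config$n_phages, config$n_hosts,
                dimnames = list(ids, sprintf("K%02d", seq_len(config$n_hosts))))
    for (i in seq_len(config$n_phages)) {
      if (runif(1) < 1 / 3) {
        susceptible <- sample.int(config$n_hosts, min(config$n_hosts, sample(3:7, 1L)))
      } else {
        susceptible <- sample.int(config$n_hosts, 1L)
      }
      m[i, susceptible] <- 2L
      n_draw <- min(config$n_hosts, sample(0:3, 1L) + length(susceptible))
      partial <- setdiff(sample.int(config$n_hosts, n_draw), susceptible)
      m[i, partial] <- 1L
    }
    m
  })
}

phage_ids_default <- function(config) phage_ids(config$n_phages)

#' Place mutations on a genome with RBP-weighted positions
#'
#' Positions are uniform over the genome except that bases inside
#' `rbp_intervals` receive `rho`-fold weight. Used by [simulate_evolution()]
#' and directly for calibration experiments on the enrichment test.
#'
#' @param n number of positions to draw (with replacement).
#' @param genome_length genome length in bases.
#' @param rbp_intervals data.frame with `start`/`end` (1-based inclusive), or
#'   `NULL` for none.
#' @param rho weight multiplier for RBP bases (`>= 1`).
#' @return integer vector of positions.
#' @export
place_mutations <- function(n, genome_length, rbp_intervals = NULL, rho = 1) {
  if (n == 0L) return(integer(0))
  if (is.null(rbp_intervals) || nrow(rbp_intervals) == 0L || rho == 1) {
    return(sample.int(genome_length, n, replace = TRUE))
  }
  u <- interval_union(rbp_intervals)
  L_r <- sum(u$end - u$start + 1L)
  p_r <- rho * L_r / (rho * L_r + (genome_length - L_r))
  inside <- runif(n) < p_r
  pos <- integer(n)
  if (any(!inside)) {
    comp <- interval_complement(rbp_intervals, genome_length)
    pos[!inside] <- sample_from_intervals(sum(!inside), comp)
  }
  if (any(inside)) {
    pos[inside] <- sample_from_intervals(sum(inside), u)
  }
  pos
}

interval_complement <- function(intervals, genome_length) {
  u <- interval_union(intervals)
  s <- c(1L, u$end + 1L)
  e <- c(u$start - 1L, genome_length)
  keep <- s <= e
  data.frame(start = s[keep], end = e[keep])
}

sample_from_intervals <- function(n, intervals) {
  w <- intervals$end - intervals$start + 1L
  k <- sample.int(nrow(intervals), n, replace = TRUE, prob = w)
  intervals$start[k] + floor(runif(n) * w[k])
}

#' Simulate community evolution over serial passages
#'
#' Replicator dynamics with a multinomial bottleneck: per passage, phage
#' fitness is `w_i = 1 + c * sum_h matrix[i, h]`, abundances update
#' `x <- x * w / sum(x * w)` and are resampled multinomially at the
#' bottleneck size (a phage drawn zero times is extinct). New mutations per
#' phage arise as `Poisson(mu * L * x_i * bottleneck)` with positions placed
#' by [place_mutations()] (RBP bases weighted `rho`); a fraction of RBP
#' mutations is beneficial and follows logistic allele-frequency growth
#' `da = s * a * (1 - a)` per passage, all alleles drift by binomial
#' resampling at depth `Ne`. Short deletions occur at `indel_rate`. At the
#' sequencing passages, variant calls (AF >= `min_emit_af`), multinomial
#' read-coverage counts (the close pair mapped under a combined label), and
#' noisy diagnostic-site allele frequencies for the pair are recorded.
#'
#' @param genome_set a [generate_genomes()] result.
#' @param host_matrix phage-by-strain matrix with entries 0/1/2; defaults to
#'   [make_host_matrix()].
#' @param config a [sim_config()]; defaults to the one in `genome_set`.
#' @return an object of class `phage_evolution`: list with `variants` (all
#'   emitted calls incl. pair diagnostic sites on the reference member),
#'   `coverage` (mapped-read counts per sample with pair-combined label),
#'   and `truth` (abundance array, all arisen mutations with RBP/beneficial
#'   flags, per-sample true pair minor fraction, emitted diagnostic AFs,
#'   extinction records).
#' @export
simulate_evolution <- function(genome_set, host_matrix = NULL,
                               config = genome_set$config) {
  stopifnot(inherits(genome_set, "phage_genome_set"))
  ids <- names(genome_set$genomes)
  n <- length(ids)
  if (is.null(host_matrix)) host_matrix <- make_host_matrix(config, ids)
  stopifnot(nrow(host_matrix) == n)
  lens <- setNames(Biostrings::width(genome_set$genomes), ids)
  seqs <- setNames(as.character(genome_set$genomes), ids)
  rbp_iv <- lapply(ids, function(id) {
    f <- genome_set$features
    f <- f[f$genome_id == id & f$is_rbp, c("start", "end")]
    f
  })
  names(rbp_iv) <- ids
  pair <- genome_set$pair
  pair_label <- paste(pair, collapse = "+")
  w <- 1 + config$fitness_scale * rowSums(host_matrix)
  seqp <- config$sequencing_passages
  s <- config$sel_coeff
  Ne <- config$Ne

  empty_alleles <- data.frame(
    phage = character(0), pos = integer(0), ref = character(0),
    alt = character(0), vtype = character(0), af = numeric(0),
    beneficial = logical(0), origin_passage = integer(0), in_rbp = logical(0),
    stringsAsFactors = FALSE
  )

  abund <- array(NA_real_,
                 dim = c(config$n_lines, config$n_passages + 1L, n),
                 dimnames = list(paste0("L", seq_len(config$n_lines)),
                                 paste0("P", 0:config$n_passages), ids))
  all_variants <- list()
  all_coverage <- list()
  all_mutations <- list()
  all_diag <- list()
  pair_minor <- list()
  extinct <- list()

  snapshot <- function(alleles, line, passage, x) {
    rows <- list()
    keep <- alleles[alleles$af >= config$min_emit_af &
                      x[alleles$phage] > 0, , drop = FALSE]
    if (nrow(keep) > 0L) {
      rows$vc <- data.frame(
        genome_id = keep$phage, pos = keep$pos, ref = keep$ref, alt = keep$alt,
        vtype = keep$vtype, af = round(keep$af, 4),
        depth = as.integer(round(config$reads_per_sample * x[keep$phage])),
        line = line, passage = passage, stringsAsFactors = FALSE
      )
    }
    # pair diagnostic sites, reported on the reference member of the pair
    psum <- x[pair[1]] + x[pair[2]]
    if (psum > 0 && length(genome_set$diagnostic_sites) > 0L) {
      mf <- x[pair[2]] / psum
      afs <- rbinom(length(genome_set$diagnostic_sites), config$diag_depth, mf) /
        config$diag_depth
      sites <- genome_set$diagnostic_sites
      nonzero <- afs > 0
      if (any(nonzero)) {
        rows$diag <- data.frame(
          genome_id = pair[1], pos = sites[nonzero],
          ref = substring(seqs[[pair[1]]], sites[nonzero], sites[nonzero]),
          alt = substring(seqs[[pair[2]]], sites[nonzero], sites[nonzero]),
          vtype = "SNP", af = round(afs[nonzero], 4),
          depth = config$diag_depth, line = line, passage = passage,
          stringsAsFactors = FALSE
        )
      }
      list(vc = do.call(rbind, rows),
           diag = data.frame(line = line, passage = passage,
                             site = sites, af = afs),
           minor = data.frame(line = line, passage = passage,
                              minor_fraction = mf))
    } else {
      list(vc = do.call(rbind, rows), diag = NULL,
           minor = data.frame(line = line, passage = passage,
                              minor_fraction = NA_real_))
    }
  }

  for (line in seq_len(config$n_lines)) {
    with_seed(substream_seed(config$seed, paste0("line", line)), {
      x <- setNames(rep(1 / n, n), ids)
      alleles <- empty_alleles
      abund[line, 1L, ] <- x
      gone <- setNames(rep(NA_integer_, n), ids)

      emit <- function(passage) {
        sn <- snapshot(alleles, line, passage, x)
        if (!is.null(sn$vc)) all_variants[[length(all_variants) + 1L]] <<- sn$vc
        if (!is.null(sn$diag)) all_diag[[length(all_diag) + 1L]] <<- sn$diag
        pair_minor[[length(pair_minor) + 1L]] <<- sn$minor
        # coverage with the close pair under a combined label
        xc <- x[setdiff(ids, pair)]
        xc[pair_label] <- x[pair[1]] + x[pair[2]]
        reads <- rmultinom(1L, config$reads_per_sample, xc)[, 1]
        all_coverage[[length(all_coverage) + 1L]] <<- data.frame(
          line = line, passage = passage, phage = names(xc),
          mapped_reads = as.integer(reads), stringsAsFactors = FALSE
        )
      }

      if (0L %in% seqp) emit(0L)

      for (t in seq_len(config$n_passages)) {
        # selection + bottleneck
        xw <- x * w
        x <- xw / sum(xw)
        counts <- rmultinom(1L, config$bottleneck, x)[, 1]
        x <- setNames(counts / config$bottleneck, ids)
        newly_gone <- x == 0 & is.na(gone)
        gone[newly_gone] <- t
        # allele-frequency update
        if (nrow(alleles) > 0L) {
          a <- alleles$af
          a <- a + s * a * (1 - a) * alleles$beneficial
          a <- pmin(pmax(a, 0), 1)
          if (is.finite(Ne)) a <- rbinom(length(a), Ne, a) / Ne
          alleles$af <- a
          alleles <- alleles[alleles$af > 0 & x[alleles$phage] > 0, , drop = FALSE]
        }
        # new point mutations and occasional short deletions
        for (i in which(x > 0)) {
          id <- ids[i]
          m <- rpois(1L, config$mu * lens[id] * x[id] * config$bottleneck)
          if (m > 0L) {
            pos <- unique(place_mutations(m, lens[id], rbp_iv[[id]], config$rho))
            pos <- setdiff(pos, alleles$pos[alleles$phage == id])
            if (length(pos) > 0L) {
              refb <- substring(seqs[[id]], pos, pos)
              in_rbp <- positions_in_intervals(pos, rbp_iv[[id]])
              a0 <- if (is.finite(Ne)) 1 / Ne else 1 / config$bottleneck
              alleles <- rbind(alleles, data.frame(
                phage = id, pos = pos, ref = refb, alt = substitute_base(refb),
                vtype = "SNP", af = a0,
                beneficial = in_rbp & runif(length(pos)) < config$beneficial_frac,
                origin_passage = t, in_rbp = in_rbp, stringsAsFactors = FALSE
              ))
            }
          }
          if (runif(1) < config$indel_rate) {
            dlen <- sample(1:30, 1L)
            dpos <- sample.int(lens[id] - dlen - 1L, 1L)
            a0 <- if (is.finite(Ne)) 1 / Ne else 1 / config$bottleneck
            alleles <- rbind(alleles, data.frame(
              phage = id, pos = dpos,
              ref = substring(seqs[[id]], dpos, dpos + dlen),
              alt = substring(seqs[[id]], dpos, dpos),
              vtype = "DEL", af = a0, beneficial = FALSE,
              origin_passage = t, in_rbp = FALSE, stringsAsFactors = FALSE
            ))
          }
        }
        abund[line, t + 1L, ] <- x
        if (t %in% seqp) emit(t)
      }

      if (nrow(alleles) > 0L) {
        all_mutations[[length(all_mutations) + 1L]] <- cbind(line = line, alleles)
      }
      if (any(!is.na(gone))) {
        extinct[[length(extinct) + 1L]] <- data.frame(
          line = line, phage = ids[!is.na(gone)],
          passage_extinct = gone[!is.na(gone)], row.names = NULL
        )
      }
    })
  }

  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  variants <- bind(all_variants, data.frame(
    genome_id = character(0), pos = integer(0), ref = character(0),
    alt = character(0), vtype = character(0), af = numeric(0),
    depth = integer(0), line = integer(0), passage = integer(0)
  ))
  rownames(variants) <- NULL
  coverage <- do.call(rbind, all_coverage)
  rownames(coverage) <- NULL

  structure(list(
    variants = variants,
    coverage = coverage,
    pair = pair,
    pair_label = pair_label,
    host_matrix = host_matrix,
    truth = list(
      abundance = abund,
      mutations = bind(all_mutations, cbind(line = integer(0), empty_alleles)),
      pair_minor = do.call(rbind, pair_minor),
      diagnostic_afs = bind(all_diag, data.frame(line = integer(0),
                                                 passage = integer(0),
                                                 site = integer(0),
                                                 af = numeric(0))),
      extinctions = bind(extinct, data.frame(line = integer(0),
                                             phage = character(0),
                                             passage_extinct = integer(0)))
    ),
    config = config
  ), class = "phage_evolution")
}

#' @export
print.phage_evolution <- function(x, ...) {
  cat("Simulated phage-community evolution\n")
  cat(sprintf("  %d lines x %d passages, %d phages (pair %s)\n",
              x$config$n_lines, x$config$n_passages,
              dim(x$truth$abundance)[3], x$pair_label))
  cat(sprintf("  %d emitted variant calls across %d samples; %d extinctions\n",
              nrow(x$variants),
              length(unique(paste(x$coverage$line, x$coverage$passage))),
              nrow(x$truth$extinctions)))
  invisible(x)
}

#' Generate recombinant mosaics between two equal-length parents
#'
#' Each recombinant alternates parental segments at `k` sorted breakpoints
#' drawn uniformly with spacing (and end margins) of at least `min_gap`.
#' Optional noise: `noise_rate` plants random substitutions genome-wide;
#' `neither_noise` flips each parent-differing position to a third base with
#' the given probability (producing sites matching neither parent). Ground
#' truth records breakpoints, per-segment donors, and per-RBP donor fractions.
#'
#' @param parent_a,parent_b parent sequences (character or
#'   [Biostrings::DNAString]); must be equal length.
#' @param n number of recombinants.
#' @param k_breakpoints breakpoint counts to sample from (scalar or vector).
#' @param min_gap minimum spacing between breakpoints and from the ends.
#' @param features optional CDS data.frame in the parents' coordinate frame;
#'   rows with `is_rbp` get planted swap truth.
#' @param noise_rate expected substitutions per base planted on each mosaic.
#' @param neither_noise per informative-site probability of a third-base flip.
#' @param start_parent `"random"`, `"A"` or `"B"`: donor of the first segment.
#' @param seed integer seed.
#' @return an object of class `recombinant_set`: list with `recombinants`
#'   ([Biostrings::DNAStringSet]) and `truth` (`breakpoints`, `segments`,
#'   `rbp` data.frames).
#' @export
generate_recombinants <- function(parent_a, parent_b, n = 27L,
                                  k_breakpoints = 1:3, min_gap = 2000L,
                                  features = NULL, noise_rate = 0,
                                  neither_noise = 0,
                                  start_parent = c("random", "A", "B"),
                                  seed = 1L) {
  start_parent <- match.arg(start_parent)
  a <- toupper(as.character(parent_a))
  b <- toupper(as.character(parent_b))
  if (nchar(a) != nchar(b)) stop("parents must be equal length")
  L <- nchar(a)
  if (max(k_breakpoints) * min_gap >= L) {
    stop("infeasible: k * min_gap >= genome length (k = ",
         max(k_breakpoints), ", min_gap = ", min_gap, ", length = ", L, ")")
  }
  stopifnot(min(k_breakpoints) >= 1L, min_gap > 0L)
  a_chars <- strsplit(a, "", fixed = TRUE)[[1]]
  b_chars <- strsplit(b, "", fixed = TRUE)[[1]]
  diff_pos <- which(a_chars != b_chars)
  rbp_feats <- if (!is.null(features)) features[features$is_rbp, , drop = FALSE] else NULL

  with_seed(seed, {
    seqs <- character(n)
    bp_rows <- list()
    seg_rows <- list()
    rbp_rows <- list()
    rec_ids <- sprintf("rec%02d", seq_len(n))
    for (r in seq_len(n)) {
      k <- if (length(k_breakpoints) == 1L) k_breakpoints else sample(k_breakpoints, 1L)
      bp <- NULL
      for (try in seq_len(1000L)) {
        cand <- sort(sample.int(L - 1L, k))
        if (all(diff(c(0L, cand, L)) >= min_gap)) {
          bp <- cand
          break
        }
      }
      if (is.null(bp)) {
        stop("could not place ", k, " breakpoints with min_gap ", min_gap,
             " on length ", L)
      }
      first <- switch(start_parent, random = sample(c("A", "B"), 1L),
                      A = "A", B = "B")
      donors <- rep(c(first, setdiff(c("A", "B"), first)),
                    length.out = k + 1L)
      starts <- c(1L, bp + 1L)
      ends <- c(bp, L)
      chars <- a_chars
      for (j in which(donors == "B")) {
        chars[starts[j]:ends[j]] <- b_chars[starts[j]:ends[j]]
      }
      if (noise_rate > 0) {
        m <- rpois(1L, noise_rate * L)
        if (m > 0L) {
          npos <- sample.int(L, min(m, L))
          chars[npos] <- substitute_base(chars[npos])
        }
      }
      if (neither_noise > 0 && length(diff_pos) > 0L) {
        flip <- diff_pos[runif(length(diff_pos)) < neither_noise]
        for (p in flip) {
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                     c(a_chars[p], b_chars[p])), 1L)
        }
      }
      seqs[r] <- paste(chars, collapse = "")
      bp_rows[[r]] <- data.frame(rec_id = rec_ids[r], breakpoint = bp)
      seg_rows[[r]] <- data.frame(rec_id = rec_ids[r], start = starts,
                                  end = ends, donor = donors)
      if (!is.null(rbp_feats) && nrow(rbp_feats) > 0L) {
        span_a <- sum((ends - starts + 1L)[donors == "A"])
        major <- if (span_a >= L - span_a) "A" else "B"
        frac_minor <- vapply(seq_len(nrow(rbp_feats)), function(fi) {
          fs <- rbp_feats$start[fi]
          fe <- rbp_feats$end[fi]
          ov <- pmax(0L, pmin(ends, fe) - pmax(starts, fs) + 1L)
          sum(ov[donors != major]) / (fe - fs + 1L)
        }, numeric(1))
        rbp_rows[[r]] <- data.frame(
          rec_id = rec_ids[r], feature_id = rbp_feats$feature_id,
          major_parent = major, minor_overlap = frac_minor,
          swapped = frac_minor >= 0.5, stringsAsFactors = FALSE
        )
      }
    }
    recs <- Biostrings::DNAStringSet(seqs)
    names(recs) <- rec_ids
    structure(list(
      recombinants = recs,
      parents = c(A = a, B = b),
      truth = list(
        breakpoints = do.call(rbind, bp_rows),
        segments = do.call(rbind, seg_rows),
        rbp = if (length(rbp_rows)) do.call(rbind, rbp_rows) else NULL
      )
    ), class = "recombinant_set")
  })
}

#' Generate spot-test and titer tables from a host matrix
#'
#' Per phage-strain pair: true titer is `inoculum_titer` for susceptible
#' strains (score 2), 1% of it for partial susceptibility (score 1) and 0
#' for resistant strains. Observed titers are lognormal around the true
#' value and written as the `ND` sentinel below `detection_limit`. Spot
#' replicate outcomes are drawn with plaque probability increasing with true
#' infectivity; zero infectivity always yields `NONE`.
#'
#' @param host_matrix phage-by-strain 0/1/2 matrix.
#' @param config a [sim_config()] (detection limit, inoculum, seed).
#' @param replicates spot/titer replicates per pair.
#' @return list with `spots` and `titers` data.frames (schemas of
#'   [read_table()]).
#' @export
generate_assays <- function(host_matrix, config, replicates = 2L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "assays"), {
    phages <- rownames(host_matrix) %||% phage_ids(nrow(host_matrix))
    strains <- colnames(host_matrix) %||% sprintf("K%02d", seq_len(ncol(host_matrix)))
    spot_rows <- list()
    titer_rows <- list()
    for (i in seq_along(phages)) {
      for (j in seq_along(strains)) {
        score <- host_matrix[i, j]
        true_titer <- c(0, config$inoculum_titer / 100, config$inoculum_titer)[score + 1L]
        for (r in seq_len(replicates)) {
          if (true_titer == 0) {
            obs <- 0
            outcome <- "NONE"
          } else {
            obs <- rlnorm(1L, meanlog = log(true_titer), sdlog = 0.3)
            p <- c(0, 0.35, 0.97)[score + 1L]
            u <- runif(1)
            outcome <- if (u < p) "PLAQUES" else if (u < p + c(0, 0.45, 0.03)[score + 1L])
              "TURBID_FIRST_ONLY" else "NONE"
          }
          lim <- if (outcome == "PLAQUES") {
            -as.integer(pmin(6, pmax(0, floor(log10(pmax(obs, 1) / config$detection_limit)))))
          } else NA_integer_
          spot_rows[[length(spot_rows) + 1L]] <- data.frame(
            phage = phages[i], strain = strains[j], replicate = r,
            outcome = outcome, limiting_dilution = lim, stringsAsFactors = FALSE
          )
          below <- obs < config$detection_limit
          titer_rows[[length(titer_rows) + 1L]] <- data.frame(
            phage = phages[i], strain = strains[j], replicate = r,
            titer = ifelse(below, NA_real_, obs), below_detection = below,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    list(spots = do.call(rbind, spot_rows), titers = do.call(rbind, titer_rows))
  })
}

#' Run the full synthetic experiment
#'
#' Convenience orchestrator: genomes, host matrix, evolution, assays, and
#' recombinants between the close pair, all from one configuration.
#'
#' @param config a [sim_config()].
#' @return list of class `phage_experiment` with components `genome_set`,
#'   `host_matrix`, `evolution`, `assays` and `recombinants`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  gs <- generate_genomes(config)
  hm <- make_host_matrix(config, names(gs$genomes))
  ev <- simulate_evolution(gs, hm, config)
  as <- generate_assays(hm, config)
  pair_feats <- gs$features[gs$features$genome_id == gs$pair[1], , drop = FALSE]
  rec <- generate_recombinants(
    as.character(gs$genomes[[gs$pair[1]]]),
    as.character(gs$genomes[[gs$pair[2]]]),
    n = config$n_recombinants, k_breakpoints = config$k_breakpoints,
    min_gap = config$min_gap, features = pair_feats,
    seed = substream_seed(config$seed, "recombinants")
  )
  structure(list(genome_set = gs, host_matrix = hm, evolution = ev,
                 assays = as, recombinants = rec, config = config),
            class = "phage_experiment")
}

#' Write a synthetic experiment to disk
#'
#' Emits `genomes.fasta`, `annotations.gff3`, per-sample
#' `L{line}_P{passage}.vcf`, `coverage.tsv`, `spots.tsv`, `titers.tsv`,
#' `recombinants.fasta` (pre-aligned: parents and mosaics are equal length)
#' and `truth.json`.
#'
#' @param experiment a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(experiment, dir) {
  stopifnot(inherits(experiment, "phage_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gs <- experiment$genome_set
  ev <- experiment$evolution
  write_genomes(gs$genomes, file.path(dir, "genomes.fasta"))
  write_annotations(gs$features, file.path(dir, "annotations.gff3"))
  samples <- unique(ev$coverage[, c("line", "passage")])
  for (i in seq_len(nrow(samples))) {
    li <- samples$line[i]
    pa <- samples$passage[i]
    v <- ev$variants[ev$variants$line == li & ev$variants$passage == pa, , drop = FALSE]
    write_variants(v, file.path(dir, sprintf("L%d_P%d.vcf", li, pa)),
                   line = li, passage = pa)
  }
  write_tsv(ev$coverage, file.path(dir, "coverage.tsv"))
  write_tsv(experiment$assays$spots, file.path(dir, "spots.tsv"))
  write_tsv(experiment$assays$titers, file.path(dir, "titers.tsv"))
  aln <- c(Biostrings::DNAStringSet(experiment$recombinants$parents),
           experiment$recombinants$recombinants)
  names(aln)[1:2] <- paste0(c("parentA|", "parentB|"), gs$pair)
  names(aln)[-(1:2)] <- paste0("recombinant|", names(experiment$recombinants$recombinants))
  Biostrings::writeXStringSet(aln, file.path(dir, "recombinants.fasta"))
  truth <- list(
    pair = gs$pair,
    diagnostic_sites = gs$diagnostic_sites,
    abundance = ev$truth$abundance,
    pair_minor = ev$truth$pair_minor,
    extinctions = ev$truth$extinctions,
    mutations = ev$truth$mutations,
    recombinant_breakpoints = experiment$recombinants$truth$breakpoints,
    recombinant_rbp = experiment$recombinants$truth$rbp
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
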