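# Community composition from mapped-read shares, with diagnostic-site
# deconvolution of closely related phage pairs whose reads co-map.

#' Minor-member fraction of a close phage pair from diagnostic-site AFs
#'
#' The relative proportion of the minor pair member among the pair's
#' co-mapped reads is the arithmetic mean of the allele frequencies observed
#' at the diagnostic sites (positions where the two pair members differ).
#'
#' @param diagnostic_afs numeric vector of allele frequencies in `[0, 1]`.
#' @return the mean frequency.
#' @export
#' @examples
#' minor_fraction(c(0.18, 0.22, 0.20))
minor_fraction <- function(diagnostic_afs) {
  if (length(diagnostic_afs) == 0L) {
    stop("no diagnostic sites: cannot estimate the pair's minor fraction")
  }
  if (any(is.na(diagnostic_afs)) || any(diagnostic_afs < 0 | diagnostic_afs > 1)) {
    stop("diagnostic allele frequencies must lie in [0, 1]")
  }
  mean(diagnostic_afs)
}

#' Extract diagnostic-site allele frequencies from variant calls
#'
#' Pulls the AFs at the pair's diagnostic positions from a sample's variant
#' table (mapped against the pair's reference member). Sites absent from the
#' calls count as AF = 0 when covered; uncovered sites are dropped rather
#' than deflating the mean.
#'
#' @param variants variant data.frame ([read_variants()]).
#' @param genome_id reference member of the pair.
#' @param sites integer vector of diagnostic positions.
#' @param covered logical vector (recycled) marking sites with read coverage.
#' @return numeric vector of AFs, one per retained site.
#' @export
extract_diagnostic_afs <- function(variants, genome_id, sites, covered = TRUE) {
  covered <- rep_len(covered, length(sites))
  v <- variants[variants$genome_id == genome_id & variants$pos %in% sites, , drop = FALSE]
  af <- setNames(rep(0, length(sites)), as.character(sites))
  if (nrow(v) > 0L) {
    agg <- tapply(v$af, as.character(v$pos), max)
    af[names(agg)] <- agg
  }
  keep <- covered | af > 0
  unname(af[keep])
}

#' Deconvolve co-mapped reads of a close phage pair
#'
#' When the minor fraction (mean diagnostic-site AF) is below
#' `split_threshold` (a 20/80 depth-ratio regime), the pair's co-mapped reads
#' are apportioned: minor reads = round(minor fraction x pair reads)
#' (round-half-to-even), major takes the remainder, so conservation is exact.
#' At or above the threshold (approaching 50-50) the correction is not
#' applicable and the pair stays under a combined label.
#'
#' @param pair_reads total reads co-mapped to the pair.
#' @param diagnostic_afs allele frequencies at diagnostic sites.
#' @param split_threshold strict upper bound for the SPLIT regime
#'   (default 0.2).
#' @param pair optional character(2): major and minor member ids.
#' @param sample optional `list(line =, passage =)` identity.
#' @return an object of class `pair_deconvolution` with `mode`
#'   (`"SPLIT"`/`"COMBINED"`), `minor_fraction`, and (for SPLIT)
#'   `minor_reads`/`major_reads`.
#' @export
deconvolve_pair <- function(pair_reads, diagnostic_afs, split_threshold = 0.2,
                            pair = c("major", "minor"), sample = NULL) {
  stopifnot(pair_reads >= 0, length(pair) == 2L)
  mf <- minor_fraction(diagnostic_afs)
  if (mf < split_threshold) {
    minor <- round(mf * pair_reads)
    out <- list(pair = pair, sample = sample, diagnostic_afs = diagnostic_afs,
                minor_fraction = mf, mode = "SPLIT",
                minor_reads = minor, major_reads = pair_reads - minor,
                pair_reads = pair_reads)
  } else {
    out <- list(pair = pair, sample = sample, diagnostic_afs = diagnostic_afs,
                minor_fraction = mf, mode = "COMBINED",
                minor_reads = NA_real_, major_reads = NA_real_,
                pair_reads = pair_reads)
  }
  structure(out, class = "pair_deconvolution")
}

#' @export
print.pair_deconvolution <- function(x, ...) {
  cat(sprintf("Pair deconvolution [%s/%s]: minor fraction %.4f over %d sites -> %s\n",
              x$pair[1], x$pair[2], x$minor_fraction,
              length(x$diagnostic_afs), x$mode))
  if (x$mode == "SPLIT") {
    cat(sprintf("  reads: %g major + %g minor (of %g)\n",
                x$major_reads, x$minor_reads, x$pair_reads))
  }
  invisible(x)
}

#' Relative phage abundances per sample from mapped-read counts
#'
#' Normalises per-sample mapped reads to relative abundances after applying
#' any SPLIT pair deconvolutions (the combined-pair row is replaced by the
#' two members with apportioned reads; COMBINED pairs keep their joint
#' label). Abundances below `low_threshold` (default 0.2%) are flagged.
#'
#' @param coverage data.frame with `line`, `passage`, `phage`,
#'   `mapped_reads` ([read_table()] coverage schema).
#' @param deconvolutions list of [deconvolve_pair()] results carrying
#'   `sample` identities.
#' @param low_threshold low-abundance display threshold.
#' @return a data.frame (class `abundance_table`) with `line`, `passage`,
#'   `phage`, `mapped_reads`, `abundance`, `low_abundance`; abundances sum
#'   to 1 per sample.
#' @export
abundance_table <- function(coverage, deconvolutions = list(), low_threshold = 0.002) {
  cov <- coverage[, c("line", "passage", "phage", "mapped_reads")]
  for (d in deconvolutions) {
    stopifnot(inherits(d, "pair_deconvolution"))
    if (d$mode != "SPLIT") next
    if (is.null(d$sample)) stop("deconvolution lacks sample identity")
    label <- paste(d$pair, collapse = "+")
    hit <- cov$line == d$sample$line & cov$passage == d$sample$passage &
      cov$phage == label
    if (!any(hit)) {
      stop("no coverage row '", label, "' for sample L", d$sample$line,
           "_P", d$sample$passage)
    }
    reads <- cov$mapped_reads[hit][1]
    minor <- round(d$minor_fraction * reads)
    cov <- rbind(cov[!hit, ],
                 data.frame(line = d$sample$line, passage = d$sample$passage,
                            phage = d$pair,
                            mapped_reads = c(reads - minor, minor)))
  }
  key <- paste(cov$line, cov$passage, sep = "_")
  totals <- tapply(cov$mapped_reads, key, sum)
  if (any(totals == 0)) {
    stop("sample(s) with zero total mapped reads: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  }
  cov$abundance <- cov$mapped_reads / as.numeric(totals[key])
  cov$low_abundance <- cov$abundance < low_threshold
  cov <- cov[order(cov$line, cov$passage, cov$phage), ]
  rownames(cov) <- NULL
  class(cov) <- c("abundance_table", "data.frame")
  cov
}

#' Phages absent at the final passage, per evolution line
#'
#' @param table an [abundance_table()].
#' @param threshold abundance at or below which a phage counts as absent
#'   (default 0: truly extinct; 0.002 also reports dot-level phages).
#' @param passage the final passage (defaults to the largest in the table).
#' @return data.frame with `line`, `phage`, `final_abundance` for each
#'   phage (seen anywhere in that line) at or below the threshold at the
#'   final passage; zero rows if none.
#' @export
extinction_report <- function(table, threshold = 0, passage = max(table$passage)) {
  out <- list()
  for (li in sort(unique(table$line))) {
    seen <- unique(table$phage[table$line == li])
    fin <- table[table$line == li & table$passage == passage, , drop = FALSE]
    final_ab <- setNames(rep(0, length(seen)), seen)
    final_ab[fin$phage] <- fin$abundance
    gone <- final_ab <= threshold
    if (any(gone)) {
      out[[length(out) + 1L]] <- data.frame(
        line = li, phage = names(final_ab)[gone],
        final_abundance = unname(final_ab[gone]), stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(line = integer(0), phage = character(0),
                      final_abundance = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
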