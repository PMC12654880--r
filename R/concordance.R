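# Concordance between community variant calling and whole-genome alignment
# of isolated variants at designated (e.g. positively selected) positions,
# with Fisher's exact test on the resulting 2x2 table.

#' Detection opportunities at designated positions, per sample
#'
#' For each (position, sample): `by_vc` is TRUE iff the sample's variant
#' calls carry a variant at the position with allele frequency strictly
#' above `af_threshold`; `by_wga` is TRUE iff at least one isolated variant
#' genome from the sample carries a non-reference allele there.
#'
#' @param sites integer positions (one genome) or data.frame with
#'   `genome_id`, `pos`.
#' @param vc_variants community variant calls ([read_variants()]).
#' @param wga_variants alignment-derived variant table
#'   ([read_table()] `alignment_variant` schema: one row per isolate
#'   carrying a non-reference allele).
#' @param samples data.frame of `line`, `passage` combinations to evaluate;
#'   defaults to those present in `wga_variants`.
#' @param af_threshold strict lower AF bound for variant-calling detection
#'   (default 0.2).
#' @return data.frame with `genome_id`, `pos`, `line`, `passage`, `by_vc`,
#'   `by_wga`.
#' @export
detect_opportunities <- function(sites, vc_variants, wga_variants,
                                 samples = unique(wga_variants[, c("line", "passage")]),
                                 af_threshold = 0.2) {
  if (!is.data.frame(sites)) {
    gid <- unique(c(vc_variants$genome_id, wga_variants$genome_id))
    if (length(gid) > 1L) stop("bare positions are ambiguous across genomes; pass a data.frame")
    sites <- data.frame(genome_id = gid, pos = as.integer(sites))
  }
  if (nrow(sites) == 0L) stop("no designated sites supplied")
  out <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(samples))) {
      g <- sites$genome_id[i]
      p <- sites$pos[i]
      li <- samples$line[j]
      pa <- samples$passage[j]
      by_vc <- any(vc_variants$genome_id == g & vc_variants$pos == p &
                     vc_variants$line == li & vc_variants$passage == pa &
                     vc_variants$af > af_threshold)
      by_wga <- any(wga_variants$genome_id == g & wga_variants$pos == p &
                      wga_variants$line == li & wga_variants$passage == pa)
      out[[length(out) + 1L]] <- data.frame(
        genome_id = g, pos = p, line = li, passage = pa,
        by_vc = by_vc, by_wga = by_wga, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Tally detection opportunities into a concordance table
#'
#' @param opportunities a [detect_opportunities()] data.frame.
#' @return an object of class `concordance_table` with counts `both`,
#'   `vc_only`, `wga_only`, `neither`.
#' @export
build_table <- function(opportunities) {
  stopifnot(nrow(opportunities) >= 1L)
  structure(list(
    both = sum(opportunities$by_vc & opportunities$by_wga),
    vc_only = sum(opportunities$by_vc & !opportunities$by_wga),
    wga_only = sum(!opportunities$by_vc & opportunities$by_wga),
    neither = sum(!opportunities$by_vc & !opportunities$by_wga)
  ), class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("Detection concordance: both %d, VC-only %d, WGA-only %d, neither %d\n",
              x$both, x$vc_only, x$wga_only, x$neither))
  invisible(x)
}

# Two-sided Fisher p by hypergeometric enumeration, minimum-likelihood
# convention (sum of table probabilities <= the observed one).
hypergeom_p <- function(m, alternative = "two.sided") {
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  n <- sum(m)
  if (r1 == 0L || r1 == n || c1 == 0L || c1 == n) return(1)
  lo <- max(0L, c1 - (n - r1))
  hi <- min(r1, c1)
  x <- m[1, 1]
  d <- dhyper(lo:hi, c1, n - c1, r1)
  obs <- dhyper(x, c1, n - c1, r1)
  switch(alternative,
    two.sided = min(1, sum(d[d <= obs * (1 + 1e-7)])),
    greater = sum(d[(lo:hi) >= x]),
    less = sum(d[(lo:hi) <= x])
  )
}

#' Fisher's exact test on a detection-concordance table
#'
#' Two 2x2 layouts are available. `"method_by_outcome"` (default) treats
#' each method as a row of detected/missed counts over the opportunities at
#' which at least the other method looked:
#' `[[both + vc_only, wga_only], [both + wga_only, vc_only]]` -- the layout
#' under which exact enumeration reproduces the reference tallies'
#' published p-value. `"detection_2x2"` cross-classifies opportunities:
#' `[[both, wga_only], [vc_only, neither]]`. The p-value is computed by
#' hypergeometric enumeration (two-sided: minimum-likelihood convention);
#' the sample odds ratio is reported.
#'
#' @param x a [build_table()] result, a named vector/list with `both`,
#'   `vc_only`, `wga_only` (and optionally `neither`), or a 2x2 matrix
#'   (used as-is, `construction` ignored).
#' @param construction 2x2 layout, see Details.
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`.
#' @return an object of classes `fisher_concordance` and `htest` with
#'   `p.value`, the sample odds ratio as `estimate`, and the table used.
#' @export
#' @examples
#' fisher_exact(list(both = 10, wga_only = 3, vc_only = 1))  # p = 0.596
fisher_exact <- function(x, construction = c("method_by_outcome", "detection_2x2"),
                         alternative = c("two.sided", "greater", "less")) {
  construction <- match.arg(construction)
  alternative <- match.arg(alternative)
  if (is.matrix(x)) {
    m <- x
    construction <- "as_given"
  } else {
    getv <- function(nm, default = NULL) {
      v <- if (nm %in% names(x)) x[[nm]] else default
      if (is.null(v)) stop("missing count '", nm, "'")
      v
    }
    both <- getv("both")
    vc_only <- getv("vc_only")
    wga_only <- getv("wga_only")
    neither <- getv("neither", 0)
    m <- switch(construction,
      method_by_outcome = matrix(c(both + vc_only, wga_only,
                                   both + wga_only, vc_only),
                                 2L, 2L, byrow = TRUE,
                                 dimnames = list(c("VC", "WGA"),
                                                 c("detected", "missed"))),
      detection_2x2 = matrix(c(both, wga_only, vc_only, neither),
                             2L, 2L, byrow = TRUE,
                             dimnames = list(c("VC+", "VC-"),
                                             c("WGA+", "WGA-")))
    )
  }
  stopifnot(all(dim(m) == 2L), all(m >= 0))
  p <- hypergeom_p(m, alternative)
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  if (is.nan(or)) or <- NA_real_
  zero_margin <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  if (zero_margin) or <- NA_real_
  structure(list(
    statistic = NULL,
    p.value = p,
    estimate = c(`odds ratio` = or),
    table = m,
    construction = construction,
    alternative = alternative,
    method = "Fisher's exact test (hypergeometric enumeration)",
    data.name = paste(deparse(substitute(x)), collapse = "")
  ), class = c("fisher_concordance", "htest"))
}

#' @export
print.fisher_concordance <- function(x, ...) {
  cat(x$method, "\n")
  cat("  construction:", x$construction, "\n")
  print(x$table)
  cat(sprintf("  p-value = %.4g (%s), odds ratio = %s\n", x$p.value,
              x$alternative,
              ifelse(is.na(x$estimate), "NA", sprintf("%.4g", x$estimate))))
  invisible(x)
}
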