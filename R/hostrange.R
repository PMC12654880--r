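# Spot-test consensus scoring, efficiency of plating (EOP) with
# detection-limit substitution, delta-log10 EOP, host-range classification,
# and the titer growth-increment statistic.

#' Consensus score for one phage-strain interaction from replicate spots
#'
#' Replicate outcomes are `PLAQUES` (single plaques at some dilution),
#' `TURBID_FIRST_ONLY` (turbid spot only at the 10^-1 dilution, ambiguous)
#' or `NONE`. Plaques in every replicate score 2; no spot in any replicate
#' scores 0; any inconsistency or ambiguity scores 1. With only two
#' replicates an inconsistent/ambiguous result is scored 1 provisionally and
#' flagged `needs_third`.
#'
#' @param outcomes character vector of 2 or 3 replicate outcomes.
#' @return an object of class `interaction_score` with `score` (0/1/2),
#'   `n_replicates` and `needs_third`.
#' @export
#' @examples
#' score_interaction(c("PLAQUES", "PLAQUES"))
#' score_interaction(c("PLAQUES", "TURBID_FIRST_ONLY", "NONE"))
score_interaction <- function(outcomes) {
  ok <- c("PLAQUES", "TURBID_FIRST_ONLY", "NONE")
  if (length(outcomes) < 2L) {
    stop("at least 2 replicates are required (got ", length(outcomes), ")")
  }
  if (length(outcomes) > 3L) stop("at most 3 replicates are expected")
  if (!all(outcomes %in% ok)) {
    stop("unknown outcome(s): ", paste(setdiff(outcomes, ok), collapse = ", "))
  }
  score <- if (all(outcomes == "PLAQUES")) 2L
           else if (all(outcomes == "NONE")) 0L
           else 1L
  structure(list(
    score = score,
    n_replicates = length(outcomes),
    needs_third = length(outcomes) == 2L && score == 1L
  ), class = "interaction_score")
}

#' @export
print.interaction_score <- function(x, ...) {
  cat(sprintf("Interaction score %d (%d replicates%s)\n", x$score,
              x$n_replicates, if (x$needs_third) ", third replicate needed" else ""))
  invisible(x)
}

#' Score matrix (strains x phages) from a spot-test table
#'
#' Applies [score_interaction()] to every phage-strain group of a spots
#' table.
#'
#' @param spots data.frame with `phage`, `strain`, `replicate`, `outcome`
#'   ([read_table()] spots schema).
#' @return an integer matrix, strains in rows, phages in columns.
#' @export
score_matrix <- function(spots) {
  phages <- sort(unique(spots$phage))
  strains <- sort(unique(spots$strain))
  m <- matrix(NA_integer_, length(strains), length(phages),
              dimnames = list(strains, phages))
  for (p in phages) {
    for (s in strains) {
      o <- spots$outcome[spots$phage == p & spots$strain == s]
      if (length(o) >= 2L) m[s, p] <- score_interaction(o)$score
    }
  }
  m
}

titer_values <- function(x) {
  # accept a titer data.frame (titer + below_detection) or a numeric vector
  # with NA meaning below detection
  if (is.data.frame(x)) {
    if (!is.null(x$replicate)) x <- x[order(x$replicate), , drop = FALSE]
    list(titer = x$titer,
         below = if (!is.null(x$below_detection)) x$below_detection else is.na(x$titer))
  } else {
    list(titer = as.numeric(x), below = is.na(x))
  }
}

#' Efficiency of plating with detection-limit substitution
#'
#' EOP is (titer on the evaluated strain) / (titer on the ancestor's
#' isolation strain). Below-detection titers are replaced by the detection
#' limit (default 10^2 PFU/mL) so the ratio stays computable; such records
#' are flagged `at_detection_floor`. Ratios are computed per paired
#' replicate and averaged (mean of ratios); the ratio of means is also
#' reported.
#'
#' @param titers_eval,titers_ref replicate titers on the evaluated and
#'   reference strain: data.frames with `titer`/`below_detection` (titers
#'   schema of [read_table()]) or numeric vectors with `NA` = below
#'   detection.
#' @param detection_limit substitute for below-detection titers (PFU/mL).
#' @return an object of class `eop_record` with `eop` (mean of replicate
#'   ratios), `log10_eop`, `eop_ratio_of_means`, `at_detection_floor`, and
#'   optional `phage`/`strain` labels.
#' @param phage,strain optional labels carried through.
#' @export
#' @examples
#' compute_eop(1e6, 1e9)                  # EOP 1e-3
#' compute_eop(NA, 1e9)                   # ND -> 1e2; EOP 1e-7, floor flag
compute_eop <- function(titers_eval, titers_ref, detection_limit = 1e2,
                        phage = NA_character_, strain = NA_character_) {
  ev <- titer_values(titers_eval)
  rf <- titer_values(titers_ref)
  if (length(ev$titer) < 1L || length(rf$titer) < 1L) {
    stop("at least one replicate is required on each side")
  }
  if (any(rf$titer == 0 & !rf$below, na.rm = TRUE)) {
    stop("reference titer of 0 not marked below detection")
  }
  if (any(ev$titer == 0 & !ev$below, na.rm = TRUE)) {
    stop("evaluated titer of 0 not marked below detection")
  }
  ev_t <- ifelse(ev$below, detection_limit, ev$titer)
  rf_t <- ifelse(rf$below, detection_limit, rf$titer)
  m <- min(length(ev_t), length(rf_t))
  ratios <- ev_t[seq_len(m)] / rf_t[seq_len(m)]
  eop <- mean(ratios)
  structure(list(
    phage = phage, strain = strain,
    eop = eop, log10_eop = log10(eop),
    eop_ratio_of_means = mean(ev_t) / mean(rf_t),
    replicate_ratios = ratios,
    at_detection_floor = any(ev$below[seq_len(m)]) || any(rf$below[seq_len(m)]),
    detection_limit = detection_limit
  ), class = "eop_record")
}

#' @export
print.eop_record <- function(x, ...) {
  cat(sprintf("EOP %.4g (log10 %.3f)%s\n", x$eop, x$log10_eop,
              if (x$at_detection_floor) " [detection floor used]" else ""))
  invisible(x)
}

#' Difference in log10 EOP between an evolved variant and its ancestor
#'
#' `delta = log10(EOP_variant) - log10(EOP_ancestor)`, on the same strain.
#' Deltas of at least `improvement_threshold` (default +1.7 log10 units)
#' are flagged as improved infectivity; deltas involving a detection-floor
#' EOP on either side are flagged floor-censored.
#'
#' @param variant,ancestor [compute_eop()] records for the same strain.
#' @param improvement_threshold reporting threshold in log10 units.
#' @return an object of class `delta_eop` with `delta`, `improved`,
#'   `floor_censored`.
#' @export
delta_log_eop <- function(variant, ancestor, improvement_threshold = 1.7) {
  stopifnot(inherits(variant, "eop_record"), inherits(ancestor, "eop_record"))
  if (!is.na(variant$strain) && !is.na(ancestor$strain) &&
      variant$strain != ancestor$strain) {
    stop("strain mismatch: '", variant$strain, "' vs '", ancestor$strain, "'")
  }
  delta <- variant$log10_eop - ancestor$log10_eop
  structure(list(
    strain = variant$strain,
    delta = delta,
    improved = delta >= improvement_threshold,
    floor_censored = variant$at_detection_floor || ancestor$at_detection_floor
  ), class = "delta_eop")
}

#' @export
print.delta_eop <- function(x, ...) {
  cat(sprintf("delta log10(EOP) = %+.3f%s%s\n", x$delta,
              if (x$improved) " [improved]" else "",
              if (x$floor_censored) " [floor-censored]" else ""))
  invisible(x)
}

#' Classify a phage as specialist, generalist or host-less
#'
#' A phage is a specialist if it productively infects (score 2) exactly one
#' strain of the community, a generalist if two or more. Partial
#' susceptibility (score 1) does not count as productive infection. Phages
#' with no score-2 strain are reported distinctly as `no_host`.
#'
#' @param scores numeric/integer vector of 0/1/2 interaction scores over the
#'   community strains.
#' @return one of `"specialist"`, `"generalist"`, `"no_host"`.
#' @export
#' @examples
#' classify_host_range(c(2, 1, 1, 1))  # specialist
#' classify_host_range(c(2, 2, 2, 2, 2, 2))  # generalist
classify_host_range <- function(scores) {
  stopifnot(all(scores %in% 0:2))
  n2 <- sum(scores == 2)
  if (n2 == 0L) "no_host" else if (n2 == 1L) "specialist" else "generalist"
}

#' Titer growth increment over an assay interval
#'
#' `delta = log10(initial titer) - log10(final titer)`; the sign convention
#' is initial minus final, so productive growth yields negative values.
#'
#' @param titer_initial,titer_final titers in PFU/mL, both > 0.
#' @return the increment in log10 units.
#' @export
#' @examples
#' growth_delta(1e4, 1e8)  # -4: the phage grew four orders of magnitude
growth_delta <- function(titer_initial, titer_final) {
  if (any(c(titer_initial, titer_final) <= 0)) {
    stop("titers must be positive to take logarithms")
  }
  log10(titer_initial) - log10(titer_final)
}
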