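# Parental painting of recombinant genomes: informative sites between two
# aligned parents, run-based segment assignment with noise absorption,
# breakpoint uncertainty intervals, RBP swap calls, and consensus
# minor-parent regions across variants. Alignment columns are 1-based.

#' Informative sites of a parent/parent/recombinant alignment
#'
#' Columns where the two parents differ and neither has a gap; the
#' recombinant's local ancestry signal. The recombinant matches parent A,
#' parent B, or `NEITHER` (a private mutation or a gap).
#'
#' @param aligned_parent_a,aligned_parent_b,aligned_recombinant equal-length
#'   aligned sequences (character; gaps as `-`).
#' @return data.frame with `aln_col`, `allele_a`, `allele_b`, `match`;
#'   the alignment length is attached as attribute `aln_length`.
#' @export
informative_sites <- function(aligned_parent_a, aligned_parent_b,
                              aligned_recombinant) {
  a <- strsplit(toupper(as.character(aligned_parent_a)), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(as.character(aligned_parent_b)), "", fixed = TRUE)[[1]]
  r <- strsplit(toupper(as.character(aligned_recombinant)), "", fixed = TRUE)[[1]]
  if (length(a) != length(b) || length(a) != length(r)) {
    stop("aligned sequences must be equal length (",
         length(a), "/", length(b), "/", length(r), ")")
  }
  keep <- a != b & a != "-" & b != "-"
  cols <- which(keep)
  match <- ifelse(r[keep] == a[keep], "A",
                  ifelse(r[keep] == b[keep], "B", "NEITHER"))
  out <- data.frame(aln_col = cols, allele_a = a[keep], allele_b = b[keep],
                    match = match, stringsAsFactors = FALSE)
  attr(out, "aln_length") <- length(a)
  out
}

#' Paint a recombinant against its parents from informative-site runs
#'
#' `NEITHER` sites (de novo mutations) are ignored; maximal runs of
#' same-parent matches become candidate segments. Candidate runs shorter
#' than `min_run` are treated as noise and absorbed into their flanking
#' segments (an interior short run sits between two segments of the other
#' parent and takes their label; a terminal short run merges into its single
#' neighbour). Each breakpoint is reported as the open interval between the
#' bounding informative sites -- the true crossover between them is
#' unobservable -- with the interval midpoint as point estimate.
#'
#' @param sites an [informative_sites()] data.frame.
#' @param min_run minimum informative-site run supporting a segment.
#' @return an object of class `recomb_report`: `segments` (`parent`,
#'   `start_col`, `end_col`, `n_sites`), `breakpoints` (`left_col`,
#'   `right_col`, `midpoint`), `major_parent`, `minor_fraction` (painted
#'   span from the minor parent), `unassigned_sites` (`NEITHER` count).
#' @export
paint <- function(sites, min_run = 3L) {
  keep <- sites$match != "NEITHER"
  if (!any(keep)) {
    stop("unpaintable: every informative site matches neither parent")
  }
  cols <- sites$aln_col[keep]
  lab <- sites$match[keep]
  r <- rle(lab)
  # absorb sub-min_run runs, shortest first
  while (length(r$lengths) > 1L && any(r$lengths < min_run)) {
    i <- which(r$lengths < min_run)
    i <- i[which.min(r$lengths[i])]
    if (i == 1L) {
      r$values[i] <- r$values[i + 1L]
    } else if (i == length(r$lengths)) {
      r$values[i] <- r$values[i - 1L]
    } else {
      r$values[i] <- r$values[i - 1L]  # flanks share the other parent's label
    }
    lab <- inverse.rle(r)
    r <- rle(lab)
  }
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1L, head(ends_idx, -1L) + 1L)
  segments <- data.frame(
    parent = r$values,
    start_col = cols[starts_idx],
    end_col = cols[ends_idx],
    n_sites = r$lengths,
    stringsAsFactors = FALSE
  )
  nseg <- nrow(segments)
  breakpoints <- if (nseg > 1L) {
    data.frame(left_col = segments$end_col[-nseg],
               right_col = segments$start_col[-1L])
  } else {
    data.frame(left_col = integer(0), right_col = integer(0))
  }
  breakpoints$midpoint <- (breakpoints$left_col + breakpoints$right_col) / 2
  span <- segments$end_col - segments$start_col + 1L
  span_a <- sum(span[segments$parent == "A"])
  span_b <- sum(span[segments$parent == "B"])
  if (span_a == span_b) {
    warning("parental spans tied; major parent set to A")
    major <- "A"
  } else {
    major <- if (span_a > span_b) "A" else "B"
  }
  structure(list(
    segments = segments,
    breakpoints = breakpoints,
    major_parent = major,
    minor_fraction = min(span_a, span_b) / (span_a + span_b),
    unassigned_sites = sum(!keep),
    n_informative = length(cols),
    aln_length = attr(sites, "aln_length")
  ), class = "recomb_report")
}

#' @export
print.recomb_report <- function(x, ...) {
  cat(sprintf("Recombinant painting: %d segments, %d breakpoints, major parent %s\n",
              nrow(x$segments), nrow(x$breakpoints), x$major_parent))
  cat(sprintf("  minor-parent fraction %.3f; %d informative sites (%d unassigned)\n",
              x$minor_fraction, x$n_informative, x$unassigned_sites))
  invisible(x)
}

# Segment spans extended to breakpoint midpoints (ends to the alignment
# ends when the alignment length is known): the painted state is constant
# between informative sites, so coverage fractions use the midpoint
# convention rather than the bare site span.
extended_spans <- function(report) {
  seg <- report$segments
  n <- nrow(seg)
  starts <- seg$start_col
  ends <- seg$end_col
  if (n > 1L) {
    mids <- report$breakpoints$midpoint
    ends[-n] <- floor(mids)
    starts[-1L] <- floor(mids) + 1L
  }
  starts[1L] <- 1L
  if (!is.null(report$aln_length)) ends[n] <- report$aln_length
  data.frame(parent = seg$parent, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

minor_spans <- function(report) {
  sp <- extended_spans(report)
  minor <- setdiff(c("A", "B"), report$major_parent)
  sp[sp$parent == minor, c("start", "end"), drop = FALSE]
}

#' RBP swap calls for a painted recombinant
#'
#' For each feature (mapped to alignment columns, e.g. via
#' [lift_to_alignment()]), the fraction of its span painted as coming from
#' the minor parent. Fractions of at least `swap_threshold` are called
#' swapped; at least 0.95, a complete swap.
#'
#' @param report a [paint()] result.
#' @param features data.frame with `feature_id`, `start`, `end` in
#'   alignment columns (typically the RBP CDS).
#' @param swap_threshold minor-overlap fraction calling a swap.
#' @return data.frame with `feature_id`, `minor_overlap_fraction`,
#'   `swapped`, `complete_swap`.
#' @export
swap_calls <- function(report, features, swap_threshold = 0.5) {
  stopifnot(inherits(report, "recomb_report"))
  if (!is.null(report$aln_length)) {
    bad <- features$start < 1L | features$end > report$aln_length
    if (any(bad)) {
      stop("feature(s) outside the alignment: ",
           paste(features$feature_id[bad], collapse = ", "))
    }
  }
  ms <- minor_spans(report)
  frac <- vapply(seq_len(nrow(features)), function(i) {
    fs <- features$start[i]
    fe <- features$end[i]
    if (nrow(ms) == 0L) return(0)
    ov <- pmax(0, pmin(ms$end, fe) - pmax(ms$start, fs) + 1)
    sum(ov) / (fe - fs + 1)
  }, numeric(1))
  data.frame(feature_id = features$feature_id,
             minor_overlap_fraction = frac,
             swapped = frac >= swap_threshold,
             complete_swap = frac >= 0.95,
             stringsAsFactors = FALSE)
}

#' Consensus minor-parent region across recombinant variants
#'
#' Intersects the minor-parent painted spans of several reports sharing one
#' alignment frame (e.g. all variants isolated from one host); an empty
#' intersection is allowed.
#'
#' @param reports list of [paint()] results on the same alignment.
#' @return data.frame of intersected intervals (`start`, `end` alignment
#'   columns); zero rows when empty.
#' @export
consensus_region <- function(reports) {
  stopifnot(length(reports) >= 2L)
  lens <- vapply(reports, function(r) r$aln_length %||% NA_integer_, numeric(1))
  if (length(unique(lens[!is.na(lens)])) > 1L) {
    stop("mixed alignment frames: reports have different alignment lengths")
  }
  acc <- minor_spans(reports[[1L]])
  for (r in reports[-1L]) {
    acc <- interval_intersect(acc, minor_spans(r))
    if (nrow(acc) == 0L) break
  }
  acc
}

#' Lift genome coordinates into alignment columns
#'
#' Maps 1-based ungapped positions of a sequence to its columns in a gapped
#' alignment.
#'
#' @param aligned_seq the aligned (gapped) sequence.
#' @param pos ungapped positions to lift.
#' @return integer alignment columns.
#' @export
#' @examples
#' lift_to_alignment("AC--GT", c(1, 3))  # columns 1 and 5
lift_to_alignment <- function(aligned_seq, pos) {
  chars <- strsplit(as.character(aligned_seq), "", fixed = TRUE)[[1]]
  map <- which(chars != "-")
  if (any(pos < 1L | pos > length(map))) {
    stop("position(s) outside the ungapped sequence length ", length(map))
  }
  map[pos]
}
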