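# Shared internal helpers: seeded substreams and interval arithmetic.
# All intervals package-wide are 1-based inclusive (GFF3/VCF convention).

#' Derive a deterministic substream seed from a master seed and a label
#'
#' Stages of the synthetic experiment (genomes, each evolution line, assays,
#' recombinants) draw from independent deterministic substreams so that any
#' stage can be regenerated on its own. The derived seed is a 31-bit integer.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the substream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1, "genomes")
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Union of 1-based inclusive intervals given as a data.frame with start/end.
# Returns a data.frame with disjoint sorted intervals.
interval_union <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(intervals$start, intervals$end)
  s <- intervals$start[o]
  e <- intervals$end[o]
  us <- s[1]
  ue <- e[1]
  out_s <- integer(0)
  out_e <- integer(0)
  if (length(s) > 1L) {
    for (i in 2:length(s)) {
      if (s[i] <= ue + 1L) {
        ue <- max(ue, e[i])
      } else {
        out_s <- c(out_s, us)
        out_e <- c(out_e, ue)
        us <- s[i]
        ue <- e[i]
      }
    }
  }
  data.frame(start = c(out_s, us), end = c(out_e, ue))
}

interval_length <- function(intervals) {
  u <- interval_union(intervals)
  sum(u$end - u$start + 1L)
}

# Intersection of two sets of disjoint sorted intervals (data.frames).
interval_intersect <- function(a, b) {
  a <- interval_union(a)
  b <- interval_union(b)
  out_s <- integer(0)
  out_e <- integer(0)
  i <- 1L
  j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a$start[i], b$start[j])
    e <- min(a$end[i], b$end[j])
    if (s <= e) {
      out_s <- c(out_s, s)
      out_e <- c(out_e, e)
    }
    if (a$end[i] < b$end[j]) i <- i + 1L else j <- j + 1L
  }
  data.frame(start = out_s, end = out_e)
}

# TRUE for each position that falls inside any of the intervals.
positions_in_intervals <- function(pos, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  u <- interval_union(intervals)
  res <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(u))) {
    res <- res | (pos >= u$start[i] & pos <= u$end[i])
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
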