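# Independent oracles used to cross-check package implementations.
# These deliberately share no code with the package internals.

# Brute-force two-sided Fisher p: enumerate every 2x2 table with the observed
# margins and sum the probabilities of those no more likely than the observed
# table, using binomial coefficients directly.
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  tab_prob <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (b < 0 || c < 0 || d < 0) return(0)
    exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(n, c1))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, tab_prob, numeric(1))
  obs <- tab_prob(m[1, 1])
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Direct binomial-tail oracle for the exact conditional Poisson-rate
# comparison (minimum-likelihood two-sided sum, written independently).
oracle_poisson_p <- function(k1, L1, k2, L2) {
  K <- k1 + k2
  if (K == 0) return(1)
  p0 <- L1 / (L1 + L2)
  probs <- vapply(0:K, function(x) {
    exp(lchoose(K, x) + x * log(p0) + (K - x) * log(1 - p0))
  }, numeric(1))
  sum(probs[probs <= probs[k1 + 1] * (1 + 1e-7)])
}

# Quadratic recount oracle for window profiles.
oracle_window <- function(pos, af, genome_length, window, step) {
  starts <- seq(1, genome_length, by = step)
  t(vapply(starts, function(s) {
    e <- min(s + window - 1, genome_length)
    inside <- which(pos >= s & pos <= e)
    c(n = length(unique(pos[inside])), af = sum(af[inside]))
  }, numeric(2)))
}

# Independent Nei-Gojobori oracle: same published definitions (stop-codon
# targets are non-synonymous sites; pathways through premature stops are
# discarded; all orderings of multi-hit codons averaged), coded from scratch
# against Biostrings' genetic code.
oracle_ng86 <- function(sa, sb) {
  code <- Biostrings::GENETIC_CODE
  aa_of <- function(cod) unname(code[cod])
  split_codons <- function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  syn_sites <- function(cod) {
    bases <- c("A", "C", "G", "T")
    orig <- aa_of(cod)
    total <- 0
    for (p in 1:3) {
      cur <- substr(cod, p, p)
      for (nb in bases[bases != cur]) {
        alt <- cod
        substr(alt, p, p) <- nb
        if (aa_of(alt) == orig) total <- total + 1
      }
    }
    total / 3
  }
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  path_counts <- function(c1, c2) {
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(dp) == 0) return(c(0, 0))
    acc <- list()
    for (ord in all_perms(dp)) {
      cur <- c1
      sd <- 0; nd <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (aa_of(nxt) == "*" && nxt != c2) { blocked <- TRUE; break }
        if (aa_of(cur) == aa_of(nxt)) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (!blocked) acc[[length(acc) + 1]] <- c(sd, nd)
    }
    if (length(acc) == 0) {
      # every path blocked: fall back to counting ignoring stops
      for (ord in all_perms(dp)) {
        cur <- c1; sd <- 0; nd <- 0
        for (p in ord) {
          nxt <- cur
          substr(nxt, p, p) <- substr(c2, p, p)
          if (aa_of(cur) == aa_of(nxt)) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        acc[[length(acc) + 1]] <- c(sd, nd)
      }
    }
    colMeans(do.call(rbind, acc))
  }
  ca <- split_codons(sa)
  cb <- split_codons(sb)
  S <- (sum(vapply(ca, syn_sites, numeric(1))) +
        sum(vapply(cb, syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) path_counts(ca[i], cb[i]), numeric(2))
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = Sd / S, pN = Nd / N)
}

# Random coding sequence without internal stops.
random_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Mutate a CDS at a few random positions, avoiding stop codons.
mutate_cds <- function(seq, n_mut) {
  code <- Biostrings::GENETIC_CODE
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_len(n_mut)) {
    repeat {
      p <- sample(length(chars), 1)
      old <- chars[p]
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      ci <- (p - 1) %/% 3
      cod <- paste(chars[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
      if (code[cod] != "*") break
      chars[p] <- old
    }
  }
  paste(chars, collapse = "")
}

small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_phages = 5L, n_hosts = 8L, n_passages = 20L,
             sequencing_passages = c(0L, 10L, 20L), n_cds_range = c(5L, 15L),
             genome_length_range = c(9000L, 12000L), mu = 2e-6, ...)
}
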