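# Variant effects, window profiles, enrichment test, parallelism, dN/dS.

make_genome <- function(seq, id = "gA") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- id
  g
}

cds_row <- function(start, end, strand = "+", id = "cds1", genome = "gA") {
  data.frame(genome_id = genome, feature_id = id, start = start, end = end,
             strand = strand, product = "hypothetical protein",
             is_rbp = FALSE, stringsAsFactors = FALSE)
}

var_row <- function(pos, ref, alt, genome = "gA", af = 0.5, vtype = NULL) {
  if (is.null(vtype)) {
    vtype <- if (nchar(ref) == nchar(alt)) "SNP"
             else if (nchar(ref) > nchar(alt)) "DEL" else "INS"
  }
  data.frame(genome_id = genome, pos = pos, ref = ref, alt = alt,
             vtype = vtype, af = af, depth = 100L, line = 1L, passage = 40L,
             stringsAsFactors = FALSE)
}

test_that("SNP effects follow the genetic code on the plus strand", {
  #          123456789
  g <- make_genome("ATGGCTTGGTAA")  # M A W *
  cds <- cds_row(1, 12)
  # GCT -> GCC: Ala -> Ala, synonymous (third codon base at pos 6)
  v <- classify_variants(var_row(6, "T", "C"), cds, g)
  expect_equal(v$effect, "SYNONYMOUS")
  expect_equal(c(v$ref_aa, v$alt_aa), c("A", "A"))
  # TGG -> TGA: Trp -> stop, nonsense (second base of codon 3 at pos 8)
  v2 <- classify_variants(var_row(8, "G", "A"), cds, g)
  expect_equal(v2$effect, "NONSENSE")
  # TGG -> TCG: Trp -> Ser
  v3 <- classify_variants(var_row(8, "G", "C"), cds, g)
  expect_equal(v3$effect, "NONSYNONYMOUS")
  expect_equal(v3$alt_aa, "S")
})

test_that("indels are frameshift iff length change is not a multiple of 3", {
  g <- make_genome("ATGGCTTGGTAAACGT")
  cds <- cds_row(1, 12)
  del2 <- classify_variants(var_row(4, "GCT", "G"), cds, g)
  expect_equal(del2$effect, "FRAMESHIFT")
  del3 <- classify_variants(var_row(3, "GGCT", "G"), cds, g)
  expect_equal(del3$effect, "INFRAME_INDEL")
})

test_that("intergenic, ambiguous-N and frame validation work", {
  g <- make_genome("ATGGCTTGGTAAACGTACGT")
  cds <- cds_row(1, 12)
  out <- classify_variants(var_row(15, "C", "T"), cds, g)
  expect_equal(out$effect, "INTERGENIC")

  gn <- make_genome("ATGGNTTGGTAA")
  vn <- classify_variants(var_row(6, "T", "C"), cds, gn)
  expect_equal(vn$effect, "AMBIGUOUS_N")

  expect_error(classify_variants(var_row(2, "T", "C"), cds_row(1, 11), g),
               "divisible")
})

test_that("minus-strand classification equals the reverse-complement construction", {
  set.seed(42)
  for (rep in 1:20) {
    n_codons <- sample(4:10, 1)
    cds_fwd <- random_cds(n_codons)
    flank_l <- paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE), collapse = "")
    flank_r <- paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE), collapse = "")
    # genome carrying the CDS on the minus strand
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_fwd)))
    gm <- make_genome(paste0(flank_l, rc, flank_r))
    cds_m <- cds_row(8, 7 + nchar(rc), strand = "-")
    # and the equivalent plus-strand genome
    gp <- make_genome(paste0(flank_l, cds_fwd, flank_r))
    cds_p <- cds_row(8, 7 + nchar(cds_fwd), strand = "+")
    # mutate one CDS base
    off <- sample(0:(nchar(cds_fwd) - 1), 1)
    pos_p <- 8 + off
    base_p <- substr(cds_fwd, off + 1, off + 1)
    alt_p <- sample(setdiff(c("A", "C", "G", "T"), base_p), 1)
    ep <- classify_variants(var_row(pos_p, base_p, alt_p), cds_p, gp)
    # the same codon change seen from the minus strand
    pos_m <- 7 + nchar(rc) - off
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    em <- classify_variants(var_row(pos_m, comp[[base_p]], comp[[alt_p]]), cds_m, gm)
    expect_equal(em$effect, ep$effect)
    expect_equal(em$ref_aa, ep$ref_aa)
    expect_equal(em$alt_aa, ep$alt_aa)
    expect_equal(em$codon_index, ep$codon_index)
  }
})

test_that("window metrics match direct counting and a brute-force oracle", {
  v <- rbind(var_row(100, "A", "G", af = 0.5), var_row(300, "C", "T", af = 0.3))
  w <- window_profile(v, genome_length = 1000L, window = 500L, step = 500L)
  expect_equal(w$n_positions[1], 2L)
  expect_equal(w$af_sum[1], 0.8)
  expect_equal(w$n_positions[2], 0L)

  empty <- v[0, ]
  w0 <- window_profile(empty, 1000L, 500L, 250L)
  expect_true(all(w0$n_positions == 0) && all(w0$af_sum == 0))

  set.seed(8)
  for (i in 1:10) {
    L <- sample(2000:6000, 1)
    n <- sample(0:80, 1)
    pos <- sample(L, n, replace = TRUE)
    af <- runif(n)
    vv <- do.call(rbind, lapply(seq_len(n), function(j)
      var_row(pos[j], "A", "G", af = af[j])))
    if (is.null(vv)) vv <- v[0, ]
    win <- sample(c(250, 500, 800), 1)
    step <- sample(c(win, win / 2), 1)
    got <- window_profile(vv, L, win, step)
    want <- oracle_window(pos, af, L, win, step)
    expect_equal(got$n_positions, unname(want[, "n"]))
    expect_equal(got$af_sum, unname(want[, "af"]))
  }
})

test_that("window metrics are additive over disjoint variant subsets", {
  set.seed(12)
  pos <- sample(5000, 60, replace = TRUE)
  af <- runif(60)
  vv <- do.call(rbind, lapply(1:60, function(j) var_row(pos[j], "A", "G", af = af[j])))
  # distinct positions are not additive, but the AF metric is
  split <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  all_w <- window_profile(vv, 5000L, 500L, 250L)
  w1 <- window_profile(vv[split, ], 5000L, 500L, 250L)
  w2 <- window_profile(vv[!split, ], 5000L, 500L, 250L)
  expect_equal(w1$af_sum + w2$af_sum, all_w$af_sum)
})

test_that("count_region_positions counts distinct positions once", {
  region <- data.frame(start = 100L, end = 200L)
  v <- rbind(
    transform(var_row(150, "A", "G"), passage = 40L),
    transform(var_row(150, "A", "G"), passage = 69L),  # same position twice
    transform(var_row(160, "A", "G"), passage = 40L),
    transform(var_row(160, "A", "T"), passage = 40L),  # two alts, one position
    transform(var_row(500, "A", "G"), passage = 69L),
    transform(var_row(600, "A", "G"), passage = 0L)    # outside passage set
  )
  k <- count_region_positions(v, region)
  expect_equal(k$k_region, 2L)
  expect_equal(k$k_rest, 1L)
  expect_equal(attr(k, "L_region"), 101L)

  # overlapping region intervals are unioned, not double-counted
  region2 <- data.frame(start = c(100L, 150L), end = c(200L, 260L))
  k2 <- count_region_positions(v, region2)
  expect_equal(k2$k_region, 2L)
  expect_equal(attr(k2, "L_region"), 161L)
})

test_that("count_region_positions recovers planted counts from the generator", {
  set.seed(30)
  region <- data.frame(start = 2001L, end = 5000L)
  pos_in <- sample(2001:5000, 12)
  pos_out <- sample(c(1:2000, 5001:45000), 20)
  v <- do.call(rbind, lapply(c(pos_in, pos_out), function(p)
    var_row(p, "A", "G")))
  k <- count_region_positions(v, region)
  expect_equal(c(k$k_region, k$k_rest), c(12L, 20L))
})

test_that("poisson_rate_test matches exact enumeration and handles edges", {
  # symmetric null: one mutation each in equal lengths
  expect_equal(poisson_rate_test(1, 1000, 1, 1000)$p.value, 1)

  t0 <- poisson_rate_test(0, 1000, 0, 1000)
  expect_equal(t0$p.value, 1)
  expect_true(is.na(t0$estimate))

  t1 <- poisson_rate_test(10, 2000, 20, 40000)
  expect_lt(t1$p.value, 1e-4)
  expect_equal(unname(t1$estimate), (10 / 2000) / (20 / 40000))

  set.seed(14)
  for (i in 1:100) {
    k1 <- rpois(1, 4); k2 <- rpois(1, 15)
    L1 <- sample(500:5000, 1); L2 <- sample(10000:60000, 1)
    expect_equal(poisson_rate_test(k1, L1, k2, L2)$p.value,
                 oracle_poisson_p(k1, L1, k2, L2), tolerance = 1e-12)
  }
})

test_that("poisson_rate_test is exchange-symmetric", {
  set.seed(15)
  for (i in 1:30) {
    k1 <- rpois(1, 5); k2 <- rpois(1, 12)
    L1 <- sample(500:5000, 1); L2 <- sample(10000:50000, 1)
    a <- poisson_rate_test(k1, L1, k2, L2)
    b <- poisson_rate_test(k2, L2, k1, L1)
    expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
    if (k1 > 0 && k2 > 0) {
      expect_equal(unname(a$estimate), 1 / unname(b$estimate))
    }
  }
})

test_that("the exact rate test is valid (type I error at most nominal) and powerful", {
  set.seed(16)
  n_rep <- 400L
  region <- data.frame(start = 1L, end = 3000L)
  rej_null <- 0L
  rej_alt <- 0L
  for (i in seq_len(n_rep)) {
    K <- rpois(1, 30)
    pos0 <- place_mutations(K, 45000L, region, rho = 1)
    k1 <- sum(pos0 <= 3000)
    if (poisson_rate_test(k1, 3000, K - k1, 42000)$p.value <= 0.05) {
      rej_null <- rej_null + 1L
    }
    pos1 <- place_mutations(K, 45000L, region, rho = 10)
    k1a <- sum(pos1 <= 3000)
    if (poisson_rate_test(k1a, 3000, K - k1a, 42000)$p.value <= 0.05) {
      rej_alt <- rej_alt + 1L
    }
  }
  # validity: empirical size below nominal + 3 binomial SEs
  expect_lt(rej_null / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
  expect_gt(rej_alt / n_rep, 0.9)
})

test_that("region_enrichment tabulates per-line exact tests", {
  v <- rbind(var_row(150, "A", "G"), var_row(160, "A", "G"),
             transform(var_row(150, "A", "G"), line = 2L),
             transform(var_row(5000, "A", "G"), line = 2L))
  res <- region_enrichment(v, data.frame(start = 100L, end = 299L),
                           genome_length = 40000L)
  expect_equal(res$line, 1:2)
  expect_equal(res$k_region, c(2L, 1L))
  expect_equal(res$k_rest, c(0L, 1L))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  res_adj <- region_enrichment(v, data.frame(start = 100L, end = 299L),
                               genome_length = 40000L, adjust = TRUE)
  expect_true("p_adjusted" %in% names(res_adj))
})

test_that("parallelism reports positions shared by two or more lines", {
  v <- rbind(
    transform(var_row(100, "A", "G"), line = 1L),
    transform(var_row(100, "A", "G"), line = 3L, af = 0.9),
    transform(var_row(200, "A", "G"), line = 2L)
  )
  p <- parallelism(v)
  expect_equal(nrow(p), 1L)
  expect_equal(p$lines, "1,3")
  expect_equal(p$max_af, 0.9)

  v2 <- rbind(transform(var_row(100, "A", "G"), line = 1L),
              transform(var_row(200, "A", "G"), line = 2L))
  expect_equal(nrow(parallelism(v2)), 0L)

  v3 <- rbind(
    transform(var_row(100, "A", "G"), line = 1L),
    transform(var_row(100, "A", "G"), line = 2L),
    transform(var_row(100, "A", "G"), line = 3L)
  )
  expect_equal(parallelism(v3)$lines, "1,2,3")
})

test_that("ng86_dnds reproduces the hand-computed single-change case", {
  r <- ng86_dnds("GGGGGG", "GGAGGG")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$S_sites, 2)
  expect_equal(r$pS, 0.5)
  expect_equal(r$dS, -3 / 4 * log(1 / 3), tolerance = 1e-12)
  expect_equal(r$dN, 0)
  expect_equal(r$ratio, 0)

  ident <- ng86_dnds("ATGGCT", "ATGGCT")
  expect_equal(c(ident$Sd, ident$Nd), c(0, 0))
  expect_true(is.na(ident$ratio))
})

test_that("ng86_dnds equals the independent pathway-enumeration oracle", {
  set.seed(17)
  for (i in 1:60) {
    n_codons <- sample(5:25, 1)
    a <- random_cds(n_codons)
    b <- mutate_cds(a, sample(0:6, 1))
    got <- ng86_dnds(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$S_sites, want$S, tolerance = 1e-9)
    expect_equal(got$N_sites, want$N, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
  }
})

test_that("ng86_dnds validates input and flags saturation", {
  expect_error(ng86_dnds("ATG", "ATGA"), "equal length")
  expect_error(ng86_dnds("ATGA", "ATGC"), "multiple of 3")
  expect_error(ng86_dnds("TAAATG", "TAAATG"), "internal stop")
  # N codons excluded and counted
  r <- ng86_dnds("ATGNNNGCT", "ATGAAAGCT")
  expect_equal(r$n_excluded, 1L)
  expect_equal(r$n_codons, 2L)
  # heavy divergence saturates the synonymous proportion
  sat <- ng86_dnds("TTATTATTATTA", "CTGCTGCTGCTG")
  expect_true(sat$status %in% c("OK", "SATURATED"))
})
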