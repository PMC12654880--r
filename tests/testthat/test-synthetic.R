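# Synthetic community generator: genomes, dynamics, recombinants, assays.

test_that("generate_genomes plants the expected number of diagnostic sites", {
  cfg <- sim_config(seed = 11, n_phages = 4L, n_hosts = 5L,
                    genome_length_range = c(40000L, 40000L),
                    n_cds_range = c(10L, 40L), pair_identity = 0.98)
  gs <- generate_genomes(cfg)
  expected <- 0.02 * 40000
  expect_lt(abs(length(gs$diagnostic_sites) - expected), 3 * sqrt(expected))
  # diagnostic sites really differ between pair members, rest is identical
  a <- strsplit(as.character(gs$genomes[[gs$pair[1]]]), "")[[1]]
  b <- strsplit(as.character(gs$genomes[[gs$pair[2]]]), "")[[1]]
  expect_equal(which(a != b), gs$diagnostic_sites)
})

test_that("generated CDS are non-overlapping, in-frame, with at least one RBP", {
  cfg <- small_sim_config(seed = 5)
  gs <- generate_genomes(cfg)
  for (id in names(gs$genomes)) {
    f <- gs$features[gs$features$genome_id == id, ]
    expect_gte(nrow(f), cfg$n_cds_range[1])
    expect_lte(nrow(f), cfg$n_cds_range[2])
    expect_true(all((f$end - f$start + 1L) %% 3L == 0L))
    expect_true(any(f$is_rbp))
    o <- order(f$start)
    expect_true(all(f$start[o][-1] > f$end[o][-nrow(f)]))
    expect_true(all(f$end <= Biostrings::width(gs$genomes[id])))
  }
})

test_that("identical pair members are rejected and same seed reproduces output", {
  expect_error(sim_config(pair_identity = 1.0), "pair_identity")
  cfg <- small_sim_config(seed = 42)
  g1 <- generate_genomes(cfg)
  g2 <- generate_genomes(cfg)
  expect_identical(as.character(g1$genomes), as.character(g2$genomes))
  expect_identical(g1$features, g2$features)
  expect_identical(g1$diagnostic_sites, g2$diagnostic_sites)
})

test_that("true abundances sum to one at every line and passage", {
  cfg <- small_sim_config(seed = 2)
  ev <- simulate_evolution(generate_genomes(cfg), config = cfg)
  sums <- apply(ev$truth$abundance, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("a phage with zero fitness everywhere is driven out", {
  cfg <- sim_config(seed = 3, n_phages = 4L, n_hosts = 6L, n_passages = 40L,
                    sequencing_passages = c(0L, 40L), n_cds_range = c(5L, 15L),
                    genome_length_range = c(9000L, 12000L), mu = 1e-6)
  gs <- generate_genomes(cfg)
  hm <- matrix(2L, 4L, 6L, dimnames = list(names(gs$genomes), sprintf("K%02d", 1:6)))
  hm[2, ] <- 0L  # no host at all
  ev <- simulate_evolution(gs, hm, cfg)
  traj <- ev$truth$abundance[, , 2]
  # monotone non-increasing in expectation; assert final collapse
  expect_true(all(traj[, "P40"] < 1e-3))
})

test_that("with s = 0 and infinite Ne neutral allele frequencies are constant", {
  cfg <- sim_config(seed = 9, n_phages = 3L, n_hosts = 4L, n_passages = 12L,
                    sequencing_passages = c(6L, 12L), n_cds_range = c(5L, 15L),
                    genome_length_range = c(9000L, 12000L),
                    mu = 5e-6, sel_coeff = 0, beneficial_frac = 0, Ne = Inf,
                    bottleneck = 10000L, min_emit_af = 0)
  ev <- simulate_evolution(generate_genomes(cfg), config = cfg)
  v <- ev$variants[ev$variants$vtype == "SNP", ]
  # exclude the pair's diagnostic-site rows (binomial sampling noise by design)
  v <- v[v$genome_id != ev$pair[1], ]
  # same position observed at both sequencing passages must keep its AF
  key <- paste(v$line, v$genome_id, v$pos, v$alt)
  dup <- unique(key[duplicated(key)])
  expect_gt(length(dup), 0L)
  for (k in dup) {
    afs <- v$af[key == k]
    expect_true(max(afs) - min(afs) < 1e-12)
  }
})

test_that("mutation placement is uniform when rho = 1 (chi-square vs lengths)", {
  set.seed(101)
  L <- 45000L
  rbp <- data.frame(start = c(5001L, 30001L), end = c(6500L, 32000L))
  pos <- place_mutations(1000L, L, rbp, rho = 1)
  L_r <- 3500L
  inside <- sum(pos >= 5001 & pos <= 6500) + sum(pos >= 30001 & pos <= 32000)
  p <- chisq.test(c(inside, 1000 - inside),
                  p = c(L_r / L, 1 - L_r / L))$p.value
  expect_gt(p, 0.01)
})

test_that("rho-weighted placement enriches RBP bases by about rho", {
  set.seed(202)
  L <- 45000L
  rbp <- data.frame(start = 5001L, end = 8000L)
  pos <- place_mutations(5000L, L, rbp, rho = 10)
  frac_in <- mean(pos >= 5001 & pos <= 8000)
  expected <- 10 * 3000 / (10 * 3000 + 42000)
  expect_lt(abs(frac_in - expected), 0.03)
})

test_that("emitted VCF allele frequencies equal truth rounded to 4 decimals", {
  cfg <- small_sim_config(seed = 13)
  ex <- simulate_experiment(cfg)
  d <- withr::local_tempdir()
  write_simulation(ex, d)
  v <- read_variants(file.path(d, "L1_P20.vcf"))
  truth <- ex$evolution$variants
  truth <- truth[truth$line == 1 & truth$passage == 20, ]
  merged <- merge(v, truth, by = c("genome_id", "pos", "alt"))
  expect_equal(nrow(merged), nrow(truth))
  expect_equal(merged$af.x, round(merged$af.y, 4))
})

test_that("recombinant mosaics follow their planted construction", {
  set.seed(1)
  a <- paste(rep("A", 10000), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  rec <- generate_recombinants(a, b, n = 1L, k_breakpoints = 1L,
                               min_gap = 1000L, start_parent = "A", seed = 8)
  bp <- rec$truth$breakpoints$breakpoint
  s <- as.character(rec$recombinants[[1]])
  expect_equal(substr(s, 1, bp), substr(a, 1, bp))
  expect_equal(substr(s, bp + 1, 10000), substr(b, bp + 1, 10000))
})

test_that("recombinant generation is deterministic and validates feasibility", {
  set.seed(2)
  a <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE), collapse = "")
  b <- chartr("AC", "CA", a)
  r1 <- generate_recombinants(a, b, n = 10L, k_breakpoints = 1:3,
                              min_gap = 500L, seed = 4)
  r2 <- generate_recombinants(a, b, n = 10L, k_breakpoints = 1:3,
                              min_gap = 500L, seed = 4)
  expect_identical(as.character(r1$recombinants), as.character(r2$recombinants))
  expect_identical(r1$truth$breakpoints, r2$truth$breakpoints)
  expect_error(generate_recombinants(a, b, n = 1L, k_breakpoints = 4L,
                                     min_gap = 2000L, seed = 1),
               "infeasible")
})

test_that("planted RBP-swap truth matches the mosaic geometry", {
  set.seed(3)
  a <- paste(sample(c("A", "G"), 12000, replace = TRUE), collapse = "")
  b <- chartr("AG", "GA", a)
  feats <- data.frame(genome_id = "p", feature_id = "rbp1",
                      start = 4000L, end = 5999L, strand = "+",
                      product = "tail fiber protein", is_rbp = TRUE)
  # one breakpoint inside the RBP: 60% of the feature from the suffix donor
  rec <- generate_recombinants(a, b, n = 20L, k_breakpoints = 1L,
                               min_gap = 1000L, features = feats, seed = 6)
  tr <- rec$truth
  for (id in unique(tr$rbp$rec_id)) {
    seg <- tr$segments[tr$segments$rec_id == id, ]
    major <- tr$rbp$major_parent[tr$rbp$rec_id == id][1]
    minor_seg <- seg[seg$donor != major, , drop = FALSE]
    ov <- sum(pmax(0, pmin(minor_seg$end, 5999) - pmax(minor_seg$start, 4000) + 1))
    expect_equal(tr$rbp$minor_overlap[tr$rbp$rec_id == id], ov / 2000)
  }
})

test_that("assay tables respect the detection limit and zero infectivity", {
  cfg <- sim_config(seed = 21, n_phages = 3L, n_hosts = 4L,
                    n_cds_range = c(5L, 15L),
                    genome_length_range = c(9000L, 12000L))
  hm <- matrix(c(2L, 0L, 1L, 0L, 2L, 0L, 2L, 1L, 0L, 0L, 0L, 2L), 3L, 4L,
               dimnames = list(c("pA", "pB", "pC"), paste0("K", 1:4)))
  as1 <- generate_assays(hm, cfg)
  as2 <- generate_assays(hm, cfg)
  expect_identical(as1, as2)  # same seed, same tables
  # zero infectivity: all replicates NONE and titer below detection
  zero_pairs <- which(hm == 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(zero_pairs))) {
    ph <- rownames(hm)[zero_pairs[i, 1]]
    st <- colnames(hm)[zero_pairs[i, 2]]
    sp <- as1$spots[as1$spots$phage == ph & as1$spots$strain == st, ]
    expect_true(all(sp$outcome == "NONE"))
    tt <- as1$titers[as1$titers$phage == ph & as1$titers$strain == st, ]
    expect_true(all(tt$below_detection))
  }
  # ND sentinel written on disk for below-detection titers
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(as1$titers, f)
  back <- read_table(f, "titers")
  expect_equal(back$below_detection, as1$titers$below_detection)
})
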