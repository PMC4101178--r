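# F3 selfing recursion: genotype frequencies after g selfing generations
# starting from a heterozygote (exact oracle, independent of the simulator)
self_recursion <- function(g) {
  p <- c(0, 1, 0)  # P(AA), P(Aa), P(aa), starting from a heterozygote
  for (i in seq_len(g))
    p <- c(p[1] + p[2] / 4, p[2] / 2, p[3] + p[2] / 4)
  p
}

test_that("parent simulation yields homozygous founders on a seven-group map", {
  ps <- simulate_parents(10, seed = 1)
  expect_equal(nrow(ps$map), 70)
  expect_equal(sort(unique(ps$map$chromosome)), 1:7)
  expect_false(any(duplicated(ps$map$marker_id)))
  # positions sorted within each chromosome
  for (ch in 1:7)
    expect_false(is.unsorted(ps$map$position[ps$map$chromosome == ch]))
  # founders are stored as single allele codes: homozygous by construction,
  # and every code is 0/1
  expect_true(all(ps$alleles %in% 0:1))
  expect_equal(rownames(ps$alleles), c("P1", "P2", "P3", "tester"))
  # determinism
  expect_identical(simulate_parents(10, seed = 7), simulate_parents(10, seed = 7))
  expect_error(simulate_parents(1), "n_markers_per_chrom")
  expect_error(simulate_parents(10, map_length_cM = -5), "map_length_cM")
})

test_that("F3 populations have the exact selfing-recursion genotype frequencies", {
  ps <- simulate_parents(15, seed = 11)
  pop <- simulate_f3_population(ps, "A", n_lines = 400, seed = 12)
  expect_equal(nrow(pop$geno), 400)
  expect_true(all(pop$geno %in% 0:2))

  seg <- which(ps$alleles["P1", ] != ps$alleles["P2", ])
  expect_gt(length(seg), 10)
  exact <- self_recursion(2)              # 3/8, 1/4, 3/8 after two selfings
  expect_equal(exact, c(3 / 8, 1 / 4, 3 / 8))

  # per-line heterozygote fraction; its spread gives a Monte-Carlo SE that is
  # robust to linkage between loci
  het_line <- rowMeans(pop$geno[, seg] == 1)
  se_het <- stats::sd(het_line) / sqrt(length(het_line))
  expect_lt(abs(mean(het_line) - exact[2]), 3 * se_het + 1e-12)

  freq_line <- rowMeans(pop$geno[, seg]) / 2
  se_f <- stats::sd(freq_line) / sqrt(length(freq_line))
  expect_lt(abs(mean(freq_line) - 0.5), 3 * se_f + 1e-12)
})

test_that("a selfed cross of identical parents is monomorphic", {
  ps <- simulate_parents(8, seg_frac = c(0, 0.5), seed = 21)
  pop <- simulate_f3_population(ps, "A", n_lines = 30, seed = 22)  # P1 x P2 identical
  expect_true(all(apply(pop$geno, 2, function(d) length(unique(d))) == 1))
})

test_that("population simulation is deterministic and validates its inputs", {
  ps <- simulate_parents(8, seed = 31)
  expect_identical(simulate_f3_population(ps, "B", 25, seed = 5),
                   simulate_f3_population(ps, "B", 25, seed = 5))
  broken <- ps
  broken$alleles <- ps$alleles[, -1]
  expect_error(simulate_f3_population(broken, "A", 10, seed = 1), "mismatch")
})

test_that("adjacent-marker recombinant fraction follows the Haldane map function", {
  ps <- simulate_parents(6, map_length_cM = 100, seed = 41)
  map <- ps$map
  h1 <- rep(0L, nrow(map)); h2 <- rep(1L, nrow(map))
  set.seed(42)
  n_gam <- 3000
  gam <- matrix(0L, n_gam, nrow(map))
  for (i in seq_len(n_gam)) gam[i, ] <- ryegs:::gamete_haldane(h1, h2, map)
  for (ch in c(1, 4, 7)) {
    idx <- which(map$chromosome == ch)
    j <- idx[1]; k <- idx[2]
    d <- map$position[k] - map$position[j]
    r_obs <- mean(gam[, j] != gam[, k])
    r_exp <- (1 - exp(-2 * d / 100)) / 2
    se <- sqrt(r_exp * (1 - r_exp) / n_gam)
    expect_lt(abs(r_obs - r_exp), 3 * se + 1e-12)
  }
})

test_that("population B (wider parental divergence) segregates at more markers", {
  w <- fx_world()
  n_seg <- function(p) sum(apply(p$geno, 2, function(d) stats::var(d) > 0))
  expect_gt(n_seg(w$pb), n_seg(w$pa))
})

test_that("trial simulation has the design arithmetic and calibrated variance", {
  tr <- fx_trial()
  w <- fx_world()
  expect_equal(nrow(tr), (80 + 80) * 3 * 2)   # lines x envs x reps
  expect_true(all(is.finite(tr$value)))
  # every genotype appears in every environment with both replicates
  counts <- table(tr$genotype, tr$env)
  expect_true(all(counts == 2))
  # per-population realized genotypic variance is calibrated to the target
  g <- attr(tr, "true_g")
  arch <- attr(tr, "arch")
  for (p in c("A", "B")) {
    i <- grepl(paste0("^", p), names(g))
    expect_equal(stats::var(g[i]), arch$sigma2_G, tolerance = 1e-10)
  }
  # determinism
  tr2 <- simulate_trial(w$pa, w$pb, trait_architecture("grain_yield", n_qtl = 12, n_env = 3),
                        environments = rye_environments(9)[1:3, ], seed = 104)
  expect_identical(tr$value, tr2$value)
})

test_that("noiseless trials repeat each genotype's value across plots and environments", {
  w <- fx_world()
  arch0 <- trait_architecture("grain_yield", n_qtl = 8, sigma2_GE = 0,
                              sigma2_e = 0, sigma2_rep = 0, sigma2_block = 0,
                              n_env = 2)
  tr0 <- simulate_trial(w$pa, NULL, arch0, rye_environments(9)[1:2, ], seed = 51)
  spread <- tapply(tr0$value, tr0$genotype, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("off-map QTL are rejected", {
  w <- fx_world()
  arch <- trait_architecture("grain_yield", n_qtl = 2, n_env = 2,
                             qtl_markers = c("NOT_A_MARKER", "M1_001"))
  expect_error(simulate_trial(w$pa, NULL, arch, rye_environments(9)[1:2, ],
                              seed = 1), "off the map")
})
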