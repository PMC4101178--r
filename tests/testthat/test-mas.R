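# 20-line fixture with two chromosomes for hand-checked scan arithmetic
mas_fixture <- function() {
  set.seed(900)
  n <- 20
  map <- data.frame(marker_id = c("c1a", "c1b", "c1c", "c2a", "c2b"),
                    chromosome = c(1, 1, 1, 2, 2),
                    position = c(0, 30, 60, 0, 40),
                    stringsAsFactors = FALSE)
  geno <- sapply(seq_len(nrow(map)), function(j) rbinom(n, 2, 0.5))
  dimnames(geno) <- list(sprintf("L%02d", 1:n), map$marker_id)
  list(geno = geno, map = map)
}

test_that("the LOD at a marker equals the simple-regression RSS ratio by hand", {
  fx <- mas_fixture()
  y <- 1.2 * fx$geno[, "c1b"] + rnorm(20, 0, 0.8)
  sc <- cim_scan(fx$geno, y, fx$map, cofactor_alpha = 0, lod_threshold = 3)
  n <- 20
  # oracle: explicit RSS computation for intercept-only vs marker regression
  rss0 <- sum((y - mean(y))^2)
  x <- fx$geno[, "c1b"]
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  rss1 <- sum((y - mean(y) - b * (x - mean(x)))^2)
  lod_hand <- (n / 2) * log10(rss0 / rss1)
  at <- sc$scan$chromosome == 1 & sc$scan$position == 30
  expect_equal(sc$scan$lod[at], lod_hand, tolerance = 1e-8)
  expect_equal(sc$scan$effect[at], b, tolerance = 1e-8)
})

test_that("a scan with no cofactors equals independent simple interval mapping", {
  fx <- mas_fixture()
  y <- rowSums(fx$geno[, c("c1a", "c2b")]) + rnorm(20, 0, 0.5)
  sc <- cim_scan(fx$geno, y, fx$map, cofactor_alpha = 0, lod_threshold = 3)
  expect_length(sc$cofactors, 0)
  reg <- qtl_regressors(fx$geno, fx$map, step = 1)
  lod_oracle <- sapply(seq_len(nrow(reg$grid)), function(j) {
    f0 <- stats::lm(y ~ 1)
    f1 <- stats::lm(y ~ reg$Z[, j])
    (20 / 2) * log10(sum(stats::resid(f0)^2) / sum(stats::resid(f1)^2))
  })
  expect_equal(sc$scan$lod, lod_oracle, tolerance = 1e-8)
})

test_that("the flanking-marker regressor is exact at markers and bounded between", {
  fx <- mas_fixture()
  reg <- qtl_regressors(fx$geno, fx$map, step = 1)
  for (mk in fx$map$marker_id) {
    j <- which(reg$grid$chromosome == fx$map$chromosome[fx$map$marker_id == mk] &
                 reg$grid$position == fx$map$position[fx$map$marker_id == mk])
    expect_equal(unname(reg$Z[, j]), unname(fx$geno[, mk]))
  }
})

test_that("a large single QTL is localized to the right chromosome and region", {
  w <- fx_world()
  ps <- simulate_parents(15, map_length_cM = 120, seed = 700)
  pop <- simulate_f3_population(ps, "A", 220, seed = 701)
  seg3 <- ps$map$marker_id[ps$map$chromosome == 3 &
                             ps$alleles["P1", ] != ps$alleles["P2", ]]
  qtl <- seg3[ceiling(length(seg3) / 2)]
  truth <- ps$map$position[ps$map$marker_id == qtl]
  set.seed(702)
  g <- pop$geno[, qtl] * 2
  y <- g + rnorm(220, 0, sqrt(stats::var(g) / 2))  # within-line h2 ~ 2/3
  sc <- cim_scan(pop$geno, y, ps$map)
  expect_gt(nrow(sc$detected), 0)
  top <- sc$detected[which.max(sc$detected$lod), ]
  expect_equal(top$chromosome, 3)
  expect_lt(abs(top$position - truth), 10)
})

test_that("pure-noise phenotypes rarely yield detections at the LOD threshold", {
  ps <- simulate_parents(15, map_length_cM = 120, seed = 710)
  pop <- simulate_f3_population(ps, "A", 180, seed = 711)
  reg <- qtl_regressors(pop$geno, ps$map)
  set.seed(712)
  n_det <- replicate(100, {
    y <- rnorm(180)
    nrow(cim_scan(pop$geno, y, ps$map, regressors = reg)$detected)
  })
  expect_gte(mean(n_det == 0), 0.95)
})

test_that("QTL detection uses only training data (no leakage)", {
  fx <- mas_fixture()
  set.seed(720)
  ytr <- fx$geno[, "c1b"] + rnorm(20, 0, 0.5)
  te_geno <- fx$geno[sample(20, 10), ]
  yte1 <- rnorm(10); yte2 <- sample(yte1)
  sc <- cim_scan(fx$geno, ytr, fx$map, lod_threshold = 2, cofactor_alpha = 0)
  p1 <- mas_qtl_predict(sc, fx$geno, ytr, te_geno, fx$map, test_pheno = yte1)
  p2 <- mas_qtl_predict(sc, fx$geno, ytr, te_geno, fx$map, test_pheno = yte2)
  expect_identical(p1$pred, p2$pred)       # detection/prediction unchanged
  expect_false(isTRUE(all.equal(p1$r2_cv, p2$r2_cv)))
})

test_that("prediction falls back to the training mean with zero detected QTL", {
  fx <- mas_fixture()
  set.seed(730)
  y <- rnorm(20)
  sc <- cim_scan(fx$geno, y, fx$map, lod_threshold = 50)   # nothing passes
  expect_equal(nrow(sc$detected), 0)
  p <- mas_qtl_predict(sc, fx$geno, y, fx$geno[1:6, ], fx$map,
                       test_pheno = rnorm(6))
  expect_true(p$degenerate)
  expect_equal(p$pred, rep(mean(y), 6))
  expect_equal(p$r2_cv, 0)
})

test_that("a perfect marker yields near-complete cross-validated R2", {
  ps <- simulate_parents(10, map_length_cM = 100, seed = 740)
  pop <- simulate_f3_population(ps, "A", 120, seed = 741)
  seg <- which(apply(pop$geno, 2, stats::var) > 0)
  y <- pop$geno[, seg[5]] * 3
  tr <- 1:80; te <- 81:120
  sc <- cim_scan(pop$geno[tr, ], y[tr], ps$map)
  p <- suppressWarnings(
    mas_qtl_predict(sc, pop$geno[tr, ], y[tr], pop$geno[te, ], ps$map,
                    test_pheno = y[te]))
  expect_gt(p$r2_cv, 0.99)
})

test_that("neutral marker sampling spreads over linkage groups as specified", {
  map <- fx_world()$ps$map
  s7 <- sample_neutral_markers(7, map, seed = 1)
  expect_length(s7, 7)
  expect_equal(sort(map$chromosome[match(s7, map$marker_id)]), 1:7)
  expect_length(sample_neutral_markers(1, map, seed = 2), 1)
  s10 <- sample_neutral_markers(10, map, seed = 3)
  expect_length(unique(s10), 10)
  expect_setequal(unique(map$chromosome[match(s10, map$marker_id)]), 1:7)
  expect_error(sample_neutral_markers(nrow(map) + 1, map), "more markers")
})

test_that("standardized MAS accuracy follows sqrt(R2cv / h2) with capping", {
  expect_equal(mas_accuracy(0.75, 0.75), 1)
  expect_equal(mas_accuracy(0, 0.8), 0)
  expect_equal(mas_accuracy(0.25, 0.75), sqrt(1 / 3))
  capped <- mas_accuracy(0.9, 0.5)
  expect_equal(as.numeric(capped), 1)
  expect_true(attr(capped, "capped"))
  expect_error(mas_accuracy(0.5, 0), "h2")
})
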