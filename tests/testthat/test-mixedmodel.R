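test_that("REML on a balanced one-way layout equals the ANOVA closed form", {
  set.seed(10)
  g <- 8; n <- 5
  d <- data.frame(group = factor(rep(1:g, each = n)),
                  y = rep(rnorm(g, sd = 2), each = n) + rnorm(g * n))
  fit <- reml_fit(y ~ (1 | group), d)
  gm <- tapply(d$y, d$group, mean)
  msb <- n * sum((gm - mean(d$y))^2) / (g - 1)
  msw <- sum((d$y - gm[d$group])^2) / (g * (n - 1))
  s2b <- (msb - msw) / n
  expect_equal(fit$varcomp$variance[fit$varcomp$term == "group"], s2b,
               tolerance = 1e-4)
  expect_equal(fit$varcomp$variance[fit$varcomp$term == "Residual"], msw,
               tolerance = 1e-4)
})

test_that("constant responses give zero variances and the constant mean", {
  d <- data.frame(group = factor(rep(1:4, each = 3)), y = 7.5)
  fit <- reml_fit(y ~ (1 | group), d)
  expect_true(all(fit$varcomp$variance == 0))
  expect_equal(unname(fit$fixef), 7.5)
})

test_that("stage-1 BLUEs reduce to plot means in the simple balanced cases", {
  # noiseless: the BLUE is the (constant) plot value
  w <- fx_world()
  arch0 <- trait_architecture("grain_yield", n_qtl = 8, sigma2_GE = 0,
                              sigma2_e = 0, sigma2_rep = 0, sigma2_block = 0,
                              n_env = 2)
  tr0 <- simulate_trial(w$pa, NULL, arch0, rye_environments(9)[1:2, ], seed = 61)
  s1 <- step1_blues(tr0)
  plot_vals <- tapply(tr0$value[tr0$env == "BEK10"],
                      tr0$genotype[tr0$env == "BEK10"], mean)
  expect_equal(s1$blues[names(plot_vals), "BEK10"], c(plot_vals))

  # two reps, single block, rep effects random: balanced GLS is the 2-plot mean
  set.seed(62)
  d <- data.frame(genotype = rep(sprintf("G%02d", 1:30), 2),
                  env = "E1", rep = rep(1:2, each = 30), block = 1,
                  trait = "t",
                  value = rep(rnorm(30, 50, 3), 2) + rnorm(60))
  s1b <- step1_blues(d)
  two_plot_mean <- tapply(d$value, d$genotype, mean)
  expect_equal(s1b$blues[names(two_plot_mean), "E1"], c(two_plot_mean),
               tolerance = 1e-6)
})

test_that("stage-1 BLUEs match a direct GLS solve at the fitted variances", {
  tr <- fx_trial()
  d <- as.data.frame(tr[tr$env == tr$env[1], ])
  d$genotype <- factor(d$genotype)
  d$repf <- factor(d$rep)
  d$blk <- factor(paste(d$rep, d$block))
  fit <- reml_fit(value ~ 0 + genotype + (1 | rep) + (1 | rep:block), d)
  vc <- fit$varcomp
  v_of <- function(t) vc$variance[match(t, vc$term)]
  Zr <- stats::model.matrix(~ 0 + repf, d)
  Zb <- stats::model.matrix(~ 0 + blk, d)
  V <- v_of("rep") * tcrossprod(Zr) + v_of("rep:block") * tcrossprod(Zb) +
    v_of("Residual") * diag(nrow(d))
  G <- stats::model.matrix(~ 0 + genotype, d)
  Vi <- solve(V)
  beta <- solve(t(G) %*% Vi %*% G, t(G) %*% Vi %*% d$value)
  expect_equal(unname(fit$fixef), unname(drop(beta)), tolerance = 1e-5)
})

test_that("stage 2 separates genotypic variance from the effective error", {
  # identical BLUEs in both environments: no interaction, common-value BLUEs
  B <- matrix(rep(rnorm(20, 10), 2), 20, 2,
              dimnames = list(sprintf("G%02d", 1:20), c("E1", "E2")))
  vc <- step2_fit(B, "random", n_rep = 2)
  expect_lt(vc$effective_error, 1e-8)
  blue <- step2_fit(B, "fixed")
  expect_equal(unname(blue), unname(B[, 1]), tolerance = 1e-6)

  # balanced data: across-environment BLUE is the mean of per-env BLUEs
  s1 <- step1_blues(fx_trial())
  across <- step2_fit(s1, "fixed")
  expect_equal(unname(across), unname(rowMeans(s1$blues)), tolerance = 1e-6)

  expect_error(step2_fit(B[, 1, drop = FALSE], "random"), "2 environments")
})

test_that("genotype-fixed BLUEs and genotype-random BLUPs correlate perfectly when balanced", {
  s1 <- step1_blues(fx_trial())
  B <- s1$blues
  long <- data.frame(genotype = rep(rownames(B), ncol(B)),
                     env = rep(colnames(B), each = nrow(B)),
                     value = as.vector(B))
  fit <- reml_fit(value ~ 1 + (1 | genotype) + (1 | env), long)
  blup <- fit$ranef$genotype[rownames(B), 1]
  blue <- step2_fit(s1, "fixed")
  expect_gt(stats::cor(blup, blue[rownames(B)]), 1 - 1e-8)
})

test_that("heritability reproduces its defining formula and is monotone", {
  expect_equal(heritability(3.33, 8.40, 3.48, n_env = 9, n_rep = 2),
               3.33 / (3.33 + 8.40 / 9 + 3.48 / 18))
  expect_equal(heritability(1, 0, 0, 5, 2), 1)   # noiseless limit
  # monotone: increasing in n_env, n_rep, sigma2_G; decreasing in noise
  h <- function(...) heritability(...)
  expect_gt(h(3, 8, 3, 9, 2), h(3, 8, 3, 5, 2))
  expect_gt(h(3, 8, 3, 9, 3), h(3, 8, 3, 9, 2))
  expect_gt(h(4, 8, 3, 9, 2), h(3, 8, 3, 9, 2))
  expect_lt(h(3, 9, 3, 9, 2), h(3, 8, 3, 9, 2))
  expect_lt(h(3, 8, 4, 9, 2), h(3, 8, 3, 9, 2))
  expect_error(heritability(0, 0, 0, 9, 2), "undefined")
  expect_error(heritability(-1, 8, 3, 9, 2), "non-negative")
})

test_that("repeatability follows the within-environment broad-sense form", {
  expect_equal(repeatability(0, 2, 2), 0)
  expect_equal(repeatability(3, 0, 2), 1)
  expect_equal(repeatability(1, 2, 2), 0.5)
  expect_error(repeatability(0, 0, 2), "undefined")
})

test_that("the G x E ratio matches direct arithmetic", {
  expect_equal(ge_ratio(3.33, 8.40), 8.40 / (3.33 + 8.40))
  expect_equal(ge_ratio(5, 0), 0)
  expect_error(ge_ratio(0, 0), "undefined")
})

test_that("closed-form h2 from a balanced BLUE matrix matches REML", {
  s1 <- step1_blues(fx_trial())
  B <- s1$blues
  h2 <- h2_from_blues(B)
  long <- data.frame(genotype = rep(rownames(B), ncol(B)),
                     env = rep(colnames(B), each = nrow(B)),
                     value = as.vector(B))
  fit <- reml_fit(value ~ 1 + (1 | genotype) + (1 | env), long)
  s2g <- fit$varcomp$variance[fit$varcomp$term == "genotype"]
  s2r <- fit$varcomp$variance[fit$varcomp$term == "Residual"]
  expect_equal(attr(h2, "sigma2_G"), s2g, tolerance = 1e-3)
  expect_equal(attr(h2, "effective_error"), s2r, tolerance = 1e-3)
  expect_equal(as.numeric(h2), s2g / (s2g + s2r / ncol(B)), tolerance = 1e-3)
})
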