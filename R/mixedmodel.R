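#' Fit a linear mixed model by REML
#'
#' Thin wrapper around [lme4::lmer()] (REML) that returns the quantities the
#' phenotypic analysis needs: fixed-effect solutions, variance components and
#' BLUPs of the random effects. Degenerate data with a constant response are
#' handled directly (all variances zero, mean equal to the constant).
#'
#' @param formula An lmer-style formula with at least one random term.
#' @param data Data frame.
#' @return Object of class `reml_fit`: list with `fixef`, `varcomp` (data
#'   frame `term`, `variance`; the residual appears as term "Residual"),
#'   `ranef` (list of BLUP vectors), `logLik` (restricted), `converged`, and
#'   the underlying `fit` (or NULL for the degenerate constant-response case).
#' @examples
#' d <- data.frame(g = gl(4, 5), y = rnorm(20))
#' reml_fit(y ~ (1 | g), d)$varcomp
#' @export
reml_fit <- function(formula, data) {
  resp <- eval(formula[[2]], data, environment(formula))
  v_resp <- stats::var(resp)
  if (is.na(v_resp)) v_resp <- 0
  if (v_resp < .Machine$double.eps * max(1, mean(resp)^2)) {
    bars <- lme4::findbars(formula)
    terms <- vapply(bars, function(b) deparse(b[[3]]), "")
    vc <- data.frame(term = c(terms, "Residual"),
                     variance = 0, stringsAsFactors = FALSE)
    return(structure(list(fixef = c(`(Intercept)` = resp[1]), varcomp = vc,
                          ranef = NULL, logLik = NA_real_, converged = TRUE,
                          fit = NULL), class = "reml_fit"))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vc <- data.frame(term = vc$grp, variance = vc$vcov, stringsAsFactors = FALSE)
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  structure(list(fixef = lme4::fixef(fit), varcomp = vc,
                 ranef = lme4::ranef(fit), logLik = as.numeric(stats::logLik(fit)),
                 converged = conv, fit = fit),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit; variance components:\n")
  print(x$varcomp, row.names = FALSE)
  invisible(x)
}

variance_of <- function(fit, term) {
  i <- match(term, fit$varcomp$term)
  if (is.na(i)) 0 else fit$varcomp$variance[i]
}

# formula for one environment's plot data; rep/block terms included only when
# they vary
step1_formula <- function(d, genotype_fixed = TRUE) {
  rand <- character(0)
  if (length(unique(d$rep)) > 1) rand <- c(rand, "(1 | rep)")
  if (length(unique(paste(d$rep, d$block))) > length(unique(d$rep)))
    rand <- c(rand, "(1 | rep:block)")
  fixed <- if (genotype_fixed) "0 + genotype" else "1 + (1 | genotype)"
  stats::as.formula(paste("value ~", paste(c(fixed, rand), collapse = " + ")))
}

#' Stage-1 analysis: per-environment BLUEs and repeatability
#'
#' For every environment the plot data are analysed with the model
#' `value = mu + genotype + rep + block(rep) + error`, genotype fixed and the
#' design terms random, yielding the genotype BLUEs of that environment. A
#' second fit with genotype random provides the within-environment genotypic
#' and error variances and the repeatability r = s2g / (s2g + s2e / n_rep).
#'
#' @param trial A `trial_data` data frame (or any long-format data frame with
#'   columns `genotype`, `env`, `rep`, `block`, `value`).
#' @return Object of class `blue_table`: list with `blues` (genotype x
#'   environment matrix; `NA` where a genotype was absent), `env_vc` (data
#'   frame `env`, `sigma2_g`, `sigma2_e`, `repeatability`), `n_rep`, `trait`.
#' @export
step1_blues <- function(trial) {
  envs <- unique(trial$env)
  genos <- unique(trial$genotype)
  B <- matrix(NA_real_, length(genos), length(envs),
              dimnames = list(genos, envs))
  vc <- data.frame(env = envs, sigma2_g = NA_real_, sigma2_e = NA_real_,
                   repeatability = NA_real_, stringsAsFactors = FALSE)
  n_rep <- max(trial$rep)
  for (e in seq_along(envs)) {
    d <- trial[trial$env == envs[e], , drop = FALSE]
    d$genotype <- factor(d$genotype, levels = genos[genos %in% d$genotype])
    within_var <- tapply(d$value, d$genotype, stats::var)
    if (max(within_var, na.rm = TRUE) < 1e-12) {
      # noiseless plots: BLUE is the plot value itself
      mu <- tapply(d$value, d$genotype, mean)
      B[names(mu), e] <- mu
      vc$sigma2_g[e] <- stats::var(mu)
      vc$sigma2_e[e] <- 0
      vc$repeatability[e] <- if (vc$sigma2_g[e] > 0) 1 else NA_real_
      next
    }
    ff <- reml_fit(step1_formula(d, TRUE), d)
    blue <- ff$fixef
    names(blue) <- sub("^genotype", "", names(blue))
    B[names(blue), e] <- blue
    fr <- reml_fit(step1_formula(d, FALSE), d)
    s2g <- variance_of(fr, "genotype")
    s2e <- variance_of(fr, "Residual")
    vc$sigma2_g[e] <- s2g
    vc$sigma2_e[e] <- s2e
    vc$repeatability[e] <- repeatability(s2g, s2e, n_rep)
  }
  structure(list(blues = B, env_vc = vc, n_rep = n_rep,
                 trait = trial$trait[1] %||% NA_character_),
            class = "blue_table")
}

#' @export
print.blue_table <- function(x, ...) {
  cat("Stage-1 BLUEs:", nrow(x$blues), "genotypes x", ncol(x$blues),
      "environments\n")
  print(x$env_vc, row.names = FALSE)
  invisible(x)
}

#' Stage-2 analysis: across-environment BLUEs or variance components
#'
#' Takes the stage-1 per-environment BLUEs (one record per genotype and
#' environment) and fits `blue = mu + genotype + env + residual` with the
#' environment random. With genotype fixed the solutions are the
#' across-environment BLUEs used as the response of genomic prediction. With
#' genotype random the fit yields the genotypic variance and the stage-2
#' residual, which is the effective error of an entry mean in one environment
#' (s2_GE + s2_e / n_rep). When the stage-1 per-environment error variances
#' are available the two components are separated as
#' s2_e = mean(per-env error), s2_GE = residual - s2_e / n_rep (clamped at 0).
#'
#' @param blues A `blue_table` from [step1_blues()], or a genotype x
#'   environment matrix.
#' @param genotype_role "fixed" for across-environment BLUEs, "random" for
#'   variance components.
#' @param n_rep Replications per environment (taken from the `blue_table` if
#'   available).
#' @return For "fixed": named vector of across-environment BLUEs. For
#'   "random": object of class `varcomp` with `sigma2_G`, `sigma2_GE`,
#'   `sigma2_e`, `effective_error`, `n_env`, `n_rep`.
#' @export
step2_fit <- function(blues, genotype_role = c("fixed", "random"),
                      n_rep = NULL) {
  genotype_role <- match.arg(genotype_role)
  env_vc <- NULL
  if (inherits(blues, "blue_table")) {
    n_rep <- n_rep %||% blues$n_rep
    env_vc <- blues$env_vc
    B <- blues$blues
  } else B <- as.matrix(blues)
  if (ncol(B) < 2)
    stop("at least 2 environments are required; G x E is inestimable from one",
         call. = FALSE)
  long <- data.frame(genotype = rep(rownames(B), ncol(B)),
                     env = rep(colnames(B), each = nrow(B)),
                     value = as.vector(B), stringsAsFactors = FALSE)
  long <- long[!is.na(long$value), ]
  if (genotype_role == "fixed") {
    long$genotype <- factor(long$genotype, levels = rownames(B))
    fit <- reml_fit(value ~ 0 + genotype + (1 | env), long)
    blue <- fit$fixef
    names(blue) <- sub("^genotype", "", names(blue))
    return(blue[rownames(B)])
  }
  fit <- reml_fit(value ~ 1 + (1 | genotype) + (1 | env), long)
  omega2 <- variance_of(fit, "Residual")
  s2e <- if (!is.null(env_vc)) mean(env_vc$sigma2_e) else NA_real_
  s2ge <- if (is.na(s2e) || is.null(n_rep)) NA_real_ else
    max(0, omega2 - s2e / n_rep)
  structure(list(sigma2_G = variance_of(fit, "genotype"),
                 sigma2_GE = s2ge, sigma2_e = s2e,
                 effective_error = omega2,
                 n_env = ncol(B), n_rep = n_rep %||% NA_integer_,
                 source = "two-step"),
            class = "varcomp")
}

#' Variance components from plot data by single-pass REML
#'
#' Fits the full plot-level model
#' `value = mu + genotype + env + genotype:env + rep(env) + block(rep) + error`
#' with all terms random, the direct REML analogue of the two-stage analysis.
#' This separates the genotypic, genotype-by-environment and plot-error
#' variances without the stage-2 confounding.
#'
#' @param trial A `trial_data` data frame.
#' @return Object of class `varcomp` (see [step2_fit()]), `source = "plot"`.
#' @export
varcomp_trial <- function(trial) {
  d <- as.data.frame(trial)
  d$ge <- interaction(d$genotype, d$env, drop = TRUE)
  d$er <- interaction(d$env, d$rep, drop = TRUE)
  d$erb <- interaction(d$env, d$rep, d$block, drop = TRUE)
  n_env <- length(unique(d$env))
  if (n_env < 2)
    stop("at least 2 environments are required to estimate G x E", call. = FALSE)
  rand <- c("(1 | genotype)", "(1 | env)", "(1 | ge)")
  if (nlevels(d$er) > n_env) rand <- c(rand, "(1 | er)")
  if (nlevels(d$erb) > nlevels(d$er)) rand <- c(rand, "(1 | erb)")
  fit <- reml_fit(stats::as.formula(paste("value ~ 1 +",
                                          paste(rand, collapse = " + "))), d)
  structure(list(sigma2_G = variance_of(fit, "genotype"),
                 sigma2_GE = variance_of(fit, "ge"),
                 sigma2_e = variance_of(fit, "Residual"),
                 effective_error = variance_of(fit, "ge") +
                   variance_of(fit, "Residual") / max(d$rep),
                 n_env = n_env, n_rep = max(d$rep), source = "plot"),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("Variance components (%s): s2_G = %.4g, s2_GE = %.4g, s2_e = %.4g\n",
              x$source, x$sigma2_G, x$sigma2_GE, x$sigma2_e))
  h2 <- tryCatch(heritability(x), error = function(e) NA_real_)
  if (!is.na(h2))
    cat(sprintf("h2 = %.3f over %d environments x %d reps\n",
                h2, x$n_env, x$n_rep))
  invisible(x)
}

#' Broad-sense heritability of entry means
#'
#' h2 = s2_G / (s2_G + s2_GE / n_env + s2_e / (n_env * n_rep)), the
#' proportion of the variance of across-environment entry means that is
#' genotypic.
#'
#' @param x Genotypic variance, or a `varcomp` object.
#' @param sigma2_GE,sigma2_e,n_env,n_rep Remaining components and trial
#'   dimensions (ignored when `x` is a `varcomp`).
#' @return h2 in [0, 1].
#' @examples
#' heritability(3.33, 8.40, 3.48, n_env = 9, n_rep = 2)  # 0.75
#' @export
heritability <- function(x, sigma2_GE = NULL, sigma2_e = NULL,
                         n_env = NULL, n_rep = NULL) {
  if (inherits(x, "varcomp")) {
    sigma2_GE <- x$sigma2_GE; sigma2_e <- x$sigma2_e
    n_env <- x$n_env; n_rep <- x$n_rep
    x <- x$sigma2_G
  }
  stopifnot(n_env >= 1, n_rep >= 1)
  if (any(c(x, sigma2_GE, sigma2_e) < 0))
    stop("variance components must be non-negative", call. = FALSE)
  denom <- x + sigma2_GE / n_env + sigma2_e / (n_env * n_rep)
  if (denom == 0) stop("all variance components are zero; h2 undefined",
                       call. = FALSE)
  x / denom
}

#' Repeatability (within-environment broad-sense heritability)
#'
#' r = s2_g / (s2_g + s2_e / n_rep) on a plot-mean basis within one
#' environment.
#'
#' @param sigma2_g,sigma2_e Within-environment genotypic and error variances.
#' @param n_rep Replications.
#' @return r in [0, 1].
#' @export
repeatability <- function(sigma2_g, sigma2_e, n_rep) {
  if (sigma2_g < 0 || sigma2_e < 0)
    stop("variances must be non-negative", call. = FALSE)
  denom <- sigma2_g + sigma2_e / n_rep
  if (denom == 0) stop("zero denominator; repeatability undefined", call. = FALSE)
  sigma2_g / denom
}

#' Ratio of genotype-by-environment interaction variance
#'
#' ratio = s2_GE / (s2_G + s2_GE), the share of the genetic-plus-interaction
#' variance that is environment-specific. Large values flag traits whose
#' prediction accuracy transfers poorly to new locations or years.
#'
#' @param x Genotypic variance or a `varcomp` object.
#' @param sigma2_GE Interaction variance (ignored when `x` is a `varcomp`).
#' @return Ratio in [0, 1].
#' @examples
#' ge_ratio(3.33, 8.40)  # 0.72
#' @export
ge_ratio <- function(x, sigma2_GE = NULL) {
  if (inherits(x, "varcomp")) {
    sigma2_GE <- x$sigma2_GE
    x <- x$sigma2_G
  }
  if (x < 0 || sigma2_GE < 0)
    stop("variances must be non-negative", call. = FALSE)
  if (x + sigma2_GE == 0)
    stop("zero denominator; G x E ratio undefined", call. = FALSE)
  sigma2_GE / (x + sigma2_GE)
}

#' Heritability from a balanced BLUE matrix (closed form)
#'
#' For a complete genotype x environment matrix of stage-1 BLUEs the REML
#' estimates of the genotypic variance and the effective error coincide with
#' the two-way ANOVA estimators: with MS_G the genotype mean square and MS_R
#' the residual (interaction) mean square, s2_G = (MS_G - MS_R) / n_env and
#' the effective error is MS_R, giving h2 = s2_G / (s2_G + MS_R / n_env).
#' Used inside cross-validation where it is re-estimated from every
#' estimation set.
#'
#' @param B Complete numeric genotype x environment matrix (>= 2 columns).
#' @param clamp Clamp h2 into `clamp` (default c(0.01, 0.99)) so that the
#'   RR-BLUP penalty stays finite; the unclamped value is returned as
#'   attribute "raw".
#' @return h2 with attributes `sigma2_G` and `effective_error`.
#' @export
h2_from_blues <- function(B, clamp = c(0.01, 0.99)) {
  B <- as.matrix(B)
  if (ncol(B) < 2) stop("need >= 2 environments for h2_from_blues()", call. = FALSE)
  if (anyNA(B)) stop("BLUE matrix must be complete", call. = FALSE)
  nG <- nrow(B); nE <- ncol(B)
  gm <- rowMeans(B); em <- colMeans(B); mu <- mean(B)
  msg <- nE * sum((gm - mu)^2) / (nG - 1)
  resid <- B - outer(gm, rep(1, nE)) - outer(rep(1, nG), em) + mu
  msr <- sum(resid^2) / ((nG - 1) * (nE - 1))
  s2g <- max(0, (msg - msr) / nE)
  h2 <- if (s2g + msr / nE == 0) 0 else s2g / (s2g + msr / nE)
  out <- min(max(h2, clamp[1]), clamp[2])
  attr(out, "raw") <- h2
  attr(out, "sigma2_G") <- s2g
  attr(out, "effective_error") <- msr
  out
}
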