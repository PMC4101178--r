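#' Predictive ability (Pearson correlation)
#'
#' r_p between observed and predicted values; returns `NA` with attribute
#' `degenerate = TRUE` when either vector has zero variance (never a silent 0).
#'
#' @param observed,predicted Equal-length numeric vectors (>= 3 pairs).
#' @return r_p in [-1, 1], or NA flagged degenerate.
#' @export
accuracy <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("`observed` and `predicted` differ in length", call. = FALSE)
  if (length(observed) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(observed) == 0 || stats::var(predicted) == 0)
    return(structure(NA_real_, degenerate = TRUE))
  stats::cor(observed, predicted)
}

#' Standardized accuracy of prediction
#'
#' r_g = r_p / sqrt(h2): predictive ability calibrated by the square root of
#' heritability, estimating the correlation with the true genotypic values.
#'
#' @param r_p Predictive ability.
#' @param h2 Heritability in (0, 1].
#' @return r_g.
#' @export
standardize_accuracy <- function(r_p, h2) {
  if (!is.numeric(h2) || any(h2 <= 0) || any(h2 > 1))
    stop("`h2` must be in (0, 1]", call. = FALSE)
  r_p / sqrt(h2)
}

#' Random k-fold partition of genotypes
#'
#' Partitions ids into k subsets whose sizes differ by at most one. In the
#' cross-validation schemes, folds S1-S4 form the estimation set and S5 the
#' test set.
#'
#' @param ids Vector of genotype ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed (optional; the CV engine manages the RNG stream).
#' @return Integer vector of fold labels (1..k) named by `ids`.
#' @export
make_folds <- function(ids, k = 5, seed = NULL) {
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (k > length(ids)) stop("more folds than genotypes", call. = FALSE)
  set_seed_if(seed)
  f <- sample(rep(seq_len(k), length.out = length(ids)))
  names(f) <- ids
  f
}

#' Assemble the inputs of the cross-validation engine
#'
#' Runs the stage-1 analysis on the trial and aligns the per-environment BLUE
#' matrix with the (QC'd, imputed) marker matrix. All cross-validation
#' drivers operate on the resulting container.
#'
#' @param trial A `trial_data` data frame.
#' @param markers A `marker_set` with no missing entries covering the trial's
#'   genotypes.
#' @param blues Optional precomputed [step1_blues()] result for `trial`.
#' @return Object of class `gs_data`: `B` (genotype x environment BLUEs),
#'   `X` (dosage matrix), `map`, `population` (per line), `env_meta`
#'   (env/location/year), `env_vc`, `n_rep`.
#' @export
prepare_gs_data <- function(trial, markers, blues = NULL) {
  stopifnot(inherits(markers, "marker_set"))
  if (anyNA(markers$geno))
    stop("markers contain missing calls; run impute_missing()", call. = FALSE)
  s1 <- blues %||% step1_blues(trial)
  B <- s1$blues
  common <- intersect(rownames(B), rownames(markers$geno))
  if (length(common) < 10)
    stop("trial and marker set share too few genotypes", call. = FALSE)
  B <- B[common, , drop = FALSE]
  X <- markers$geno[common, , drop = FALSE]
  pop <- markers$population[match(common, rownames(markers$geno))]
  env_meta <- unique(as.data.frame(trial)[, c("env", "location", "year")])
  env_meta <- env_meta[match(colnames(B), env_meta$env), ]
  rownames(env_meta) <- NULL
  structure(list(B = B, X = X, map = markers$map, population = pop,
                 env_meta = env_meta, env_vc = s1$env_vc, n_rep = s1$n_rep),
            class = "gs_data")
}

#' @export
print.gs_data <- function(x, ...) {
  cat("GS data:", nrow(x$B), "genotypes,", ncol(x$B), "environments,",
      ncol(x$X), "markers\n")
  invisible(x)
}

# One replicate's predictor dispatch. `predictor` is "rrblup", "mas_qtl",
# "mas_neut", or a function(y_es, X_es, X_ts, h2_es, data, es, ts) -> pred.
fit_and_predict <- function(predictor, y_es, X_es, X_ts, h2_es, data,
                            es, ts, regressors = NULL, n_qtl_neut = 7,
                            lod_threshold = 3.73, ...) {
  if (is.function(predictor))
    return(list(pred = predictor(y_es, X_es, X_ts, h2_es, data, es, ts),
                n_qtl = NA_integer_))
  switch(predictor,
    rrblup = {
      lambda <- lambda_from_h2(ncol(X_es), h2_es)
      fit <- rrblup(y_es, X_es, lambda)
      list(pred = predict(fit, X_ts), n_qtl = NA_integer_)
    },
    mas_qtl = {
      scan <- cim_scan(X_es, y_es, data$map, lod_threshold = lod_threshold,
                       regressors = regressors, ...)
      mp <- mas_qtl_predict(scan, X_es, y_es, X_ts, data$map)
      list(pred = mp$pred, n_qtl = mp$n_qtl)
    },
    mas_neut = {
      ids <- sample_neutral_markers(n_qtl_neut, data$map)
      df_tr <- data.frame(y = y_es, X_es[, ids, drop = FALSE])
      fit <- stats::lm(y ~ ., data = df_tr)
      pred <- drop(stats::predict(fit,
                                  newdata = as.data.frame(X_ts[, ids, drop = FALSE])))
      list(pred = pred, n_qtl = length(ids))
    },
    stop("unknown predictor: ", predictor, call. = FALSE)
  )
}

cv_summarize <- function(reps, scheme, predictor, n_excluded, extra = NULL) {
  structure(c(list(replicates = reps, scheme = scheme,
                   predictor = if (is.function(predictor)) "custom" else predictor,
                   n_excluded = n_excluded), extra),
            class = "cv_result")
}

#' @export
summary.cv_result <- function(object, ...) {
  r <- object$replicates
  num <- function(v) c(median = stats::median(v, na.rm = TRUE),
                       q1 = unname(stats::quantile(v, 0.25, na.rm = TRUE)),
                       q3 = unname(stats::quantile(v, 0.75, na.rm = TRUE)),
                       mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  out <- rbind(r_p = num(r$r_p), r_g = num(r$r_g))
  structure(list(stats = out, n = nrow(r), scheme = object$scheme,
                 predictor = object$predictor,
                 n_excluded = object$n_excluded), class = "summary.cv_result")
}

#' @export
print.summary.cv_result <- function(x, ...) {
  cat(sprintf("CV scheme %s / predictor %s: %d replicates (%d degenerate excluded)\n",
              x$scheme, x$predictor, x$n, x$n_excluded))
  print(round(x$stats, 3))
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Box-plot comparison of cross-validation accuracy distributions
#'
#' Draws side-by-side box plots of the per-replicate accuracies of one or
#' more `cv_result` objects, the standard display for comparing predictors or
#' schemes.
#'
#' @param x A `cv_result`.
#' @param ... Further `cv_result` objects to compare against `x`.
#' @param measure "r_p" (predictive ability) or "r_g" (standardized).
#' @return The list of per-replicate vectors, invisibly.
#' @export
plot.cv_result <- function(x, ..., measure = c("r_p", "r_g")) {
  measure <- match.arg(measure)
  objs <- c(list(x), Filter(function(o) inherits(o, "cv_result"), list(...)))
  vals <- lapply(objs, function(o) o$replicates[[measure]])
  names(vals) <- vapply(objs, function(o)
    paste(o$scheme, o$predictor, sep = "\n"), "")
  graphics::boxplot(vals, ylab = measure)
  invisible(vals)
}

# shared replicate core: given ES/TS genotype indices and the environment
# columns for ES and TS, compute one replicate's accuracies
cv_replicate <- function(data, es, ts, es_envs, ts_envs, predictor,
                         regressors, h2_override = NULL, ...) {
  Bes <- data$B[es, es_envs, drop = FALSE]
  y_es <- rowMeans(Bes)
  h2_es <- if (!is.null(h2_override)) h2_override else
    as.numeric(h2_from_blues(Bes))
  obs <- rowMeans(data$B[ts, ts_envs, drop = FALSE])
  fp <- fit_and_predict(predictor, y_es, data$X[es, , drop = FALSE],
                        data$X[ts, , drop = FALSE], h2_es, data, es, ts,
                        regressors = regressors, ...)
  r_p <- accuracy(obs, fp$pred)
  data.frame(r_p = as.numeric(r_p),
             r_g = as.numeric(r_p) / sqrt(h2_es),
             h2_es = h2_es, n_qtl = fp$n_qtl,
             degenerate = isTRUE(attr(r_p, "degenerate")))
}

#' Cross-validation over genotypes within and across populations
#'
#' Implements the genotype-sampling schemes: per replicate the genotypes are
#' split into five subsets of which four form the estimation set (ES) and one
#' the test set (TS). Marker effects are fit on the ES only; the heritability
#' used for the RR-BLUP penalty and for r_g is re-estimated from the ES of
#' every replicate.
#'
#' Schemes:
#' \describe{
#'   \item{within_within_same}{ES and TS folds from one population.}
#'   \item{within_within_different}{ES is the whole of `population`, TS the
#'     whole of the other population (no fold sampling; replicates coincide).}
#'   \item{across_across}{Folds drawn over the pooled lines, stratified by
#'     population when `stratify = TRUE`.}
#'   \item{across_within}{Folds drawn within each population; ES pools the
#'     S1-S4 folds of both, TS is the held-out fold of `population`.}
#' }
#'
#' @param data A `gs_data` from [prepare_gs_data()].
#' @param scheme One of the schemes above.
#' @param predictor "rrblup", "mas_qtl", "mas_neut", or a function
#'   `(y_es, X_es, X_ts, h2_es, data, es, ts) -> predictions`.
#' @param population Focal population label (ES for within-within-different;
#'   TS fold source otherwise).
#' @param n_resamples Number of resampled ES/TS splits.
#' @param n_folds Number of subsets (default 5).
#' @param seed Integer seed for the whole run.
#' @param stratify Balance across-across folds by population.
#' @param ... Passed to the predictor (e.g. `n_qtl_neut`, `lod_threshold`).
#' @return A `cv_result`: per-replicate data frame of r_p, r_g and the ES
#'   heritability, plus metadata; degenerate replicates are excluded from
#'   summaries and counted.
#' @export
run_cv_population <- function(data, scheme = c("within_within_same",
                                               "within_within_different",
                                               "across_across",
                                               "across_within"),
                              predictor = "rrblup", population = "A",
                              n_resamples = 100, n_folds = 5, seed = 1,
                              stratify = TRUE, ...) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(data, "gs_data"))
  set_seed_if(seed)
  pops <- unique(data$population)
  if (scheme != "within_within_same" && length(pops) < 2)
    stop("scheme ", scheme, " needs two populations", call. = FALSE)
  all_envs <- colnames(data$B)
  regress <- if (identical(predictor, "mas_qtl"))
    qtl_regressors(data$X, data$map) else NULL

  idx_pop <- function(p) which(data$population == p)
  other <- if (length(pops) > 1) setdiff(pops, population)[1] else NA

  reps <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    if (scheme == "within_within_same") {
      i <- idx_pop(population)
      f <- make_folds(i, n_folds)
      ts <- i[f == n_folds]; es <- i[f != n_folds]
    } else if (scheme == "within_within_different") {
      es <- idx_pop(population); ts <- idx_pop(other)
    } else if (scheme == "across_across") {
      if (stratify) {
        f <- integer(nrow(data$B))
        for (p in pops) f[idx_pop(p)] <- make_folds(idx_pop(p), n_folds)
      } else f <- make_folds(seq_len(nrow(data$B)), n_folds)
      ts <- which(f == n_folds); es <- which(f != n_folds)
    } else { # across_within
      f <- integer(nrow(data$B))
      for (p in pops) f[idx_pop(p)] <- make_folds(idx_pop(p), n_folds)
      es <- which(f != n_folds)
      ts <- intersect(which(f == n_folds), idx_pop(population))
    }
    reps[[b]] <- cv_replicate(data, es, ts, all_envs, all_envs, predictor,
                              regress, ...)
  }
  reps <- do.call(rbind, reps)
  reps$replicate <- seq_len(nrow(reps))
  n_excl <- sum(reps$degenerate)
  cv_summarize(reps, scheme, predictor, n_excl,
               extra = list(population = population, n_folds = n_folds,
                            seed = seed))
}

#' Cross-validation with a limited number of environments
#'
#' Per replicate, `k_env` environments are drawn at random; estimation- and
#' test-set BLUEs are both computed from those environments only, and the
#' genotypes are split 5-fold within `population`. With `k_env = 1` the ES
#' heritability cannot be separated from the environment mean, so the
#' stage-1 repeatability of the drawn environment is used for the penalty
#' and for r_g.
#'
#' @inheritParams run_cv_population
#' @param k_env Number of environments to include (1 to the number available).
#' @return A `cv_result`.
#' @export
run_cv_env <- function(data, k_env, predictor = "rrblup", population = "A",
                       n_resamples = 100, n_folds = 5, seed = 1, ...) {
  stopifnot(inherits(data, "gs_data"))
  all_envs <- colnames(data$B)
  if (k_env > length(all_envs))
    stop("`k_env` exceeds the available environments", call. = FALSE)
  if (k_env < 1) stop("`k_env` must be >= 1", call. = FALSE)
  set_seed_if(seed)
  i_pop <- which(data$population == population)
  regress <- if (identical(predictor, "mas_qtl"))
    qtl_regressors(data$X, data$map) else NULL

  reps <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    envs <- sample(all_envs, k_env)
    f <- make_folds(i_pop, n_folds)
    ts <- i_pop[f == n_folds]; es <- i_pop[f != n_folds]
    h2o <- NULL
    if (k_env == 1) {
      r <- data$env_vc$repeatability[data$env_vc$env == envs]
      h2o <- min(max(r, 0.01, na.rm = TRUE), 0.99)
    }
    reps[[b]] <- cv_replicate(data, es, ts, envs, envs, predictor, regress,
                              h2_override = h2o, ...)
  }
  reps <- do.call(rbind, reps)
  reps$replicate <- seq_len(nrow(reps))
  cv_summarize(reps, sprintf("env_k%d", k_env), predictor,
               sum(reps$degenerate),
               extra = list(population = population, k_env = k_env,
                            seed = seed))
}

#' Cross-validation across locations and years
#'
#' Implements the location/year transfer schemes. Estimation-set data come
#' from two randomly chosen locations over both years (location modes) or
#' from one randomly chosen year at the locations with complete two-year
#' data (year modes); test-set data come either from the same environments
#' (`G_L`, `G_Y`) or from the complementary locations/year (`GxL`, `GxY`).
#' Genotype folds are disjoint in every mode. Environments listed in
#' `exclude_env` are never used in a test set (the trial-network convention
#' of dropping a low-quality environment).
#'
#' @inheritParams run_cv_population
#' @param mode One of "G_L", "GxL", "G_Y", "GxY".
#' @param exclude_env Environment keys excluded from test sets (default
#'   "HOH10", the incomplete location of the nine-environment network).
#' @return A `cv_result`.
#' @export
run_cv_location_year <- function(data, mode = c("G_L", "GxL", "G_Y", "GxY"),
                                 predictor = "rrblup", population = "A",
                                 n_resamples = 100, n_folds = 5, seed = 1,
                                 exclude_env = "HOH10", ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "gs_data"))
  em <- data$env_meta
  years <- unique(em$year)
  tab <- table(em$location)
  complete_locs <- names(tab)[tab == length(years)]
  if (length(years) < 2 || length(complete_locs) < 4)
    stop("location/year schemes need >= 4 locations with complete two-year data",
         call. = FALSE)
  set_seed_if(seed)
  i_pop <- which(data$population == population)
  regress <- if (identical(predictor, "mas_qtl"))
    qtl_regressors(data$X, data$map) else NULL

  reps <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    if (mode %in% c("G_L", "GxL")) {
      locs <- sample(complete_locs, 2)
      es_envs <- em$env[em$location %in% locs]
      ts_envs <- if (mode == "G_L") es_envs else
        setdiff(em$env[!(em$location %in% locs)], exclude_env)
    } else {
      yr <- sample(years, 1)
      es_envs <- em$env[em$year == yr & em$location %in% complete_locs]
      ts_envs <- if (mode == "G_Y")
        setdiff(em$env[em$year == yr], exclude_env) else
        setdiff(em$env[em$year != yr & em$location %in% complete_locs],
                exclude_env)
    }
    f <- make_folds(i_pop, n_folds)
    ts <- i_pop[f == n_folds]; es <- i_pop[f != n_folds]
    reps[[b]] <- cv_replicate(data, es, ts, es_envs, ts_envs, predictor,
                              regress, ...)
  }
  reps <- do.call(rbind, reps)
  reps$replicate <- seq_len(nrow(reps))
  cv_summarize(reps, mode, predictor, sum(reps$degenerate),
               extra = list(population = population, seed = seed,
                            exclude_env = exclude_env))
}
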