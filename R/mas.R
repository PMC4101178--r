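#' QTL regressors on a cM grid from flanking markers
#'
#' For every grid position the putative-QTL dosage is approximated by the
#' best linear predictor from the two flanking markers, with correlations
#' taken as 1 - 2 theta under the Haldane map function (no interference, so
#' the flanking-marker correlation factorizes). At a marker position the
#' regressor reduces exactly to that marker's dosage; beyond the terminal
#' markers the single nearest flank is used. Weights depend only on the map,
#' so the regressor matrix can be computed once per population and rows
#' subset per cross-validation replicate.
#'
#' @param geno Lines x markers dosage matrix (no missing values).
#' @param map Genetic map matching the columns of `geno`.
#' @param step Grid step in cM (marker positions are always included).
#' @return List with `Z` (lines x positions regressor matrix), `grid` (data
#'   frame `chromosome`, `position`, `at_marker`).
#' @export
qtl_regressors <- function(geno, map, step = 1) {
  stopifnot(identical(colnames(geno), map$marker_id))
  if (anyNA(geno)) stop("impute genotypes before scanning", call. = FALSE)
  Zs <- list(); grids <- list()
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    pos <- map$position[idx]
    grid <- sort(unique(c(seq(0, max(pos), by = step), pos)))
    W <- matrix(0, nrow = length(idx), ncol = length(grid))  # marker x grid
    for (j in seq_along(grid)) {
      x <- grid[j]
      i <- findInterval(x, pos)
      hit <- which(pos == x)
      if (length(hit)) {
        W[hit[1], j] <- 1
      } else if (i == 0) {
        W[1, j] <- 1 - 2 * haldane(pos[1] - x)
      } else if (i == length(pos)) {
        W[length(pos), j] <- 1 - 2 * haldane(x - pos[length(pos)])
      } else {
        rL <- 1 - 2 * haldane(x - pos[i])
        rR <- 1 - 2 * haldane(pos[i + 1] - x)
        rLR <- rL * rR
        den <- 1 - rLR^2
        if (den < 1e-12) {
          W[i, j] <- 1
        } else {
          W[i, j] <- (rL - rR * rLR) / den
          W[i + 1, j] <- (rR - rL * rLR) / den
        }
      }
    }
    Zs[[as.character(ch)]] <- geno[, idx, drop = FALSE] %*% W
    grids[[as.character(ch)]] <- data.frame(chromosome = ch, position = grid,
                                            at_marker = grid %in% pos)
  }
  list(Z = do.call(cbind, Zs), grid = do.call(rbind, c(grids, list(make.row.names = FALSE))))
}

# Forward stepwise cofactor selection among markers: at each step the marker
# with the largest partial F given the current model enters if its p-value is
# below `alpha`, up to `max_cofactors`. Returns column indices into geno.
select_cofactors <- function(geno, pheno, alpha = 0.01, max_cofactors = NULL) {
  n <- length(pheno)
  max_cofactors <- max_cofactors %||% floor(n / 5)
  Q <- matrix(1 / sqrt(n), n, 1)          # orthonormal basis of the model
  r <- pheno - Q %*% crossprod(Q, pheno)
  M <- geno - Q %*% crossprod(Q, geno)    # residualized candidates
  chosen <- integer(0)
  while (length(chosen) < max_cofactors && ncol(Q) + 2 <= n) {
    ss <- colSums(M^2)
    ok <- ss > 1e-10
    if (!any(ok)) break
    rho2 <- rep(0, ncol(M))
    rho2[ok] <- (crossprod(r, M)[1, ok])^2 / (sum(r^2) * ss[ok])
    j <- which.max(rho2)
    df2 <- n - ncol(Q) - 1
    Fj <- rho2[j] * df2 / (1 - rho2[j])
    if (stats::pf(Fj, 1, df2, lower.tail = FALSE) >= alpha) break
    chosen <- c(chosen, j)
    q <- M[, j] / sqrt(ss[j])
    Q <- cbind(Q, q)
    r <- r - q * sum(q * r)
    M <- M - q %*% crossprod(q, M)
  }
  sort(chosen)
}

#' Composite interval mapping by the regression approach
#'
#' Scans the genome on a cM grid. Background markers (cofactors) are chosen
#' by forward stepwise regression; at each tested position, cofactors within
#' `window` cM on the same chromosome are dropped from both the reduced and
#' the full model, and the LOD score is
#' LOD = (n / 2) * log10(RSS_reduced / RSS_full). Peaks at or above
#' `lod_threshold`, separated by at least `min_peak_distance` cM (always
#' distinct across chromosomes), are reported as detected QTL. With
#' `cofactor_alpha = 0` no cofactor enters and the scan is plain interval
#' mapping.
#'
#' @param geno Lines x markers dosage matrix (QC'd and imputed).
#' @param pheno Named or positionally matched phenotype vector (BLUEs).
#' @param map Genetic map for the columns of `geno`.
#' @param lod_threshold Detection threshold (default 3.73).
#' @param window Cofactor exclusion window in cM around the tested position.
#' @param step Scan grid step in cM.
#' @param cofactor_alpha Entry p-value for stepwise cofactor selection; 0
#'   disables cofactors.
#' @param max_cofactors Cap on the number of cofactors (default n/5).
#' @param min_peak_distance Minimum cM separation of distinct detected QTL.
#' @param regressors Optional precomputed [qtl_regressors()] for `geno`'s
#'   population (rows are subset to `geno`'s rows by name).
#' @return Object of class `qtl_scan`: `scan` (data frame `chromosome`,
#'   `position`, `lod`, `effect`), `detected` (the QTL list, same columns),
#'   `cofactors` (marker ids), `r2_adj` (adjusted R2 of the joint QTL
#'   model), `threshold`, `n`.
#' @export
cim_scan <- function(geno, pheno, map, lod_threshold = 3.73, window = 10,
                     step = 1, cofactor_alpha = 0.01, max_cofactors = NULL,
                     min_peak_distance = 20, regressors = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (length(pheno) != n)
    stop("phenotypes must match the genotype rows", call. = FALSE)
  if (anyNA(pheno) || anyNA(geno))
    stop("missing values; QC and impute first", call. = FALSE)
  max_cofactors <- max_cofactors %||% floor(n / 5)
  if (n < max(3, 2 + (cofactor_alpha > 0)))
    stop("too few lines for the scan", call. = FALSE)

  if (is.null(regressors)) regressors <- qtl_regressors(geno, map, step)
  Z <- regressors$Z
  if (!is.null(rownames(Z)) && !is.null(rownames(geno)))
    Z <- Z[rownames(geno), , drop = FALSE]
  grid <- regressors$grid

  cof <- if (cofactor_alpha > 0)
    select_cofactors(geno, pheno, cofactor_alpha, max_cofactors) else integer(0)
  if (n < length(cof) + 2)
    stop("fewer lines than cofactors + 2", call. = FALSE)
  cof_chr <- map$chromosome[cof]
  cof_pos <- map$position[cof]

  # exclusion signature per grid position: which cofactors are within `window`
  excl <- lapply(seq_len(nrow(grid)), function(j) {
    which(cof_chr == grid$chromosome[j] & abs(cof_pos - grid$position[j]) <= window)
  })
  sig <- vapply(excl, function(e) paste(e, collapse = ","), "")
  lod <- numeric(nrow(grid)); eff <- rep(NA_real_, nrow(grid))
  for (s in unique(sig)) {
    cols <- which(sig == s)
    drop_idx <- excl[[cols[1]]]
    active <- if (length(drop_idx)) cof[-drop_idx] else cof
    Xr <- cbind(1, geno[, active, drop = FALSE])
    Q <- qr.Q(qr(Xr))
    yres <- pheno - Q %*% crossprod(Q, pheno)
    rss0 <- sum(yres^2)
    Zr <- Z[, cols, drop = FALSE]
    Zres <- Zr - Q %*% crossprod(Q, Zr)
    zz <- colSums(Zres^2)
    zy <- drop(crossprod(Zres, yres))
    ok <- zz > 1e-10 & rss0 > 1e-20
    rho2 <- rep(0, length(cols))
    rho2[ok] <- pmin(zy[ok]^2 / (zz[ok] * rss0), 1 - 1e-12)
    lod[cols] <- -(n / 2) * log10(1 - rho2)
    eff[cols][ok] <- zy[ok] / zz[ok]
  }

  scan <- data.frame(chromosome = grid$chromosome, position = grid$position,
                     lod = lod, effect = eff)
  detected <- pick_peaks(scan, lod_threshold, min_peak_distance)
  r2_adj <- NA_real_
  if (nrow(detected)) {
    at <- match(paste(detected$chromosome, detected$position),
                paste(grid$chromosome, grid$position))
    fitq <- stats::lm(pheno ~ Z[, at, drop = FALSE])
    rss <- sum(stats::resid(fitq)^2)
    tss <- sum((pheno - mean(pheno))^2)
    p_used <- fitq$rank - 1
    r2_adj <- 1 - (rss / tss) * (n - 1) / max(1, n - p_used - 1)
  }
  structure(list(scan = scan, detected = detected,
                 cofactors = colnames(geno)[cof], r2_adj = r2_adj,
                 threshold = lod_threshold, window = window,
                 min_peak_distance = min_peak_distance, n = n,
                 step = step),
            class = "qtl_scan")
}

# greedy peak picking: repeatedly take the highest position at/above the
# threshold and mask everything within min_dist cM on the same chromosome
pick_peaks <- function(scan, threshold, min_dist) {
  cand <- scan[scan$lod >= threshold, , drop = FALSE]
  out <- cand[0, , drop = FALSE]
  while (nrow(cand)) {
    i <- which.max(cand$lod)
    out <- rbind(out, cand[i, ])
    keep <- !(cand$chromosome == cand$chromosome[i] &
                abs(cand$position - cand$position[i]) < min_dist)
    cand <- cand[keep, , drop = FALSE]
  }
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("CIM scan: %d positions, %d cofactors, LOD threshold %.2f\n",
              nrow(x$scan), length(x$cofactors), x$threshold))
  if (nrow(x$detected)) {
    cat(nrow(x$detected), "QTL detected (joint model adj. R2 =",
        round(x$r2_adj, 3), "):\n")
    print(x$detected, row.names = FALSE)
  } else cat("no QTL detected\n")
  invisible(x)
}

#' @export
plot.qtl_scan <- function(x, ...) {
  s <- x$scan
  chr <- unique(s$chromosome)
  offs <- c(0, cumsum(tapply(s$position, s$chromosome, max) + 10))
  xx <- s$position + offs[match(s$chromosome, chr)]
  graphics::plot(xx, s$lod, type = "n",
                 xlab = "map position (cM, chromosomes offset)",
                 ylab = "LOD", ...)
  for (ch in chr) {
    i <- s$chromosome == ch
    graphics::lines(xx[i], s$lod[i])
  }
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Marker-assisted prediction from detected QTL
#'
#' Regresses the training phenotypes on the QTL regressors at the detected
#' positions (multiple regression) and predicts the test lines. When no QTL
#' was detected the prediction is the training mean and R2_cv is 0 (flagged).
#'
#' @param scan A `qtl_scan` from the training lines only (no test-set
#'   phenotypes may enter the detection).
#' @param train_geno,train_pheno Training dosage matrix and phenotypes.
#' @param test_geno Test dosage matrix (same markers).
#' @param map Genetic map shared by both sets.
#' @param test_pheno Optional observed test phenotypes; if given, R2_cv (the
#'   squared Pearson correlation of predicted and observed test values) is
#'   returned.
#' @return List: `pred` (predictions for test lines), `r2_cv`, `n_qtl`,
#'   `degenerate` (TRUE when no QTL or constant predictions).
#' @export
mas_qtl_predict <- function(scan, train_geno, train_pheno, test_geno, map,
                            test_pheno = NULL) {
  stopifnot(inherits(scan, "qtl_scan"))
  det <- scan$detected
  n_test <- nrow(test_geno)
  if (nrow(det) == 0) {
    pred <- rep(mean(train_pheno), n_test)
    return(list(pred = pred, r2_cv = 0, n_qtl = 0L, degenerate = TRUE))
  }
  Ztr <- qtl_at_positions(train_geno, map, det)
  Zte <- qtl_at_positions(test_geno, map, det)
  df_tr <- data.frame(y = train_pheno, Ztr)
  fit <- stats::lm(y ~ ., data = df_tr)
  pred <- drop(stats::predict(fit, newdata = as.data.frame(Zte)))
  degenerate <- stats::var(pred) < 1e-20
  r2_cv <- NA_real_
  if (!is.null(test_pheno)) {
    r2_cv <- if (degenerate || stats::var(test_pheno) == 0) 0 else
      stats::cor(pred, test_pheno)^2
  }
  list(pred = pred, r2_cv = r2_cv, n_qtl = nrow(det), degenerate = degenerate)
}

# regressor columns at arbitrary map positions (same flanking-marker BLP as
# the scan grid), as a data frame with stable names
qtl_at_positions <- function(geno, map, det) {
  Z <- matrix(0, nrow(geno), nrow(det))
  for (q in seq_len(nrow(det))) {
    idx <- which(map$chromosome == det$chromosome[q])
    pos <- map$position[idx]
    x <- det$position[q]
    hit <- which(pos == x)
    if (length(hit)) {
      Z[, q] <- geno[, idx[hit[1]]]
    } else {
      i <- findInterval(x, pos)
      if (i == 0) Z[, q] <- geno[, idx[1]] * (1 - 2 * haldane(pos[1] - x))
      else if (i == length(pos))
        Z[, q] <- geno[, idx[length(pos)]] * (1 - 2 * haldane(x - pos[length(pos)]))
      else {
        rL <- 1 - 2 * haldane(x - pos[i]); rR <- 1 - 2 * haldane(pos[i + 1] - x)
        den <- 1 - (rL * rR)^2
        bL <- (rL - rR * rL * rR) / den; bR <- (rR - rL * rL * rR) / den
        Z[, q] <- geno[, idx[i]] * bL + geno[, idx[i + 1]] * bR
      }
    }
  }
  colnames(Z) <- sprintf("q%d", seq_len(nrow(det)))
  as.data.frame(Z)
}

#' Sample neutral markers across linkage groups
#'
#' Draws the marker set for neutral marker-assisted selection (MAS-NEUT):
#' with up to 7 markers, one random marker from each of `n_qtl` randomly
#' chosen distinct linkage groups; beyond 7, one per group plus additional
#' random markers without replacement.
#'
#' @param n_qtl Number of markers to draw (matches the QTL count of the
#'   MAS-QTL scan it mirrors).
#' @param map Genetic map (every linkage group must carry >= 1 marker).
#' @param seed Integer seed.
#' @return Character vector of marker ids.
#' @export
sample_neutral_markers <- function(n_qtl, map, seed = NULL) {
  if (n_qtl < 1) stop("`n_qtl` must be >= 1", call. = FALSE)
  if (n_qtl > nrow(map))
    stop("more markers requested than exist on the map", call. = FALSE)
  set_seed_if(seed)
  groups <- split(map$marker_id, map$chromosome)
  if (n_qtl <= length(groups)) {
    gs <- sample(names(groups), n_qtl)
    vapply(groups[gs], function(g) if (length(g) == 1) g else sample(g, 1), "")
  } else {
    first <- vapply(groups, function(g) if (length(g) == 1) g else sample(g, 1), "")
    extra <- sample(setdiff(map$marker_id, first), n_qtl - length(groups))
    unname(c(first, extra))
  }
}

#' Standardized accuracy of marker-assisted selection
#'
#' r_g = sqrt(R2_cv / h2): the cross-validated phenotypic variance explained
#' by the QTL model, expressed on the genotypic scale. Values above 1 are
#' capped (attribute "capped").
#'
#' @param r2_cv Cross-validated R2 in [0, 1].
#' @param h2 Heritability in (0, 1].
#' @return Standardized accuracy in [0, 1].
#' @examples
#' mas_accuracy(0.25, 0.75)  # sqrt(1/3)
#' @export
mas_accuracy <- function(r2_cv, h2) {
  stop_if_not_scalar_prob(r2_cv, "r2_cv")
  if (!is.numeric(h2) || h2 <= 0 || h2 > 1)
    stop("`h2` must be in (0, 1]", call. = FALSE)
  rg <- sqrt(r2_cv / h2)
  if (rg > 1) structure(1, capped = TRUE) else rg
}
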