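#' RR-BLUP penalty from heritability
#'
#' The ridge penalty of RR-BLUP is the ratio of the error variance to the
#' per-marker effect variance. With all genetic variance spread over m
#' markers this is lambda = m * (1 - h2) / h2, where h2 is the heritability
#' of the estimation set.
#'
#' @param m Number of markers (>= 1).
#' @param h2 Heritability of the estimation set, strictly inside (0, 1);
#'   vectorized.
#' @return The penalty lambda (> 0).
#' @examples
#' lambda_from_h2(100, 0.5)   # 100
#' lambda_from_h2(394, 0.75)  # 394/3
#' @export
lambda_from_h2 <- function(m, h2) {
  if (!is.numeric(m) || m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (!is.numeric(h2) || !length(h2) || any(!is.finite(h2)) ||
      any(h2 <= 0) || any(h2 >= 1))
    stop("`h2` must lie strictly inside (0, 1)", call. = FALSE)
  m * (1 - h2) / h2
}

#' Fit a ridge-regression BLUP model of marker effects
#'
#' Solves the RR-BLUP mixed-model equations
#' \deqn{\begin{pmatrix} 1'1 & 1'X \\ X'1 & X'X + \lambda I \end{pmatrix}
#'       \begin{pmatrix} \hat\mu \\ \hat a \end{pmatrix} =
#'       \begin{pmatrix} 1'y \\ X'y \end{pmatrix}}
#' for the overall mean and the vector of marker effects. Marker columns are
#' centred before solving, which makes the intercept orthogonal to the
#' markers (so `mu_hat = mean(y)`) and leaves the marker effects and all
#' predictions identical to the raw-coding solution.
#'
#' Two algebraically equivalent solvers are available: the m-dimensional
#' marker system (Cholesky on X'X + lambda I) and the N-dimensional kernel
#' system (X X' + lambda I), useful when markers far outnumber lines.
#'
#' @param y Numeric response vector (across-environment BLUEs), length N >= 2.
#' @param X N x m dosage matrix with column names (marker ids).
#' @param lambda Ridge penalty (> 0); see [lambda_from_h2()].
#' @param method "auto" picks the marker system when m <= 4 N, else the
#'   kernel system; "direct"/"kernel" force one path.
#' @return Object of class `rrblup`: `mu` (overall mean), `effects` (named
#'   marker-effect vector), `lambda`, `centers` (column means used for
#'   centring), `marker_ids`, `method`.
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(60, 2, 0.5), 12, 5,
#'             dimnames = list(NULL, paste0("m", 1:5)))
#' y <- X %*% rnorm(5) + rnorm(12)
#' fit <- rrblup(drop(y), X, lambda = 5)
#' head(coef(fit))
#' @export
rrblup <- function(y, X, lambda, method = c("auto", "direct", "kernel")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X))
    stop("length(y) must equal nrow(X)", call. = FALSE)
  if (length(y) < 2) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0)
    stop("`lambda` must be a single positive number", call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("m", seq_len(ncol(X)))
  n <- nrow(X); m <- ncol(X)
  if (method == "auto") method <- if (m <= 4 * n) "direct" else "kernel"
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  mu <- mean(y)
  yc <- y - mu
  if (method == "direct") {
    A <- crossprod(Xc)
    diag(A) <- diag(A) + lambda
    a <- drop(solve(A, crossprod(Xc, yc)))
  } else {
    K <- tcrossprod(Xc)
    diag(K) <- diag(K) + lambda
    alpha <- solve(K, yc)
    a <- drop(crossprod(Xc, alpha))
  }
  names(a) <- colnames(X)
  structure(list(mu = mu, effects = a, lambda = lambda, centers = centers,
                 marker_ids = colnames(X), method = method, n = n),
            class = "rrblup")
}

#' @export
coef.rrblup <- function(object, ...) object$effects

#' @export
print.rrblup <- function(x, ...) {
  cat(sprintf("RR-BLUP model: %d markers, %d training lines, lambda = %.4g\n",
              length(x$effects), x$n, x$lambda))
  cat(sprintf("mu = %.4g; |effects| in [%.3g, %.3g]\n", x$mu,
              min(abs(x$effects)), max(abs(x$effects))))
  invisible(x)
}

#' Predict genotypic values from an RR-BLUP model
#'
#' g_hat = mu + (X_new - centers) a_hat, with the same column centring as the
#' fit. Columns of `newdata` are matched to the model's marker ids by name.
#'
#' @param object An `rrblup` model.
#' @param newdata n x m dosage matrix whose columns cover the model's markers.
#' @param ... Unused.
#' @return Numeric vector of predicted genotypic values.
#' @export
predict.rrblup <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(object$marker_ids))
      stop("`newdata` has no column names and the wrong column count",
           call. = FALSE)
    colnames(X) <- object$marker_ids
  }
  missing <- setdiff(object$marker_ids, colnames(X))
  if (length(missing))
    stop("markers absent from `newdata`: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  unknown <- setdiff(colnames(X), object$marker_ids)
  if (length(unknown))
    stop("unknown markers in `newdata`: ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  X <- X[, object$marker_ids, drop = FALSE]
  drop(object$mu + sweep(X, 2, object$centers) %*% object$effects)
}
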