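#' @keywords internal
"_PACKAGE"

# Haldane map function: recombination fraction for a distance in centimorgans.
haldane <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

`%||%` <- function(a, b) if (is.null(a)) b else a

# set.seed only when a seed is supplied; all exported functions with a `seed`
# argument route through this so that seed = NULL means "continue the RNG".
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

stop_if_not_scalar_prob <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) stop(sprintf("`%s` must be a single value in %s", name,
                        if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  invisible(x)
}
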