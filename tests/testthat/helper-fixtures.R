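# Shared fixtures, built once per test run and memoized. Sizes are kept small:
# two populations of 80 lines, 12 markers per chromosome, 3 environments.
.fx <- new.env(parent = emptyenv())

fx_world <- function() {
  if (is.null(.fx$world)) {
    ps <- simulate_parents(12, map_length_cM = 120, seed = 101)
    pa <- simulate_f3_population(ps, "A", n_lines = 80, seed = 102)
    pb <- simulate_f3_population(ps, "B", n_lines = 80, seed = 103)
    .fx$world <- list(ps = ps, pa = pa, pb = pb)
  }
  .fx$world
}

fx_trial <- function() {
  if (is.null(.fx$trial)) {
    w <- fx_world()
    arch <- trait_architecture("grain_yield", n_qtl = 12, n_env = 3)
    .fx$trial <- simulate_trial(w$pa, w$pb, arch,
                                environments = rye_environments(9)[1:3, ],
                                seed = 104)
  }
  .fx$trial
}

fx_markers <- function() {
  if (is.null(.fx$markers)) {
    w <- fx_world()
    ms <- combine_populations(w$pa, w$pb)
    .fx$markers <- filter_markers(ms)$markers
  }
  .fx$markers
}

fx_gs_data <- function() {
  if (is.null(.fx$gs)) {
    .fx$gs <- prepare_gs_data(fx_trial(), fx_markers())
  }
  .fx$gs
}

# hand-rolled Pearson correlation from raw sums (independent of stats::cor)
pearson_by_hand <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}
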