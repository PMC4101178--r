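#' Published variance components for the rye testcross trial network
#'
#' Variance-component estimates, trait means and heritabilities reported for
#' testcross progenies of two half-sib bi-parental winter rye populations
#' (Pop-A and Pop-B, 220 F3:4 lines each), evaluated for grain yield and plant
#' height in nine location-year environments and for starch and total pentosan
#' content in six environments, with two replications throughout.
#'
#' These values serve two purposes: they are the canonical plug-in inputs for
#' [heritability()] and [ge_ratio()], and they calibrate the default trait
#' architectures of the simulator (see [trait_architecture()]).
#'
#' @return A data frame with one row per population x trait: `population`
#'   ("A"/"B"), `trait`, `mean`, `sigma2_G` (genotypic variance), `sigma2_GE`
#'   (genotype-by-environment interaction variance), `sigma2_e` (effective
#'   plot-error variance), `n_env`, `n_rep`, and the published `h2`.
#' @examples
#' tab <- rye_variance_components()
#' gy <- tab[tab$population == "A" & tab$trait == "grain_yield", ]
#' heritability(gy$sigma2_G, gy$sigma2_GE, gy$sigma2_e, gy$n_env, gy$n_rep)
#' @export
rye_variance_components <- function() {
  data.frame(
    population = rep(c("A", "B"), each = 4L),
    trait = rep(c("grain_yield", "plant_height", "starch_content",
                  "pentosan_content"), 2L),
    mean     = c(79.3, 118.2, 61.6, 10.0, 75.6, 115.6, 61.5, 10.3),
    sigma2_G = c(3.33, 7.30, 0.24, 0.03, 3.76, 12.62, 0.44, 0.03),
    sigma2_GE = c(8.40, 4.03, 0.26, 0.08, 9.18, 4.02, 0.24, 0.09),
    sigma2_e = c(3.48, 2.94, 0.14, 0.04, 3.72, 2.22, 0.14, 0.04),
    n_env = rep(c(9L, 9L, 6L, 6L), 2L),
    n_rep = 2L,
    h2 = c(0.75, 0.92, 0.87, 0.75, 0.75, 0.96, 0.93, 0.73),
    stringsAsFactors = FALSE
  )
}

#' Location-year environments of the rye trial network
#'
#' The trial network spans five locations (BEK, PET, HOH, WAL, WOH) over the
#' years 2010 and 2011. Grain yield and plant height were analysed in nine
#' environments (HOH11 dropped for low repeatability); starch and pentosan
#' content in six environments at three locations.
#'
#' @param n_env Either 9 (yield/height network) or 6 (quality-trait network).
#' @return Data frame with columns `env`, `location`, `year`.
#' @examples
#' rye_environments(9)
#' @export
rye_environments <- function(n_env = 9) {
  if (n_env == 9) {
    loc <- c("BEK", "BEK", "PET", "PET", "HOH", "WAL", "WAL", "WOH", "WOH")
    yr <- c(2010, 2011, 2010, 2011, 2010, 2010, 2011, 2010, 2011)
  } else if (n_env == 6) {
    loc <- c("PET", "PET", "WAL", "WAL", "WOH", "WOH")
    yr <- c(2010, 2011, 2010, 2011, 2010, 2011)
  } else {
    stop("`n_env` must be 9 or 6; pass an explicit environment data frame to ",
         "simulate_trial() for other layouts", call. = FALSE)
  }
  data.frame(env = paste0(loc, substr(as.character(yr), 3, 4)),
             location = loc, year = yr, stringsAsFactors = FALSE)
}
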