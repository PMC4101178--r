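#' Simulate inbred parents, a tester and a genetic map
#'
#' Generates the founder material for two half-sib bi-parental populations:
#' three fully homozygous inbred parents (P1 shared between the crosses, P2
#' and P3 cross-specific) plus one unrelated tester, on a random genetic map
#' of seven rye linkage groups.
#'
#' Markers are biallelic with alleles coded 0/1. P1 carries allele 0
#' everywhere; P2 and P3 carry allele 1 at independently drawn subsets of
#' loci, so `seg_frac[1]` is the expected fraction of loci segregating in
#' cross P1 x P2 and `seg_frac[2]` in cross P1 x P3. The tester's alleles are
#' drawn independently of all parents (it contributes a constant to testcross
#' values and never enters the marker matrix).
#'
#' @param n_markers_per_chrom Markers per linkage group (>= 2).
#' @param map_length_cM Length of each linkage group in centimorgans.
#' @param seg_frac Length-2 vector: expected fraction of loci polymorphic
#'   between P1 and P2, and between P1 and P3. A larger second value emulates
#'   the wider parental divergence of population B.
#' @param seed Integer seed; identical seeds give identical parent sets.
#' @return An object of class `parent_set`: list with `map` (data frame
#'   `marker_id`, `chromosome`, `position`) and `alleles` (4 x m 0/1 matrix,
#'   rows P1, P2, P3, tester).
#' @examples
#' ps <- simulate_parents(10, seed = 1)
#' nrow(ps$map)            # 70 markers
#' rowSums(ps$alleles)     # allele-1 counts per founder
#' @export
simulate_parents <- function(n_markers_per_chrom, map_length_cM = 150,
                             seg_frac = c(0.40, 0.60), seed = NULL) {
  if (!is.numeric(n_markers_per_chrom) || n_markers_per_chrom < 2)
    stop("`n_markers_per_chrom` must be >= 2", call. = FALSE)
  if (!is.numeric(map_length_cM) || map_length_cM <= 0)
    stop("`map_length_cM` must be positive", call. = FALSE)
  stopifnot(length(seg_frac) == 2, all(seg_frac >= 0), all(seg_frac <= 1))
  set_seed_if(seed)

  n_chrom <- 7L
  k <- as.integer(n_markers_per_chrom)
  chrom <- rep(seq_len(n_chrom), each = k)
  pos <- as.vector(vapply(seq_len(n_chrom),
                          function(i) sort(stats::runif(k, 0, map_length_cM)),
                          numeric(k)))
  marker_id <- sprintf("M%d_%03d", chrom, rep(seq_len(k), times = n_chrom))
  map <- data.frame(marker_id = marker_id, chromosome = chrom,
                    position = pos, stringsAsFactors = FALSE)
  attr(map, "chrom_length") <- map_length_cM

  m <- nrow(map)
  alleles <- rbind(
    P1 = integer(m),
    P2 = as.integer(stats::runif(m) < seg_frac[1]),
    P3 = as.integer(stats::runif(m) < seg_frac[2]),
    tester = as.integer(stats::runif(m) < 0.5)
  )
  colnames(alleles) <- marker_id
  structure(list(map = map, alleles = alleles), class = "parent_set")
}

#' @export
print.parent_set <- function(x, ...) {
  cat("Parent set:", ncol(x$alleles), "markers on",
      length(unique(x$map$chromosome)), "linkage groups\n")
  cat("Segregating P1 x P2:", sum(x$alleles["P1", ] != x$alleles["P2", ]),
      " P1 x P3:", sum(x$alleles["P1", ] != x$alleles["P3", ]), "\n")
  invisible(x)
}

# One meiosis under the Haldane model: crossovers form a Poisson process on
# the cM map (rate 1 per Morgan), no interference. h1/h2 are the two parental
# haplotypes (0/1 vectors over all markers); returns one gamete.
gamete_haldane <- function(h1, h2, map) {
  out <- integer(length(h1))
  chrom_length <- attr(map, "chrom_length") %||% NA_real_
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    pos <- map$position[idx]
    L <- if (is.finite(chrom_length)) chrom_length else max(pos)
    nx <- stats::rpois(1L, L / 100)
    phase0 <- sample.int(2L, 1L) - 1L
    if (nx == 0L) {
      phase <- rep.int(phase0, length(idx))
    } else {
      xloc <- sort(stats::runif(nx, 0, L))
      phase <- (phase0 + findInterval(pos, xloc)) %% 2L
    }
    out[idx] <- ifelse(phase == 0L, h1[idx], h2[idx])
  }
  out
}

#' Simulate an F3 population by single seed descent
#'
#' Crosses two homozygous parents, selfs the F1 for two generations by single
#' seed descent (one random F2 plant per line, one random F3 plant from it)
#' and records the F3 plant genotype of each line. This is the genotype that
#' represents an F3:4 line in downstream analyses. Recombination follows the
#' Haldane model (Poisson crossovers, no interference).
#'
#' At a locus segregating between the parents the expected genotype
#' frequencies after two selfing generations are 3/8 : 1/4 : 3/8
#' (hom/het/hom), i.e. expected heterozygosity 0.25 and allele frequency 0.5.
#'
#' @param parents A `parent_set` from [simulate_parents()], or a list with
#'   elements `map` and `alleles` of the same shape.
#' @param cross Which cross to simulate: "A" (P1 x P2) or "B" (P1 x P3).
#' @param n_lines Number of F3:4 lines (the study template uses 220).
#' @param seed Integer seed.
#' @return Object of class `f3_population`: list with `geno` (n_lines x m
#'   integer dosage matrix in {0,1,2}, counting the allele of the non-shared
#'   parent), `map`, `label`, `parents` (2 x m allele matrix of the cross).
#' @examples
#' ps <- simulate_parents(8, seed = 1)
#' pop <- simulate_f3_population(ps, "A", n_lines = 20, seed = 2)
#' dim(pop$geno)
#' @export
simulate_f3_population <- function(parents, cross = c("A", "B"),
                                   n_lines = 220, seed = NULL) {
  cross <- match.arg(cross)
  map <- parents$map
  alleles <- parents$alleles
  if (ncol(alleles) != nrow(map))
    stop("parent alleles and map have mismatched marker counts", call. = FALSE)
  if (n_lines < 1) stop("`n_lines` must be positive", call. = FALSE)
  set_seed_if(seed)

  p1 <- alleles["P1", ]
  p2 <- if (cross == "A") alleles["P2", ] else alleles["P3", ]
  m <- length(p1)
  geno <- matrix(0L, nrow = n_lines, ncol = m)
  for (i in seq_len(n_lines)) {
    # F1 is (p1 | p2); two meioses give the F2 plant, two more the F3 plant
    f2a <- gamete_haldane(p1, p2, map)
    f2b <- gamete_haldane(p1, p2, map)
    f3a <- gamete_haldane(f2a, f2b, map)
    f3b <- gamete_haldane(f2a, f2b, map)
    geno[i, ] <- f3a + f3b
  }
  rownames(geno) <- sprintf("%s%03d", cross, seq_len(n_lines))
  colnames(geno) <- map$marker_id
  structure(list(geno = geno, map = map, label = cross,
                 parents = rbind(p1 = p1, p2 = p2)),
            class = "f3_population")
}

#' @export
print.f3_population <- function(x, ...) {
  seg <- sum(apply(x$geno, 2, function(d) stats::var(d) > 0))
  cat("F3:4 population", x$label, ":", nrow(x$geno), "lines,",
      ncol(x$geno), "markers (", seg, "segregating )\n")
  invisible(x)
}

#' Specify a testcross trait architecture
#'
#' Bundles the genetic architecture and trial dimensioning used by
#' [simulate_trial()]. Defaults for the variance magnitudes, trait mean and
#' trial dimensions come from the published population-A estimates
#' ([rye_variance_components()]); the polygenic QTL number and the design
#' nuisance variances are simulator choices (see the package vignette).
#'
#' @param trait One of "grain_yield", "plant_height", "starch_content",
#'   "pentosan_content" (sets defaults), or any other label if all variance
#'   arguments are given explicitly.
#' @param n_qtl Number of additive QTL (>= 1), placed at randomly chosen
#'   segregating marker positions unless `qtl_markers` is given.
#' @param sigma2_G Target genotypic variance of testcross values.
#' @param sigma2_GE Genotype-by-environment interaction variance.
#' @param sigma2_e Plot-error variance.
#' @param mean Trait mean (tester contribution is absorbed here).
#' @param n_env,n_rep Number of environments and replications.
#' @param sigma2_rep,sigma2_block Replication and incomplete-block variances
#'   (defaults 0.1 and 0.25 times `sigma2_e`).
#' @param block_size Plots per incomplete block within a replication.
#' @param qtl_markers Optional character vector of marker ids to use as QTL.
#' @param ge_genetic Fraction of the interaction variance realized as
#'   QTL-by-environment effects (marker-linked and therefore transferable to
#'   relatives within the same environments); the remainder is line-specific
#'   non-genetic noise. Default 0.5; see the vignette.
#' @return Object of class `trait_architecture` (a list of the above).
#' @examples
#' trait_architecture("grain_yield", n_qtl = 50)
#' @export
trait_architecture <- function(trait = "grain_yield", n_qtl = 50,
                               sigma2_G = NULL, sigma2_GE = NULL,
                               sigma2_e = NULL, mean = NULL,
                               n_env = NULL, n_rep = 2,
                               sigma2_rep = NULL, sigma2_block = NULL,
                               block_size = 22, qtl_markers = NULL,
                               ge_genetic = 0.5) {
  tab <- rye_variance_components()
  row <- tab[tab$population == "A" & tab$trait == trait, ]
  if (nrow(row) == 1) {
    sigma2_G <- sigma2_G %||% row$sigma2_G
    sigma2_GE <- sigma2_GE %||% row$sigma2_GE
    sigma2_e <- sigma2_e %||% row$sigma2_e
    mean <- mean %||% row$mean
    n_env <- n_env %||% row$n_env
  }
  if (is.null(sigma2_G) || is.null(sigma2_GE) || is.null(sigma2_e))
    stop("variances must be given for trait '", trait, "'", call. = FALSE)
  if (n_qtl < 1) stop("`n_qtl` must be >= 1", call. = FALSE)
  if (any(c(sigma2_G, sigma2_GE, sigma2_e) < 0))
    stop("variance components must be non-negative", call. = FALSE)
  structure(list(
    trait = trait, n_qtl = as.integer(n_qtl),
    sigma2_G = sigma2_G, sigma2_GE = sigma2_GE, sigma2_e = sigma2_e,
    mean = mean %||% 0, n_env = as.integer(n_env %||% 9), n_rep = as.integer(n_rep),
    sigma2_rep = sigma2_rep %||% (0.1 * sigma2_e),
    sigma2_block = sigma2_block %||% (0.25 * sigma2_e),
    block_size = as.integer(block_size), qtl_markers = qtl_markers,
    ge_genetic = stop_if_not_scalar_prob(ge_genetic, "ge_genetic")
  ), class = "trait_architecture")
}

#' Simulate a multi-environment testcross trial
#'
#' Generates plot-level phenotypes for the testcross progenies of one or two
#' F3:4 populations. The testcross value of a line is purely additive in its
#' marker dosage at the QTL (the unrelated CMS tester contributes a constant
#' absorbed into the trait mean):
#' \deqn{y = \mu + \sum_q a_q x_q + GE_{g,e} + rep + block + \epsilon}
#' with replication and block effects drawn from their respective variances
#' and plot error from N(0, sigma2_e). The genotype-by-environment deviation
#' is drawn once per line and environment with variance sigma2_GE; a fraction
#' `arch$ge_genetic` of it is realized as QTL-by-environment effects (each
#' environment draws its own deviation of every QTL effect), the remainder as
#' line-specific Gaussian noise. Marker-linked interaction makes prediction
#' accuracy transfer poorly to new locations and years, as observed in
#' multi-environment trials; purely non-genetic interaction would not.
#' QTL main effects and the per-environment interaction effects are rescaled
#' so that the realized genotypic variance within each population equals
#' `arch$sigma2_G` and the realized interaction variance `arch$sigma2_GE`
#' (calibration; see vignette).
#'
#' @param popA An `f3_population`.
#' @param popB Optional second `f3_population` on the same map.
#' @param arch A [trait_architecture()].
#' @param environments Data frame with columns `env`, `location`, `year`;
#'   defaults to [rye_environments()] for `arch$n_env`.
#' @param seed Integer seed.
#' @param calibrate One of "per_population" (each population's realized
#'   genotypic variance equals the target exactly), "pooled" (the mean of the
#'   within-population variances is matched), or "none" (effects used as drawn,
#'   scaled only by a theoretical factor).
#' @return A `trial_data` data frame with columns `genotype`, `population`,
#'   `location`, `year`, `env`, `rep`, `block`, `trait`, `value`, and
#'   attributes `true_g` (named vector of simulated genotypic values), `qtl`
#'   (data frame of QTL markers and effects) and `arch`.
#' @examples
#' ps <- simulate_parents(8, seed = 1)
#' pa <- simulate_f3_population(ps, "A", 30, seed = 2)
#' tr <- simulate_trial(pa, arch = trait_architecture(n_qtl = 5, n_env = 2),
#'                      environments = rye_environments(9)[1:2, ], seed = 3)
#' nrow(tr)  # 30 lines x 2 env x 2 reps
#' @export
simulate_trial <- function(popA, popB = NULL, arch = trait_architecture(),
                           environments = NULL, seed = NULL,
                           calibrate = c("per_population", "pooled", "none")) {
  calibrate <- match.arg(calibrate)
  if (is.null(environments)) environments <- rye_environments(arch$n_env)
  if (nrow(environments) < 1) stop("`environments` must be non-empty", call. = FALSE)
  pops <- if (is.null(popB)) list(popA) else list(popA, popB)
  if (length(pops) == 2 &&
      !identical(popA$map$marker_id, popB$map$marker_id))
    stop("populations are on different maps", call. = FALSE)
  set_seed_if(seed)

  geno <- do.call(rbind, lapply(pops, `[[`, "geno"))
  pop_of <- rep(vapply(pops, `[[`, "", "label"),
                vapply(pops, function(p) nrow(p$geno), 0L))
  map <- popA$map

  # QTL at marker positions segregating in at least one population
  if (is.null(arch$qtl_markers)) {
    seg <- colnames(geno)[apply(geno, 2, function(d) stats::var(d) > 0)]
    if (length(seg) < arch$n_qtl)
      stop("fewer segregating markers than requested QTL", call. = FALSE)
    qtl_id <- sample(seg, arch$n_qtl)
  } else {
    qtl_id <- arch$qtl_markers
    if (!all(qtl_id %in% map$marker_id))
      stop("QTL positions off the map: ",
           paste(setdiff(qtl_id, map$marker_id), collapse = ", "), call. = FALSE)
  }
  eff <- stats::rnorm(length(qtl_id))
  g_raw <- drop(geno[, qtl_id, drop = FALSE] %*% eff)

  scale_of <- function(v_target, v_real) {
    if (v_target == 0) return(0)
    if (v_real <= 0) stop("no genotypic variance realized; cannot calibrate",
                          call. = FALSE)
    sqrt(v_target / v_real)
  }
  g <- numeric(length(g_raw))
  names(g) <- rownames(geno)
  if (calibrate == "per_population") {
    sc <- numeric(0)
    for (p in unique(pop_of)) {
      i <- pop_of == p
      s <- scale_of(arch$sigma2_G, stats::var(g_raw[i]))
      g[i] <- g_raw[i] * s
      sc[p] <- s
    }
    eff_out <- eff * mean(sc)   # representative scale for reporting
  } else if (calibrate == "pooled") {
    vbar <- mean(vapply(unique(pop_of),
                        function(p) stats::var(g_raw[pop_of == p]), 0))
    s <- scale_of(arch$sigma2_G, vbar)
    g <- g_raw * s
    eff_out <- eff * s
  } else {
    g <- g_raw
    eff_out <- eff
  }

  n_g <- nrow(geno)
  n_env <- nrow(environments)
  n_rep <- arch$n_rep

  # genotype-by-environment deviations: marker-linked QTL x E share plus
  # line-specific noise, each calibrated to its variance share within
  # population and environment
  v_gen <- arch$ge_genetic * arch$sigma2_GE
  v_iid <- (1 - arch$ge_genetic) * arch$sigma2_GE
  ge <- matrix(stats::rnorm(n_g * n_env, 0, sqrt(v_iid)),
               n_g, n_env, dimnames = list(rownames(geno), environments$env))
  if (v_gen > 0) {
    Xq <- geno[, qtl_id, drop = FALSE]
    for (e in seq_len(n_env)) {
      b_e <- stats::rnorm(length(qtl_id))
      u <- drop(Xq %*% b_e)
      for (p in unique(pop_of)) {
        i <- pop_of == p
        vu <- stats::var(u[i])
        if (sum(i) > 1 && vu > 0)
          ge[i, e] <- ge[i, e] + (u[i] - mean(u[i])) * sqrt(v_gen / vu)
      }
    }
  }

  rows <- vector("list", n_env * n_rep)
  k <- 0L
  n_block <- max(1L, ceiling(n_g / arch$block_size))
  for (e in seq_len(n_env)) {
    rep_eff <- stats::rnorm(n_rep, 0, sqrt(arch$sigma2_rep))
    for (r in seq_len(n_rep)) {
      block <- sample(rep(seq_len(n_block), length.out = n_g))
      block_eff <- stats::rnorm(n_block, 0, sqrt(arch$sigma2_block))
      err <- stats::rnorm(n_g, 0, sqrt(arch$sigma2_e))
      k <- k + 1L
      rows[[k]] <- data.frame(
        genotype = rownames(geno), population = pop_of,
        location = environments$location[e], year = environments$year[e],
        env = environments$env[e], rep = r, block = block,
        trait = arch$trait,
        value = arch$mean + g + ge[, e] + rep_eff[r] + block_eff[block] + err,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_g") <- g
  attr(out, "qtl") <- data.frame(
    marker_id = qtl_id,
    chromosome = map$chromosome[match(qtl_id, map$marker_id)],
    position = map$position[match(qtl_id, map$marker_id)],
    effect = eff_out, stringsAsFactors = FALSE)
  attr(out, "arch") <- arch
  class(out) <- c("trial_data", "data.frame")
  out
}
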