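#' Construct a marker set
#'
#' Couples a lines-by-markers dosage matrix with its genetic map and the
#' population membership of each line. Dosages are 0/1/2 counts of the
#' non-shared-parent allele; `NA` marks missing genotype calls.
#'
#' @param geno Numeric matrix, lines x markers, entries in {0, 1, 2, NA},
#'   with row and column names.
#' @param map Data frame `marker_id`, `chromosome`, `position` covering every
#'   column of `geno` (order must match).
#' @param population Character vector of population labels per line.
#' @return Object of class `marker_set`.
#' @export
marker_set <- function(geno, map, population) {
  geno <- as.matrix(geno)
  if ((ncol(geno) > 0 && is.null(colnames(geno))) || is.null(rownames(geno)))
    stop("`geno` must have row and column names", call. = FALSE)
  if (!identical(as.character(colnames(geno) %||% character(0)),
                 as.character(map$marker_id)))
    stop("`geno` columns and `map` marker ids disagree", call. = FALSE)
  if (length(population) != nrow(geno))
    stop("`population` must have one label per line", call. = FALSE)
  bad <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(bad)) stop("invalid dosage codes (must be 0, 1, 2 or NA)", call. = FALSE)
  structure(list(geno = geno, map = map,
                 population = as.character(population)),
            class = "marker_set")
}

#' Combine F3:4 populations into one marker set
#'
#' @param ... `f3_population` objects sharing a map.
#' @return A `marker_set` over the stacked lines.
#' @export
combine_populations <- function(...) {
  pops <- list(...)
  maps <- lapply(pops, function(p) p$map$marker_id)
  if (!all(vapply(maps, identical, TRUE, maps[[1]])))
    stop("populations are on different maps", call. = FALSE)
  geno <- do.call(rbind, lapply(pops, `[[`, "geno"))
  population <- rep(vapply(pops, `[[`, "", "label"),
                    vapply(pops, function(p) nrow(p$geno), 0L))
  marker_set(geno, pops[[1]]$map, population)
}

#' @export
print.marker_set <- function(x, ...) {
  cat("Marker set:", nrow(x$geno), "lines x", ncol(x$geno), "markers;",
      sum(is.na(x$geno)), "missing calls\n")
  cat("Populations:", paste(sprintf("%s=%d", names(table(x$population)),
                                    table(x$population)), collapse = ", "), "\n")
  invisible(x)
}

# allele frequency of the counted allele: mean(dosage)/2 over non-missing lines
allele_freq <- function(geno) colMeans(geno, na.rm = TRUE) / 2

#' Marker quality control
#'
#' Excludes markers with a missing rate above `max_missing` and markers whose
#' allele frequency falls outside `maf_bounds` (exclusion is strict: a marker
#' at exactly 0.05 or 0.95 is kept). Frequencies are computed on the matrix
#' as given, i.e. on combined populations when the set spans both.
#'
#' @param m A `marker_set`.
#' @param max_missing Maximum tolerated missing-call rate (default 0.05).
#' @param maf_bounds Allele-frequency window; markers with frequency smaller
#'   than `maf_bounds[1]` or larger than `maf_bounds[2]` are excluded.
#' @return List with `markers` (the filtered `marker_set`, column order
#'   preserved) and `report` (data frame `marker_id`, `missing_rate`, `freq`,
#'   `pass`, `reason`).
#' @examples
#' ps <- simulate_parents(8, seed = 1)
#' pop <- simulate_f3_population(ps, "A", 40, seed = 2)
#' ms <- marker_set(pop$geno, pop$map, rep("A", 40))
#' qc <- filter_markers(ms)
#' table(qc$report$pass)
#' @export
filter_markers <- function(m, max_missing = 0.05, maf_bounds = c(0.05, 0.95)) {
  stopifnot(inherits(m, "marker_set"))
  miss <- colMeans(is.na(m$geno))
  freq <- allele_freq(m$geno)
  reason <- rep("", ncol(m$geno))
  reason[freq < maf_bounds[1] | freq > maf_bounds[2]] <- "allele frequency"
  reason[miss > max_missing] <- "missing rate"  # missing rate reported first
  pass <- reason == ""
  report <- data.frame(marker_id = colnames(m$geno), missing_rate = miss,
                       freq = freq, pass = pass, reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!any(pass)) warning("no markers passed quality control", call. = FALSE)
  keep <- which(pass)
  out <- marker_set(m$geno[, keep, drop = FALSE],
                    m$map[keep, , drop = FALSE], m$population)
  list(markers = out, report = report)
}

#' Impute missing genotype calls from a binomial distribution
#'
#' Each missing dosage is drawn as Binomial(2, p) where p is the observed
#' allele frequency of that marker within the line's population. Observed
#' entries are never modified.
#'
#' @param m A `marker_set`.
#' @param seed Integer seed.
#' @return The `marker_set` with no missing entries.
#' @export
impute_missing <- function(m, seed = NULL) {
  stopifnot(inherits(m, "marker_set"))
  set_seed_if(seed)
  geno <- m$geno
  if (!anyNA(geno)) return(m)
  for (p in unique(m$population)) {
    rows <- which(m$population == p)
    sub <- geno[rows, , drop = FALSE]
    miss <- is.na(sub)
    cols <- which(colSums(miss) > 0)
    for (j in cols) {
      obs <- sub[!miss[, j], j]
      if (length(obs) == 0)
        stop("marker ", colnames(geno)[j], " is fully missing in population ",
             p, call. = FALSE)
      phat <- mean(obs) / 2
      sub[miss[, j], j] <- stats::rbinom(sum(miss[, j]), 2L, phat)
    }
    geno[rows, ] <- sub
  }
  m$geno <- geno
  m
}

#' Linkage disequilibrium as squared allele-frequency correlation
#'
#' r-squared between marker pairs is the squared Pearson correlation of the
#' dosage columns. Impute missing data first.
#'
#' @param m A `marker_set` without missing entries.
#' @param pairs Optional two-column matrix/data frame of marker ids; if
#'   omitted, the full marker x marker matrix is returned.
#' @return Either an m x m symmetric matrix of r-squared values, or a data
#'   frame `marker1`, `marker2`, `r2` for the requested pairs. Pairs
#'   involving a zero-variance (monomorphic) column get `NA` and raise a
#'   warning rather than a silent 0.
#' @export
ld_r2 <- function(m, pairs = NULL) {
  stopifnot(inherits(m, "marker_set"))
  if (anyNA(m$geno))
    stop("missing genotypes present; run impute_missing() first", call. = FALSE)
  v <- apply(m$geno, 2, stats::var)
  if (any(v == 0))
    warning("zero-variance markers produce undefined r2 (NA): ",
            paste(utils::head(colnames(m$geno)[v == 0], 5), collapse = ", "),
            call. = FALSE)
  if (is.null(pairs)) {
    r <- suppressWarnings(stats::cor(m$geno))
    r[, v == 0] <- NA_real_
    r[v == 0, ] <- NA_real_
    return(r^2)
  }
  pairs <- as.matrix(pairs)
  r2 <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- m$geno[, pairs[i, 1]]; b <- m$geno[, pairs[i, 2]]
    if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
    stats::cor(a, b)^2
  }, 0)
  data.frame(marker1 = pairs[, 1], marker2 = pairs[, 2], r2 = r2,
             stringsAsFactors = FALSE)
}

#' Pairwise LD against map distance
#'
#' Convenience table of within-chromosome marker pairs with their map
#' distance and r-squared, for inspecting LD decay.
#'
#' @param m A `marker_set` without missing entries.
#' @return Data frame `marker1`, `marker2`, `chromosome`, `dist_cM`, `r2`.
#' @export
ld_vs_distance <- function(m) {
  r2 <- ld_r2(m)
  out <- list()
  for (ch in unique(m$map$chromosome)) {
    idx <- which(m$map$chromosome == ch)
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    out[[as.character(ch)]] <- data.frame(
      marker1 = m$map$marker_id[cmb[1, ]],
      marker2 = m$map$marker_id[cmb[2, ]],
      chromosome = ch,
      dist_cM = abs(m$map$position[cmb[2, ]] - m$map$position[cmb[1, ]]),
      r2 = r2[cbind(cmb[1, ], cmb[2, ])],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Dominant (presence/absence) view of a marker set
#'
#' Collapses dosages to 0/1 presence calls, emulating dominant DArT scoring.
#'
#' @param m A `marker_set`.
#' @return The `marker_set` with entries `as.integer(dosage > 0)`.
#' @export
dominant_view <- function(m) {
  stopifnot(inherits(m, "marker_set"))
  g <- m$geno
  g[!is.na(g)] <- as.integer(g[!is.na(g)] > 0)
  m$geno <- g
  m
}
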