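#' Read and write the pipeline's plain-text formats
#'
#' Genotypes travel as TSV (rows = lines, columns = marker ids, values
#' 0/1/2/NA), maps as TSV (`marker_id`, `chromosome`, `position_cM`), trial
#' data as long-format CSV (`genotype,population,location,year,env,rep,block,
#' trait,value`).
#'
#' @param m A `marker_set` (genotypes + map) or `trial_data`.
#' @param path Output file path.
#' @return The path, invisibly; readers return the reconstructed object.
#' @name ryegs-io
NULL

#' @rdname ryegs-io
#' @export
write_geno_tsv <- function(m, path) {
  stopifnot(inherits(m, "marker_set"))
  df <- data.frame(line = rownames(m$geno), population = m$population,
                   m$geno, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ryegs-io
#' @export
write_map_tsv <- function(m, path) {
  map <- if (inherits(m, "marker_set")) m$map else m
  out <- data.frame(marker_id = map$marker_id, chromosome = map$chromosome,
                    position_cM = map$position)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ryegs-io
#' @param geno_path,map_path Paths written by the writers.
#' @export
read_marker_set <- function(geno_path, map_path) {
  g <- utils::read.delim(geno_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  names(map) <- c("marker_id", "chromosome", "position")
  geno <- as.matrix(g[, -(1:2), drop = FALSE])
  rownames(geno) <- g$line
  marker_set(geno, map, g$population)
}

#' @rdname ryegs-io
#' @export
write_trial_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ryegs-io
#' @export
read_trial_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(d) <- c("trial_data", "data.frame")
  d
}
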