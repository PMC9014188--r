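#' Write and read locus tables as TSV
#'
#' Tab-separated interchange format with a header row and frequencies as
#' decimals; round-trips the output of [locus_table()] (optionally after
#' [ascertain()]).
#'
#' @param loci a locus-table data.frame.
#' @param path file path.
#' @return `write_loci_tsv` returns `path` invisibly; `read_loci_tsv`
#'   returns the data.frame.
#' @export
write_loci_tsv <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_loci_tsv
#' @export
read_loci_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write per-generation state summaries as JSON
#'
#' Serializes one or more recorded variance series (the `"summary"`
#' attribute of [advance_generation()] / [burn_in_to_equilibrium()] results)
#' together with the configuration echo and seed.
#'
#' @param summaries named list of summary data.frames (e.g.
#'   `list(A = ..., B = ...)`).
#' @param path file path.
#' @param cfg optional [sim_config()] echoed into the file.
#' @return `path`, invisibly.
#' @export
write_state_summary_json <- function(summaries, path, cfg = NULL) {
  payload <- list(populations = summaries)
  if (!is.null(cfg))
    payload$config <- list(N = cfg$N, w = cfg$w, U = cfg$U,
                           env_sd = cfg$env_sd, burn_in = cfg$burn_in,
                           split_time = cfg$split_time,
                           neutral_loci = cfg$neutral_loci,
                           seed = cfg$seed,
                           effect_weights = cfg$effect_dist_scaled$weights,
                           effect_sds = cfg$effect_dist_scaled$sds)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write a genotype matrix as TSV
#'
#' Individuals in rows, loci in columns (named by locus id), copy counts as
#' integers.
#'
#' @param pop a [population_state()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(pop, path) {
  g <- pop$geno
  colnames(g) <- pop$id
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
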