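#' Population state
#'
#' A diploid population at one point in time: per-individual copy counts at
#' every tracked locus, the additive effect of each locus, and the cumulative
#' phenotypic offset contributed by loci fixed since the reference epoch
#' (substitutions). Copy counts refer to the derived (mutant) allele.
#'
#' @param geno integer matrix, individuals x loci, entries in `{0, 1, 2}`.
#' @param eff numeric vector of per-locus additive effects (0 marks a neutral
#'   marker).
#' @param id integer locus identifiers (negative ids are neutral markers).
#' @param offset substitution offset: sum of `2a` over loci fixed since the
#'   reference epoch.
#' @param generation generation counter.
#' @param next_id next unused locus id.
#' @return An object of class `population_state`.
#' @export
population_state <- function(geno, eff, id = seq_along(eff), offset = 0,
                             generation = 0L, next_id = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(ncol(geno) == length(eff), length(id) == length(eff))
  if (length(geno) && (min(geno) < 0 || max(geno) > 2))
    stop("genotypes must be copy counts in {0, 1, 2}")
  if (is.null(next_id)) next_id <- if (length(id)) max(id, 0L) + 1L else 1L
  structure(list(geno = geno, eff = as.numeric(eff), id = as.integer(id),
                 offset = offset, generation = as.integer(generation),
                 next_id = as.integer(next_id)),
            class = "population_state")
}

#' Start a population with no standing variation
#' @param cfg a [sim_config()].
#' @return A monomorphic `population_state` of `cfg$N` individuals.
#' @export
new_population <- function(cfg) {
  population_state(matrix(integer(), cfg$N, 0), numeric(0), integer(0))
}

#' @export
print.population_state <- function(x, ...) {
  s <- summarize_state(x)
  cat(sprintf("<population_state> %d individuals, %d tracked loci (gen %d)\n",
              nrow(x$geno), ncol(x$geno), x$generation))
  cat(sprintf("  V_a = %.4g, V_A = %.4g, mean phenotype = %.4g\n",
              s$V_a, s$V_A, s$mean_phenotype))
  invisible(x)
}

#' Derived-allele frequencies
#' @param pop a `population_state`.
#' @param trait_only drop zero-effect markers.
#' @return Named numeric vector of frequencies (names = locus ids).
#' @export
allele_freqs <- function(pop, trait_only = TRUE) {
  keep <- if (trait_only) pop$eff != 0 else rep(TRUE, length(pop$eff))
  p <- colSums(pop$geno[, keep, drop = FALSE]) / (2 * nrow(pop$geno))
  names(p) <- pop$id[keep]
  p
}

#' Additive genetic values
#'
#' `G_i = sum_l a_l g_il` over the population's tracked loci: each
#' individual's additive deviation, interpreted relative to the population
#' mean. Loci fixed within the population add an equal constant to everyone
#' and so do not affect deviations.
#'
#' @param pop a `population_state`.
#' @return Numeric vector of length `N`.
#' @export
additive_values <- function(pop) {
  as.numeric(pop$geno %*% pop$eff)
}

#' Variance components of a population
#'
#' Computes the additive genic variance `V_a = sum 2 p (1-p) a^2` from current
#' allele frequencies, the additive genetic variance `V_A = Var(G_i)` over
#' individuals, their difference (the linkage-disequilibrium term), the
#' phenotypic variance `V_P = V_A + env_sd^2`, and the mean phenotype
#' including the substitution offset.
#'
#' @param pop a `population_state`.
#' @param env_sd environmental noise sd used for `V_P`.
#' @return A list with `V_a`, `V_A`, `LD`, `V_P`, `mean_phenotype`, `n_seg`.
#' @examples
#' pop <- population_state(matrix(c(0L, 1L, 2L, 1L), 4, 1), eff = 0.1)
#' summarize_state(pop)
#' @export
summarize_state <- function(pop, env_sd = 0) {
  g <- additive_values(pop)
  p <- allele_freqs(pop)
  a <- pop$eff[pop$eff != 0]
  va <- sum(2 * p * (1 - p) * a^2)
  n <- length(g)
  vA <- if (n) sum((g - mean(g))^2) / n else 0
  list(V_a = va, V_A = vA, LD = vA - va, V_P = vA + env_sd^2,
       mean_phenotype = mean(g) + pop$offset,
       n_seg = sum(p > 0 & p < 1))
}
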