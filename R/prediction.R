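#' Polygenic scores from ascertained loci
#'
#' `S_i = sum a_l g_il` over the ascertained loci, using the true effects (no
#' estimation noise). Ascertained loci absent from the population's tracked
#' columns (e.g. private to the other population) contribute nothing; loci
#' fixed in this population contribute an equal constant to every individual,
#' which is how a portable genotyping panel behaves.
#'
#' @param pop a [population_state()].
#' @param loci a [locus_table()] with `ascertained` flags set (see
#'   [ascertain()]).
#' @return Numeric vector of per-individual scores.
#' @export
polygenic_scores <- function(pop, loci) {
  ids <- loci$locus_id[loci$ascertained]
  if (!length(ids)) return(numeric(nrow(pop$geno)))
  cols <- match(ids, pop$id)
  cols <- cols[!is.na(cols)]
  as.numeric(pop$geno[, cols, drop = FALSE] %*% pop$eff[cols])
}

#' Scores and additive genetic values for one population
#'
#' Bundles per-individual polygenic scores and additive genetic values with
#' their variances and the within-population accuracy ratio
#' `Var(S)/Var(G)`: the proportion of the additive genetic variance (the
#' heritable variance, when effects are strictly additive and estimated
#' perfectly) that the score captures.
#'
#' @param pop a [population_state()].
#' @param loci a [locus_table()] with `ascertained` flags.
#' @param label population label carried through summaries.
#' @return An object of class `score_set` with fields `S`, `G`, `var_S`,
#'   `var_G`, `accuracy_ratio`, `label`.
#' @export
score_set <- function(pop, loci, label = "") {
  S <- polygenic_scores(pop, loci)
  G <- additive_values(pop)
  n <- length(G)
  vS <- stats::var(S) * (n - 1) / n
  vG <- stats::var(G) * (n - 1) / n
  structure(list(S = S, G = G, var_S = vS, var_G = vG,
                 accuracy_ratio = if (vG > 0) vS / vG else NA_real_,
                 label = label),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set%s> Var(S) = %.4g, Var(G) = %.4g, Var(S)/Var(G) = %.4g\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$var_S, x$var_G, x$accuracy_ratio))
  invisible(x)
}

#' Within-population reduction in prediction accuracy
#'
#' The ratio `Var(S)/Var(G)` of a [score_set()]: how much of the phenotype
#' prediction accuracy achievable with full additive genetic values the
#' polygenic score retains within that population (`r^2_S / r^2_G`).
#'
#' @param scores a [score_set()].
#' @return A ratio in `[0, 1]`, or `NA` when `Var(G) = 0`.
#' @export
accuracy_reduction <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  scores$accuracy_ratio
}

#' Portability: relative accuracy in the unrepresented population
#'
#' The ratio of `Var(S)/Var(G)` in population B to population A quantifies
#' the loss of prediction accuracy attributable purely to B not being
#' represented in the GWAS.
#'
#' @param ratio_B,ratio_A within-population accuracy ratios (see
#'   [accuracy_reduction()]); `score_set` objects are also accepted.
#' @return `ratio_B / ratio_A`.
#' @export
relative_accuracy <- function(ratio_B, ratio_A) {
  if (inherits(ratio_B, "score_set")) ratio_B <- ratio_B$accuracy_ratio
  if (inherits(ratio_A, "score_set")) ratio_A <- ratio_A$accuracy_ratio
  if (!is.na(ratio_A) && ratio_A <= 0)
    stop("represented-population accuracy ratio must be positive")
  ratio_B / ratio_A
}
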