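#' Mutation effect-size distributions
#'
#' Trait mutations draw their additive effect `a` (phenotype units, effect of
#' the derived allele per copy) from a symmetric, mean-zero distribution:
#' either a single Gaussian or a finite mixture of mean-zero Gaussians. The
#' mixture form produces heavy-tailed architectures in which a minority of
#' mutations have much larger effects.
#'
#' @param kind `"gaussian"` or `"mixture"`.
#' @param sd standard deviation of the single component (`kind = "gaussian"`).
#' @param weights,sds component weights (summing to 1) and standard deviations
#'   (`kind = "mixture"`).
#' @return An object of class `effect_distribution` with fields `weights` and
#'   `sds`.
#' @examples
#' effect_distribution("gaussian", sd = 0.1)
#' heavy_tail_effects()
#' @export
effect_distribution <- function(kind = c("gaussian", "mixture"), sd = 0.1,
                                weights = NULL, sds = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    weights <- 1
    sds <- sd
  }
  weights <- as.numeric(weights)
  sds <- as.numeric(sds)
  stopifnot(length(weights) == length(sds), length(weights) >= 1)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("component weights must be positive and finite")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("component weights must sum to 1")
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop("component sds must be positive and finite")
  structure(list(kind = kind, weights = weights, sds = sds),
            class = "effect_distribution")
}

#' @export
print.effect_distribution <- function(x, ...) {
  cat("<effect_distribution>", x$kind, "\n")
  cat(sprintf("  component: weight %.3f, sd %.4g\n", x$weights, x$sds), sep = "")
  invisible(x)
}

#' Default heavy-tailed mutation effect distribution
#'
#' A two-component mean-zero mixture in which most mutations are nearly
#' neutral (`S << 1` at `w = 5`) while a small minority draw from a component
#' an order of magnitude wider, so strongly selected large-effect alleles
#' dominate the standing variance. This architecture makes the ancestral
#' variance decay steeply at first (the strongly selected share is purged)
#' and then at a near-neutral rate. The `sd` values are quoted at the
#' reference population size `N = 10000`; use [rescale_effects()] for
#' desk-scale runs.
#'
#' @param w_big weight of the large-effect component.
#' @param sd_small,sd_big component standard deviations (phenotype units).
#' @return An `effect_distribution`.
#' @export
heavy_tail_effects <- function(w_big = 0.05, sd_small = 0.01, sd_big = 0.2) {
  effect_distribution("mixture", weights = c(1 - w_big, w_big),
                      sds = c(sd_small, sd_big))
}

#' Rescale effect sizes to preserve the population-scaled selection strength
#'
#' The dynamics of a locus depend on the effect size only through
#' `S = 2*N*a^2/w^2` (and on time through `t/2N`), so a simulation at reduced
#' `N` reproduces full-scale behaviour when every effect-size sd is multiplied
#' by `sqrt(N_ref/N)`.
#'
#' @param dist an [effect_distribution()].
#' @param N the population size the simulation will use.
#' @param N_ref the reference population size at which `dist`'s sds are quoted.
#' @return The rescaled `effect_distribution`.
#' @export
rescale_effects <- function(dist, N, N_ref = 10000) {
  stopifnot(inherits(dist, "effect_distribution"), N >= 2, N_ref >= 2)
  effect_distribution("mixture", weights = dist$weights,
                      sds = dist$sds * sqrt(N_ref / N))
}

#' Sample mutation effects
#' @param n number of draws.
#' @param dist an [effect_distribution()].
#' @return Numeric vector of effects.
#' @export
reffects <- function(n, dist) {
  comp <- sample.int(length(dist$weights), n, replace = TRUE,
                     prob = dist$weights)
  stats::rnorm(n, 0, dist$sds[comp])
}

#' Density of the mutation effect distribution
#' @param a effect sizes.
#' @param dist an [effect_distribution()].
#' @export
deffects <- function(a, dist) {
  out <- 0
  for (k in seq_along(dist$weights))
    out <- out + dist$weights[k] * stats::dnorm(a, 0, dist$sds[k])
  out
}

# second moment E[a^2] of the mutation distribution
effect_second_moment <- function(dist) sum(dist$weights * dist$sds^2)
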