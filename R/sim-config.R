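#' Simulation configuration
#'
#' Collects every knob of the forward simulator. Defaults are the package's
#' desk-scale study conditions: `N = 1000` diploids with effect sizes rescaled
#' from the `N = 10000` reference by `sqrt(10)` so that the population-scaled
#' selection coefficient `S = 2*N*a^2/w^2` of every mutation class is
#' preserved, divergence measured in units of `t/2N`, and a mutation rate
#' giving an equilibrium trait basis of roughly a thousand segregating loci.
#'
#' @param N diploid population size (>= 2).
#' @param w width of the Gaussian fitness peak in phenotype units (`w^2` is the
#'   usual `V_S`); `Inf` switches selection off (neutral trait).
#' @param U expected number of new trait mutations per diploid genome per
#'   generation.
#' @param env_sd environmental noise sd added to the genetic value when
#'   computing fitness (default 0, so the phenotype is the genetic value).
#' @param effect_dist an [effect_distribution()] quoted at `N_ref`.
#' @param N_ref reference population size at which `effect_dist` sds are
#'   quoted; effects are rescaled to `N` with [rescale_effects()].
#' @param burn_in burn-in length in generations (default `10 * N`).
#' @param split_time divergence time in generations used by
#'   [split_and_evolve()] when not given explicitly.
#' @param optimum ancestral optimum phenotype.
#' @param neutral_loci number of unlinked zero-effect markers attached at the
#'   split for F_ST estimation.
#' @param seed optional master seed recorded in outputs.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(N = 200, w = 5, U = 0.02, burn_in = 400)
#' @export
sim_config <- function(N = 1000, w = 5, U = 0.1, env_sd = 0,
                       effect_dist = effect_distribution("gaussian", sd = 0.1),
                       N_ref = 10000, burn_in = 10 * N,
                       split_time = round(0.05 * 2 * N), optimum = 0,
                       neutral_loci = 200, seed = NULL) {
  stopifnot(N >= 2, U >= 0, env_sd >= 0, burn_in >= 0, split_time >= 0,
            neutral_loci >= 0)
  if (!(is.infinite(w) || w > 0)) stop("w must be positive or Inf")
  stopifnot(inherits(effect_dist, "effect_distribution"))
  scaled <- if (N_ref == N) effect_dist else rescale_effects(effect_dist, N, N_ref)
  structure(list(N = as.integer(N), w = w, U = U, env_sd = env_sd,
                 effect_dist = effect_dist, effect_dist_scaled = scaled,
                 N_ref = N_ref, burn_in = as.integer(burn_in),
                 split_time = as.integer(split_time), optimum = optimum,
                 neutral_loci = as.integer(neutral_loci), seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> N = %d, w = %s, U = %g, burn_in = %d, split_time = %d\n",
              x$N, format(x$w), x$U, x$burn_in, x$split_time))
  cat(sprintf("  effects (at N): %s with sd(s) %s\n", x$effect_dist_scaled$kind,
              paste(signif(x$effect_dist_scaled$sds, 3), collapse = ", ")))
  invisible(x)
}
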