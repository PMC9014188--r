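#' Gaussian stabilizing-selection fitness
#'
#' Relative fitness of a phenotype `z` under a Gaussian fitness peak of width
#' `w` centred on the optimum: `exp(-(z - opt)^2 / (2 w^2))`.
#'
#' @param z phenotype(s).
#' @param opt optimum phenotype.
#' @param w fitness peak width (finite, positive).
#' @return Relative fitness in `(0, 1]`.
#' @examples
#' gaussian_fitness(0, 0, 5)        # 1 at the peak
#' gaussian_fitness(5, 0, 5)        # exp(-1/2)
#' @export
gaussian_fitness <- function(z, opt, w) {
  if (any(!is.finite(z)) || !is.finite(opt) || !is.finite(w) || w <= 0)
    stop("z and opt must be finite and w a finite positive number")
  exp(-(z - opt)^2 / (2 * w^2))
}

# low-level wrapper around the compiled Wright-Fisher cycle
wf_run <- function(pop, cfg, ngen, optimum, drop_fixed, record_every = 0) {
  dist <- cfg$effect_dist_scaled
  res <- wf_run_cpp(pop$geno, pop$eff, pop$id, pop$offset, as.integer(ngen),
                    cfg$w, as.numeric(optimum), cfg$env_sd, cfg$U,
                    dist$weights, dist$sds, drop_fixed, pop$next_id,
                    as.integer(record_every))
  out <- population_state(res$geno, res$eff, res$id, res$offset,
                          pop$generation + ngen, res$next_id)
  summ <- as.data.frame(res$summary)
  names(summ) <- c("gen", "mean_phenotype", "V_a", "V_A", "n_seg")
  summ$gen <- summ$gen + pop$generation
  attr(out, "summary") <- summ
  out
}

#' Advance a population by Wright-Fisher generations
#'
#' One cycle: additive genetic values are summed over loci, fitness is
#' Gaussian in the deviation of the phenotype (genetic value plus optional
#' environmental noise) from the optimum, parents are sampled with probability
#' proportional to fitness, every locus is transmitted independently (free
#' recombination), and `Poisson(N * U)` new mutations arise at fresh sites
#' with effects drawn from the configured distribution. With
#' `drop_fixed = TRUE`, loci hitting frequency 0 are dropped and loci hitting
#' 1 are folded into the substitution offset (`+2a`).
#'
#' @param pop a [population_state()].
#' @param cfg a [sim_config()].
#' @param generations number of cycles.
#' @param optimum optimum phenotype: scalar, or vector of length `generations`.
#' @param drop_fixed fold fixed loci into the offset (set `FALSE` to keep
#'   columns aligned across diverging populations).
#' @param record_every record variance summaries every this many generations
#'   (0 = final state only); retrieved with `attr(, "summary")`.
#' @return The evolved `population_state`.
#' @export
advance_generation <- function(pop, cfg, generations = 1,
                               optimum = cfg$optimum, drop_fixed = TRUE,
                               record_every = 0) {
  stopifnot(inherits(pop, "population_state"), inherits(cfg, "sim_config"))
  if (length(optimum) != 1 && length(optimum) != generations)
    stop("optimum must be scalar or one value per generation")
  wf_run(pop, cfg, generations, optimum, drop_fixed, record_every)
}

#' Burn a population to mutation-selection-drift equilibrium
#'
#' Starts from a monomorphic population and runs `cfg$burn_in` generations
#' (10N by default). Stationarity is asserted by regressing the recorded
#' `V_a` series over the last `N` generations on time; a significant trend
#' triggers a warning and is reported in the attributes.
#'
#' @param cfg a [sim_config()].
#' @param record_every sampling interval for the `V_a` series.
#' @return A `population_state` with attributes `summary` (the recorded
#'   series), `equilibrium_va` (mean `V_a` over the last `N` generations) and
#'   `stationary` (logical).
#' @export
burn_in_to_equilibrium <- function(cfg, record_every = max(1L, cfg$N %/% 20L)) {
  pop <- new_population(cfg)
  pop <- advance_generation(pop, cfg, cfg$burn_in, drop_fixed = TRUE,
                            record_every = record_every)
  summ <- attr(pop, "summary")
  tail_w <- summ[summ$gen > cfg$burn_in - cfg$N, , drop = FALSE]
  stationary <- NA
  if (nrow(tail_w) >= 5 && stats::sd(tail_w$V_a) > 0) {
    fit <- stats::lm(V_a ~ gen, data = tail_w)
    pval <- summary(fit)$coefficients[2, 4]
    # drift makes successive V_a values autocorrelated, so use a permissive
    # cutoff: only a strong monotone trend flags non-equilibrium
    stationary <- pval > 1e-4
  } else if (cfg$U == 0) {
    stationary <- FALSE
  }
  if (isFALSE(stationary))
    warning("V_a still trending at the end of the burn-in; population may not be at equilibrium")
  attr(pop, "equilibrium_va") <- mean(tail_w$V_a)
  attr(pop, "stationary") <- stationary
  pop
}

# draw standing neutral marker frequencies from the equilibrium 1/x spectrum
# truncated to [1/2N, 1 - 1/2N], and HWE genotypes
attach_markers <- function(pop, n_markers) {
  if (n_markers == 0) return(pop)
  n <- nrow(pop$geno)
  lo <- 1 / (2 * n)
  p <- lo * (( (1 - lo) / lo)^stats::runif(n_markers))
  g <- matrix(stats::rbinom(n * n_markers, 2L, rep(p, each = n)), n, n_markers)
  population_state(cbind(pop$geno, g), c(pop$eff, numeric(n_markers)),
                   c(pop$id, -seq_len(n_markers)), pop$offset,
                   pop$generation, pop$next_id)
}

#' Split an ancestral population and evolve two descendants
#'
#' Copies the ancestor into populations A and B and evolves each
#' independently for `t` generations with no gene flow, using derived child
#' seeds so the two branches draw from independent randomness. Neutral
#' zero-effect markers (for F_ST estimation) are attached to the ancestor at
#' the split, with frequencies drawn from the neutral equilibrium spectrum.
#' Ancestral locus columns are kept aligned (not folded on fixation) so that
#' cross-population frequencies, scores and origins stay reconstructible;
#' mutations arising after the split are private to their branch. An optional
#' optimum schedule is applied identically to both branches.
#'
#' @param ancestor an equilibrium [population_state()].
#' @param cfg a [sim_config()].
#' @param t generations of divergence.
#' @param snapshot_gens generations (each `<= t`) at which to save both
#'   populations; defaults to `t` only.
#' @param optimum_schedule `NULL` for a constant optimum, or a data.frame with
#'   columns `generation` (non-decreasing, post-split) and `optimum`.
#' @return A list of class `split_result` with the ancestor, per-snapshot
#'   population pairs, and bookkeeping needed by [locus_table()].
#' @export
split_and_evolve <- function(ancestor, cfg, t = cfg$split_time,
                             snapshot_gens = t, optimum_schedule = NULL) {
  stopifnot(inherits(ancestor, "population_state"))
  snapshot_gens <- sort(unique(as.integer(snapshot_gens)))
  if (any(snapshot_gens > t) || any(snapshot_gens < 0))
    stop("snapshot generations must lie in [0, t]")
  anc <- attach_markers(ancestor, cfg$neutral_loci)
  p_anc <- colSums(anc$geno) / (2 * nrow(anc$geno))
  anc_ids <- anc$id

  opt <- rep(cfg$optimum, t)
  if (!is.null(optimum_schedule)) {
    stopifnot(all(c("generation", "optimum") %in% names(optimum_schedule)),
              !is.unsorted(optimum_schedule$generation))
    for (k in seq_len(nrow(optimum_schedule))) {
      gk <- optimum_schedule$generation[k]
      if (gk <= t) opt[seq.int(max(gk, 1), t)] <- optimum_schedule$optimum[k]
    }
  }

  seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  id_shift <- 10000000L
  evolve_branch <- function(seed, shift) {
    set.seed(seed)
    pop <- anc
    pop$next_id <- pop$next_id + shift
    out <- vector("list", length(snapshot_gens))
    prev <- 0L
    for (k in seq_along(snapshot_gens)) {
      gk <- snapshot_gens[k]
      if (gk > prev)
        pop <- wf_run(pop, cfg, gk - prev, opt[seq.int(prev + 1L, gk)],
                      drop_fixed = FALSE)
      out[[k]] <- pop
      prev <- gk
    }
    out
  }
  A <- evolve_branch(seeds[1], 0L)
  B <- evolve_branch(seeds[2], id_shift)

  structure(list(ancestor = anc, p_anc = p_anc, anc_ids = anc_ids,
                 id_shift = id_shift, first_new_id = ancestor$next_id,
                 snapshot_gens = snapshot_gens, A = A, B = B, cfg = cfg,
                 t = t, seeds = seeds, optimum = opt),
            class = "split_result")
}

snapshot_index <- function(sr, gen) {
  k <- match(as.integer(gen), sr$snapshot_gens)
  if (is.na(k)) stop("no snapshot was recorded at generation ", gen)
  k
}

#' Extract one population from a split snapshot
#' @param sr a [split_and_evolve()] result.
#' @param gen a recorded snapshot generation.
#' @param pop `"A"` or `"B"`.
#' @export
snapshot_population <- function(sr, gen, pop = c("A", "B")) {
  pop <- match.arg(pop)
  sr[[pop]][[snapshot_index(sr, gen)]]
}

#' Per-locus interchange table for a pair of diverged populations
#'
#' One row per locus known to either population at the snapshot: its effect,
#' derived-allele frequency in the ancestor (at the split) and in each
#' descendant, its origin (`ancestral`, `private_A`, `private_B`), its status
#' in each population (`segregating`, `lost`, `fixed`) and an `ascertained`
#' flag initialized to `FALSE` (set by [ascertain()]).
#'
#' @param sr a [split_and_evolve()] result.
#' @param gen a recorded snapshot generation.
#' @param markers if `TRUE`, return the zero-effect neutral markers instead of
#'   the trait loci.
#' @return A data.frame.
#' @export
locus_table <- function(sr, gen = sr$t, markers = FALSE) {
  k <- snapshot_index(sr, gen)
  A <- sr$A[[k]]
  B <- sr$B[[k]]
  ids <- sort(union(A$id, B$id))
  n2 <- 2 * nrow(A$geno)
  pA <- pB <- rep(0, length(ids))
  iA <- match(A$id, ids)
  pA[iA] <- colSums(A$geno) / n2
  eff <- rep(NA_real_, length(ids))
  eff[iA] <- A$eff
  iB <- match(B$id, ids)
  pB[iB] <- colSums(B$geno) / n2
  eff[iB] <- B$eff
  p0 <- rep(0, length(ids))
  ianc <- match(sr$anc_ids, ids)
  p0[ianc[!is.na(ianc)]] <- sr$p_anc[!is.na(ianc)]
  origin <- ifelse(ids < 0, "marker",
            ifelse(ids %in% sr$anc_ids, "ancestral",
            ifelse(ids >= sr$first_new_id + sr$id_shift, "private_B",
                   "private_A")))
  status <- function(p) ifelse(p == 0, "lost", ifelse(p == 1, "fixed",
                                                      "segregating"))
  out <- data.frame(locus_id = ids, effect = eff, p_anc = p0, p_A = pA,
                    p_B = pB, origin = origin, status_A = status(pA),
                    status_B = status(pB), ascertained = FALSE)
  if (markers) out[out$origin == "marker", , drop = FALSE]
  else out[out$origin != "marker", , drop = FALSE]
}
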