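#' Replicate ensemble of ancestral-variance decay curves
#'
#' Burns replicate ancestors to equilibrium, splits each into two
#' descendants, and tracks the fraction of the ancestor's genic variance
#' still contributed by ancestral polymorphisms at each requested time,
#' alongside the diffusion-tier analytic prediction.
#'
#' @param cfg a [sim_config()].
#' @param times snapshot generations (each `<= max(times)`).
#' @param n_ancestors independent equilibrium burn-ins.
#' @param splits_per_ancestor independent splits of each ancestor.
#' @param theory attach the analytic prediction as attribute `"theory"`.
#' @return A data.frame with one row per (ancestor, split, branch, time):
#'   columns `ancestor`, `split`, `branch`, `t`, `retention`.
#' @export
run_decay <- function(cfg, times, n_ancestors = 5, splits_per_ancestor = 4,
                      theory = TRUE) {
  times <- sort(unique(as.integer(times)))
  rows <- list()
  for (anc_i in seq_len(n_ancestors)) {
    anc <- suppressWarnings(burn_in_to_equilibrium(cfg))
    for (sp in seq_len(splits_per_ancestor)) {
      sr <- split_and_evolve(anc, cfg, t = max(times), snapshot_gens = times)
      for (tt in times) {
        loci <- locus_table(sr, tt)
        ancrows <- loci[loci$origin == "ancestral", , drop = FALSE]
        v0 <- sum(per_locus_variance(ancrows$p_anc, ancrows$effect))
        for (br in c("A", "B")) {
          p <- ancrows[[paste0("p_", br)]]
          rows[[length(rows) + 1]] <- data.frame(
            ancestor = anc_i, split = sp, branch = br, t = tt,
            retention = sum(per_locus_variance(p, ancrows$effect)) / v0)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (theory)
    attr(out, "theory") <- ancestral_variance_remaining(
      cfg$effect_dist_scaled, cfg$N, cfg$w, times)
  out
}

#' Replicate ensemble of polygenic-score portability
#'
#' For each replicate split and each ascertainment scheme, ascertains loci in
#' population A, builds polygenic scores in both populations from their
#' genotypes, and records the within-population accuracy ratios
#' `Var(S)/Var(G)` and their B/A ratio (the portability of the score).
#'
#' @inheritParams run_decay
#' @param schemes named list of [ascertainment_scheme()] objects.
#' @return A data.frame with columns `ancestor`, `split`, `t`, `scheme`,
#'   `ratio_A`, `ratio_B`, `relative`; analytic predictions per scheme in
#'   attribute `"theory"` when requested.
#' @export
run_portability <- function(cfg, times,
                            schemes = list(all = ascertainment_scheme("all")),
                            n_ancestors = 5, splits_per_ancestor = 4,
                            theory = FALSE) {
  times <- sort(unique(as.integer(times)))
  rows <- list()
  for (anc_i in seq_len(n_ancestors)) {
    anc <- suppressWarnings(burn_in_to_equilibrium(cfg))
    for (sp in seq_len(splits_per_ancestor)) {
      sr <- split_and_evolve(anc, cfg, t = max(times), snapshot_gens = times)
      for (tt in times) {
        loci <- locus_table(sr, tt)
        popA <- snapshot_population(sr, tt, "A")
        popB <- snapshot_population(sr, tt, "B")
        for (sc in names(schemes)) {
          flagged <- ascertain(loci, schemes[[sc]])
          sA <- score_set(popA, flagged, "A")
          sB <- score_set(popB, flagged, "B")
          rows[[length(rows) + 1]] <- data.frame(
            ancestor = anc_i, split = sp, t = tt, scheme = sc,
            ratio_A = sA$accuracy_ratio, ratio_B = sB$accuracy_ratio,
            relative = relative_accuracy(sB, sA))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (theory) {
    th <- lapply(names(schemes), function(sc) {
      cbind(scheme = sc,
            shared_variance_ratio(cfg$effect_dist_scaled, cfg$N, cfg$w,
                                  times, schemes[[sc]]))
    })
    attr(out, "theory") <- do.call(rbind, th)
  }
  out
}

#' Replicate ensemble of Q_X statistics
#'
#' Runs the constant-optimum (`optimum_shift = 0`) or shared-optimum-shift
#' experiment: each replicate split is evolved with the optimum moved by
#' `optimum_shift` phenotypic standard deviations (of the ancestral
#' equilibrium) in both descendants immediately after the split, loci are
#' ascertained in population A, and the full [qx_result()] record is kept at
#' every requested time.
#'
#' @inheritParams run_decay
#' @param scheme an [ascertainment_scheme()].
#' @param optimum_shift shift applied identically to both populations, in
#'   units of the ancestral phenotypic standard deviation.
#' @param fst_source `"markers"` (Hudson estimator on the simulated neutral
#'   markers) or `"expected"` (`t/2N`).
#' @return A data.frame with one row per (ancestor, split, time) carrying the
#'   `qx_result` fields.
#' @export
run_qx <- function(cfg, times, scheme = ascertainment_scheme("all"),
                   n_ancestors = 5, splits_per_ancestor = 4,
                   optimum_shift = 0, fst_source = c("markers", "expected")) {
  fst_source <- match.arg(fst_source)
  times <- sort(unique(as.integer(times)))
  rows <- list()
  for (anc_i in seq_len(n_ancestors)) {
    anc <- suppressWarnings(burn_in_to_equilibrium(cfg))
    sched <- NULL
    if (optimum_shift != 0) {
      vp <- summarize_state(anc, cfg$env_sd)$V_P
      sched <- data.frame(generation = 1,
                          optimum = cfg$optimum + optimum_shift * sqrt(vp))
    }
    for (sp in seq_len(splits_per_ancestor)) {
      sr <- split_and_evolve(anc, cfg, t = max(times), snapshot_gens = times,
                             optimum_schedule = sched)
      for (tt in times) {
        loci <- ascertain(locus_table(sr, tt), scheme)
        mk <- locus_table(sr, tt, markers = TRUE)
        qr <- qx_result(loci, mk, fst_source = fst_source, N = cfg$N, t = tt)
        rows[[length(rows) + 1]] <- data.frame(
          ancestor = anc_i, split = sp, t = tt,
          Z_A = qr$Z_A, Z_B = qr$Z_B, V_a = qr$V_a, fst = qr$fst,
          Q_X = qr$Q_X, p_value = qr$p_value, std_diff = qr$std_diff,
          delta_ascertained = qr$delta_ascertained,
          delta_non_ascertained = qr$delta_non_ascertained,
          delta_total = qr$delta_total)
      }
    }
  }
  do.call(rbind, rows)
}

#' False-positive rate of the Q_X test by time point
#' @param qx_table output of [run_qx()].
#' @param alpha significance level.
#' @return A data.frame with columns `t`, `n`, `fpr`.
#' @export
fpr_by_time <- function(qx_table, alpha = 0.05) {
  agg <- stats::aggregate(p_value ~ t, data = qx_table,
                          FUN = function(p) mean(p < alpha, na.rm = TRUE))
  n <- stats::aggregate(p_value ~ t, data = qx_table, FUN = length)
  data.frame(t = agg$t, n = n$p_value, fpr = agg$p_value)
}
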