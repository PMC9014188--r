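#' Mean polygenic score of a population
#'
#' Twice the sum of allele frequencies weighted by effect sizes over the
#' flagged loci: `Z = 2 sum p_l a_l`. Loci fixed in the population among the
#' flagged set enter with `p = 1` (contributing `2a`), since a genotyped
#' score panel keeps its markers regardless of local polymorphism.
#'
#' @param p allele frequencies of the flagged loci in this population.
#' @param a matching effect sizes.
#' @return The mean score `Z`.
#' @examples
#' mean_polygenic_score(0.5, 1)  # 1
#' @export
mean_polygenic_score <- function(p, a) {
  stopifnot(length(p) == length(a), all(p >= 0), all(p <= 1))
  2 * sum(p * a)
}

#' Hudson-type F_ST from a pair of allele-frequency vectors
#'
#' Ratio-of-averages estimator on population frequencies:
#' `sum (p_A - p_B)^2 / sum (p_A (1 - p_B) + p_B (1 - p_A))`. The expected
#' value for a clean split of `t` generations without migration is
#' approximately `t / 2N`.
#'
#' @param p_A,p_B frequency vectors at the same (neutral) markers.
#' @return A list with `fst` (`NA` if every marker is monomorphic in both
#'   populations) and `n_markers` used.
#' @examples
#' fst_hudson(0.2, 0.4)  # 0.04 / 0.44
#' @export
fst_hudson <- function(p_A, p_B) {
  stopifnot(length(p_A) == length(p_B),
            all(p_A >= 0 & p_A <= 1), all(p_B >= 0 & p_B <= 1))
  den <- sum(p_A * (1 - p_B) + p_B * (1 - p_A))
  if (den == 0) {
    warning("all markers monomorphic; F_ST undefined")
    return(list(fst = NA_real_, n_markers = length(p_A)))
  }
  list(fst = sum((p_A - p_B)^2) / den, n_markers = length(p_A))
}

#' Q_X statistic for a pair of populations
#'
#' `Q_X = (Z_A - Z_B)^2 / (4 V_a F_ST)`, chi-square distributed with one
#' degree of freedom when the trait evolves neutrally (the two-population
#' Lewontin-Krakauer-style null). Values well below 1 indicate
#' under-dispersion of mean scores, as expected under stabilizing selection
#' to a shared optimum; values above 1 suggest directional differentiation.
#'
#' @param Z_A,Z_B mean polygenic scores.
#' @param V_a genic variance of the score's loci (see [qx_result()] for the
#'   convention used).
#' @param fst neutral-marker F_ST.
#' @return A list with `Q_X` and `p_value` (upper tail of chi-square df 1).
#' @examples
#' qx(0.2, 0, 1, 0.01)  # Q_X = 1, p ~ 0.317
#' @export
qx <- function(Z_A, Z_B, V_a, fst) {
  if (is.na(fst) || fst <= 0) {
    warning("F_ST is zero or undefined; Q_X undefined")
    return(list(Q_X = NA_real_, p_value = NA_real_))
  }
  stopifnot(V_a > 0)
  stat <- (Z_A - Z_B)^2 / (4 * V_a * fst)
  list(Q_X = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Q_ST from additive genetic values of two populations
#'
#' The proportion of additive-genetic-value variance attributable to
#' among-population differences: `Q_ST = V_between / (V_between + V_within)`
#' with `V_between = (mean_A - mean_B)^2 / 2` (the one-degree-of-freedom
#' among-group variance component of the two population means) and
#' `V_within` the average within-population variance of the values. For a
#' neutral strictly additive trait the expectation is `2 F_ST / (1 + 2
#' F_ST)`, i.e. approximately twice the neutral-marker F_ST when divergence
#' is small. A single population pair yields a one-degree-of-freedom
#' (chi-square-shaped) `V_between`, so ensemble summaries should pool the
#' returned components across replicates rather than average `Q_ST` itself.
#'
#' @param values_A,values_B additive genetic values (one per individual).
#' @return A list with `Q_ST`, `V_between` and `V_within`.
#' @export
qst <- function(values_A, values_B) {
  vw <- (stats::var(values_A) + stats::var(values_B)) / 2
  if (!is.finite(vw) || vw == 0) {
    warning("within-population variance is zero; Q_ST undefined")
    return(list(Q_ST = NA_real_, V_between = NA_real_, V_within = vw))
  }
  vb <- (mean(values_A) - mean(values_B))^2 / 2
  list(Q_ST = vb / (vb + vw), V_between = vb, V_within = vw)
}

#' Partition the mean score difference by ascertainment
#'
#' Splits the full additive-genetic-value mean difference
#' `2 sum a (p_A - p_B)` into the part carried by ascertained loci and the
#' part carried by the rest. The two parts sum to the total exactly; under
#' stabilizing selection to a shared optimum they tend to oppose each other.
#'
#' @param loci a [locus_table()] with `ascertained` flags.
#' @return A list with `delta_ascertained`, `delta_non_ascertained`,
#'   `delta_total`.
#' @export
partition_mean_difference <- function(loci) {
  d <- 2 * loci$effect * (loci$p_A - loci$p_B)
  asc <- sum(d[loci$ascertained])
  non <- sum(d[!loci$ascertained])
  list(delta_ascertained = asc, delta_non_ascertained = non,
       delta_total = asc + non)
}

#' Full Q_X record for one replicate
#'
#' Computes mean scores over the ascertained loci, the genic variance of
#' those loci (by default with frequencies averaged across the two
#' populations, which is symmetric and reduces to the single-population
#' genic variance when the populations coincide), F_ST (from neutral markers
#' or the expected `t/2N`), `Q_X` with its p-value, the standardized mean
#' difference `|Z_A - Z_B| / sqrt(V_a)` (which equals
#' `sqrt(4 Q_X F_ST)` exactly), and the ascertained / non-ascertained
#' partition of the mean difference.
#'
#' @param loci a [locus_table()] with `ascertained` flags.
#' @param markers marker table (from `locus_table(sr, gen, markers = TRUE)`),
#'   required when `fst_source = "markers"`.
#' @param fst_source `"markers"` or `"expected"`.
#' @param va_freqs `"mean"` (average frequencies across populations) or
#'   `"A"` (population-A frequencies) in the Q_X denominator.
#' @param N,t population size and divergence time, needed for
#'   `fst_source = "expected"`.
#' @return An object of class `qx_result`: a list with fields `Z_A`, `Z_B`,
#'   `V_a`, `fst`, `Q_X`, `p_value`, `std_diff`, `delta_ascertained`,
#'   `delta_non_ascertained`, `delta_total`.
#' @export
qx_result <- function(loci, markers = NULL,
                      fst_source = c("markers", "expected"),
                      va_freqs = c("mean", "A"), N = NULL, t = NULL) {
  fst_source <- match.arg(fst_source)
  va_freqs <- match.arg(va_freqs)
  asc <- loci[loci$ascertained, , drop = FALSE]
  Z_A <- mean_polygenic_score(asc$p_A, asc$effect)
  Z_B <- mean_polygenic_score(asc$p_B, asc$effect)
  pbar <- switch(va_freqs, mean = (asc$p_A + asc$p_B) / 2, A = asc$p_A)
  V_a <- sum(per_locus_variance(pbar, asc$effect))
  fst <- if (fst_source == "markers") {
    stopifnot(!is.null(markers))
    fst_hudson(markers$p_A, markers$p_B)$fst
  } else {
    stopifnot(!is.null(N), !is.null(t))
    t / (2 * N)
  }
  qres <- if (V_a > 0) qx(Z_A, Z_B, V_a, fst)
          else list(Q_X = NA_real_, p_value = NA_real_)
  part <- partition_mean_difference(loci)
  structure(c(list(Z_A = Z_A, Z_B = Z_B, V_a = V_a, fst = fst,
                   Q_X = qres$Q_X, p_value = qres$p_value,
                   std_diff = if (V_a > 0) abs(Z_A - Z_B) / sqrt(V_a)
                              else NA_real_),
              part),
            class = "qx_result")
}

#' @export
print.qx_result <- function(x, ...) {
  cat(sprintf("<qx_result> Z_A = %.4g, Z_B = %.4g, V_a = %.4g, F_ST = %.4g\n",
              x$Z_A, x$Z_B, x$V_a, x$fst))
  cat(sprintf("  Q_X = %.4g (p = %.4g), std diff = %.4g\n", x$Q_X, x$p_value,
              x$std_diff))
  cat(sprintf("  mean-difference partition: ascertained %.4g, rest %.4g\n",
              x$delta_ascertained, x$delta_non_ascertained))
  invisible(x)
}
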