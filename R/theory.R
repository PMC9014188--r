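#' Population-scaled selection coefficient of a trait allele
#'
#' Under Gaussian stabilizing selection with the population mean at the
#' optimum, an allele of effect `a` experiences underdominant selection whose
#' strength relative to drift is `S = 2 N a^2 / w^2`.
#'
#' @param a allele effect size (phenotype units).
#' @param N diploid population size.
#' @param w fitness peak width.
#' @return Dimensionless `S >= 0`.
#' @examples
#' scaled_selection(0.1, 10000, 5)  # 8
#' @export
scaled_selection <- function(a, N, w) {
  stopifnot(w > 0)
  2 * N * a^2 / w^2
}

# per-generation underdominant selection coefficient against heterozygotes
# induced at a trait locus when the mean phenotype sits at the optimum:
# marginal fitnesses of the three genotypes under a Gaussian peak give
# delta p = s * p * q * (2p - 1) with s = a^2 / (2 (w^2 + V_P))
underdominant_s <- function(a, w, V_P = 0) a^2 / (2 * (w^2 + V_P))

#' Deterministic underdominant allele-frequency trajectory
#'
#' Iterates the infinite-population per-generation frequency change of a
#' trait allele under stabilizing selection with the mean at the optimum:
#' `p' = p + s p (1-p) (2p - 1)` with `s = a^2 / (2 (w^2 + V_P))`. The point
#' `p = 1/2` is an unstable equilibrium; the minor allele is driven out.
#'
#' @param p0 starting frequency in (0, 1).
#' @param a allele effect size.
#' @param w fitness peak width.
#' @param generations number of generations to iterate.
#' @param V_P phenotypic variance entering the effective peak width.
#' @return Numeric vector of length `generations + 1` starting at `p0`.
#' @export
deterministic_trajectory <- function(p0, a, w, generations, V_P = 0) {
  stopifnot(p0 > 0, p0 < 1, generations >= 0)
  s <- underdominant_s(a, w, V_P)
  p <- numeric(generations + 1)
  p[1] <- p0
  for (g in seq_len(generations))
    p[g + 1] <- p[g] + s * p[g] * (1 - p[g]) * (2 * p[g] - 1)
  p
}

#' Closed-form retention of ancestral genic variance
#'
#' The classical per-generation-loss approximation for the fraction of genic
#' variance (equivalently heterozygosity) contributed by an ancestral allele
#' of effect `a` that remains after `t` generations: the exact product form
#' `(1 - 1/2N)^t (1 - a^2/(4 (w^2 + V_P)))^t` and its exponential
#' approximation `exp(-F_ST (1 + S/4))` with `F_ST = t/2N` and
#' `S = 2 N a^2 / w^2`. These closed forms are cheap and offer good
#' intuition; [diffusion_retention()] is the more accurate tier.
#'
#' @param a allele effect size (may be a vector).
#' @param t generations (may be a vector if `a` is scalar).
#' @param N diploid population size.
#' @param w fitness peak width; `Inf` for a neutral allele.
#' @param V_P phenotypic variance (`V_P << w^2` is assumed).
#' @return A data.frame with columns `a`, `t`, `product`, `exponential`.
#' @examples
#' closed_form_retention(0.1, 1500, 10000, 5)
#' @export
closed_form_retention <- function(a, t, N, w, V_P = 0) {
  stopifnot(all(t >= 0), V_P >= 0)
  if (is.infinite(w)) {
    sel_loss <- 0 * a
    S <- 0 * a
  } else {
    sel_loss <- a^2 / (4 * (w^2 + V_P))
    S <- scaled_selection(a, N, w)
  }
  if (any(sel_loss >= 1))
    stop("a^2 / (4 (w^2 + V_P)) >= 1: outside the approximation's domain")
  fst <- t / (2 * N)
  data.frame(a = a, t = t,
             product = (1 - 1 / (2 * N))^t * (1 - sel_loss)^t,
             exponential = exp(-fst * (1 + S / 4)))
}

# unnormalized stationary sojourn density of the underdominant diffusion with
# influx at frequency 0 (Wright's formula): psi(x) = I(x) e^{-S x q} / (x q),
# where I(x) = int_x^1 e^{S y (1-y)} dy. Neutral limit: psi = 1/x.
standing_density <- function(x, S) {
  grid <- seq(0, 1, length.out = 4001)
  f <- exp(S * grid * (1 - grid))
  # I as right-to-left cumulative trapezoid
  dg <- diff(grid)
  seg <- dg * (f[-1] + f[-length(f)]) / 2
  Irev <- c(rev(cumsum(rev(seg))), 0)
  I <- stats::approx(grid, Irev, xout = x)$y
  I * exp(-S * x * (1 - x)) / (x * (1 - x))
}

# normalizing constant J = int_0^1 e^{S y (1-y)} dy
sojourn_J <- function(S) {
  grid <- seq(0, 1, length.out = 4001)
  f <- exp(S * grid * (1 - grid))
  sum(diff(grid) * (f[-1] + f[-length(f)]) / 2)
}

#' Wright-Fisher transition-matrix oracle for heterozygosity retention
#'
#' Brute-force companion to the analytic tiers: builds the full binomial
#' Wright-Fisher transition matrix at a small population size with the
#' deterministic underdominant frequency change applied before sampling,
#' iterates it from a starting distribution over segregating states, and
#' returns the expected retained heterozygosity fraction
#' `E[2pq]_t / E[2pq]_0` at each requested time.
#'
#' @param a allele effect size.
#' @param t vector of generation counts.
#' @param N diploid population size (`<= 500`; matrix is `(2N+1)^2`).
#' @param w fitness peak width; `Inf` for neutral.
#' @param start `"equilibrium"` for the stationary sojourn density of the
#'   matched diffusion, `"uniform"` for equal mass on segregating states, or
#'   a numeric vector of length `2N - 1` over counts `1..2N-1`.
#' @param V_P phenotypic variance in the effective peak width.
#' @return A data.frame with columns `t` and `retention`.
#' @export
wf_matrix_retention <- function(a, t, N, w, start = "equilibrium", V_P = 0) {
  stopifnot(N >= 2, all(t >= 0))
  if (N > 500) stop("N too large for the dense transition matrix; use N <= 500")
  t <- as.integer(t)
  n2 <- 2L * N
  p <- (0:n2) / n2
  s <- if (is.infinite(w)) 0 else underdominant_s(a, w, V_P)
  pp <- pmin(pmax(p + s * p * (1 - p) * (2 * p - 1), 0), 1)
  # rows: destination count j; columns: parent state i with mean pp[i]
  M <- vapply(pp, function(prob) stats::dbinom(0:n2, n2, prob),
              numeric(n2 + 1L))
  interior <- 2:n2
  if (is.character(start)) {
    start <- match.arg(start, c("equilibrium", "uniform"))
    S <- if (is.infinite(w)) 0 else scaled_selection(a, N, w) *
      w^2 / (w^2 + V_P)
    phi0 <- if (start == "uniform") rep(1, n2 - 1L)
            else standing_density(p[interior], S)
  } else {
    stopifnot(length(start) == n2 - 1L)
    phi0 <- start
  }
  phi <- numeric(n2 + 1L)
  phi[interior] <- phi0 / sum(phi0)
  h <- 2 * p * (1 - p)
  h0 <- sum(h * phi)
  out <- numeric(length(t))
  ord <- order(t)
  cur <- 0L
  for (k in ord) {
    while (cur < t[k]) {
      phi <- as.numeric(M %*% phi)
      cur <- cur + 1L
    }
    out[k] <- sum(h * phi) / h0
  }
  data.frame(t = t, retention = out)
}

# implicit-Euler solver for the backward Kolmogorov equation of the
# underdominant diffusion in units of 2N generations:
#   dh/dtau = (S/2) x q (2x - 1) h' + (x q / 2) h''
# with absorbing boundaries. Returns h(x, tau) at the interior grid for each
# requested tau, for initial payoff g(x).
diffusion_payoff <- function(S, taus, payoff, M = 1200, dtau = 5e-4) {
  taus <- sort(unique(taus))
  stopifnot(all(taus >= 0))
  x <- seq(0, 1, length.out = M + 2)[2:(M + 1)]
  dx <- 1 / (M + 1)
  alpha <- (S / 2) * x * (1 - x) * (2 * x - 1)
  beta <- x * (1 - x) / 2
  lower <- beta / dx^2 - alpha / (2 * dx)
  upper <- beta / dx^2 + alpha / (2 * dx)
  centr <- -2 * beta / dx^2
  h <- if (is.function(payoff)) payoff(x) else payoff
  stopifnot(length(h) == M)
  out <- matrix(NA_real_, M, length(taus))
  colnames(out) <- as.character(taus)
  if (taus[1] == 0) out[, 1] <- h
  todo <- taus[taus > 0]
  if (length(todo)) {
    nsteps <- pmax(1L, as.integer(round(todo / dtau)))
    dts <- todo / nsteps
    # single step size keyed to the finest requirement keeps one factorization
    dt <- min(dts)
    steps_at <- as.integer(round(todo / dt))
    A <- Matrix::bandSparse(M, M,
                            k = c(-1, 0, 1),
                            diagonals = list(-dt * lower[-1],
                                             1 - dt * centr,
                                             -dt * upper[-M]))
    A <- methods::as(A, "CsparseMatrix")
    fac <- Matrix::lu(A)
    cur <- 0L
    for (k in seq_along(todo)) {
      while (cur < steps_at[k]) {
        h <- as.numeric(Matrix::solve(fac, h))
        cur <- cur + 1L
      }
      out[, as.character(todo[k])] <- h
    }
  }
  list(x = x, tau = taus, h = out)
}

#' Diffusion-tier retention of ancestral genic variance
#'
#' Numerically solves the backward equation of the underdominant diffusion
#' for the expected heterozygosity `E[2pq]` after `t` generations, averaged
#' over the stationary sojourn density of segregating ancestral alleles, and
#' returns it as a fraction of the starting value. This is the accurate tier
#' used for figure-grade predictions; [closed_form_retention()] is its
#' small-`S` approximation.
#'
#' @param a allele effect size.
#' @param t vector of generation counts.
#' @param N diploid population size.
#' @param w fitness peak width; `Inf` for neutral.
#' @param M interior grid points of the frequency discretization.
#' @param dtau implicit-Euler step in units of `2N` generations.
#' @param V_P phenotypic variance entering the effective peak width
#'   `w^2 + V_P` (the background variance seen by each locus).
#' @return A data.frame with columns `t` and `retention`.
#' @export
diffusion_retention <- function(a, t, N, w, M = 1200, dtau = 5e-4, V_P = 0) {
  S <- if (is.infinite(w)) 0 else 4 * N * underdominant_s(a, w, V_P)
  taus <- t / (2 * N)
  sol <- diffusion_payoff(S, taus, function(x) 2 * x * (1 - x), M = M,
                          dtau = dtau)
  psi <- standing_density(sol$x, S)
  wts <- psi / sum(psi)
  h0 <- sum(2 * sol$x * (1 - sol$x) * wts)
  ret <- colSums(sol$h * wts) / h0
  data.frame(t = t, retention = as.numeric(ret[as.character(taus)]))
}

#' Equilibrium density of genic variance over effect sizes
#'
#' At mutation-selection-drift equilibrium the genic variance contributed by
#' alleles of effect size `a` is the mutational influx at that effect times
#' the expected heterozygosity integrated over an allele's sojourn:
#' `v(a) = mu(a) * N U * 2 a^2 * (2/J) * int e^{-S x q} I(x) dx`, with
#' `I(x) = int_x^1 e^{S y q} dy` and `J = I(0)`. Integrated over `a` this
#' equals the total equilibrium genic variance (for a neutral trait,
#' `2 N U E[a^2]`, and `v(a)` is proportional to `mu(a) a^2`).
#'
#' @param effect_dist an [effect_distribution()] (already at the scale of
#'   `N`; see [rescale_effects()]).
#' @param N diploid population size.
#' @param w fitness peak width; `Inf` for neutral.
#' @param U trait mutation rate per diploid genome per generation.
#' @param a_grid grid of (positive) effect sizes; defaults to an even grid to
#'   six sds of the widest component.
#' @return A data.frame with columns `a`, `density` (variance per unit
#'   effect, both signs of `a` folded), and attribute `total_va`.
#' @export
equilibrium_variance_density <- function(effect_dist, N, w, U = 1,
                                         a_grid = NULL, V_P = 0) {
  if (is.null(a_grid))
    a_grid <- seq(1e-4, 6 * max(effect_dist$sds), length.out = 80)
  stopifnot(all(a_grid > 0), !is.unsorted(a_grid))
  xg <- seq(0, 1, length.out = 2001)
  dens <- vapply(a_grid, function(a) {
    S <- if (is.infinite(w)) 0 else 4 * N * underdominant_s(a, w, V_P)
    f <- exp(S * xg * (1 - xg))
    seg <- diff(xg) * (f[-1] + f[-length(f)]) / 2
    I <- c(rev(cumsum(rev(seg))), 0)
    J <- I[1]
    integrand <- I / f # e^{-Sxq} I(x)
    quad <- sum(diff(xg) * (integrand[-1] + integrand[-length(integrand)]) / 2)
    # 2 N U mu(a) influx folded over both signs of a, times the expected
    # heterozygosity 2 a^2 (2/J) int I e^{-Sxq} integrated over a sojourn
    2 * N * U * deffects(a, effect_dist) * 2 * a^2 * 2 * quad / J
  }, numeric(1))
  total <- sum(diff(a_grid) * (dens[-1] + dens[-length(dens)]) / 2)
  # mass-conservation guard: refuse grids too coarse to integrate the density
  fine <- a_grid[-length(a_grid)] + diff(a_grid) / 2
  if (length(a_grid) < 20)
    stop("effect grid too coarse for a stable variance integral")
  out <- data.frame(a = a_grid, density = dens)
  attr(out, "total_va") <- total
  out
}

#' Predicted fraction of ancestral genic variance remaining after t generations
#'
#' Integrates the per-effect retention `R(a, t)` against the equilibrium
#' variance density `v(a)`: `int v(a) R(a,t) da / int v(a) da`. With
#' `method = "diffusion"` (default) the retention comes from the numerical
#' diffusion; `"closed_form"` uses the exponential approximation.
#'
#' @param effect_dist an [effect_distribution()] at the scale of `N`.
#' @param N,w population size and peak width (`w = Inf` for neutral).
#' @param t vector of generation counts.
#' @param method `"diffusion"` or `"closed_form"`.
#' @param n_effects number of effect-size quadrature points.
#' @param ... passed to [diffusion_retention()].
#' @return A data.frame with columns `t` and `retention`.
#' @export
ancestral_variance_remaining <- function(effect_dist, N, w, t,
                                         method = c("diffusion", "closed_form"),
                                         n_effects = 30, V_P = 0, ...) {
  method <- match.arg(method)
  vd <- equilibrium_variance_density(effect_dist, N, w,
                                     a_grid = seq(1e-4,
                                                  6 * max(effect_dist$sds),
                                                  length.out = n_effects),
                                     V_P = V_P)
  wts <- vd$density
  R <- vapply(vd$a, function(a) {
    if (method == "diffusion")
      diffusion_retention(a, t, N, w, V_P = V_P, ...)$retention
    else
      closed_form_retention(a, t, N, w, V_P = V_P)$exponential
  }, numeric(length(t)))
  R <- matrix(R, nrow = length(t))
  data.frame(t = t, retention = as.numeric(R %*% wts) / sum(wts))
}

# standing (a, x) measure over segregating loci at equilibrium, truncated to
# x in [1/2N, 1 - 1/2N]: count weight mu(a) * psi(x; S(a)) / J(S(a)).
# Used both for variance-threshold ascertainment quantiles and for
# equilibrium variance shares.
standing_measure <- function(effect_dist, N, w, n_effects = 40, n_freq = 400,
                             V_P = 0) {
  a <- seq(1e-4, 6 * max(effect_dist$sds), length.out = n_effects)
  lo <- 1 / (2 * N)
  x <- seq(lo, 1 - lo, length.out = n_freq)
  wts <- matrix(0, n_effects, n_freq)
  for (i in seq_len(n_effects)) {
    S <- if (is.infinite(w)) 0 else 4 * N * underdominant_s(a[i], w, V_P)
    wts[i, ] <- deffects(a[i], effect_dist) * standing_density(x, S) /
      sojourn_J(S)
  }
  list(a = a, x = x, count = wts,
       variance = outer(a^2, 2 * x * (1 - x)))
}

#' Variance cutoff and share of top variance-ranked loci at equilibrium
#'
#' For a population at mutation-selection-drift equilibrium, finds the
#' per-locus genic-variance cutoff `c` such that a fraction `q` of
#' segregating loci contribute more than `c`, and the share of the total
#' genic variance those top loci explain.
#'
#' @param effect_dist an [effect_distribution()] at the scale of `N`.
#' @param N,w population size and fitness peak width (`Inf` = neutral).
#' @param q fraction of loci ranked in (default 0.05).
#' @return A list with `cutoff` and `share`.
#' @export
equilibrium_top_share <- function(effect_dist, N, w, q = 0.05, V_P = 0) {
  sm <- standing_measure(effect_dist, N, w, V_P = V_P)
  cw <- as.numeric(sm$count)
  v <- as.numeric(sm$variance)
  ord <- order(v)
  cum <- cumsum(cw[ord]) / sum(cw)
  cutoff <- v[ord][which(cum >= 1 - q)[1]]
  top <- v > cutoff
  list(cutoff = cutoff,
       share = sum(cw[top] * v[top]) / sum(cw * v))
}

#' Predicted relative accuracy of polygenic scores in an unrepresented population
#'
#' Analytic counterpart of the simulated portability curves. Population A is
#' at equilibrium and hosts the GWAS; population B split from the same
#' ancestor `t` generations ago. An ancestral locus contributes to the score
#' variance in B if it still segregates in B (expected heterozygosity from
#' the diffusion, started from the stationary sojourn density) and if it is
#' ascertained in A (an independent lineage, so the probability that A's
#' present-day frequency satisfies the scheme is a second backward-equation
#' payoff). Private loci contribute variance only in their own population.
#' The returned ratio compares `Var(S)/Var(G)` in B against A and equals 1
#' at `t = 0` under the `all` scheme.
#'
#' @param effect_dist an [effect_distribution()] at the scale of `N`.
#' @param N,w population size and fitness peak width (`Inf` = neutral).
#' @param t vector of divergence times in generations.
#' @param scheme an [ascertainment_scheme()] (source `"A"`).
#' @param n_effects effect-size quadrature points.
#' @param M,dtau diffusion-solver resolution.
#' @return A data.frame with columns `t`, `ratio_A`, `ratio_B`, `relative`.
#' @export
shared_variance_ratio <- function(effect_dist, N, w, t,
                                  scheme = ascertainment_scheme("all"),
                                  n_effects = 30, M = 800, dtau = 1e-3,
                                  V_P = 0) {
  stopifnot(inherits(scheme, "ascertainment_scheme"), all(t >= 0))
  taus <- t / (2 * N)
  a_grid <- seq(1e-4, 6 * max(effect_dist$sds), length.out = n_effects)
  cutoff <- if (scheme$kind == "top_variance_fraction")
    equilibrium_top_share(effect_dist, N, w, scheme$q, V_P = V_P)$cutoff
    else NA_real_
  num_B <- matrix(0, n_effects, length(taus))
  var_SA <- den <- numeric(n_effects)
  for (i in seq_along(a_grid)) {
    a <- a_grid[i]
    S <- if (is.infinite(w)) 0 else 4 * N * underdominant_s(a, w, V_P)
    g_of <- function(x) {
      asc <- switch(scheme$kind,
        all = rep(TRUE, length(x)),
        maf_threshold = pmin(x, 1 - x) > scheme$m,
        top_variance_fraction = 2 * x * (1 - x) * a^2 > cutoff)
      as.numeric(asc)
    }
    solh <- diffusion_payoff(S, taus, function(x) 2 * x * (1 - x), M = M,
                             dtau = dtau)
    solu <- diffusion_payoff(S, taus, g_of, M = M, dtau = dtau)
    x <- solh$x
    psi <- standing_density(x, S)
    wt <- deffects(a, effect_dist) / sojourn_J(S)
    h2 <- 2 * x * (1 - x)
    dx <- x[2] - x[1]
    den[i] <- wt * a^2 * sum(psi * h2) * dx
    var_SA[i] <- wt * a^2 * sum(psi * h2 * g_of(x)) * dx
    for (k in seq_along(taus)) {
      ck <- as.character(taus[k])
      num_B[i, k] <- wt * a^2 *
        sum(psi * solh$h[, ck] * solu$h[, ck]) * dx
    }
  }
  total <- sum(den)
  ratio_A <- sum(var_SA) / total
  ratio_B <- colSums(num_B) / total
  data.frame(t = t, ratio_A = ratio_A, ratio_B = ratio_B,
             relative = ratio_B / ratio_A)
}
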