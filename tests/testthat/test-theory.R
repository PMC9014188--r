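test_that("scaled selection matches hand arithmetic and is even in a", {
  expect_equal(scaled_selection(0, 1000, 5), 0)
  expect_equal(scaled_selection(0.1, 10000, 5), 8)
  a <- seq(-0.5, 0.5, by = 0.05)
  expect_equal(scaled_selection(a, 1000, 5), scaled_selection(-a, 1000, 5))
})

test_that("closed-form retention reproduces hand-evaluated values", {
  # pure drift: (1 - 1/20000)^1500
  r0 <- closed_form_retention(0, 1500, 10000, 5)
  expect_equal(r0$product, (1 - 1 / 20000)^1500, tolerance = 1e-12)
  expect_equal(r0$product, 0.9277, tolerance = 1e-4)
  expect_equal(r0$exponential, exp(-1500 / 20000), tolerance = 1e-12)
  # S = 8 allele: exp(-0.075 * (1 + 2))
  r8 <- closed_form_retention(0.1, 1500, 10000, 5)
  expect_equal(r8$exponential, exp(-0.075 * 3), tolerance = 1e-12)
  expect_equal(r8$exponential, 0.7985, tolerance = 1e-4)
  expect_equal(closed_form_retention(0.1, 0, 10000, 5)$product, 1)
  expect_error(closed_form_retention(12, 10, 100, 1), "domain")
})

test_that("deterministic underdominant trajectories behave as expected", {
  expect_equal(deterministic_trajectory(0.5, 0.3, 5, 50),
               rep(0.5, 51))
  up <- deterministic_trajectory(0.7, 0.3, 5, 200)
  dn <- deterministic_trajectory(0.3, 0.3, 5, 200)
  expect_equal(up, 1 - dn, tolerance = 1e-12)
  expect_true(all(diff(dn) <= 0))
  slow <- deterministic_trajectory(0.3, 0.1, 5, 200)
  expect_lt(dn[201], slow[201])  # larger effect reaches the boundary faster
  expect_error(deterministic_trajectory(0, 0.1, 5, 10))
})

test_that("the Wright-Fisher matrix oracle nails the neutral identity", {
  tt <- c(10, 40)
  ret <- wf_matrix_retention(0, tt, 150, Inf)
  expect_equal(ret$retention, (1 - 1 / 300)^tt, tolerance = 1e-10)
  # uniform start changes nothing under neutrality
  ret_u <- wf_matrix_retention(0, tt, 150, Inf, start = "uniform")
  expect_equal(ret_u$retention, (1 - 1 / 300)^tt, tolerance = 1e-10)
})

test_that("matrix retention is invariant under S-preserving rescaling", {
  w <- 5
  S <- 8
  a1 <- sqrt(S * w^2 / (2 * 100))
  a2 <- sqrt(S * w^2 / (2 * 200))
  r1 <- wf_matrix_retention(a1, c(10, 20), 100, w)   # tau = 0.05, 0.1
  r2 <- wf_matrix_retention(a2, c(20, 40), 200, w)
  expect_equal(r1$retention, r2$retention, tolerance = 0.01)
})

test_that("selection pushes retention below the neutral curve", {
  tt <- c(20, 60)
  sel <- wf_matrix_retention(sqrt(8 * 25 / 600), tt, 300, 5)
  neu <- wf_matrix_retention(0, tt, 300, Inf)
  expect_true(all(sel$retention < neu$retention))
})

test_that("diffusion retention matches the matrix oracle at moderate S", {
  N <- 300
  for (S in c(0, 2, 8)) {
    a <- sqrt(S * 25 / (2 * N))
    tt <- c(15, 60)
    mx <- wf_matrix_retention(a, tt, N, 5)
    df <- diffusion_retention(a, tt, N, 5)
    expect_equal(df$retention, mx$retention, tolerance = 0.01)
  }
})

test_that("retention is monotone in t and |a| and symmetric in sign", {
  r <- diffusion_retention(0.3, c(0, 20, 50, 100), 500, 5)
  expect_equal(r$retention[1], 1, tolerance = 1e-9)
  expect_true(all(diff(r$retention) < 0))
  by_a <- vapply(c(0.05, 0.2, 0.4, 0.6),
                 function(a) diffusion_retention(a, 50, 500, 5)$retention,
                 numeric(1))
  expect_true(all(diff(by_a) < 0))
  expect_equal(diffusion_retention(-0.3, 50, 500, 5)$retention,
               diffusion_retention(0.3, 50, 500, 5)$retention)
})

test_that("equilibrium variance density has the right limits and mass", {
  d <- effect_distribution("gaussian", sd = 0.1)
  vd_neu <- equilibrium_variance_density(d, 10000, Inf, U = 0.01)
  # neutral: v(a) proportional to mu(a) a^2, total 2 N U E[a^2]
  shape <- 2 * deffects(vd_neu$a, d) * vd_neu$a^2
  expect_equal(vd_neu$density / vd_neu$density[40],
               shape / shape[40], tolerance = 1e-6)
  expect_equal(attr(vd_neu, "total_va"), 2 * 10000 * 0.01 * 0.01^2 * 100,
               tolerance = 0.01)
  # stronger selection (smaller w) removes more variance and shifts the
  # surviving mass toward smaller effects
  vd5 <- equilibrium_variance_density(d, 10000, 5, U = 0.01)
  vd8 <- equilibrium_variance_density(d, 10000, 8, U = 0.01)
  expect_lt(attr(vd5, "total_va"), attr(vd8, "total_va"))
  mean_a <- function(vd) sum(vd$a * vd$density) / sum(vd$density)
  expect_lt(mean_a(vd5), mean_a(vd8))  # wider peak: large effects drift up
  expect_error(equilibrium_variance_density(d, 100, 5,
                                            a_grid = c(0.1, 0.2, 0.3)),
               "coarse")
})

test_that("integrated ancestral variance decay has the right limits", {
  d <- effect_distribution("gaussian", sd = 0.1)
  neu <- ancestral_variance_remaining(d, 10000, Inf, c(0, 1500))
  expect_equal(neu$retention[1], 1, tolerance = 1e-9)
  expect_equal(neu$retention[2], exp(-1500 / 20000), tolerance = 1e-3)
  sel <- ancestral_variance_remaining(d, 10000, 5, c(0, 500, 1000, 1500))
  expect_true(all(diff(sel$retention) < 0))
  expect_true(all(sel$retention[-1] < neu$retention[2] ^
                    (c(500, 1000, 1500) / 1500)))
  # heavy-tailed mutation input decays faster at matched w
  hv <- ancestral_variance_remaining(heavy_tail_effects(), 10000, 5, 500)
  expect_lt(hv$retention, ancestral_variance_remaining(d, 10000, 5,
                                                       500)$retention)
})

test_that("predicted portability has its limits and orderings", {
  d <- effect_distribution("gaussian", sd = 0.1)
  at0 <- shared_variance_ratio(d, 10000, 5, 0)
  expect_equal(at0$relative, 1, tolerance = 1e-6)
  expect_equal(at0$ratio_A, 1, tolerance = 1e-6)
  r4 <- shared_variance_ratio(d, 10000, 4, 1500)$relative
  r5 <- shared_variance_ratio(d, 10000, 5, 1500)$relative
  rn <- shared_variance_ratio(d, 10000, Inf, 1500)$relative
  expect_lt(r4, r5)
  expect_lt(r5, rn)
  expect_lt(rn, 1)
  # under a subset scheme the within-A share drops below 1
  top <- shared_variance_ratio(d, 10000, 5, 1500,
                               ascertainment_scheme("top_variance_fraction"))
  expect_lt(top$ratio_A, 1)
})

test_that("heavy-tailed architectures port worse under top-5% discovery", {
  d <- effect_distribution("gaussian", sd = 0.1)
  s5 <- ascertainment_scheme("top_variance_fraction", q = 0.05)
  rg <- shared_variance_ratio(d, 10000, 5, 1500, s5)$relative
  rh <- shared_variance_ratio(heavy_tail_effects(), 10000, 5, 1500,
                              s5)$relative
  expect_lt(rh, rg)
  # for Gaussian effects the top-5% curve tracks the all-loci curve
  r_all <- shared_variance_ratio(d, 10000, 5, 1500)$relative
  expect_equal(rg, r_all, tolerance = 0.05)
})

test_that("equilibrium top-variance share is just under half at w = 5 desk scale", {
  d <- rescale_effects(effect_distribution("gaussian", sd = 0.1), 500)
  sh <- equilibrium_top_share(d, 500, 5, q = 0.05)
  expect_gt(sh$share, 0.3)
  expect_lt(sh$share, 0.55)
})
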