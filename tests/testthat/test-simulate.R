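test_that("gaussian fitness has the right peak, scale and symmetry", {
  expect_equal(gaussian_fitness(0.7, 0.7, 3), 1)
  expect_equal(gaussian_fitness(5, 0, 5), exp(-1 / 2))
  expect_equal(gaussian_fitness(0.3, 0, 5), gaussian_fitness(-0.3, 0, 5))
  expect_lt(gaussian_fitness(1, 0, 5), 1)
  expect_error(gaussian_fitness(NA, 0, 5))
  expect_error(gaussian_fitness(0, 0, Inf))
  expect_error(gaussian_fitness(0, 0, -1))
})

test_that("neutral reproduction has Wright-Fisher moments", {
  set.seed(101)
  n <- 200
  g <- matrix(rbinom(n, 2, 0.5), n, 1)
  pop <- population_state(g, eff = 0.1)
  p0 <- sum(g) / (2 * n)
  cfg <- sim_config(N = n, w = Inf, U = 0, burn_in = 0)
  freqs <- replicate(600, {
    sum(advance_generation(pop, cfg, 1, drop_fixed = FALSE)$geno) / (2 * n)
  })
  expect_equal(mean(freqs), p0, tolerance = 0.01)
  expect_equal(var(freqs), p0 * (1 - p0) / (2 * n), tolerance = 0.15)
})

test_that("a population with no segregating loci is a fixed point", {
  cfg <- sim_config(N = 50, w = 5, U = 0, burn_in = 0)
  pop <- population_state(matrix(2L, 50, 1), eff = 0.3)
  out <- advance_generation(pop, cfg, 5, drop_fixed = FALSE)
  expect_equal(out$geno, pop$geno)
  expect_equal(summarize_state(out)$mean_phenotype,
               summarize_state(pop)$mean_phenotype)
  expect_equal(summarize_state(out)$V_a, 0)
})

test_that("invalid inputs are rejected", {
  expect_error(sim_config(N = 1), "N")
  expect_error(sim_config(U = -0.1))
  expect_error(sim_config(w = 0))
  expect_error(population_state(matrix(3L, 2, 1), eff = 0.1), "copy counts")
})

test_that("substitution folding and explicit fixed columns agree exactly", {
  # the same trajectory run with and without fixation folding consumes the
  # same randomness, so phenotypes and genic variance must match exactly
  cfg <- sim_config(N = 150, w = 5, U = 0.1, burn_in = 0)
  set.seed(7)
  start <- hwe_population(150, runif(60, 0.05, 0.95), rnorm(60, 0, 0.3))
  set.seed(99)
  a <- advance_generation(start, cfg, 300, drop_fixed = TRUE)
  set.seed(99)
  b <- advance_generation(start, cfg, 300, drop_fixed = FALSE)
  sa <- summarize_state(a)
  sb <- summarize_state(b)
  expect_equal(sa$mean_phenotype, sb$mean_phenotype, tolerance = 1e-12)
  expect_equal(sa$V_a, sb$V_a, tolerance = 1e-12)
  # offset accounts exactly for the loci fixed along the way
  fixed_b <- colSums(b$geno) == 2 * 150 & b$eff != 0
  expect_equal(a$offset, sum(2 * b$eff[fixed_b]), tolerance = 1e-12)
})

test_that("burn-in reaches a stationary equilibrium with small V_P/w^2", {
  set.seed(11)
  cfg <- sim_config(N = 300, w = 5, U = 0.05, burn_in = 3000)
  pop <- burn_in_to_equilibrium(cfg)
  expect_true(attr(pop, "stationary"))
  s <- summarize_state(pop)
  expect_gt(s$V_a, 0)
  expect_lt(s$V_P / cfg$w^2, 0.5)
  # equilibrium V_a under selection is below the neutral level at equal U
  set.seed(11)
  ncfg <- sim_config(N = 300, w = Inf, U = 0.05, burn_in = 3000)
  # neutral V_a mixes on a 4N timescale, so its trend test is permissive
  npop <- suppressWarnings(burn_in_to_equilibrium(ncfg))
  expect_lt(s$V_a, summarize_state(npop)$V_a)
})

test_that("zero mutation makes equilibrium detection flag non-stationarity", {
  set.seed(12)
  cfg <- sim_config(N = 100, w = Inf, U = 0, burn_in = 300)
  expect_warning(burn_in_to_equilibrium(cfg), "equilibrium")
})

test_that("a split at t = 0 leaves both descendants identical to the ancestor", {
  fx <- selected_split()
  loci0 <- locus_table(fx$sr, 0)
  expect_equal(loci0$p_A, loci0$p_anc)
  expect_equal(loci0$p_B, loci0$p_anc)
  expect_true(all(loci0$origin == "ancestral"))
})

test_that("locus table bookkeeping tracks origins and status correctly", {
  fx <- selected_split()
  loci <- fx$loci
  expect_true(all(loci$p_B[loci$origin == "private_A"] == 0))
  expect_true(all(loci$p_A[loci$origin == "private_B"] == 0))
  expect_true(all(loci$p_anc[loci$origin != "ancestral"] == 0))
  expect_true(all(loci$p_anc[loci$origin == "ancestral"] > 0))
  expect_true(all(loci$status_A[loci$p_A == 0] == "lost"))
  expect_true(all(loci$status_A[loci$p_A == 1] == "fixed"))
  expect_true(all(loci$status_A[loci$p_A > 0 & loci$p_A < 1] == "segregating"))
  expect_error(locus_table(fx$sr, 17), "snapshot")
  # markers live in their own table
  expect_true(all(locus_table(fx$sr, 30, markers = TRUE)$effect == 0))
})

test_that("selection removes ancestral polymorphisms faster than drift", {
  set.seed(205)
  surv <- sapply(c(5, Inf), function(w) {
    cfg <- sim_config(N = 200, w = w, U = 0.05, burn_in = 2000,
                      neutral_loci = 0)
    anc <- suppressWarnings(burn_in_to_equilibrium(cfg))
    mean(replicate(4, {
      sr <- split_and_evolve(anc, cfg, t = 60)
      lo <- locus_table(sr, 60)
      an <- lo[lo$origin == "ancestral", ]
      both <- an$status_A == "segregating" & an$status_B == "segregating"
      mean(both)
    }))
  })
  expect_lt(surv[1], surv[2])
})

test_that("the mean phenotype tracks a shifting optimum schedule", {
  set.seed(206)
  cfg <- sim_config(N = 200, w = 4, U = 0.05, burn_in = 2000,
                    neutral_loci = 0)
  anc <- suppressWarnings(burn_in_to_equilibrium(cfg))
  vp <- summarize_state(anc)$V_P
  shift <- 2 * sqrt(vp)
  sr <- split_and_evolve(anc, cfg, t = 80,
                         optimum_schedule = data.frame(generation = 1,
                                                       optimum = shift))
  mA <- summarize_state(snapshot_population(sr, 80, "A"))$mean_phenotype
  mB <- summarize_state(snapshot_population(sr, 80, "B"))$mean_phenotype
  anc_mean <- summarize_state(anc)$mean_phenotype
  # both populations respond in parallel toward the new optimum
  expect_gt(mA - anc_mean, shift / 2)
  expect_gt(mB - anc_mean, shift / 2)
})
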