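test_that("per-locus variance is the genic term with its symmetries", {
  expect_equal(per_locus_variance(0.5, 0.1), 0.005)
  expect_equal(per_locus_variance(c(0, 1), 0.3), c(0, 0))
  p <- runif(20)
  a <- rnorm(20)
  expect_equal(per_locus_variance(p, a), per_locus_variance(1 - p, a))
  expect_equal(per_locus_variance(p, a), per_locus_variance(p, -a))
  expect_error(per_locus_variance(1.2, 0.1))
})

test_that("scheme validation enforces invariants", {
  expect_error(ascertainment_scheme("top_variance_fraction", q = 0))
  expect_error(ascertainment_scheme("maf_threshold", m = 0.5))
  expect_error(ascertainment_scheme("nonsense"))
})

make_table <- function(p_A, p_B, a, p_anc = pmax(p_A, p_B) / 2) {
  data.frame(locus_id = seq_along(a), effect = a, p_anc = p_anc,
             p_A = p_A, p_B = p_B,
             origin = "ancestral",
             status_A = ifelse(p_A %in% c(0, 1), "boundary", "segregating"),
             status_B = ifelse(p_B %in% c(0, 1), "boundary", "segregating"),
             ascertained = FALSE)
}

test_that("scheme 'all' flags exactly the loci segregating in the source", {
  set.seed(5)
  tab <- make_table(p_A = c(0, 0.2, 0.5, 1, 0.9), p_B = runif(5),
                    a = rnorm(5))
  out <- ascertain(tab, ascertainment_scheme("all"))
  expect_equal(out$ascertained, tab$p_A > 0 & tab$p_A < 1)
})

test_that("top-variance ranking keeps the largest contributors deterministically", {
  set.seed(6)
  p <- runif(100, 0.01, 0.99)
  a <- rnorm(100, 0, 0.3)
  tab <- make_table(p, runif(100), a)
  out <- ascertain(tab, ascertainment_scheme("top_variance_fraction",
                                             q = 0.05))
  expect_equal(sum(out$ascertained), 5)
  v <- per_locus_variance(p, a)
  expect_setequal(which(out$ascertained), order(-v)[1:5])
  # deterministic given the table
  expect_identical(out$ascertained,
                   ascertain(tab, ascertainment_scheme("top_variance_fraction",
                                                       q = 0.05))$ascertained)
})

test_that("MAF threshold keeps common loci and nests the top set's common loci", {
  set.seed(7)
  p <- c(0.005, 0.02, 0.5, 0.995, 0.2)
  tab <- make_table(p, p, rnorm(5))
  out <- ascertain(tab, ascertainment_scheme("maf_threshold", m = 0.01))
  expect_equal(out$ascertained, pmin(p, 1 - p) > 0.01)
  # nesting: every top-variance locus with MAF > m is in the MAF set
  p2 <- runif(200, 0.001, 0.999)
  a2 <- rnorm(200, 0, 0.3)
  tab2 <- make_table(p2, p2, a2)
  top <- ascertain(tab2, ascertainment_scheme("top_variance_fraction",
                                              q = 0.1))$ascertained
  maf <- ascertain(tab2, ascertainment_scheme("maf_threshold",
                                              m = 0.01))$ascertained
  common_top <- top & pmin(p2, 1 - p2) > 0.01
  expect_true(all(maf[common_top]))
})

test_that("loci private to B are never ascertained from source A", {
  fx <- selected_split()
  out <- ascertain(fx$loci, ascertainment_scheme("all", source = "A"))
  expect_false(any(out$ascertained[out$origin == "private_B"]))
  out2 <- ascertain(fx$loci, ascertainment_scheme("top_variance_fraction",
                                                  q = 0.2, source = "A"))
  expect_false(any(out2$ascertained[out2$origin == "private_B"]))
})

test_that("an empty ascertained set warns and downstream scores are zero", {
  tab <- make_table(c(0, 1), c(0.4, 0.5), c(0.1, 0.2))
  expect_warning(out <- ascertain(tab, ascertainment_scheme("all")),
                 "zero variance")
  pop <- hwe_population(30, c(0.4, 0.5), c(0.1, 0.2))
  pop$id <- tab$locus_id
  expect_equal(polygenic_scores(pop, out), rep(0, 30))
})
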