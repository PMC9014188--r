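# Shared fixture builders. Everything is generated in code; moderately
# expensive objects are cached so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, fun) {
  if (is.null(.fixtures[[name]])) assign(name, fun(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Hardy-Weinberg population at given frequencies; columns drawn
# independently, so loci are in linkage equilibrium by construction.
hwe_population <- function(n, p, eff) {
  g <- matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)),
              n, length(p))
  population_state(g, eff)
}

# small equilibrium ancestor + split under stabilizing selection, reused by
# the ascertainment / prediction / differentiation tests
selected_split <- function() {
  get_fixture("selected_split", function() {
    set.seed(402)
    cfg <- sim_config(N = 200, w = 5, U = 0.05, burn_in = 2000,
                      neutral_loci = 150)
    anc <- suppressWarnings(burn_in_to_equilibrium(cfg))
    sr <- split_and_evolve(anc, cfg, t = 30, snapshot_gens = c(0, 30))
    list(cfg = cfg, anc = anc, sr = sr,
         loci = locus_table(sr, 30),
         markers = locus_table(sr, 30, markers = TRUE),
         popA = snapshot_population(sr, 30, "A"),
         popB = snapshot_population(sr, 30, "B"))
  })
}
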