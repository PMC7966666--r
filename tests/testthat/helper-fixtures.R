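# memoized fixtures shared across test files (built once per session)
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small world for structural tests
small_world <- function() memo("small_world", function() {
  simulate_world(n_countries = 5, n_regions = 2, seed = 42)
})

# quick B3 configuration for unit tests (acceptance uses the default)
quick_b3 <- function(seed = 7) {
  b3_config(chains = 2, warmup = 250, samples = 350, seed = seed)
}

# frozen log-quadratic reference fit
ref_fit <- function() memo("ref_fit", function() {
  fit_logquad(reference_pairs(generate_truth(60, 4, seed = 100), seed = 101))
})

# full default-conditions pipeline runs; coverage statistics pool the three
# replicate worlds (seeds 1:3) because a single 20-country world carries only
# ~20 effectively independent coverage units
acceptance_run <- function(seed = 1) memo(paste0("acceptance_run_", seed), function() {
  run_pipeline(run_config(seed = seed, outdir = tempfile("acc-")))
})
acceptance_seeds <- function() 1:3

# pooled coverage of the true 10q15 by the 90% intervals
pooled_coverage <- function(posteriors, truth, years = 1990:2019) {
  hits <- c()
  for (cc in names(posteriors)) {
    s <- summarize_posterior(posteriors[[cc]], years)
    tr <- truth[truth$country == cc & truth$year %in% years, ]
    hits <- c(hits, tr$q15_24_true >= s$lower & tr$q15_24_true <= s$upper)
  }
  mean(hits)
}
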