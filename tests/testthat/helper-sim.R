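## shared fixtures, memoized within the test session

.cache <- new.env(parent = emptyenv())

## a small, fast landscape: 40 x 40 m (4 patches)
tiny_config <- function(years = 20, seed = 7, ...) {
  sim_config(plot_edge = 40, n_replicates = 1, years = years,
             rng_seed = seed, ...)
}

tiny_sim <- function() {
  if (is.null(.cache$tiny)) .cache$tiny <- run_succession(tiny_config(30))
  .cache$tiny
}

## the study-condition run shared by the acceptance tests:
## 5 replicate 200 x 200 m plots over 320 years
study_sim <- function() {
  if (is.null(.cache$study)) {
    .cache$study <- run_succession(sim_config(n_replicates = 5,
                                              rng_seed = 1))
  }
  .cache$study
}

## parameters for a single-PFT setup without stochastic death,
## used by growth/bookkeeping oracles
immortal_pft <- function() {
  p <- default_pfts()[[2]]
  p$m_b <- 0
  p$i_seed <- 0
  p
}

no_death_config <- function(...) {
  sim_config(plot_edge = 40, n_replicates = 1, rng_seed = 1,
             stress_mort = 0, p_fall = 0, crowd_mort_max = 0,
             pfts = list(immortal_pft()), ...)
}
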