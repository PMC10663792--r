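test_that("an empty landscape without seed rain is a fixed point", {
  cfg <- no_death_config(years = 5)
  state <- new_landscape(cfg)
  set.seed(3)
  for (t in 1:5) {
    out <- annual_step(state, cfg)
    state <- out$state
  }
  expect_equal(nrow(state), 0L)
  expect_true(all(out$patch$agb == 0))
  expect_true(all(out$floor_light == 1))
})

test_that("annual_step is deterministic under a fixed seed", {
  cfg <- tiny_config(years = 5)
  state <- new_landscape(cfg)
  set.seed(11); s1 <- annual_step(state, cfg)
  set.seed(11); s2 <- annual_step(state, cfg)
  expect_identical(s1, s2)
})

test_that("carbon bookkeeping holds for surviving trees", {
  cfg <- no_death_config()
  p <- cfg$pfts[[1]]
  d <- c(0.05, 0.2, 0.5)
  state <- data.table::data.table(
    pft = 1L, patch = c(1L, 2L, 3L), dbh = d,
    biomass = allometry(p, d)$biomass, stress = 0L,
    gpp = 0, npp = 0, alloc = 0)
  b_before <- state$biomass
  set.seed(5)
  nxt <- annual_step(state, cfg)$state
  ## no mortality processes are active, so rows align
  expect_equal(nrow(nxt), 3L)
  expect_equal(nxt$biomass - b_before, nxt$alloc * nxt$npp,
               tolerance = 1e-9)
  ## dbh consistent with the inverted allometry
  expect_equal(nxt$dbh, dbh_from_biomass(p, nxt$biomass),
               tolerance = 1e-10)
})

test_that("run_succession output is reproducible and well-formed", {
  s1 <- tiny_sim()
  s2 <- run_succession(tiny_config(30))
  expect_identical(s1$patches, s2$patches)
  expect_identical(s1$plots, s2$plots)

  ## bare-ground start: year-0 rows are zero
  expect_true(all(s1$plots[year == 0, c(agb, gpp, npp)] == 0))
  ## patch rows: replicates x (years + 1) x patches
  expect_equal(nrow(s1$patches), 1 * 31 * 4)
  ## layer columns sum to AGB (conservation through the profile)
  lc <- grep("^b[0-9]+$", names(s1$patches), value = TRUE)
  expect_equal(rowSums(s1$patches[, lc, with = FALSE]),
               s1$patches$agb, tolerance = 1e-9)
})

test_that("replicates come from independent reproducible streams", {
  cfg2 <- tiny_config(10); cfg2$n_replicates <- 2
  both <- run_succession(cfg2)
  solo <- run_succession(tiny_config(10))
  expect_equal(both$plots[replicate == 1], solo$plots,
               tolerance = 1e-12)
  ## the two replicates genuinely differ
  expect_false(isTRUE(all.equal(both$plots[replicate == 1]$agb,
                                both$plots[replicate == 2]$agb)))
})

test_that("tree recording mode emits per-tree state", {
  sim <- run_succession(tiny_config(8), record = "trees")
  tr <- sim$trees
  expect_true(all(c("replicate", "year", "patch", "pft", "dbh",
                    "height", "biomass", "gpp_year", "npp_year")
                  %in% names(tr)))
  expect_true(all(tr$biomass > 0))
  expect_true(all(tr$height > 0))
  expect_true(all(tr$gpp_year >= 0))
})
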