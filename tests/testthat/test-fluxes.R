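test_that("cell flux aggregation is sum over area", {
  empty <- aggregate_fluxes(make_stand(0), 0.04)
  expect_equal(unname(empty), c(0, 0, 0))
  two <- data.frame(biomass = c(1, 2), gpp_year = c(0.8, 1.2),
                    npp_year = c(0.2, 0.3))
  out <- aggregate_fluxes(two, 0.04)
  expect_equal(unname(out["gpp"]), 50)
  expect_equal(unname(out["agb"]), 75)
  expect_error(aggregate_fluxes(two, 0), "area")
})

test_that("aggregation at 4 ha equals the mean over patch aggregates", {
  sim <- tiny_sim()
  tab40 <- stand_year_table(sim, 40, 20)   # whole tiny plot
  tab20 <- stand_year_table(sim, 20, 20)   # per patch
  joint <- tab20[, .(agb = mean(agb), gpp = mean(gpp),
                     npp = mean(npp)), by = .(replicate, year)]
  merged <- merge(tab40, joint, by = c("replicate", "year"))
  expect_equal(merged$agb.x, merged$agb.y, tolerance = 1e-9)
  expect_equal(merged$gpp.x, merged$gpp.y, tolerance = 1e-9)
  expect_equal(merged$npp.x, merged$npp.y, tolerance = 1e-9)
})

test_that("turnover time is biomass over GPP with flagged zeros", {
  expect_equal(turnover_time(300, 50), 6)
  expect_equal(turnover_time(0, 10), 0)
  expect_true(is.na(turnover_time(10, 0)))
  agb <- runif(20, 0, 400); gpp <- runif(20, 1, 60)
  expect_equal(turnover_time(agb, gpp) * gpp, agb, tolerance = 1e-12)
})

test_that("age categories split at the equilibrium boundary", {
  expect_equal(categorize_by_age(0), "disturbed")
  expect_equal(categorize_by_age(159), "disturbed")
  expect_equal(categorize_by_age(160), "mature")
  expect_equal(categorize_by_age(320), "mature")
  expect_equal(categorize_by_age(160, boundary = 200), "disturbed")
})

test_that("stand-year tables carry consistent fluxes and layers", {
  sim <- tiny_sim()
  tab <- stand_year_table(sim, 20, 10)
  lc <- grep("^b[0-9]+$", names(tab), value = TRUE)
  expect_length(lc, 10)
  expect_equal(rowSums(tab[, lc, with = FALSE]), tab$agb,
               tolerance = 1e-9)
  ## NPP never exceeds GPP (respiration is non-negative)
  expect_true(all(tab$npp <= tab$gpp + 1e-12))
  ## tau * gpp returns agb wherever defined
  ok <- !is.na(tab$tau)
  expect_equal(tab$tau[ok] * tab$gpp[ok], tab$agb[ok],
               tolerance = 1e-9)
  ## tau is independent of the dh used for the profile
  tab2 <- stand_year_table(sim, 20, 100)
  expect_equal(tab$tau, tab2$tau, tolerance = 1e-12)
})
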