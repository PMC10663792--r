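test_that("a 56 m tree splits 1 t of biomass as 20:20:16 over 20 m layers", {
  v <- tree_layer_biomass(height = 56, biomass = 1, dh = 20)
  expect_equal(v[1:3], c(20, 20, 16) / 56, tolerance = 1e-12)
  expect_true(all(v[4:5] == 0))
})

test_that("layer decomposition conserves biomass and handles exact fits", {
  v <- tree_layer_biomass(20, 2.5, dh = 20)
  expect_equal(v, c(2.5, 0, 0, 0, 0))
  set.seed(9)
  for (i in 1:25) {
    h <- runif(1, 0.1, 99.9); b <- runif(1, 0, 10)
    dh <- sample(c(2, 10, 20, 100), 1)
    expect_equal(sum(tree_layer_biomass(h, b, dh)), b, tolerance = 1e-12)
  }
  expect_error(tree_layer_biomass(0, 1, 20), "height")
  expect_error(tree_layer_biomass(101, 1, 20), "height")
})

test_that("stand profiles match a naive per-tree double loop", {
  trees <- make_stand(100, hmax = 80, seed = 4)
  spec <- profile_spec(10, 20)
  prof <- stand_profile(trees, spec)
  oracle <- numeric(10)
  for (i in seq_len(nrow(trees)))
    oracle <- oracle +
      tree_layer_biomass(trees$height[i], trees$biomass[i], 10)
  oracle <- oracle / 0.04
  expect_equal(prof$layers, oracle, tolerance = 1e-9)
  expect_equal(prof$agb, sum(trees$biomass) / 0.04, tolerance = 1e-9)

  ## single tree density example: 0.5 t over 0.04 ha, one layer
  one <- stand_profile(data.frame(height = 10, biomass = 0.5),
                       profile_spec(100, 20))
  expect_equal(one$layers, 12.5)

  ## empty cell is valid and zero
  empty <- stand_profile(make_stand(0), profile_spec(20, 20))
  expect_equal(empty$layers, numeric(5))
})

test_that("fine layers aggregate exactly to coarse layers", {
  trees <- make_stand(60, hmax = 95, seed = 12)
  p2 <- stand_profile(trees, profile_spec(2, 20))$layers
  p20 <- stand_profile(trees, profile_spec(20, 20))$layers
  expect_equal(drop(coarsen_layers(p2, 2, 20)), p20, tolerance = 1e-9)
  p100 <- stand_profile(trees, profile_spec(100, 20))$layers
  expect_equal(sum(p2), p100, tolerance = 1e-9)
  expect_error(coarsen_layers(p2, 2, 5), "multiple")
})

test_that("cells tile the plot exactly", {
  px <- rep(0:9, 10); py <- rep(0:9, each = 10)
  ## one 4 ha cell per 200 m plot
  c200 <- tile_cells(px, py, 200)
  expect_equal(nrow(unique(c200)), 1L)
  ## four 1 ha cells, 25 patches each
  c100 <- tile_cells(px, py, 100)
  expect_equal(nrow(unique(c100)), 4L)
  expect_true(all(table(paste(c100$cell_x, c100$cell_y)) == 25))
  ## one patch per 0.04 ha cell
  c20 <- tile_cells(px, py, 20)
  expect_equal(nrow(unique(c20)), 100L)
  expect_error(tile_cells(px, py, 60), "divide")
  expect_error(tile_cells(10, 0, 20), "bounds")
})

test_that("profile spec validates layering", {
  expect_error(profile_spec(30, 200), "divisible")
  expect_error(profile_spec(20, 50), "multiple")
  expect_silent(profile_spec(2, 20))
})
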