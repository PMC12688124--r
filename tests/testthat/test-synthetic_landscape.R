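test_that("environmental stacks are deterministic under a fixed seed", {
  lc <- landscape_config(grid = grid_spec(30, 30, cell_size = 1), seed = 5,
                         n_layers = 3)
  s1 <- generate_env_stack(lc)
  s2 <- generate_env_stack(lc)
  expect_identical(lapply(s1, `[[`, "values"), lapply(s2, `[[`, "values"))
  s3 <- generate_env_stack(landscape_config(grid = grid_spec(30, 30,
                                                             cell_size = 1),
                                            seed = 6, n_layers = 3))
  expect_false(identical(s1[[1]]$values, s3[[1]]$values))
})

test_that("near-duplicate layer is highly rank-correlated with layer 1", {
  lc <- landscape_config(grid = grid_spec(40, 40, cell_size = 1), seed = 2,
                         near_duplicate = TRUE)
  stack <- generate_env_stack(lc)
  expect_true("layer1_dup" %in% names(stack))
  rho <- cor(as.vector(stack$layer1$values),
             as.vector(stack$layer1_dup$values), method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("autocorrelation scale controls neighbor correlation", {
  neighbor_cor <- function(scale) {
    lc <- landscape_config(grid = grid_spec(60, 60, cell_size = 1),
                           seed = 11, autocorrelation_scale = scale)
    v <- generate_env_stack(lc)[[1]]$values
    cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  }
  expect_lt(abs(neighbor_cor(0)), 0.05)   # white noise
  expect_gt(neighbor_cor(6), 0.8)         # smoothed field
})

test_that("the true biome matches its rule's quantile construction", {
  lc <- landscape_config(grid = grid_spec(50, 50, cell_size = 1), seed = 9,
                         rule = biome_rule(list(list(layer = 1, op = ">=",
                                                     q = 0.70))))
  stack <- generate_env_stack(lc)
  tb <- true_biome_map(stack, lc$rule)
  expect_equal(mean(tb$map$values), 0.30, tolerance = 0.02 / 0.30)
  # degenerate rule selecting everything / nothing
  all_rule <- biome_rule(list(list(layer = 1, op = ">=", q = 0)))
  expect_true(all(true_biome_map(stack, all_rule)$map$values == 1))
  # q ~ 1 keeps at least the maximum cell, so force emptiness with two
  # opposed conditions instead
  impossible <- biome_rule(list(list(layer = 1, op = ">=", q = 0.99),
                                list(layer = 1, op = "<=", q = 0.01)))
  expect_error(true_biome_map(stack, impossible), "empty biome")
})

test_that("vectorized outline rasterizes back to the exact biome map", {
  land <- tiny_landscape()
  back <- rasterize_polygons(land$outline, land$map$grid)
  expect_equal(back$values, land$map$values)
})

test_that("species sampling realizes the target affinity exactly", {
  land <- tiny_landscape()
  occ <- sample_species(species_spec("sp", 20, 1.0), land$map, seed = 3)
  v <- extract_values(land$map, occ$x, occ$y)
  expect_equal(sum(v == 1), 20L)
  occ <- sample_species(species_spec("sp", 10, 0.8), land$map, seed = 3)
  expect_equal(sum(extract_values(land$map, occ$x, occ$y) == 1), 8L)
  # rounding contract over assorted n and affinities
  set.seed(1)
  for (i in 1:25) {
    n <- sample(c(1:10, 50L, 400L, 3000L), 1)
    a <- runif(1)
    occ <- sample_species(species_spec("sp", n, a), land$map, seed = i,
                          margin = land$margin)
    expect_identical(sum(extract_values(land$map, occ$x, occ$y) == 1),
                     as.integer(round(a * n)))
    expect_identical(nrow(occ), n)
  }
})

test_that("species sampling appends the configured share of duplicates", {
  land <- tiny_landscape()
  occ <- sample_species(species_spec("sp", 10, 0.5, duplicate_rate = 0.2),
                        land$map, seed = 4)
  expect_equal(nrow(occ), 12L)
  key <- paste(occ$locality, occ$collector, occ$date)
  expect_equal(sum(duplicated(key)), 2L)
})

test_that("impossible affinities are rejected", {
  g <- grid_spec(5, 5, cell_size = 1)
  all1 <- binary_map(g, matrix(1, 5, 5))
  expect_error(sample_species(species_spec("sp", 10, 0.5), all1),
               "impossible affinity")
  all0 <- binary_map(g, matrix(0, 5, 5))
  expect_error(sample_species(species_spec("sp", 10, 1.0), all0),
               "impossible affinity")
})

test_that("validation points are labelled by their own mutually exclusive biome", {
  land <- tiny_landscape()
  biomes <- partition_biomes(land$stack, land$map, n_biomes = 5)
  expect_identical(names(biomes)[1], "SDTF")
  # partition covers every valid cell exactly once
  tot <- Reduce(`+`, lapply(biomes, `[[`, "values"))
  expect_true(all(tot == 1))
  pts <- sample_validation_points(biomes, 40, seed = 8)
  expect_identical(nrow(pts), 200L)
  expect_true(all(table(pts$label) == 40))
  for (nm in names(biomes)) {
    sub <- pts[pts$label == nm, ]
    expect_true(all(extract_values(biomes[[nm]], sub$x, sub$y) == 1))
    # mutual exclusivity: inside no other biome map
    for (other in setdiff(names(biomes), nm))
      expect_true(all(extract_values(biomes[[other]], sub$x, sub$y) == 0))
  }
})

test_that("validation sampling rejects overlapping or too-small biomes", {
  g <- grid_spec(6, 6, cell_size = 1)
  a <- binary_map(g, matrix(c(rep(1, 6), rep(0, 30)), 6, 6))
  b <- binary_map(g, matrix(c(rep(1, 12), rep(0, 24)), 6, 6))
  expect_error(sample_validation_points(list(a = a, b = b), 2), "overlap")
  c6 <- binary_map(g, matrix(c(rep(0, 12), rep(1, 6), rep(0, 18)), 6, 6))
  expect_error(sample_validation_points(list(a = a, c = c6), 10),
               "too small")
  pts <- sample_validation_points(list(a = a, c = c6), 6, seed = 1)
  expect_identical(nrow(pts), 12L)
})

test_that("sampling is deterministic under a fixed seed", {
  land <- tiny_landscape()
  o1 <- sample_species(species_spec("sp", 30, 0.75), land$map, seed = 10,
                       margin = land$margin)
  o2 <- sample_species(species_spec("sp", 30, 0.75), land$map, seed = 10,
                       margin = land$margin)
  expect_identical(o1, o2)
  biomes <- partition_biomes(land$stack, land$map, 3)
  expect_identical(sample_validation_points(biomes, 10, seed = 2),
                   sample_validation_points(biomes, 10, seed = 2))
})
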