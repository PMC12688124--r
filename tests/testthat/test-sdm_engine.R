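# sample points over a stack: presences biased to the biome, background uniform
sdm_points <- function(land, n = 200, seed = 1) {
  set.seed(seed)
  bg <- sample_background(land$stack, n, seed = seed)
  occ <- sample_species(species_spec("sp", n, 1.0), land$map, seed = seed,
                        margin = land$margin)
  rbind(data.frame(x = occ$x, y = occ$y, label = "presence"),
        data.frame(x = bg$x, y = bg$y, label = "background"))
}

test_that("an exact copy of a layer is filtered out", {
  land <- tiny_landscape()
  stack <- land$stack[1:3]
  stack$copy_of_1 <- raster_layer(stack[[1]]$grid, stack[[1]]$values,
                                  "copy_of_1")
  sel <- spearman_filter(stack, sdm_points(land), cutoff = 0.7)
  expect_identical(sum(c("layer1", "copy_of_1") %in% sel$kept), 1L)
  expect_true(any(sel$dropped$layer %in% c("layer1", "copy_of_1")))
})

test_that("independent layers are all kept and the kept set verifies", {
  land <- tiny_landscape()
  pts <- sdm_points(land)
  sel <- spearman_filter(land$stack, pts, cutoff = 0.7)
  expect_setequal(sel$kept, names(land$stack))
  # direct recomputation of the pairwise invariant
  vals <- sapply(land$stack[sel$kept], extract_values, x = pts$x, y = pts$y)
  rho <- cor(vals, method = "spearman")
  expect_true(all(abs(rho[upper.tri(rho)]) < 0.7))
})

test_that("of a correlated pair plus an independent layer, two are kept", {
  land <- tiny_landscape()
  g <- land$stack[[1]]$grid
  a <- land$stack[[1]]
  set.seed(13)
  b <- raster_layer(g, a$values + matrix(rnorm(length(a$values), sd = 0.25),
                                         nrow(a$values)), "b_near_a")
  stack <- list(layer1 = a, b_near_a = b, layer3 = land$stack[[3]])
  pts <- sdm_points(land)
  vals <- sapply(stack, extract_values, x = pts$x, y = pts$y)
  expect_gt(abs(cor(vals[, 1], vals[, 2], method = "spearman")), 0.9)
  sel <- spearman_filter(stack, pts, cutoff = 0.7)
  expect_length(sel$kept, 2L)
  expect_true("layer3" %in% sel$kept)
  expect_identical(sum(c("layer1", "b_near_a") %in% sel$kept), 1L)
  expect_identical(nrow(sel$dropped), 1L)
  expect_gte(abs(sel$dropped$rho), 0.7)
})

test_that("constant layers are dropped with a zero-variance reason", {
  land <- tiny_landscape()
  stack <- land$stack[1:2]
  stack$flat <- raster_layer(stack[[1]]$grid,
                             matrix(3, nrow(stack[[1]]$values),
                                    ncol(stack[[1]]$values)), "flat")
  sel <- spearman_filter(stack, sdm_points(land))
  expect_false("flat" %in% sel$kept)
  expect_identical(sel$dropped$correlated_with[sel$dropped$layer == "flat"],
                   "zero variance")
})

test_that("the split scheme follows the record-count rule", {
  expect_identical(split_scheme(5), "bootstrap")
  expect_identical(split_scheme(19), "bootstrap")
  expect_identical(split_scheme(20), "kfold")
  expect_identical(split_scheme(100), "kfold")
  expect_error(split_scheme(4), "not modelable")
})

test_that("rank AUC matches the ordered-pair definition", {
  expect_equal(auc_rank(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(auc_rank(c(0.8, 0.4), c(0.6, 0.2)), 0.75)
  expect_equal(auc_rank(c(0.5, 0.5), c(0.5, 0.5)), 0.5)  # all ties
  set.seed(31)
  for (i in 1:50) {
    pos <- sample(seq(0, 1, 0.1), sample(2:30, 1), replace = TRUE)
    neg <- sample(seq(0, 1, 0.1), sample(2:30, 1), replace = TRUE)
    expect_equal(auc_rank(pos, neg), oracle_auc(pos, neg))
  }
})

test_that("fitted models separate presences from background", {
  land <- tiny_landscape()
  occ <- sample_species(species_spec("sp", 40, 1.0), land$map, seed = 6,
                        margin = land$margin)
  bg <- sample_background(land$stack, 500, seed = 60)
  for (bk in c("envelope", "weighted_logistic")) {
    fit <- fit_suitability(occ, land$stack, background_n = 500, backend = bk,
                           seed = 1)
    pos <- predict(fit, land$stack, occ$x, occ$y)
    neg <- predict(fit, land$stack, bg$x, bg$y)
    expect_true(all(pos >= 0 & pos <= 1))
    expect_gt(mean(pos), mean(neg))
    # determinism: same seed, same parameters
    fit2 <- fit_suitability(occ, land$stack, background_n = 500,
                            backend = bk, seed = 1)
    expect_identical(fit$parameters, fit2$parameters)
  }
})

test_that("an envelope with a single presence scores 1 at that presence", {
  land <- tiny_landscape()
  occ <- sample_species(species_spec("sp", 1, 1.0), land$map, seed = 2)
  fit <- fit_suitability(occ, land$stack, background_n = 200,
                         backend = "envelope")
  expect_equal(predict(fit, land$stack, occ$x, occ$y), 1)
})

test_that("LPT binarization never omits a training presence", {
  land <- tiny_landscape()
  for (bk in c("envelope", "weighted_logistic")) {
    occ <- sample_species(species_spec("sp", 25, 0.8), land$map, seed = 14,
                          margin = land$margin)
    fit <- fit_suitability(occ, land$stack, background_n = 300, backend = bk)
    bl <- binarize_lpt(fit, occ, land$stack)
    expect_equal(bl$lpt, min(predict(fit, land$stack, occ$x, occ$y)),
                 tolerance = 1e-10)
    expect_true(all(extract_values(bl$map, occ$x, occ$y) == 1))
  }
})

test_that("a constant suitability surface binarizes to an all-1 map", {
  g <- grid_spec(10, 10, cell_size = 1)
  flat_stack <- list(layer1 = raster_layer(g, matrix(1, 10, 10)),
                     layer2 = raster_layer(g, matrix(2, 10, 10)))
  occ <- data.frame(species = "sp", x = c(2.5, 7.5), y = c(2.5, 7.5))
  fit <- fit_suitability(occ, flat_stack, background_n = 50,
                         backend = "envelope")
  bl <- binarize_lpt(fit, occ, flat_stack)
  expect_true(all(bl$map$values == 1))
})

test_that("evaluation produces a pass flag consistent with the AUC cutoff", {
  land <- tiny_landscape()
  occ <- sample_species(species_spec("sp", 30, 1.0), land$map, seed = 5,
                        margin = land$margin)
  ev <- evaluate_model(occ, land$stack, backend = "weighted_logistic",
                       background_n = 500, seed = 2)
  expect_identical(ev$scheme, "kfold")
  expect_identical(ev$passed, ev$auc >= 0.7)
  expect_true(ev$lpt >= 0 && ev$lpt <= 1)
  occ2 <- occ[1:10, ]
  ev2 <- evaluate_model(occ2, land$stack, backend = "weighted_logistic",
                        background_n = 500, seed = 2)
  expect_identical(ev2$scheme, "bootstrap")
  expect_identical(ev2$n_replicates + ev2$n_skipped, 10L)
})

test_that("strict biome specialists evaluate with high AUC", {
  land <- tiny_landscape()
  set.seed(17)
  for (i in 1:5) {
    occ <- sample_species(species_spec("sp", 60, 1.0), land$map,
                          seed = 40 + i, margin = land$margin)
    ev <- evaluate_model(occ, land$stack, backend = "weighted_logistic",
                         background_n = 1000, seed = 40 + i)
    expect_gt(ev$auc, 0.9)
  }
})
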