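# Reference in-silico experiment: can a pool of biome-affiliated species
# recover the true biome boundary through the full modeling chain
# (sampling -> thinning -> suitability model -> AUC gate -> LPT -> stacking
# -> Kappa-optimal threshold)?

#' Biome-recovery experiment on a synthetic landscape
#'
#' Generates a landscape with a rule-defined true biome, samples a pool of
#' species with affinities drawn from `affinity_range`, runs each species
#' through thinning, suitability modeling, the AUC gate and LPT
#' binarization, stacks the resulting maps and selects the Kappa-maximizing
#' richness threshold against the true biome. The returned Kappa measures
#' how well the pool recovers the truth.
#'
#' @param seed Integer seed controlling every stochastic step.
#' @param affinity_range Length-2 vector: species affinities are drawn
#'   uniformly from this interval.
#' @param n_species Pool size (default 30).
#' @param record_range Records per species drawn uniformly from this
#'   integer range (default 30-120).
#' @param gate Apply the AUC >= 0.7 gate before stacking (default TRUE).
#' @param backend SDM backend.
#' @param grid_size Landscape edge in cells (default 100, 1-km cells).
#' @param background_n Background sample size per fit.
#' @return A list: `kappa`, `selected_t`, `n_maps` (stacked species),
#'   `n_gated_out`, `mean_auc`, `area_fraction`, `result` (the full
#'   `delimitation_result`), `true_map`.
#' @export
recovery_experiment <- function(seed = 1L, affinity_range = c(0.75, 1),
                                n_species = 30, record_range = c(30, 120),
                                gate = TRUE, backend = "weighted_logistic",
                                grid_size = 100, background_n = 2000) {
  lc <- landscape_config(grid = grid_spec(grid_size, grid_size,
                                          cell_size = 1, crs_id = "ea_km"),
                         seed = seed)
  stk <- generate_env_stack(lc)
  tb <- true_biome_map(stk, lc$rule)
  marg <- rule_margin(stk, lc$rule)
  set.seed(seed + 1L)
  affs <- stats::runif(n_species, affinity_range[1], affinity_range[2])
  nrec <- sample(seq(record_range[1], record_range[2]), n_species,
                 replace = TRUE)
  maps <- list()
  aucs <- numeric(0)
  gated_out <- 0L
  for (i in seq_len(n_species)) {
    occ <- sample_species(species_spec(sprintf("sp%02d", i), nrec[i],
                                       affs[i]),
                          tb$map, seed = seed + 100L + i, margin = marg)
    occ <- thin_occurrences(occ, 5, geographic = FALSE, seed = seed)
    if (nrow(occ) < 5) next
    ev <- evaluate_model(occ, stk, backend = backend,
                         background_n = background_n,
                         seed = seed + 200L + i)
    aucs <- c(aucs, ev$auc)
    if (gate && !ev$passed) { gated_out <- gated_out + 1L; next }
    maps[[length(maps) + 1]] <- binarize_lpt(ev$model, occ, stk)$map
  }
  if (!length(maps)) stop("no species maps survived modeling")
  res <- delimit(maps, tb$map)
  list(kappa = res$kappa, selected_t = res$selected_t,
       n_maps = length(maps), n_gated_out = gated_out,
       mean_auc = mean(aucs), area_fraction = res$area_fraction,
       result = res, true_map = tb$map)
}
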