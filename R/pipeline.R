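# End-to-end orchestration: synth -> prep -> affinity -> sdm -> delimit ->
# validate. Stages exchange data only through files in the output directory
# (CSV, ASCII grid, GeoJSON, JSON), so any stage can be re-run from the
# manifest alone.

#' Default run configuration
#'
#' Every method constant is surfaced as a key with its standard value:
#' 5-km thinning, Spearman cutoff 0.7, AUC cutoff 0.7, inclusive affinity
#' tiers at 0.50 / 0.75 / 1.00, LPT binarization.
#'
#' @param outdir Output directory.
#' @param seed Integer seed used by every stochastic stage.
#' @param grid_size Synthetic landscape edge length in cells.
#' @param n_species Number of synthetic species in the pool.
#' @param backend SDM backend (`"envelope"` or `"weighted_logistic"`).
#' @param background_n Background sample size.
#' @param n_validation_per_biome Validation points per synthetic biome.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(outdir = tempfile("biomestack_run_"),
                               seed = 1L, grid_size = 100, n_species = 30,
                               backend = "weighted_logistic",
                               background_n = 2000,
                               n_validation_per_biome = 200) {
  structure(list(
    outdir = outdir, seed = as.integer(seed),
    grid_size = as.integer(grid_size),
    n_layers = 6, autocorrelation_scale = 8, n_biomes = 5,
    n_species = as.integer(n_species),
    thinning_km = 5, spearman_cutoff = 0.7, auc_cutoff = 0.7,
    tier_thresholds = c(characteristic = 0.50, high_affinity = 0.75,
                        strict = 1.00),
    backend = backend, background_n = as.integer(background_n),
    min_records = 5, n_validation_per_biome = as.integer(n_validation_per_biome)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file with keys of [default_run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg$tier_thresholds <- unlist(cfg$tier_thresholds)
  stopifnot(all(cfg$tier_thresholds > 0), all(cfg$tier_thresholds <= 1),
            !is.unsorted(cfg$tier_thresholds, strictly = TRUE))
  cfg
}

# species pool covering all affinity tiers plus out-of-biome species;
# affinities and record counts are deterministic functions of the seed
.default_species_pool <- function(config) {
  set.seed(config$seed + 7L)
  n <- config$n_species
  aff <- c(rep(1.0, ceiling(n * 0.25)),
           stats::runif(ceiling(n * 0.30), 0.75, 0.95),
           stats::runif(ceiling(n * 0.25), 0.50, 0.70),
           stats::runif(n, 0.10, 0.45))[seq_len(n)]
  data.frame(name = sprintf("species_%02d", seq_len(n)),
             n_records = sample(30:120, n, replace = TRUE),
             target_affinity = round(aff, 2),
             duplicate_rate = stats::runif(n, 0, 0.2),
             stringsAsFactors = FALSE)
}

.paths <- function(outdir) {
  list(env = file.path(outdir, "env"),
       occurrences = file.path(outdir, "occurrences_raw.csv"),
       cleaned = file.path(outdir, "occurrences_cleaned.csv"),
       thinned = file.path(outdir, "occurrences_thinned.csv"),
       rejections = file.path(outdir, "rejection_log.csv"),
       reference = file.path(outdir, "reference_biome.geojson"),
       true_map = file.path(outdir, "true_biome.asc"),
       validation = file.path(outdir, "validation_points.csv"),
       biomes = file.path(outdir, "biomes"),
       affinity = file.path(outdir, "affinity.csv"),
       models = file.path(outdir, "models"),
       evaluation = file.path(outdir, "model_evaluation.csv"),
       delimit = file.path(outdir, "delimitation"),
       metrics = file.path(outdir, "validation_metrics.csv"),
       manifest = file.path(outdir, "manifest.json"))
}

#' Synthetic-data stage: landscape, species records, validation points
#' @param config A `run_config`.
#' @return Invisibly, the list of files written.
#' @export
stage_synth <- function(config) {
  p <- .paths(config$outdir)
  for (d in c(config$outdir, p$env, p$biomes))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  lc <- landscape_config(
    grid = grid_spec(config$grid_size, config$grid_size, cell_size = 1,
                     crs_id = "ea_km"),
    n_layers = config$n_layers,
    autocorrelation_scale = config$autocorrelation_scale,
    seed = config$seed, n_biomes = config$n_biomes)
  stack <- generate_env_stack(lc)
  for (nm in names(stack))
    write_raster(stack[[nm]], file.path(p$env, paste0(nm, ".asc")))
  tb <- true_biome_map(stack, lc$rule)
  write_raster(tb$map, p$true_map)
  write_polygons_geojson(tb$outline, p$reference)
  margin <- rule_margin(stack, lc$rule)
  pool <- .default_species_pool(config)
  occ <- do.call(rbind, lapply(seq_len(nrow(pool)), function(i) {
    sp <- species_spec(pool$name[i], pool$n_records[i],
                       pool$target_affinity[i], pool$duplicate_rate[i])
    sample_species(sp, tb$map, seed = config$seed + 100L + i, margin = margin)
  }))
  write_occurrences_csv(occ, p$occurrences)
  biomes <- partition_biomes(stack, tb$map, config$n_biomes)
  for (nm in names(biomes))
    write_raster(biomes[[nm]], file.path(p$biomes, paste0(nm, ".asc")))
  pts <- sample_validation_points(biomes, config$n_validation_per_biome,
                                  seed = config$seed + 500L)
  write_points_csv(pts, p$validation)
  invisible(p)
}

#' Cleaning stage: criteria filters, deduplication and 5-km thinning
#' @param config A `run_config`.
#' @return Invisibly, the cleaned per-species record list.
#' @export
stage_prep <- function(config) {
  p <- .paths(config$outdir)
  occ <- read_occurrences_csv(p$occurrences)
  grid <- read_raster(p$true_map)$grid
  region <- rect_polygon(grid$origin_x,
                         grid$origin_x + grid$n_cols * grid$cell_size,
                         grid$origin_y - grid$n_rows * grid$cell_size,
                         grid$origin_y, crs_id = grid$crs_id)
  cleaned <- clean_records(occ, region = region)
  write_occurrences_csv(cleaned$records, p$cleaned)
  utils::write.csv(cleaned$rejections, p$rejections, row.names = FALSE)
  thinned <- do.call(rbind, lapply(cleaned$per_species, thin_occurrences,
                                   min_dist_km = config$thinning_km,
                                   geographic = FALSE, seed = config$seed))
  rownames(thinned) <- NULL
  write_occurrences_csv(thinned, p$thinned)
  message("prep: ", nrow(cleaned$records), " records kept, ",
          nrow(cleaned$rejections), " rejected, ",
          nrow(thinned), " after thinning")
  invisible(cleaned)
}

#' Affinity stage: in-biome proportions and nested tier rosters
#' @param config A `run_config`.
#' @return Invisibly, the assignment table.
#' @export
stage_affinity <- function(config) {
  p <- .paths(config$outdir)
  cleaned <- read_occurrences_csv(p$cleaned)
  reference <- read_polygons_geojson(p$reference)
  assignments <- classify_affinity_pool(split(cleaned, cleaned$species),
                                        reference,
                                        thresholds = config$tier_thresholds)
  write_affinity_csv(assignments, p$affinity)
  invisible(assignments)
}

#' SDM stage: variable filter, per-species fit, AUC gate, LPT maps
#' @param config A `run_config`.
#' @return Invisibly, the evaluation table.
#' @export
stage_sdm <- function(config) {
  p <- .paths(config$outdir)
  dir.create(p$models, showWarnings = FALSE)
  thinned <- read_occurrences_csv(p$thinned)
  occ_sets <- modelable_species(split(thinned, thinned$species),
                                config$min_records)
  stack <- lapply(list.files(p$env, pattern = "\\.asc$", full.names = TRUE),
                  read_raster)
  names(stack) <- vapply(stack, `[[`, "", "name")
  stack <- stack[order(as.integer(sub("layer(\\d+).*", "\\1", names(stack))),
                       names(stack))]
  bg <- sample_background(stack, max(nrow(thinned) * 2, 500),
                          seed = config$seed + 900L)
  pts <- rbind(data.frame(x = thinned$x, y = thinned$y, label = "presence"),
               data.frame(x = bg$x, y = bg$y, label = "background"))
  sel <- spearman_filter(stack, pts, cutoff = config$spearman_cutoff)
  rows <- lapply(names(occ_sets$modelable), function(sp) {
    occ <- occ_sets$modelable[[sp]]
    ev <- evaluate_model(occ, stack, backend = config$backend,
                         background_n = config$background_n,
                         layers = sel$kept, auc_cutoff = config$auc_cutoff,
                         seed = config$seed + 2000L +
                           match(sp, names(occ_sets$modelable)))
    if (ev$passed) {
      bl <- binarize_lpt(ev$model, occ, stack)
      write_raster(bl$map, file.path(p$models, paste0(sp, ".asc")))
    }
    data.frame(species = sp, n_records = nrow(occ), scheme = ev$scheme,
               auc = ev$auc, lpt = ev$lpt, passed = ev$passed)
  })
  evaluation <- do.call(rbind, rows)
  utils::write.csv(cbind(evaluation,
                         kept_layers = paste(sel$kept, collapse = ";")),
                   p$evaluation, row.names = FALSE)
  message("sdm: ", sum(evaluation$passed), "/", nrow(evaluation),
          " species passed the AUC gate (layers kept: ",
          paste(sel$kept, collapse = ", "), ")")
  invisible(evaluation)
}

#' Delimitation stage: stack, sweep and threshold selection per tier
#' @param config A `run_config`.
#' @return Invisibly, a named list of `delimitation_result`s.
#' @export
stage_delimit <- function(config) {
  p <- .paths(config$outdir)
  dir.create(p$delimit, showWarnings = FALSE)
  assignments <- utils::read.csv(p$affinity, stringsAsFactors = FALSE)
  evaluation <- utils::read.csv(p$evaluation, stringsAsFactors = FALSE)
  reference <- read_raster(p$true_map)
  reference <- binary_map(reference$grid, reference$values, "reference")
  rosters <- tier_rosters(assignments)
  passed <- evaluation$species[evaluation$passed]
  results <- list()
  for (tier in names(rosters)) {
    roster <- intersect(rosters[[tier]], passed)
    if (!length(roster)) {
      message("delimit: tier '", tier, "' has no AUC-passed species; skipped")
      next
    }
    maps <- lapply(roster, function(sp) {
      r <- read_raster(file.path(p$models, paste0(sp, ".asc")))
      binary_map(r$grid, r$values, sp)
    })
    res <- delimit(maps, reference)
    write_raster(res$map, file.path(p$delimit, paste0(tier, ".asc")))
    write_sweep_csv(res$sweep, file.path(p$delimit, paste0(tier, "_sweep.csv")))
    jsonlite::write_json(
      list(tier = tier, n_species = length(roster), selected_t = res$selected_t,
           kappa = res$kappa, sensitivity = res$sensitivity,
           specificity = res$specificity, area_km2 = res$area_km2,
           area_fraction = res$area_fraction),
      file.path(p$delimit, paste0(tier, "_summary.json")),
      auto_unbox = TRUE, digits = NA)
    message(sprintf(
      "delimit: %s: %d species, t* = %d, kappa = %.3f, area = %.0f km2 (%.1f%%)",
      tier, length(roster), res$selected_t, res$kappa, res$area_km2,
      100 * res$area_fraction))
    results[[tier]] <- res
  }
  invisible(results)
}

#' Validation stage: point-based confusion metrics and tier comparison
#' @param config A `run_config`.
#' @param positive_label Label of the focal biome among the validation
#'   points (default `"SDTF"`).
#' @return Invisibly, a list with per-tier metrics, the map-agreement Kappa
#'   matrix and the Wilcoxon comparison of the two best tiers.
#' @export
stage_validate <- function(config, positive_label = "SDTF") {
  p <- .paths(config$outdir)
  pts <- read_points_csv(p$validation)
  tier_files <- list.files(p$delimit, pattern = "^[a-z_]+\\.asc$",
                           full.names = TRUE)
  maps <- lapply(tier_files, function(f) {
    r <- read_raster(f)
    binary_map(r$grid, r$values, r$name)
  })
  names(maps) <- vapply(maps, `[[`, "", "name")
  metrics <- lapply(maps, function(m)
    compute_metrics(confusion_from_points(pts, positive_label, m)))
  write_metrics_csv(metrics, p$metrics)
  agreement <- outer(names(maps), names(maps),
                     Vectorize(function(a, b)
                       map_agreement_kappa(maps[[a]], maps[[b]])))
  dimnames(agreement) <- list(names(maps), names(maps))
  wilcoxon <- NULL
  if (all(c("high_affinity", "characteristic") %in% names(maps))) {
    agree_vec <- function(m) {
      v <- extract_values(m, pts$x, pts$y)
      as.numeric((v == 1) == (pts$label == positive_label))[!is.na(v)]
    }
    wilcoxon <- compare_models_wilcoxon(agree_vec(maps$high_affinity),
                                        agree_vec(maps$characteristic))
  }
  invisible(list(metrics = metrics, agreement = agreement,
                 wilcoxon = wilcoxon))
}

#' Run the full pipeline
#'
#' Executes synth, prep, affinity, sdm, delimit and validate in order, then
#' writes a manifest (seed, configuration, stage timings, md5 hash of every
#' artifact) sufficient to re-run any stage.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_run_config()) {
  p <- .paths(config$outdir)
  stages <- list(synth = stage_synth, prep = stage_prep,
                 affinity = stage_affinity, sdm = stage_sdm,
                 delimit = stage_delimit, validate = stage_validate)
  timings <- list()
  for (nm in names(stages)) {
    t0 <- proc.time()[["elapsed"]]
    tryCatch(stages[[nm]](config), error = function(e)
      stop("stage '", nm, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[nm]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  files <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, p$manifest)
  manifest <- list(
    package_version = as.character(utils::packageVersion("biomestack")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = unclass(config),
    stage_timings_s = timings,
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            sub(paste0("^", config$outdir, "/?"), "", files)))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
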