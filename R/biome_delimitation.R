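# Stacking per-species binary maps into richness surfaces, sweeping richness
# thresholds against a reference map, and selecting the Kappa-maximizing
# threshold as the delimited biome boundary.

#' Stack binary species maps into a richness map
#'
#' Cell-wise sum of the per-species presence maps; a cell is no-data if any
#' input map is no-data there.
#'
#' @param maps List of aligned `binary_map`s.
#' @return A `raster_layer` of class `richness_map` with attribute
#'   `n_species`.
#' @export
stack_models <- function(maps) {
  stopifnot(length(maps) >= 1)
  g <- maps[[1]]$grid
  for (m in maps) {
    stopifnot(inherits(m, "binary_map"))
    if (!grids_aligned(m$grid, g)) stop("maps are not aligned")
  }
  vals <- Reduce(`+`, lapply(maps, `[[`, "values"))
  r <- raster_layer(g, vals, "richness")
  class(r) <- c("richness_map", class(r))
  attr(r, "n_species") <- length(maps)
  r
}

#' Sweep richness thresholds against a reference map
#'
#' For each threshold t = 1, 2, ..., max(richness), the prediction
#' (richness >= t) is cross-tabulated against the reference over jointly
#' valid cells and scored with sensitivity, specificity and Cohen's Kappa.
#'
#' @param richness A `richness_map` (from [stack_models()]).
#' @param reference An aligned reference `binary_map` with both classes
#'   present.
#' @return A data.frame with columns t, tp, fp, tn, fn, sensitivity,
#'   specificity, kappa.
#' @export
sweep_thresholds <- function(richness, reference) {
  if (!grids_aligned(richness$grid, reference$grid))
    stop("richness and reference are not aligned")
  ok <- !is.na(richness$values) & !is.na(reference$values)
  rv <- richness$values[ok]
  ref <- reference$values[ok] == 1
  if (all(ref) || !any(ref))
    stop("reference map has a single class: Kappa is undefined")
  t_max <- max(rv)
  if (t_max < 1) stop("richness map is empty (no species predicted anywhere)")
  rows <- lapply(seq_len(t_max), function(t) {
    pred <- rv >= t
    m <- compute_metrics(confusion_counts(tp = sum(pred & ref),
                                          fp = sum(pred & !ref),
                                          tn = sum(!pred & !ref),
                                          fn = sum(!pred & ref)))
    data.frame(t = t, tp = m$counts$tp, fp = m$counts$fp, tn = m$counts$tn,
               fn = m$counts$fn, sensitivity = m$sensitivity,
               specificity = m$specificity, kappa = m$kappa)
  })
  do.call(rbind, rows)
}

#' Select the Kappa-maximizing richness threshold
#'
#' The final threshold is the one with the highest Kappa; ties go to the
#' smallest (most inclusive) threshold, or with `tiebreak = "tss"` to the
#' Kappa-tied threshold maximizing sensitivity + specificity - 1.
#'
#' @param sweep Data.frame from [sweep_thresholds()].
#' @param tiebreak `"smallest_t"` (default) or `"tss"`.
#' @return The selected row of `sweep` (one-row data.frame).
#' @export
select_threshold <- function(sweep, tiebreak = c("smallest_t", "tss")) {
  tiebreak <- match.arg(tiebreak)
  stopifnot(nrow(sweep) >= 1)
  best <- max(sweep$kappa)
  tied <- sweep[abs(sweep$kappa - best) < 1e-12, , drop = FALSE]
  if (tiebreak == "tss" && nrow(tied) > 1) {
    tss <- tied$sensitivity + tied$specificity - 1
    tied <- tied[abs(tss - max(tss)) < 1e-12, , drop = FALSE]
  }
  tied[which.min(tied$t), , drop = FALSE]
}

#' Delimit a biome from a roster of species maps
#'
#' Composes the full delimitation: stack the roster's binary maps into a
#' richness surface, sweep richness thresholds against the reference map,
#' select the Kappa-maximizing threshold, and measure the area of the
#' delimited map.
#'
#' @param maps Named list of per-species `binary_map`s (all AUC-passed).
#' @param reference Reference `binary_map` (or `polygon_set`, rasterized
#'   onto the maps' grid).
#' @param region Optional region `binary_map`: cells outside it are treated
#'   as no-data in the evaluation and area fractions.
#' @param tiebreak Passed to [select_threshold()].
#' @return A list of class `delimitation_result`: selected_t, map, sweep,
#'   richness, kappa, sensitivity, specificity, area_km2, area_fraction.
#' @export
delimit <- function(maps, reference, region = NULL,
                    tiebreak = c("smallest_t", "tss")) {
  if (!length(maps)) stop("empty roster: no species maps to stack")
  richness <- stack_models(maps)
  if (inherits(reference, "polygon_set"))
    reference <- rasterize_polygons(reference, richness$grid)
  if (!is.null(region)) {
    mask <- is.na(region$values) | region$values == 0
    richness$values[mask] <- NA
    reference$values[mask] <- NA
  }
  sweep <- sweep_thresholds(richness, reference)
  sel <- select_threshold(sweep, tiebreak)
  vals <- ifelse(is.na(richness$values), NA,
                 as.numeric(richness$values >= sel$t))
  map <- binary_map(richness$grid, vals, "delimited_biome")
  area <- equal_area_km2(map)
  structure(list(selected_t = sel$t, map = map, sweep = sweep,
                 richness = richness, kappa = sel$kappa,
                 sensitivity = sel$sensitivity, specificity = sel$specificity,
                 area_km2 = area$area_km2, area_fraction = area$fraction),
            class = "delimitation_result")
}

#' Write a threshold sweep table to CSV
#' @param sweep Data.frame from [sweep_thresholds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}
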