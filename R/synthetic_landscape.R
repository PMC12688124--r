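# Synthetic landscapes with a rule-defined true biome, species occurrence
# sets with exact biome affinity, and multi-biome validation points. Every
# downstream stage can therefore be exercised against known truth without
# any external download.

#' Biome rule: a conjunction of quantile thresholds on environmental layers
#'
#' Each condition compares one layer against a quantile of its own values,
#' e.g. layer 1 at or above its 70th percentile AND layer 2 at or below its
#' 60th percentile. The rule also defines a continuous margin (standardized
#' distance from the limiting threshold) used to weight in-biome sampling so
#' that suitability models can learn the biome.
#'
#' @param conditions List of conditions, each `list(layer =, op =, q =)` with
#'   `op` one of `">="`, `"<="` and `q` a quantile probability in (0, 1).
#' @return An object of class `biome_rule`.
#' @export
biome_rule <- function(conditions) {
  for (cond in conditions) {
    stopifnot(is.numeric(cond$layer), cond$op %in% c(">=", "<="),
              cond$q >= 0, cond$q <= 1)
  }
  structure(list(conditions = conditions), class = "biome_rule")
}

#' Landscape configuration
#'
#' @param grid A `grid_spec`; defaults to a 100 x 100 equal-area grid with
#'   1-km cells.
#' @param n_layers Number of environmental layers (>= 2).
#' @param autocorrelation_scale Gaussian smoothing scale in cells; 0 yields
#'   spatially independent noise.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param rule A `biome_rule` defining the true biome; the default keeps
#'   roughly a fifth of the landscape (layer 1 >= q70 and layer 2 <= q60).
#' @param n_biomes Number of mutually exclusive synthetic biomes (>= 2) for
#'   validation-point sampling.
#' @param near_duplicate If TRUE, append a near-copy of layer 1 (rank
#'   correlation > 0.95) for variable-selection tests.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(grid = grid_spec(100, 100, cell_size = 1,
                                              crs_id = "ea_km"),
                             n_layers = 6, autocorrelation_scale = 8,
                             seed = 1L,
                             rule = biome_rule(list(
                               list(layer = 1, op = ">=", q = 0.70),
                               list(layer = 2, op = "<=", q = 0.60))),
                             n_biomes = 5, near_duplicate = FALSE) {
  stopifnot(n_layers >= 2, n_biomes >= 2, autocorrelation_scale >= 0)
  for (cond in rule$conditions)
    if (cond$layer > n_layers) stop("biome rule references missing layer ",
                                    cond$layer)
  structure(list(grid = grid, n_layers = as.integer(n_layers),
                 autocorrelation_scale = autocorrelation_scale,
                 seed = as.integer(seed), rule = rule,
                 n_biomes = as.integer(n_biomes),
                 near_duplicate = near_duplicate),
            class = "landscape_config")
}

# separable Gaussian smoothing with edge renormalization (kernel mass that
# falls off the grid is excluded from the average, so edges are unbiased)
.smooth_field <- function(m, scale) {
  if (scale <= 0) return(m)
  half <- max(1L, ceiling(3 * scale))
  k <- stats::dnorm(seq(-half, half), sd = scale)
  band <- function(n) {
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - half):min(n, i + half)
      kv <- k[j - i + half + 1]
      w[i, j] <- kv / sum(kv)
    }
    w
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Generate a stack of spatially autocorrelated environmental layers
#'
#' Each layer is Gaussian white noise smoothed with a Gaussian kernel of the
#' configured scale, then standardized to zero mean and unit variance. With
#' `near_duplicate = TRUE` an extra layer highly rank-correlated with layer 1
#' is appended.
#'
#' @param config A `landscape_config`.
#' @return A named list of `raster_layer`s (`layer1`, `layer2`, ...;
#'   the near-duplicate is `layer1_dup`).
#' @export
generate_env_stack <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  g <- config$grid
  set.seed(config$seed)
  stack <- list()
  for (i in seq_len(config$n_layers)) {
    m <- matrix(stats::rnorm(g$n_rows * g$n_cols), g$n_rows, g$n_cols)
    m <- .smooth_field(m, config$autocorrelation_scale)
    m <- (m - mean(m)) / stats::sd(m)
    nm <- paste0("layer", i)
    stack[[nm]] <- raster_layer(g, m, nm)
  }
  if (config$near_duplicate) {
    base <- stack[[1]]$values
    dup <- base + matrix(stats::rnorm(length(base), sd = 0.05),
                         nrow(base), ncol(base))
    stack[["layer1_dup"]] <- raster_layer(g, dup, "layer1_dup")
  }
  stack
}

# threshold value for one rule condition on this stack
.rule_thresholds <- function(stack, rule) {
  lapply(rule$conditions, function(cond) {
    v <- stack[[cond$layer]]$values
    list(layer = cond$layer, op = cond$op,
         value = stats::quantile(v[!is.na(v)], cond$q, names = FALSE),
         sd = stats::sd(v[!is.na(v)]))
  })
}

#' Continuous margin of a biome rule
#'
#' For each cell, the minimum over conditions of the signed, standardized
#' distance to the condition's threshold (positive inside the biome). Used
#' to weight in-biome occurrence sampling and as the learnable environmental
#' signal.
#'
#' @param stack Named list of `raster_layer`s.
#' @param rule A `biome_rule`.
#' @return A `raster_layer` named `"rule_margin"`.
#' @export
rule_margin <- function(stack, rule) {
  th <- .rule_thresholds(stack, rule)
  g <- stack[[1]]$grid
  margin <- NULL
  for (cond in th) {
    d <- (stack[[cond$layer]]$values - cond$value) / cond$sd
    if (cond$op == "<=") d <- -d
    margin <- if (is.null(margin)) d else pmin(margin, d)
  }
  raster_layer(g, margin, "rule_margin")
}

#' True biome map and its vectorized outline
#'
#' Evaluates the rule on the stack to produce the true-biome binary map, and
#' vectorizes that map into cell-boundary polygons (one rectangle per
#' horizontal run of 1-cells), so that rasterizing the outline reproduces
#' the map exactly.
#'
#' @param stack Named list of `raster_layer`s.
#' @param rule A `biome_rule`.
#' @return A list with `map` (a `binary_map`) and `outline` (a
#'   `polygon_set`).
#' @export
true_biome_map <- function(stack, rule) {
  m <- rule_margin(stack, rule)
  vals <- ifelse(is.na(m$values), NA, as.numeric(m$values >= 0))
  if (sum(vals, na.rm = TRUE) == 0)
    stop("empty biome: the rule selects no cells")
  map <- binary_map(stack[[1]]$grid, vals, "true_biome")
  list(map = map, outline = vectorize_map(map))
}

#' Vectorize a binary map into run-rectangle polygons
#'
#' Each maximal horizontal run of 1-cells becomes one axis-aligned rectangle
#' on cell boundaries. Rasterizing the result (cell-center rule) reproduces
#' the input map exactly.
#'
#' @param map A `binary_map`.
#' @return A `polygon_set`.
#' @export
vectorize_map <- function(map) {
  g <- map$grid
  polys <- list()
  for (r in seq_len(g$n_rows)) {
    v <- map$values[r, ]
    v[is.na(v)] <- 0
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    for (k in which(rl$values == 1)) {
      xmin <- g$origin_x + (starts[k] - 1) * g$cell_size
      xmax <- g$origin_x + ends[k] * g$cell_size
      ymax <- g$origin_y - (r - 1) * g$cell_size
      ymin <- g$origin_y - r * g$cell_size
      polys[[length(polys) + 1]] <-
        cbind(c(xmin, xmax, xmax, xmin, xmin), c(ymin, ymin, ymax, ymax, ymin))
    }
  }
  polygon_set(polys, crs_id = g$crs_id)
}

#' Species specification for occurrence sampling
#'
#' @param name Species name.
#' @param n_records Number of unique records to emit (>= 1).
#' @param target_affinity Intended proportion of records inside the true
#'   biome, in [0, 1]. The realized in-biome count is exactly
#'   `round(target_affinity * n_records)`.
#' @param duplicate_rate Proportion of duplicate rows appended (copying
#'   locality, collector and date of an existing record).
#' @param coordinate_jitter Half-width of the uniform within-cell placement,
#'   in map units; capped at half a cell so the affinity contract is exact.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(name, n_records, target_affinity,
                         duplicate_rate = 0, coordinate_jitter = NULL) {
  stopifnot(n_records >= 1, target_affinity >= 0, target_affinity <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1)
  structure(list(name = name, n_records = as.integer(n_records),
                 target_affinity = target_affinity,
                 duplicate_rate = duplicate_rate,
                 coordinate_jitter = coordinate_jitter),
            class = "species_spec")
}

# draw k cells (with replacement) from the cells where mask is TRUE,
# optionally weighted; returns matrix of (row, col)
.sample_cells <- function(mask, k, weights = NULL) {
  cells <- which(mask, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("no cells available to sample from")
  w <- if (is.null(weights)) NULL else weights[mask]
  idx <- sample.int(nrow(cells), k, replace = TRUE, prob = w)
  cells[idx, , drop = FALSE]
}

.cell_xy <- function(g, rc, jitter) {
  cx <- g$origin_x + (rc[, 2] - 0.5) * g$cell_size
  cy <- g$origin_y - (rc[, 1] - 0.5) * g$cell_size
  n <- nrow(rc)
  cbind(x = cx + stats::runif(n, -jitter, jitter),
        y = cy + stats::runif(n, -jitter, jitter))
}

#' Sample a species' occurrence records with exact biome affinity
#'
#' Emits exactly `n_records` unique records of which exactly
#' `round(target_affinity * n_records)` fall inside the biome. In-biome
#' records are drawn preferentially from cells with a high rule margin
#' (environmentally suitable), so that a suitability model can recover the
#' biome; outside records are uniform over outside cells. Duplicate rows
#' (same locality, collector, date) are appended at `duplicate_rate`.
#'
#' @param spec A `species_spec`.
#' @param biome The true-biome `binary_map`.
#' @param seed Integer seed.
#' @param margin Optional `raster_layer` from [rule_margin()] used to weight
#'   in-biome cells; NULL weights them uniformly.
#' @return A data.frame of occurrence records with columns species, x, y,
#'   locality, collector, date, habitat, flags.
#' @export
sample_species <- function(spec, biome, seed = 1L, margin = NULL) {
  stopifnot(inherits(spec, "species_spec"), inherits(biome, "binary_map"))
  g <- biome$grid
  set.seed(seed)
  n_in <- as.integer(round(spec$target_affinity * spec$n_records))
  n_out <- spec$n_records - n_in
  inside_mask <- !is.na(biome$values) & biome$values == 1
  outside_mask <- !is.na(biome$values) & biome$values == 0
  if (n_in > 0 && !any(inside_mask))
    stop("impossible affinity: biome has no inside cells")
  if (n_out > 0 && !any(outside_mask))
    stop("impossible affinity: biome has no outside cells")
  # records follow the species' environmental suitability in both strata:
  # inside records concentrate at the biome core, outside records near the
  # biome margin (not uniformly over the landscape). This is the
  # learnability guarantee: a suitability model fitted to the records can
  # recover the biome.
  w <- if (!is.null(margin)) exp(4 * pmin(margin$values, 2)) else NULL
  jitter <- min(spec$coordinate_jitter %||% (g$cell_size / 2), g$cell_size / 2)
  xy <- rbind(
    if (n_in > 0) .cell_xy(g, .sample_cells(inside_mask, n_in, w), jitter),
    if (n_out > 0) .cell_xy(g, .sample_cells(outside_mask, n_out, w), jitter))
  n <- spec$n_records
  rec <- data.frame(
    species = spec$name, x = xy[, 1], y = xy[, 2],
    locality = sprintf("%s_loc_%03d", spec$name, seq_len(n)),
    collector = sprintf("coll_%02d", sample.int(20, n, replace = TRUE)),
    date = sprintf("19%02d-%02d-%02d", sample.int(99, n, TRUE),
                   sample.int(12, n, TRUE), sample.int(28, n, TRUE)),
    habitat = "dry forest", flags = "", stringsAsFactors = FALSE)
  n_dup <- as.integer(round(spec$duplicate_rate * n))
  if (n_dup > 0) {
    dup <- rec[sample.int(n, n_dup, replace = n_dup > n), , drop = FALSE]
    rec <- rbind(rec, dup)
  }
  rownames(rec) <- NULL
  rec
}

#' Partition a landscape into mutually exclusive synthetic biomes
#'
#' Biome 1 is the rule-defined true biome; the remaining cells are split
#' into `n_biomes - 1` classes by quantile bins of layer 1 restricted to
#' outside cells. The result emulates a map of a region's major biomes for
#' validation-point sampling.
#'
#' @param stack Named list of `raster_layer`s.
#' @param biome The true-biome `binary_map`.
#' @param n_biomes Total number of biomes (>= 2).
#' @param labels Optional character vector of biome names; the first names
#'   the true biome.
#' @return Named list of mutually exclusive `binary_map`s.
#' @export
partition_biomes <- function(stack, biome, n_biomes = 5, labels = NULL) {
  stopifnot(n_biomes >= 2)
  labels <- labels %||% c("SDTF", paste0("biome_", seq_len(n_biomes - 1) + 1))
  stopifnot(length(labels) == n_biomes)
  g <- biome$grid
  out <- list()
  out[[labels[1]]] <- biome
  outside <- !is.na(biome$values) & biome$values == 0
  v <- stack[[1]]$values
  qs <- stats::quantile(v[outside], probs = seq(0, 1, length.out = n_biomes),
                        names = FALSE)
  qs[1] <- -Inf; qs[n_biomes] <- Inf
  for (b in seq_len(n_biomes - 1)) {
    sel <- outside & v > qs[b] & v <= qs[b + 1]
    out[[labels[b + 1]]] <- binary_map(g, matrix(as.numeric(sel),
                                                 g$n_rows, g$n_cols))
  }
  out
}

#' Sample labelled validation points across mutually exclusive biomes
#'
#' Draws `n_per_biome` points per biome, each inside a distinct cell of its
#' biome map, labelled with the biome name.
#'
#' @param biome_maps Named list of mutually exclusive `binary_map`s.
#' @param n_per_biome Points per biome.
#' @param seed Integer seed.
#' @return A data.frame with columns x, y, label.
#' @export
sample_validation_points <- function(biome_maps, n_per_biome, seed = 1L) {
  stopifnot(length(names(biome_maps)) == length(biome_maps))
  # mutual exclusivity over valid cells
  tot <- Reduce(`+`, lapply(biome_maps, function(m) {
    v <- m$values; v[is.na(v)] <- 0; v
  }))
  if (any(tot > 1)) stop("biome maps overlap: validation biomes must be ",
                         "mutually exclusive")
  set.seed(seed)
  out <- lapply(names(biome_maps), function(nm) {
    m <- biome_maps[[nm]]
    g <- m$grid
    cells <- which(!is.na(m$values) & m$values == 1, arr.ind = TRUE)
    if (nrow(cells) < n_per_biome)
      stop("biome '", nm, "' too small: ", nrow(cells), " cells for ",
           n_per_biome, " points")
    rc <- cells[sample.int(nrow(cells), n_per_biome), , drop = FALSE]
    xy <- .cell_xy(g, rc, g$cell_size / 2 * 0.999)
    data.frame(x = xy[, 1], y = xy[, 2], label = nm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
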