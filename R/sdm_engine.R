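# Per-species suitability modeling: Spearman variable filtering, presence vs
# background fitting, AUC evaluation with the record-count split rule, and
# lowest-presence-threshold (LPT) binarization.
#
# The suitability algorithm itself is deliberately lightweight; the method's
# contribution is downstream of the SDM. Two backends share one contract
# (suitability in [0, 1], LPT, AUC):
#   envelope          product of per-variable triangular kernels centred on
#                     the presence range (a continuous bioclimatic envelope)
#   weighted_logistic presence-vs-background logistic regression with linear
#                     and quadratic features, classes balanced by weights

#' Greedy Spearman correlation filter over environmental layers
#'
#' Retains a maximal set of layers whose pairwise |Spearman rho| (computed
#' at the sample points) is below `cutoff`. Layers are considered in
#' priority order: |rho| between the layer and the presence indicator at the
#' sample points (how well the layer separates presences from background),
#' ties broken by input order. Constant layers are dropped with reason
#' `"zero variance"`.
#'
#' @param stack Named list of `raster_layer`s.
#' @param sample_points Data.frame with x, y and label (`"presence"` /
#'   `"background"`).
#' @param cutoff Absolute Spearman threshold (default 0.7): kept layers all
#'   satisfy |rho| < cutoff pairwise.
#' @return A list with `kept` (character vector, in priority order) and
#'   `dropped` (data.frame: layer, correlated_with, rho).
#' @export
spearman_filter <- function(stack, sample_points, cutoff = 0.7) {
  stopifnot(length(stack) >= 2, nrow(sample_points) >= 10)
  vals <- vapply(stack, extract_values, numeric(nrow(sample_points)),
                 x = sample_points$x, y = sample_points$y)
  complete <- stats::complete.cases(vals)
  vals <- vals[complete, , drop = FALSE]
  pres <- as.numeric(sample_points$label[complete] == "presence")
  dropped <- data.frame(layer = character(0), correlated_with = character(0),
                        rho = numeric(0), stringsAsFactors = FALSE)
  sds <- apply(vals, 2, stats::sd)
  for (nm in names(stack)[sds == 0 | is.na(sds)])
    dropped <- rbind(dropped, data.frame(layer = nm,
                                         correlated_with = "zero variance",
                                         rho = NA_real_))
  usable <- names(stack)[!(names(stack) %in% dropped$layer)]
  prio <- abs(vapply(usable, function(nm)
    suppressWarnings(stats::cor(vals[, nm], pres, method = "spearman")),
    numeric(1)))
  prio[is.na(prio)] <- 0
  # stable sort keeps input order on ties
  usable <- usable[order(-prio)]
  kept <- character(0)
  for (nm in usable) {
    rho <- if (length(kept))
      vapply(kept, function(k) suppressWarnings(
        stats::cor(vals[, nm], vals[, k], method = "spearman")), numeric(1))
    else numeric(0)
    worst <- if (length(rho)) which.max(abs(rho)) else integer(0)
    if (!length(rho) || abs(rho[worst]) < cutoff) {
      kept <- c(kept, nm)
    } else {
      dropped <- rbind(dropped, data.frame(layer = nm,
                                           correlated_with = kept[worst],
                                           rho = rho[worst]))
    }
  }
  list(kept = kept, dropped = dropped)
}

#' Data-split scheme from the record count
#'
#' Species with 5-20 records (exclusive of 20) are evaluated by bootstrap
#' resampling; species with 20 or more records by k-fold cross-validation.
#' Fewer than 5 records is not modelable.
#'
#' @param n_records Post-thinning record count.
#' @return `"bootstrap"` or `"kfold"`.
#' @export
split_scheme <- function(n_records) {
  if (n_records < 5)
    stop("not modelable: ", n_records, " records (minimum is 5)")
  if (n_records < 20) "bootstrap" else "kfold"
}

#' Sample background points within an accessible area
#'
#' Uniform over the valid cells of the grid whose centers fall inside the
#' accessible-area polygon (all valid cells when `accessible_area` is NULL),
#' one point uniformly placed within each sampled cell.
#'
#' @param stack Named list of `raster_layer`s (defines grid and no-data).
#' @param n Number of background points (capped at the number of available
#'   cells).
#' @param accessible_area Optional `polygon_set` (the accessible area M).
#' @param seed Integer seed.
#' @return Data.frame with columns x, y.
#' @export
sample_background <- function(stack, n = 10000, accessible_area = NULL,
                              seed = 1L) {
  g <- stack[[1]]$grid
  valid <- Reduce(`&`, lapply(stack, function(l) !is.na(l$values)))
  if (!is.null(accessible_area)) {
    m <- rasterize_polygons(accessible_area, g)
    valid <- valid & m$values == 1
  }
  cells <- which(valid, arr.ind = TRUE)
  if (!nrow(cells)) stop("no valid cells to draw background from")
  set.seed(seed)
  k <- min(n, nrow(cells))
  rc <- cells[sample.int(nrow(cells), k), , drop = FALSE]
  xy <- .cell_xy(g, rc, g$cell_size / 2 * 0.999)
  data.frame(x = xy[, 1], y = xy[, 2])
}

# design matrix for either backend: values of kept layers at points
.env_at <- function(stack, layers, x, y) {
  m <- vapply(stack[layers], extract_values, numeric(length(x)), x = x, y = y)
  if (is.null(dim(m))) m <- matrix(m, nrow = length(x))
  colnames(m) <- layers
  m
}

.fit_envelope <- function(pe, probs = c(0.1, 0.9)) {
  # percentile envelope: the 10th-90th presence percentiles bound the core
  # of the kernel, so a minority of stray records cannot flatten it
  lo <- apply(pe, 2, stats::quantile, probs[1], names = FALSE)
  hi <- apply(pe, 2, stats::quantile, probs[2], names = FALSE)
  mid <- (lo + hi) / 2
  half <- pmax((hi - lo) / 2, 1e-8)
  list(mid = mid, half = half)
}

.predict_envelope <- function(par, env) {
  s <- rep(1, nrow(env))
  for (j in seq_along(par$mid)) {
    # triangular kernel: 1 at the presence mid-range, 0.5 at the range
    # limits, 0 beyond twice the half-range
    sj <- pmax(0, 1 - abs(env[, j] - par$mid[j]) / (2 * par$half[j]))
    s <- s * sj
  }
  s
}

.fit_logistic <- function(pe, be) {
  x <- rbind(pe, be)
  mu <- colMeans(x); sdv <- pmax(apply(x, 2, stats::sd), 1e-8)
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  feats <- cbind(z, z^2)
  colnames(feats) <- c(colnames(x), paste0(colnames(x), "_sq"))
  y <- c(rep(1, nrow(pe)), rep(0, nrow(be)))
  # balance total class weights so background size does not dominate
  w <- ifelse(y == 1, 1, nrow(pe) / nrow(be))
  fit <- suppressWarnings(stats::glm.fit(cbind(1, feats), y,
                                         weights = w,
                                         family = stats::binomial()))
  list(coef = fit$coefficients, mu = mu, sd = sdv)
}

.predict_logistic <- function(par, env) {
  z <- sweep(sweep(env, 2, par$mu), 2, par$sd, "/")
  feats <- cbind(1, z, z^2)
  beta <- par$coef
  beta[is.na(beta)] <- 0
  stats::plogis(drop(feats %*% beta))
}

#' Fit a per-species suitability model
#'
#' Trains the chosen backend on the species' presence records against
#' background points drawn uniformly within the accessible area.
#'
#' @param occ Data.frame of one species' records (cleaned and thinned).
#' @param stack Named list of `raster_layer`s (already variable-filtered).
#' @param background_n Number of background points (default 10000, capped at
#'   the number of cells in the accessible area).
#' @param accessible_area Optional `polygon_set` (accessible area M).
#' @param backend `"envelope"` or `"weighted_logistic"`.
#' @param seed Integer seed (background sampling).
#' @param layers Layers to use; default all layers of `stack`.
#' @return An object of class `suitability_model`.
#' @export
fit_suitability <- function(occ, stack, background_n = 10000,
                            accessible_area = NULL,
                            backend = c("envelope", "weighted_logistic"),
                            seed = 1L, layers = names(stack)) {
  backend <- match.arg(backend)
  pe <- .env_at(stack, layers, occ$x, occ$y)
  ok <- stats::complete.cases(pe)
  if (!any(ok)) stop("all presences fall on no-data cells")
  pe <- pe[ok, , drop = FALSE]
  bg <- sample_background(stack, background_n, accessible_area, seed)
  be <- .env_at(stack, layers, bg$x, bg$y)
  be <- be[stats::complete.cases(be), , drop = FALSE]
  par <- switch(backend,
                envelope = .fit_envelope(pe),
                weighted_logistic = .fit_logistic(pe, be))
  structure(list(species = occ$species[1] %||% "species", backend = backend,
                 layers = layers, parameters = par,
                 training_summary = c(presences = nrow(pe),
                                      background = nrow(be))),
            class = "suitability_model")
}

#' Predict suitability at points
#' @param object A `suitability_model`.
#' @param stack Named list of `raster_layer`s.
#' @param x,y Coordinates; default NULL predicts the whole grid.
#' @param ... Unused.
#' @return If `x` is given, a numeric vector in [0, 1] (NA on no-data);
#'   otherwise a `raster_layer` suitability surface.
#' @export
predict.suitability_model <- function(object, stack, x = NULL, y = NULL, ...) {
  g <- stack[[1]]$grid
  if (is.null(x)) {
    cc <- cell_centers(g)
    x <- cc$xy[, 1]; y <- cc$xy[, 2]
    as_layer <- TRUE
  } else as_layer <- FALSE
  env <- .env_at(stack, object$layers, x, y)
  s <- rep(NA_real_, length(x))
  ok <- stats::complete.cases(env)
  s[ok] <- switch(object$backend,
                  envelope = .predict_envelope(object$parameters,
                                               env[ok, , drop = FALSE]),
                  weighted_logistic = .predict_logistic(object$parameters,
                                                        env[ok, , drop = FALSE]))
  if (!as_layer) return(s)
  raster_layer(g, matrix(s, g$n_rows, g$n_cols, byrow = TRUE),
               paste0(object$species, "_suitability"))
}

#' Rank-based AUC (presence vs background)
#'
#' Probability that a random presence outranks a random background point in
#' predicted suitability, ties counting one half. Equivalent to the
#' Mann-Whitney statistic normalized by the number of pairs.
#'
#' @param pos,neg Suitability scores at presences / background points.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  stopifnot(length(pos) >= 1, length(neg) >= 1)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Evaluate a suitability model (AUC with bootstrap or k-fold splits)
#'
#' For `"bootstrap"`, the presences are split 70/30 train/test for each of
#' `n_boot` replicates and the background is redrawn per replicate; for
#' `"kfold"`, presences are partitioned into `k` folds. In both cases the
#' AUC of held-out presences against background points is averaged across
#' replicates/folds. The LPT is computed from a full-data refit: the minimum
#' predicted suitability over all training presences.
#'
#' @param occ Data.frame of one species' records.
#' @param stack Named list of `raster_layer`s.
#' @param scheme `"bootstrap"` or `"kfold"` (see [split_scheme()]); default
#'   chosen from `nrow(occ)`.
#' @param backend,background_n,accessible_area,layers Passed to
#'   [fit_suitability()].
#' @param auc_cutoff AUC pass threshold (default 0.7).
#' @param n_boot Bootstrap replicates (default 10).
#' @param k Folds for k-fold (default 5).
#' @param seed Integer seed.
#' @return A list of class `model_evaluation`: species, auc, scheme,
#'   n_replicates, n_skipped, lpt, passed, and `model` (the full-data fit).
#' @export
evaluate_model <- function(occ, stack, scheme = split_scheme(nrow(occ)),
                           backend = "envelope", background_n = 2000,
                           accessible_area = NULL, layers = names(stack),
                           auc_cutoff = 0.7, n_boot = 10, k = 5, seed = 1L) {
  stopifnot(scheme %in% c("bootstrap", "kfold"))
  n <- nrow(occ)
  set.seed(seed)
  splits <- if (scheme == "bootstrap") {
    n_test <- max(1L, round(0.3 * n))
    lapply(seq_len(n_boot), function(i) sample.int(n, n_test))
  } else {
    fold <- sample(rep_len(seq_len(k), n))
    lapply(seq_len(k), function(i) which(fold == i))
  }
  aucs <- numeric(0); skipped <- 0L
  for (i in seq_along(splits)) {
    test <- splits[[i]]
    if (length(test) < 2 || length(test) >= n) { skipped <- skipped + 1L; next }
    fit <- fit_suitability(occ[-test, , drop = FALSE], stack,
                           background_n = background_n,
                           accessible_area = accessible_area,
                           backend = backend, seed = seed + i,
                           layers = layers)
    bg <- sample_background(stack, max(200L, background_n %/% 4),
                            accessible_area, seed = seed + 1000L + i)
    pos <- predict(fit, stack, occ$x[test], occ$y[test])
    neg <- predict(fit, stack, bg$x, bg$y)
    aucs <- c(aucs, auc_rank(pos, neg))
  }
  full <- fit_suitability(occ, stack, background_n = background_n,
                          accessible_area = accessible_area,
                          backend = backend, seed = seed, layers = layers)
  lpt <- min(predict(full, stack, occ$x, occ$y), na.rm = TRUE)
  auc <- if (length(aucs)) mean(aucs) else NA_real_
  structure(list(species = occ$species[1] %||% "species", auc = auc,
                 scheme = scheme, n_replicates = length(aucs),
                 n_skipped = skipped, lpt = lpt,
                 passed = !is.na(auc) && auc >= auc_cutoff, model = full),
            class = "model_evaluation")
}

#' Binarize a suitability surface at the lowest presence threshold
#'
#' The LPT is the minimum predicted suitability over the training presences;
#' every cell with suitability at or above it becomes 1. By construction no
#' training presence is omitted.
#'
#' @param model A `suitability_model`.
#' @param occ The training records.
#' @param stack Named list of `raster_layer`s.
#' @return A list with `map` (a `binary_map`) and `lpt`.
#' @export
binarize_lpt <- function(model, occ, stack) {
  surface <- predict(model, stack)
  # threshold taken from the surface itself so the zero-omission guarantee
  # is exact in floating point
  lpt <- min(extract_values(surface, occ$x, occ$y), na.rm = TRUE)
  vals <- ifelse(is.na(surface$values), NA,
                 as.numeric(surface$values >= lpt))
  list(map = binary_map(surface$grid, vals, paste0(model$species, "_lpt")),
       lpt = lpt)
}
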