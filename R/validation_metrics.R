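# Confusion-matrix construction and the five evaluation statistics:
# sensitivity, specificity, Cohen's Kappa, underprediction (false-omission
# rate) and overprediction (false-discovery rate). Every derived statistic
# is reported alongside its counts so all numbers are auditable.

#' Confusion counts
#' @param tp,fp,tn,fn Non-negative integer counts; at least one positive.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn >= 1)
  structure(list(tp = unname(tp), fp = unname(fp), tn = unname(tn),
                 fn = unname(fn)),
            class = "confusion_counts")
}

#' Round half-up to a number of decimals
#'
#' Display rounding for metric tables (base `round` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Evaluation statistics from confusion counts
#'
#' Computes sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), Cohen's
#' Kappa = (p_o - p_e)/(1 - p_e) with observed agreement
#' p_o = (TP+TN)/n and chance agreement from the marginal products
#' p_e = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN))/n^2, underprediction = FN/(FN+TN)
#' (the share of predicted-absence units that are actually the biome) and
#' overprediction = FP/(FP+TP) (the share of predicted-presence units that
#' are not). Statistics with a zero denominator are returned NA and listed
#' in `undefined`.
#'
#' @param c A `confusion_counts` object.
#' @return A list of class `validation_metrics`: counts, n, the five
#'   unrounded statistics, `rounded` (2-dp half-up versions) and
#'   `undefined` (names of statistics with zero denominators; includes
#'   `"kappa"` when p_e = 1).
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$tp + c$fp + c$tn + c$fn
  if (n == 0) stop("empty confusion matrix")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rat(c$tp, c$tp + c$fn)
  spec <- rat(c$tn, c$tn + c$fp)
  under <- rat(c$fn, c$fn + c$tn)
  over <- rat(c$fp, c$fp + c$tp)
  p_o <- (c$tp + c$tn) / n
  p_e <- ((c$tp + c$fp) * (c$tp + c$fn) + (c$fn + c$tn) * (c$fp + c$tn)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  stats <- c(sensitivity = sens, specificity = spec, kappa = kappa,
             underprediction = under, overprediction = over)
  structure(list(counts = c, n = n,
                 sensitivity = sens, specificity = spec, kappa = kappa,
                 underprediction = under, overprediction = over,
                 rounded = round_half_up(stats, 2),
                 undefined = names(stats)[is.na(stats)]),
            class = "validation_metrics")
}

#' Confusion counts of labelled points against a binary map
#'
#' Points carrying the positive label on 1-cells are true positives, on
#' 0-cells false negatives; other-label points on 1-cells are false
#' positives, on 0-cells true negatives. Points on no-data cells (or off
#' the grid) are excluded and counted in `n_excluded`.
#'
#' @param points Data.frame with x, y, label.
#' @param positive_label The label of the focal biome.
#' @param map A `binary_map`.
#' @return A `confusion_counts` object with attribute `n_excluded`.
#' @export
confusion_from_points <- function(points, positive_label, map) {
  if (!any(points$label == positive_label))
    stop("no points carry the positive label '", positive_label, "'")
  v <- extract_values(map, points$x, points$y)
  ok <- !is.na(v)
  pos <- points$label[ok] == positive_label
  pred <- v[ok] == 1
  out <- confusion_counts(tp = sum(pos & pred), fp = sum(!pos & pred),
                          tn = sum(!pos & !pred), fn = sum(pos & !pred))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Cohen's Kappa agreement between two binary maps
#'
#' Cross-tabulates the two maps over jointly valid cells and computes
#' Cohen's Kappa. Symmetric in its arguments.
#'
#' @param map_a,map_b Aligned `binary_map`s.
#' @return Kappa in [-1, 1]; NA with a warning when either map has a single
#'   class (agreement is then undefined).
#' @export
map_agreement_kappa <- function(map_a, map_b) {
  if (!grids_aligned(map_a$grid, map_b$grid)) stop("maps are not aligned")
  ok <- !is.na(map_a$values) & !is.na(map_b$values)
  a <- map_a$values[ok]; b <- map_b$values[ok]
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    warning("kappa undefined: a map has a single class")
    return(NA_real_)
  }
  m <- compute_metrics(confusion_counts(tp = sum(a == 1 & b == 1),
                                        fp = sum(a == 1 & b == 0),
                                        tn = sum(a == 0 & b == 0),
                                        fn = sum(a == 0 & b == 1)))
  m$kappa
}

#' Wilcoxon rank-sum comparison of two models' per-point agreement
#'
#' Compares two vectors of per-point scores (here: 0/1 agreement indicators
#' of two delimitation maps on the same validation points) with the
#' rank-sum test: exact for small untied samples, tie-corrected normal
#' approximation otherwise (as in [stats::wilcox.test()]).
#'
#' @param scores_a,scores_b Numeric vectors.
#' @return A list with `W` (rank-sum statistic of the first sample) and
#'   `p_value`. All-tied inputs return p = 1 with a warning.
#' @export
compare_models_wilcoxon <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) >= 1, length(scores_b) >= 1)
  if (length(unique(c(scores_a, scores_b))) == 1L) {
    warning("all values tied across both samples; p = 1")
    return(list(W = length(scores_a) * length(scores_b) / 2, p_value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(scores_a, scores_b))
  list(W = unname(wt$statistic), p_value = wt$p.value)
}

#' Write a metrics report (counts plus statistics) to CSV
#' @param metrics_list Named list of `validation_metrics`.
#' @param path Output path.
#' @return The assembled data.frame, invisibly.
#' @export
write_metrics_csv <- function(metrics_list, path) {
  rows <- lapply(names(metrics_list), function(nm) {
    m <- metrics_list[[nm]]
    data.frame(model = nm, tp = m$counts$tp, fp = m$counts$fp,
               tn = m$counts$tn, fn = m$counts$fn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               kappa = m$kappa, underprediction = m$underprediction,
               overprediction = m$overprediction)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
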