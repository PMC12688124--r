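# Brute-force oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (per-point loops, O(n^2) scans, pair
# enumeration) and independent of the package's implementation paths.

# small landscape used by many tests; memoised per test run
tiny_landscape <- local({
  cache <- NULL
  function(seed = 7, grid_size = 50) {
    if (!is.null(cache) && cache$seed == seed && cache$size == grid_size)
      return(cache$value)
    lc <- landscape_config(grid = grid_spec(grid_size, grid_size,
                                            cell_size = 1, crs_id = "ea_km"),
                           seed = seed)
    stack <- generate_env_stack(lc)
    tb <- true_biome_map(stack, lc$rule)
    val <- list(config = lc, stack = stack, map = tb$map,
                outline = tb$outline, margin = rule_margin(stack, lc$rule))
    cache <<- list(seed = seed, size = grid_size, value = val)
    val
  }
})

# per-point confusion tally by explicit loop
oracle_confusion <- function(points, positive_label, map) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(points))) {
    v <- extract_values(map, points$x[i], points$y[i])
    if (is.na(v)) next
    pos <- points$label[i] == positive_label
    if (pos && v == 1) tp <- tp + 1L
    else if (pos && v == 0) fn <- fn + 1L
    else if (!pos && v == 1) fp <- fp + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# AUC by enumerating all presence/background pairs (ties count one half)
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# O(n^2) thinning verification: minimum pairwise distance and maximality
oracle_thinning_ok <- function(retained, all_records, min_dist,
                               geographic = FALSE) {
  if (nrow(retained) > 1) {
    d <- distance_matrix_km(retained$x, retained$y, geographic)
    if (min(d[upper.tri(d)]) < min_dist) return(FALSE)
  }
  key <- function(df) paste(df$x, df$y, df$locality, df$date)
  dropped <- all_records[!(key(all_records) %in% key(retained)), ,
                         drop = FALSE]
  for (i in seq_len(nrow(dropped))) {
    d <- if (geographic)
      geosphere::distHaversine(c(dropped$x[i], dropped$y[i]),
                               cbind(retained$x, retained$y)) / 1000
    else sqrt((dropped$x[i] - retained$x)^2 + (dropped$y[i] - retained$y)^2)
    if (all(d >= min_dist)) return(FALSE)  # could have been kept
  }
  TRUE
}

# random binary map on a given grid
random_binary_map <- function(grid, p = 0.5) {
  binary_map(grid, matrix(rbinom(grid$n_rows * grid$n_cols, 1, p),
                          grid$n_rows, grid$n_cols))
}

# confusion counts of two 0/1 vectors by explicit cross-tab
oracle_crosstab <- function(pred, ref) {
  c(tp = sum(pred == 1 & ref == 1), fp = sum(pred == 1 & ref == 0),
    tn = sum(pred == 0 & ref == 0), fn = sum(pred == 0 & ref == 1))
}
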