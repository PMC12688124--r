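# Species affinity to the biome: proportion of records inside the reference
# polygon, and nested tier membership. Tiers follow the majority-style
# grouping: characteristic (>= 50% of records in-biome), high-affinity
# (>= 75%) and strict endemic (100%). All thresholds are inclusive and the
# tiers are nested by construction: strict implies high-affinity implies
# characteristic.

#' Classify one species' biome affinity
#'
#' Counts records inside the reference polygon (closed boundary rule:
#' records exactly on the boundary count as inside) and assigns the nested
#' affinity tiers.
#'
#' @param occ Data.frame of one species' georeferenced records (columns
#'   species, x, y at least).
#' @param reference A `polygon_set` (the reference biome polygon), or a
#'   `binary_map` (records on 1-cells count as inside).
#' @param thresholds Named numeric vector of inclusive tier thresholds;
#'   default `c(characteristic = 0.50, high_affinity = 0.75, strict = 1.00)`.
#' @return A one-row data.frame: species, n_records, n_inside, proportion,
#'   and one logical column per tier.
#' @export
classify_affinity <- function(occ, reference,
                              thresholds = c(characteristic = 0.50,
                                             high_affinity = 0.75,
                                             strict = 1.00)) {
  if (!nrow(occ)) stop("empty occurrence set")
  if (any(!is.finite(occ$x) | !is.finite(occ$y)))
    stop("all records must be georeferenced before affinity classification")
  stopifnot(!is.unsorted(thresholds))
  inside <- if (inherits(reference, "binary_map")) {
    v <- extract_values(reference, occ$x, occ$y)
    !is.na(v) & v == 1
  } else {
    points_in_polygons(reference, occ$x, occ$y)
  }
  n <- nrow(occ)
  n_in <- sum(inside)
  p <- n_in / n
  out <- data.frame(species = occ$species[1], n_records = n,
                    n_inside = n_in, proportion = p,
                    stringsAsFactors = FALSE)
  for (tier in names(thresholds)) out[[tier]] <- p >= thresholds[[tier]]
  out
}

#' Classify a pool of species
#'
#' @param occ_sets Named list of per-species record data.frames.
#' @param reference See [classify_affinity()].
#' @param thresholds See [classify_affinity()].
#' @return Data.frame with one row per species.
#' @export
classify_affinity_pool <- function(occ_sets, reference,
                                   thresholds = c(characteristic = 0.50,
                                                  high_affinity = 0.75,
                                                  strict = 1.00)) {
  rows <- lapply(occ_sets, classify_affinity, reference = reference,
                 thresholds = thresholds)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tier rosters (species lists per affinity tier)
#'
#' Rosters are nested: every strict endemic is also high-affinity, and every
#' high-affinity species is also characteristic.
#'
#' @param assignments Data.frame from [classify_affinity_pool()].
#' @return Named list of character vectors, one per tier column present.
#' @export
tier_rosters <- function(assignments) {
  tiers <- setdiff(names(assignments),
                   c("species", "n_records", "n_inside", "proportion"))
  out <- lapply(tiers, function(t) assignments$species[assignments[[t]]])
  names(out) <- tiers
  out
}

#' Write an affinity assignment table to CSV
#' @param assignments Data.frame from [classify_affinity_pool()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affinity_csv <- function(assignments, path) {
  utils::write.csv(assignments, path, row.names = FALSE)
  invisible(path)
}
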