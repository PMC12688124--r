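# Record cleaning, spatial thinning and the modelability partition.
#
# Cleaning criteria (in the order applied):
#   malformed        missing/empty species field
#   flagged          fossil / introduced / unidentified records
#   no_coordinates   coordinate-less records (georeferencing is out of
#                    scope; such records are rejected, not recovered)
#   duplicate        exact duplicate on (species, locality, collector, date),
#                    case-insensitive, whitespace-normalized
#   outside_region   record outside the region polygon

.norm_key <- function(x) tolower(gsub("\\s+", " ", trimws(as.character(x))))

#' Clean occurrence records
#'
#' Applies the standard record-cleaning criteria: drops flagged
#' (fossil/introduced/unidentified) and coordinate-less records, removes
#' exact duplicates on (species, locality, collector, date), keeps only
#' records inside the region polygon, and rewrites the habitat field to
#' canonical terms via the synonym map. Every rejection is logged with its
#' criterion.
#'
#' @param records Data.frame with columns species, x, y, locality, collector,
#'   date, habitat and optionally flags (semicolon-separated subset of
#'   fossil/introduced/unidentified).
#' @param region A `polygon_set` delimiting the study region, or NULL to
#'   skip the within-region filter.
#' @param habitat_synonyms Named character vector mapping variant habitat
#'   terms (names, matched case-insensitively) to canonical biome names.
#' @param species_synonyms Optional named character vector applied verbatim
#'   to the species field before deduplication.
#' @return A list with `records` (cleaned data.frame), `per_species` (split
#'   by species) and `rejections` (rejected rows plus a `reason` column).
#' @export
clean_records <- function(records, region = NULL,
                          habitat_synonyms = default_habitat_synonyms(),
                          species_synonyms = NULL) {
  cols <- c("species", "x", "y", "locality", "collector", "date", "habitat")
  for (cl in setdiff(cols, names(records))) records[[cl]] <- NA
  if (is.null(records$flags)) records$flags <- ""
  records$x <- suppressWarnings(as.numeric(records$x))
  records$y <- suppressWarnings(as.numeric(records$y))
  rej <- records[0, , drop = FALSE]
  rej$reason <- character(0)
  reject <- function(rows, reason) {
    if (!any(rows)) return(invisible())
    r <- records[rows, , drop = FALSE]
    r$reason <- reason
    rej <<- rbind(rej, r)
  }
  if (!is.null(species_synonyms)) {
    hit <- records$species %in% names(species_synonyms)
    records$species[hit] <- unname(species_synonyms[records$species[hit]])
  }
  bad <- is.na(records$species) | .norm_key(records$species) == ""
  reject(bad, "malformed"); records <- records[!bad, , drop = FALSE]
  flagged <- grepl("fossil|introduced|unidentified", records$flags,
                   ignore.case = TRUE)
  reject(flagged, "flagged"); records <- records[!flagged, , drop = FALSE]
  nocoord <- !is.finite(records$x) | !is.finite(records$y)
  reject(nocoord, "no_coordinates")
  records <- records[!nocoord, , drop = FALSE]
  key <- paste(.norm_key(records$species), .norm_key(records$locality),
               .norm_key(records$collector), .norm_key(records$date),
               sep = "\r")
  dup <- duplicated(key)
  reject(dup, "duplicate"); records <- records[!dup, , drop = FALSE]
  if (!is.null(region) && nrow(records)) {
    inside <- points_in_polygons(region, records$x, records$y)
    reject(!inside, "outside_region")
    records <- records[inside, , drop = FALSE]
  }
  if (nrow(records)) {
    hk <- .norm_key(records$habitat)
    syn <- stats::setNames(unname(habitat_synonyms),
                           .norm_key(names(habitat_synonyms)))
    hit <- hk %in% names(syn)
    records$habitat[hit] <- unname(syn[hk[hit]])
  }
  rownames(records) <- NULL
  rownames(rej) <- NULL
  list(records = records,
       per_species = split(records, records$species),
       rejections = rej)
}

#' Default habitat-term synonym map
#'
#' Maps common variant names for seasonally dry tropical forest ('dry
#' forest', 'BTC', 'selva baja caducifolia', ...) to the canonical term
#' `"SDTF"`.
#'
#' @return Named character vector (variant -> canonical).
#' @export
default_habitat_synonyms <- function() {
  c("dry forest" = "SDTF",
    "BTC" = "SDTF",
    "bosque tropical caducifolio" = "SDTF",
    "selva baja caducifolia" = "SDTF",
    "tropical dry forest" = "SDTF",
    "seasonally dry tropical forest" = "SDTF",
    "SDTF" = "SDTF")
}

#' Pairwise distance between occurrence points
#'
#' Great-circle (haversine) distance for geographic coordinates, Euclidean
#' for projected ones. Map units of projected grids are kilometres
#' throughout the package.
#'
#' @param x,y Coordinate vectors.
#' @param geographic TRUE for lon/lat degrees.
#' @return A dense n x n matrix of distances in km.
#' @export
distance_matrix_km <- function(x, y, geographic = FALSE) {
  n <- length(x)
  if (geographic) {
    m <- geosphere::distm(cbind(x, y), fun = geosphere::distHaversine) / 1000
  } else {
    m <- as.matrix(stats::dist(cbind(x, y)))
  }
  dimnames(m) <- NULL
  m
}

#' Spatially thin occurrence records to a minimum separation
#'
#' Greedy thinning: records are shuffled with a fixed seed, then accepted
#' one by one if at least `min_dist_km` from every already-accepted record.
#' The retained set therefore has all pairwise distances >= `min_dist_km`
#' and is maximal (every rejected record is within `min_dist_km` of a
#' retained one). The 5-km default reflects the scale at which
#' environmental conditions vary between localities.
#'
#' @param occ Data.frame of one species' records with coordinates.
#' @param min_dist_km Minimum pairwise distance in km (default 5).
#' @param geographic TRUE if coordinates are lon/lat degrees.
#' @param seed Integer seed for the shuffle.
#' @return The retained subset of `occ` (original row order preserved).
#' @export
thin_occurrences <- function(occ, min_dist_km = 5, geographic = FALSE,
                             seed = 1L) {
  n <- nrow(occ)
  if (n <= 1) return(occ)
  set.seed(seed)
  ord <- sample.int(n)
  d <- distance_matrix_km(occ$x, occ$y, geographic)
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) || all(d[i, keep] >= min_dist_km)) keep <- c(keep, i)
  }
  occ[sort(keep), , drop = FALSE]
}

#' Partition species by modelability (minimum record count)
#'
#' Species with at least `min_records` cleaned-and-thinned records can enter
#' distribution modeling; the rest are set aside.
#'
#' @param occ_sets Named list of per-species record data.frames.
#' @param min_records Minimum records for modeling (default 5).
#' @return A list with `modelable` and `too_few`, both named lists.
#' @export
modelable_species <- function(occ_sets, min_records = 5) {
  counts <- vapply(occ_sets, nrow, integer(1))
  list(modelable = occ_sets[counts >= min_records],
       too_few = occ_sets[counts < min_records])
}

#' Read occurrence records from CSV
#' @param path CSV with header species,x,y,locality,collector,date,habitat,flags.
#' @return Data.frame of records.
#' @export
read_occurrences_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  df
}

#' Write occurrence records to CSV
#' @param records Data.frame of records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
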