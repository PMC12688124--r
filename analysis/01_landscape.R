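#!/usr/bin/env Rscript
# Step 1 — build the study system: a 100 x 100 km synthetic landscape with
# six autocorrelated environmental layers, a rule-defined true biome
# (layer1 >= q70 AND layer2 <= q60, the "dry forest" of this world), a pool
# of 30 species whose records hit prescribed in-biome affinities exactly,
# and 5 x 200 labelled validation points across five mutually exclusive
# biomes. All artifacts land in results/run/ as plain text (ASCII grids,
# GeoJSON, CSV).

library(biomestack)

cfg <- default_run_config(outdir = "results/run", seed = 1)
stage_synth(cfg)

tb <- read_raster("results/run/true_biome.asc")
occ <- read_occurrences_csv("results/run/occurrences_raw.csv")
pts <- read_points_csv("results/run/validation_points.csv")
area <- equal_area_km2(binary_map(tb$grid, tb$values))

cat(sprintf(
  "landscape: %d x %d km grid, true biome %.0f km2 (%.1f%% of the region)\n",
  tb$grid$n_rows, tb$grid$n_cols, area$area_km2, 100 * area$fraction))
cat(sprintf("species pool: %d species, %d raw records (duplicates included)\n",
            length(unique(occ$species)), nrow(occ)))
cat(sprintf("validation points: %d across %d biomes\n",
            nrow(pts), length(unique(pts$label))))
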