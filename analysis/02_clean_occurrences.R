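#!/usr/bin/env Rscript
# Step 2 — record cleaning and spatial thinning. Drops flagged and
# coordinate-less records, collapses duplicates on locality+collector+date,
# restricts to the region, standardizes habitat terms, then thins each
# species to a 5-km minimum separation. Writes the cleaned and thinned
# record sets plus a rejection log with one reason per dropped record.

library(biomestack)

cfg <- default_run_config(outdir = "results/run", seed = 1)
stage_prep(cfg)

rej <- read.csv("results/run/rejection_log.csv")
cleaned <- read_occurrences_csv("results/run/occurrences_cleaned.csv")
thinned <- read_occurrences_csv("results/run/occurrences_thinned.csv")

cat("rejections by criterion:\n")
print(table(rej$reason))
cat(sprintf("cleaned records: %d; after 5-km thinning: %d\n",
            nrow(cleaned), nrow(thinned)))
counts <- table(thinned$species)
cat(sprintf("records per species after thinning: median %.0f (range %d-%d)\n",
            median(counts), min(counts), max(counts)))
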