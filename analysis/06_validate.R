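#!/usr/bin/env Rscript
# Step 6 — independent validation. The multi-biome labelled points (never
# used in modeling) score each tier's delimited map: sensitivity,
# specificity, Cohen's Kappa, underprediction FN/(FN+TN) and overprediction
# FP/(FP+TP); tier maps are also compared pairwise by map-vs-map Kappa, and
# the two closest tiers by a Wilcoxon rank-sum test on per-point agreement.

library(biomestack)

cfg <- default_run_config(outdir = "results/run", seed = 1)
v <- stage_validate(cfg)

tab <- read.csv("results/run/validation_metrics.csv")
print(tab, row.names = FALSE, digits = 3)
cat("\nmap-vs-map Kappa between tier delimitations:\n")
print(round(v$agreement, 3))
if (!is.null(v$wilcoxon))
  cat(sprintf("\nWilcoxon rank-sum, high-affinity vs characteristic per-point agreement: W = %.0f, p = %.3g\n",
              v$wilcoxon$W, v$wilcoxon$p_value))
best <- tab$model[which.max(tab$kappa)]
cat(sprintf("best tier by point-validation Kappa: %s\n", best))
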