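---
title: "Delimiting a biome from stacked species distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting a biome from stacked species distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Biome boundaries drawn from vegetation maps or expert knowledge disagree,
sometimes substantially. An alternative is to let the biome's own flora
draw the line: species tightly associated with a biome are distributed
where its environmental conditions hold, so the stack of their individual
distribution models is an estimate of the biome's extent. `biomestack`
implements this delimitation chain end to end:

1. **Occurrence preparation** — records are cleaned (flagged and
   coordinate-less records dropped, exact duplicates on
   locality + collector + date collapsed, out-of-region records removed,
   habitat vocabulary standardized) and spatially thinned to a minimum
   separation of 5 km, the scale at which environmental conditions vary
   appreciably between localities.
2. **Affinity grouping** — each species' proportion of records inside a
   reference biome polygon assigns it to nested tiers: *characteristic*
   (≥ 50 % of records in-biome), *high-affinity* (≥ 75 %) and *strict
   endemic* (100 %). Thresholds are inclusive, and the tiers nest by
   construction: strict ⊆ high-affinity ⊆ characteristic.
3. **Suitability modeling** — per species, a presence–background
   suitability model on environmental layers pre-filtered to pairwise
   |Spearman ρ| < 0.7, evaluated by AUC (bootstrap replicates for 5–19
   records, k-fold cross-validation for ≥ 20), gated at AUC ≥ 0.7, and
   binarized at the *lowest presence threshold* (LPT): every cell whose
   suitability is at least the minimum suitability observed at a training
   presence is called suitable, so no training record is omitted.
4. **Stacking and threshold selection** — the tier's binary maps are
   summed into a richness surface; for each richness threshold
   *t* = 1, 2, … the map (richness ≥ *t*) is scored against the reference
   with Cohen's Kappa, sensitivity and specificity, and the
   Kappa-maximizing *t* defines the delimited biome.
5. **Independent validation** — labelled points spread over the region's
   major biomes score the delimited map through a confusion matrix:
   sensitivity TP/(TP+FN), specificity TN/(TN+FP), Cohen's Kappa, plus the
   two error rates practitioners care about, *underprediction*
   FN/(FN+TN) (share of predicted-absence units that are actually the
   biome) and *overprediction* FP/(FP+TP) (share of predicted-presence
   units that are not). Cohen's Kappa uses the two-class marginal-product
   chance agreement: with observed agreement p_o = (TP+TN)/n and
   p_e = [(TP+FP)(TP+FN) + (FN+TN)(FP+TN)]/n²,
   κ = (p_o − p_e)/(1 − p_e).

Every quantity is computed alongside its confusion counts so each derived
number is auditable.

## The synthetic landscape

Real inputs for this analysis (aggregator occurrence downloads, national
vegetation maps, published biome polygons) cannot ship with a package, so
`biomestack` includes a first-class generator whose outputs have known
truth:

* **Environmental layers** are Gaussian white noise smoothed with a
  Gaussian kernel (`autocorrelation_scale`, default 8 cells) and
  standardized; an optional near-duplicate of layer 1 exercises the
  correlation filter.
* **The true biome** is a conjunction of quantile thresholds on layers
  (default: layer 1 ≥ its 70th percentile AND layer 2 ≤ its 60th
  percentile, keeping roughly a fifth of the landscape). Its vectorized
  outline (run-rectangles on cell boundaries) rasterizes back to the map
  exactly, giving a loss-free reference polygon.
* **Species records** realize a target in-biome affinity *exactly*:
  round(affinity × n) records fall inside the biome, by stratified
  sampling, so tier classification is deterministic. Records in both
  strata are weighted by the rule's continuous margin — inside records
  concentrate toward the biome core and outside records near the biome
  boundary, not uniformly over the landscape. This mirrors how stray
  records of biome-affiliated taxa sit near habitat margins, and it is
  the generator's learnability guarantee: a suitability model fitted to
  the records can recover the biome. Duplicate rows (same locality,
  collector, date) are appended at a configurable rate to exercise
  deduplication.
* **Validation points** come from five mutually exclusive synthetic
  biomes (the true biome plus quantile bins of layer 1 outside it), each
  point in a distinct cell of its biome.

Grids declare an equal-area CRS with 1-km cells, so area fractions are
exact cell ratios. What the generator does *not* emulate: realistic
climate fields, sampling bias along roads or rivers, taxonomic
uncertainty, georeferencing error beyond within-cell jitter. Passing
tests therefore demonstrate the machinery is correct under known truth,
not that any particular real map is right.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| thinning distance | 5 km | environmental turnover scale between localities |
| Spearman cutoff | 0.7 | standard multicollinearity bound for niche models |
| minimum records | 5 | below this no meaningful model can be fitted |
| split rule | bootstrap &lt; 20 records, else 5-fold | small samples cannot spare a fold |
| AUC gate | 0.7 | conventional "good model" line for presence-only AUC |
| tier thresholds | 0.50 / 0.75 / 1.00 (inclusive) | majority-style grouping; 50 % ties a species to a single dominant biome |
| background size | 10,000 (2,000 in the bundled runs) | capped at the accessible area's cell count |
| binarization | LPT | conservative: zero training omission by construction |

## The suitability backends

The delimitation method is agnostic to the SDM algorithm, and this package
deliberately does not re-implement a maximum-entropy model. Two
lightweight backends share one contract (suitability in [0, 1], LPT, AUC):

* `weighted_logistic` (default) — presence-vs-background logistic
  regression with linear + quadratic features, classes balanced by
  weights; a standard approximation to maximum-entropy fitting.
* `envelope` — product of per-variable triangular kernels whose shoulders
  are the 10th–90th presence percentiles. Robust to stray records, but it
  weights all variables equally and is the coarser of the two; it exists
  as a dependency-free baseline.

On strict (affinity 1.0) synthetic species the default backend evaluates
above 0.9 AUC; the envelope typically sits near 0.75–0.85. Both obey the
LPT zero-omission guarantee for every species, which is asserted
per-backend in the tests.

## Numerical and design choices

* **Rasterization and point-in-polygon** use the cell-center rule and a
  closed-set boundary: a point exactly on a polygon edge counts as
  inside, consistently across rasterization, affinity counting and
  validation overlay. Cell (r, c) has its center at
  (origin_x + (c − 0.5)·cell, origin_y − (r − 0.5)·cell), row-major from
  the top-left.
* **Affinity uses cleaned, pre-thinning records** (a flagged alternative
  exists): affinity measures biological fidelity, thinning is a modeling
  convenience, and thinning systematically dilutes the affinity of
  compact-biome species because inside records are closer together than
  outside ones.
* **Thinning is greedy** — seeded shuffle, then accept records ≥ 5 km
  from everything accepted. The retained set is verified in tests against
  the O(n²) oracle for both the distance and the maximality property.
  Great-circle (haversine) distances serve geographic coordinates,
  Euclidean distances projected ones (map unit = km).
* **The LPT is taken from the prediction surface itself** (minimum of the
  surface values at presence cells), so the zero-omission guarantee is
  exact in floating point rather than up to BLAS rounding.
* **Threshold ties go to the smallest t** (the most inclusive map); an
  optional tie-break maximizes sensitivity + specificity − 1 among
  Kappa-tied thresholds.
* **Statistics with empty denominators are flagged undefined**, never
  imputed; a single-class reference map is an error for the sweep and a
  flagged NA for map-vs-map Kappa.
* **Areas** on projected equal-area grids are exact cell sums; on
  geographic grids the analytic spherical cell area
  R²·Δλ·(sin φ_top − sin φ_bot) is used — the cylindrical equal-area
  treatment evaluated exactly. The area backend is an explicit property of
  the grid, since published area figures rarely state their projection.
* **Display rounding is half-up to 2 decimals**; all computations and
  comparisons use unrounded values.
* **The rank-sum comparison** between two delimitations is run on
  per-point agreement indicators (1 = the point is classified correctly)
  over the same validation points; published uses of this test rarely
  state their exact input vectors, so this interpretation is documented
  rather than assumed unique.

## Problem sizes

The bundled analysis scripts and the acceptance script run a 100 × 100 km
landscape (120 km where 5 × 2,000 validation points need room), 6 layers,
30 species of 30–120 records, 2,000 background points, 10 bootstrap
replicates or 5 folds — sizes chosen so a complete run takes seconds on a
laptop while leaving every statistical moving part exercised. Tests use
20 × 20 to 50 × 50 grids with the same structure.

## Known limitations

* Suitability backends are intentionally simple; with few presences and
  many layers the logistic can overfit, which the AUC gate is there to
  catch.
* Stacked binary maps overpredict at low richness thresholds — visible in
  the sweep tables — and the Kappa-optimal threshold only partially
  compensates; this is a property of the method, not of the
  implementation.
* Published figures that depend on the real occurrence, vegetation-map
  and polygon inputs (national species counts, absolute areas in km²,
  per-threshold Kappa maxima, map-vs-map Kappas between published
  proposals) are outside what a synthetic landscape can reproduce; the
  package reproduces the *published confusion-matrix statistics* exactly
  from their printed counts and demonstrates the method's behaviour on
  known truth.
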