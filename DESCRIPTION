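Package: biomestack
Title: Biome Delimitation from Stacked Species Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delimits the geographic boundary of a biome from the
    distributions of its affiliated plant species. Occurrence records are
    cleaned, deduplicated and spatially thinned; species are grouped into
    nested affinity tiers (characteristic >= 50%, high-affinity >= 75%,
    strict endemic = 100% of records inside a reference polygon); a
    per-species suitability model is fitted, gated on AUC and binarized at
    the lowest presence threshold; binary maps are stacked into a richness
    surface and a richness threshold is selected by maximizing Cohen's
    Kappa against a reference map. Validation against independently
    labelled points yields sensitivity, specificity, Kappa, underprediction
    and overprediction. Includes a synthetic-landscape generator with a
    rule-defined true biome so the whole pipeline can be exercised
    end-to-end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    caret,
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
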