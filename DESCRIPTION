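Package: anccap
Title: Ancestral Mitogenome Capture Simulation and Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating hybridisation-capture
    experiments that use a reconstructed ancestral mitochondrial genome as
    bait source. Provides bait tiling at a fixed step, a mapping-quality
    filter and PCR-duplicate removal keyed on joint fragment-end
    coordinates, depth/majority consensus calling with screening for
    nuclear-mitochondrial (numt) artefacts, sliding-window quantification
    of bait-to-target divergence versus capture efficiency, logistic
    capture-model fitting, pre-capture pooling plans, and a minimum
    spanning haplotype network. A synthetic-data generator emulates
    degraded-specimen capture and shotgun libraries with terminal
    deamination damage and PCR duplicates, so the whole analysis can be
    exercised end to end with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
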