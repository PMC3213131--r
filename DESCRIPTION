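Package: cnvburden
Title: CNV Calling and Case-Control Burden Analysis for Hotspot-Targeted Array CGH
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments array-CGH log2-ratio tracks into copy-number-variant
    (CNV) calls using chromosome-wise z-scoring and a three-state Gaussian
    hidden Markov model with explicit segment-merging, bridging and
    quality-control rules; annotates calls against genomic hotspots, genes,
    genomic-disorder regions, a frequency-annotated control CNV map (50%
    reciprocal-overlap rarity filtering) and trio pedigrees (de novo
    classification); and computes cohort-level burden statistics
    (largest-CNV survivor functions, Fisher exact odds ratios, rare-carrier,
    de novo and two-hit comparisons, two-proportion power). Includes a
    synthetic-data generator producing hotspot-enriched probe designs,
    cohorts with planted CNVs, trio structure and control CNV maps, so the
    whole pipeline is testable without raw microarray data.
License: MIT
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
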