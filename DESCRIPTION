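Package: chromtrace
Title: Cell Type-Resolved 3D Genome Analysis of Multiplexed DNA-FISH Chromatin Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for multiplexed DNA-FISH (DNA-MERFISH)
    chromatin tracing data. Covers constant-weight error-correcting barcode
    (codebook) design and decoding, genome-wide locus panel selection with
    encoding-probe sequence filters and super-enhancer calling from ATAC
    peaks, per-cell nuclear geometry (convex-hull volume, normalized radial
    positions, chromosome-territory statistics), spatial-versus-genomic
    distance scaling, A/B compartment calling from imaged loci with
    segregation, insulation and megadomain statistics, locus-level chromatin
    environment scores (trans-chromosomal local A/B density ratio), and
    wild-type versus knockout perturbation comparisons. A synthetic-data
    generator plants compartments, megadomains, scaling regimes, radial
    biases and detection dropout so that every estimator can be tested
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
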