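Package: dmgquant
Title: Quantification Pipelines for Cholinergic Neuron-Glioma Interaction Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantification pipelines
    used in studies of neuronal-activity-driven diffuse midline glioma (DMG)
    growth: single-cell cholinergic-receptor and cell-state signature scoring
    with bin-matched control genes, the stemness-lineage two-dimensional
    cell-state representation, pseudo-bulk correlation screening with FDR
    control, fiber-photometry trace processing (exponential debleaching,
    baseline z-scoring, LOESS smoothing, windowed trapezoidal AUC),
    difference-of-Gaussians synaptic-puncta detection with micrometer-space
    proximity colocalization, and simple assay metrics (EdU proliferation
    indices, spheroid migration ratios). A synthetic-data module generates
    every input with known ground truth so all stages are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
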