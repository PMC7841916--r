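Package: lrrscan
Title: Plant Leucine-Rich-Repeat Motif Prediction and Ectodomain Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects leucine-rich-repeat (LRR) motifs in the ectodomains of
    plant LRR receptor-like kinases with a trainable 16-position
    position-specific scoring matrix (Laplace-smoothed log-odds), resolves
    overlapping candidate windows by maximum-score non-overlapping selection,
    and layers ectodomain annotation on top of the predictions: canonical
    N-glycosylation sequons (Asn-x-Ser/Thr, x != Pro), superhelix side and
    terminal-region mapping, per-100-residue densities, positional
    histograms, solvent-accessibility window means, residue logos, and
    grouped subgroup/species summaries. Includes a two-round (bootstrap)
    training protocol, a crystal-structure-style accuracy evaluator, a
    ground-truthed synthetic ectodomain generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
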