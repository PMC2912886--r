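Package: dualtf
Title: Dual-Function Transcription Factor Inference from Thermodynamic
    Models of CRM-Driven Expression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether site-specific transcription
    factors (TFs) act as activators, repressors, or both ("dual
    function") in a developmental gene network.  A Reinitz-style
    thermodynamic model predicts the expression profile driven by a
    cis-regulatory module (CRM) from its predicted binding sites, TF
    concentration gradients along the anterior-posterior axis, and an
    activator/repressor role configuration; parameters are fitted by
    simulated annealing against observed profiles.  Role inference
    combines three methods (smallest-optimal configuration cover,
    best-n configuration search, and per-TF sensitivity analysis) into
    a majority-vote ensemble, supports retraining with split
    activator/repressor effectiveness for dual TFs, classifies motif
    enrichment p-values, and scans protein sequences for SUMOylation
    consensus motifs.  A synthetic-data generator emulates the
    gap-gene dataset structure so the full pipeline runs end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
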