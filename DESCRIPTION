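Package: ki67ith
Title: Intratumoral Heterogeneity of Ki67 and Tumor Regression in
    Neoadjuvantly Treated Gastric Cancer
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies intratumoral heterogeneity of the Ki67
    proliferation index and of tumor regression in perioperatively
    treated gastric carcinoma from digital-pathology slide annotations.
    Computes per-block hotspot/coldspot proliferation indices (KiH, KiL,
    KiD) and the tumor bed ratio (TBR), rolls blocks up to cases (max
    KiH, min KiL, case KiD, median TBR), grades regression on the Becker
    scale, and runs the associated statistics: point-probability exact
    tests for 2x2 and r x c contingency tables, tie-corrected Kendall
    tau-b, Benjamini-Hochberg FDR control, Kaplan-Meier estimation and
    Mantel-Cox log-rank cut-off scans. A seeded simulator of subclonal
    chemotherapy selection (spatial tumor beds, Voronoi subclone
    territories, competitive release) generates annotation files and
    cohort tables with known ground truth so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
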