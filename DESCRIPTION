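Package: inips
Title: Size-Selection Enriched Non-Invasive Prenatal Screening on Simulated cfDNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulation and analysis pipeline for non-invasive prenatal
    screening (NIPS) of fetal aneuploidy from maternal-plasma cell-free DNA,
    with in-silico fragment-size selection. Simulates maternal/fetal cfDNA
    mixtures with distinct fragment-length distributions over a binned
    (scaled hg19) genome, applies inclusive insert-size windows (e.g. the
    125-135 bp window that maximises fetal enrichment), performs 20-kb
    binning with GC-LOESS correction, calls trisomy 13/18/21 by
    reference-cohort z-scores with a no-call band, estimates the fetal
    fraction from the chrY read share, and quantifies placental mosaicism.
    Cohort-level experiment drivers reproduce enrichment fold-changes and
    low-fetal-fraction sensitivity on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
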