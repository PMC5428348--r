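Package: cftralpha
Title: Pancreatic Alpha-Cell Electrophysiology with a CFTR Chloride Current
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based modelling and analysis of pancreatic alpha-cell
    electrophysiology in the presence of the cystic fibrosis transmembrane
    conductance regulator (CFTR), a cAMP-activated chloride channel. The
    package couples a Hodgkin-Huxley-type alpha-cell model extended with a
    passive CFTR current to the quantitative procedures used on patch-clamp
    and secretion data: whole-cell ramp I-V analysis (slope conductance,
    conductance density, reversal potential, CFTR-dependent fraction),
    single-channel idealization and open probability, capacitance-train
    exocytosis summaries, secretion fold-change tables, and membrane-to-
    cytosol immunofluorescence ratios. Seeded synthetic-data generators
    produce every input the analysis pipelines consume, with ground truth
    returned alongside the data for round-trip validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    signal,
    jsonlite,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
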