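Package: oculasym
Title: Inter-Eye Asymmetry Analysis of Optic Nerve Head and RNFL
    Measurements for Glaucoma Screening
Version: 0.1.0
Authors@R:
    person("Open", "Contributor", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the asymmetry between the two eyes of a
    patient from fundus-photograph optic disc and cup contour annotations
    and from peripapillary OCT retinal nerve fiber layer sector thickness
    tables. Provides direct least-squares ellipse fitting of contour
    annotations, sector-wise neuroretinal rim width profiles, cup-to-disc
    and rim-to-disc ratios, a family of six inter-eye asymmetry metrics,
    ISNT-rule compliance evaluation, cost-sensitive decision trees and
    support vector machines with a stratified cross-validation protocol
    and hyperparameter sweeps, and a paired-eye synthetic cohort generator
    for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
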