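Package: glycotarget
Title: Glycoproteomics Target Prioritization for Cell-Surface Glycoprotein
    Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolchain for prioritizing targetable cell-surface glycoproteins
    from shotgun proteomics identifications. Implements a Target Score that
    rewards plasma-membrane location, tumor abundance and poor-prognosis
    association while penalizing healthy-tissue expression (with extra weight
    on reproductive, immune and nervous systems); monoisotopic m/z computation
    and composition assignment for permethylated benzyl O-glycosides (the
    cellular O-glycome reporter readout); posterior-error-probability based
    top-N selection and cross-method intersection of identification lists;
    an oxonium-ion-gated glycopeptide search with b/y-ion glycosite
    localization for the sialyl-Tn (STn) modification; and the contingency
    and survival statistics used to associate markers with clinical outcome.
    Seeded generators produce every input format the pipeline consumes, so
    the full workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
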