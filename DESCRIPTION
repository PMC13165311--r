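Package: cqdnegspace
Title: Negative Chemical Space Analysis of Carbon-Dot Ion-Sensing Selectivity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of carbon quantum dot (CQD) fluorescence
    ion-sensing selectivity data. Treats the routinely reported
    "non-interfering" ions of selectivity panels as explicit negative test
    outcomes and computes per-ion failure ratios over all explicit challenges,
    annotates ions with hard-soft acid-base (HSAB) class, standard reduction
    potentials and electronic-pathway flags, and correlates reduction
    potential with detection failure. Also implements a rule-based
    discrimination of fluorescence quenching mechanisms (dynamic, static,
    inner filter effect, mixed) from Stern-Volmer fits, lifetime ratios,
    spectral overlap, dilution and temperature evidence, and ships synthetic
    generators for selectivity corpora and titration data with known ground
    truth. A curated 60-study literature corpus is included as a packaged
    fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
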