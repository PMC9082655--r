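Package: jigplan
Title: Jig-Based Minimally Invasive Cochlear-Implant Access Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planning geometry for jig-guided minimally invasive cochlear
    implantation. Detects fiducial marker balls in CT-like volumes and
    registers image coordinates to a bone-anchored frame; plans and evaluates
    straight access paths through the facial recess with centerline-to-surface
    clearances to the facial nerve, chorda tympani and external auditory canal
    wall; checks drill-diameter feasibility, insertion angles and screw-site
    bone thickness; converts paths to jig through-hole poses and projects
    manufacturing deviations to the target depth. Includes a synthetic
    temporal-bone phantom generator with exact geometric ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
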