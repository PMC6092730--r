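Package: endoguide
Title: Simulation and Accuracy Analysis of Fiducial-Based Augmented-Reality
    Needle Guidance
Version: 0.1.0
Authors@R:
    person("endoguide", "developers", email = "endoguide@example.org",
           role = c("aut", "cre"))
Description: An in-silico testbed for augmented-reality needle guidance in
    interventional oncology. Generates synthetic CT-like volumes of phantom,
    porcine and cadaver scenes carrying radiopaque skin fiducials and
    internal targets; segments fiducials and targets and extracts marker
    frames by principal component analysis; simulates pinhole-camera pose
    tracking of planar marker clusters; performs closed-form rigid
    registration between the CT and tracker frames; models gated versus
    free-breathing respiratory motion; and drives a simulated needle
    insertion from the displayed tip-to-target distance, reporting target
    registration errors against the 5 mm clinical accuracy threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
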