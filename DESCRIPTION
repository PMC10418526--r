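Package: fieldcable
Title: Patient-Specific Field-Cable Models of Epiretinal Prosthesis Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage ("field-cable") computational models of epiretinal
    prosthesis stimulation. Builds parametric slab tissue models per electrode
    from clinical geometry measurements (electrode-retina distance, retinal
    thickness, fibrotic tissue thickness), solves the quasi-static
    volume-conduction problem on a nonuniform voxel grid with a conservative
    finite-volume scheme, drives multicompartment retinal ganglion cell cable
    models placed along retinal nerve fiber trajectories, and predicts
    per-electrode neural activation thresholds by bisection as well as
    phosphene sizes from the convex hull of activated cell bodies. Includes a
    synthetic-patient generator and the regression analyses used to compare
    predictions with perceptual thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
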