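Package: tailquant
Title: Quantitative Image Analysis of Zebrafish Larval Tail Regeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reproducible quantification of zebrafish larval tail
    regeneration from calibrated 2-D micrographs: blinded analysis via
    random renaming with a key table, chromogenic in situ staining area by
    per-channel RGB intensity windowing, background-corrected wound
    reactive-oxygen-species fluorescence (mean over a 50 micrometre wound
    band minus the trunk median 1 mm distal), signed Menger curvature of
    notochord cell membranes from three-point circumcircles, trunk
    contraction and tail-length morphometry, notochord-bead area, and
    mitotic-figure counting with size and distance filters. Includes a
    seeded synthetic-image generator that renders ground-truthed fixtures
    (wound embryos, stain blobs, membrane arcs, landmark pairs, spot
    fields) with machine-readable manifests for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
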