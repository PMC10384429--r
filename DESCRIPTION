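Package: lycosense
Title: Tomato Lycopene Estimation from Epicarp Color Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A software implementation of a colorimetric soft sensor for
    lycopene content in tomato fruit. Single-fruit RGB images are segmented
    from their background by hue thresholding in HSV space with
    connected-component area filtering, reduced to epicarp color features
    (red/green/blue pixel areas, CIE-L*a*b* aggregates and the a*/b*
    chromaticity ratio), and mapped to a lycopene concentration in ppm by a
    Takagi-Sugeno fuzzy inference system with triangular membership
    functions and least-squares (ANFIS-style) consequent fitting.
    Levenberg-Marquardt-trained feed-forward network and linear-regression
    baselines, an evaluation harness, and a seeded synthetic-image
    generator for end-to-end testing are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, grDevices, utils, jsonlite, jpeg, png, MASS,
    Rcpp, rlang, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
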