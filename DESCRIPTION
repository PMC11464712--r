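Package: pennation
Title: Pennation-Angle Mapping of Skeletal Muscle from Diffusion Tensor MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes two-dimensional pennation-angle maps of skeletal muscle
    from diffusion-weighted MRI. Provides log-linear diffusion tensor fitting,
    projection of the principal eigenvector onto the imaging plane against a
    manually drawn tendon line, region-of-interest aggregation, deterministic
    tensor streamline tractography, absolute-agreement intraclass correlation
    coefficients for test-retest and reader-agreement studies, and a digital
    bipennate-muscle phantom with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
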