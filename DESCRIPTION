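Package: glcmrobust
Title: Robustness of GLCM Texture Features to Estimation Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how gray-level quantization, region-of-interest
    (ROI) size, pixel offset, noise filtering, and tissue density drive the
    magnitudes of Haralick gray-level co-occurrence matrix (GLCM) texture
    features in grayscale images, with digital breast tomosynthesis slabs as
    the motivating modality. Provides a synthetic two-tissue phantom generator
    with correlated spatial structure and scaled-Poisson plus Gaussian
    acquisition noise, an adaptive Wiener denoiser, min-max gray-level
    quantization, lattice ROI segmentation, symmetric probability-normalized
    GLCMs, ten Haralick features, a multi-resolution min-max normalization
    that suppresses quantization-induced magnitude disparities, robustness
    summary tables (consecutive-offset deltas, cross-quantization ranges,
    density contrasts), and factorial ANOVA/MANOVA of parameter effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    car,
    dplyr,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
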