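Package: retinamil
Title: Attention-Based Multiple-Instance Learning for Referable Diabetic
    Retinopathy Detection in Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects referable diabetic retinopathy (rDR) from colour fundus
    photographs with a weakly supervised, interpretable pipeline: circular
    retina-disk localisation and normalisation, a bag-of-patches image
    encoding, an attention-based multiple-instance classifier whose per-patch
    attention weights double as a lesion-localisation signal, attention
    heatmap construction, and a quantitative heatmap-evaluation protocol
    (patch- and pixel-level lesion prediction, attention-versus-lesion-area
    regression). Ships a seeded synthetic fundus generator with planted
    microaneurysms, haemorrhages and exudates so the whole pipeline is
    exercisable without external data. The compact convolutional encoder and
    its training loop are implemented in RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
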