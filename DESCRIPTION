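Package: octgrade
Title: Simulation, Reconstruction and Attention-ResNet Grading of Lung
    SD-OCT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for AI-assisted grading of lung adenocarcinoma from
    spectral-domain optical coherence tomography (SD-OCT). Provides a
    synthetic tissue-phantom and interferogram simulator with
    class-specific textures (invasive adenocarcinoma, minimally invasive
    adenocarcinoma, normal parenchyma), spectral reconstruction
    (k-linearization, apodization, FFT, log compression) with closed-form
    system parameters, despeckling by registered adjacent-frame
    averaging, an attention-gated residual convolutional network with its
    own training engine, grad-CAM saliency maps and t-SNE embeddings for
    model inspection, evaluation metrics (confusion matrix, one-vs-rest
    sensitivity/specificity, ROC/AUC), and an inspection-record session
    layer linking embedding points to images, metadata and predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    MASS,
    pROC,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
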