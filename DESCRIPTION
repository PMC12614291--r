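Package: cbctdiff
Title: Channel- and Noised-Conditioned Denoising Diffusion for CBCT-to-CT Translation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for training and sampling conditional denoising diffusion
    probabilistic models (DDPMs) that translate cone-beam CT (CBCT) slices into
    synthetic CT (sCT) images for adaptive radiotherapy workflows. Implements
    linear, cosine and sigmoid forward noise schedules; uniform, exponential and
    triangular timestep samplers; channel conditioning (the guiding CBCT is
    concatenated as a second network input channel) and noised-conditioned
    sampling, in which reverse diffusion starts from the guiding CBCT noised to
    a tunable timestep rather than from pure noise. Ships a CPU-trainable
    conditional U-Net denoiser, a seeded generator of paired planning-CT/CBCT
    phantom slices with CBCT-specific degradations (cupping bias, streaks,
    noise, reduced field of view, rigid shift and contour change), Hounsfield
    unit preprocessing, masked image-quality metrics (MAE, PSNR, NCC), and
    reproducible experiment harnesses for t_con sweeps and training-set-size
    sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
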