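Package: mitgan
Title: Two-Stage Adversarial Image Reconstruction for Magnetic Induction
    Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates an eight-coil magnetic induction tomography (MIT)
    measurement system with a linearized eddy-current sensitivity model,
    generates paired voltage/conductivity training corpora by polar
    placement sweeps with rotational augmentation, and reconstructs
    conductivity images with a two-stage adversarially trained
    fully-connected network (L2-pretrained generator followed by
    generator/discriminator fine-tuning with a validation-MSE stopping
    rule).  Ships Tikhonov-regularized and supervised-only network
    baselines, RMSE/SSIM/PSNR/correlation image-quality metrics, and a
    reproducible experiment harness over controlled measurement noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
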