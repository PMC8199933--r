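# mitgan

Adversarial image reconstruction for magnetic induction tomography (MIT),
as a self-contained R package: simulate an eight-coil MIT measurement
ring, generate paired voltage/conductivity training corpora, train a
two-stage fully-connected adversarial reconstructor, and benchmark it
against Tikhonov regularization and a supervised-only network with the
standard image-quality metrics under controlled noise.

## The problem

MIT recovers the internal conductivity distribution of an object from the
phase changes that its eddy currents induce between pairs of coils.  An
eight-coil ring yields only 56 measurements per frame
(8 excitations x 7 receivers), from which a 3409-pixel image (a 67 x 67
lattice masked to the circular field) must be recovered — an ill-posed
inverse problem made worse by the soft-field effect, which concentrates
sensitivity near the coils.

The forward model is the standard linearization of difference imaging,

    V = S (sigma - sigma0),

with the sensitivity of coil pair (i, j) at pixel r proportional to
`omega * A_i(r) . A_j(r) * h^2` (dipole coil fields `A_k`).  The
reconstructor is a fully-connected generator
`G: V in [0,1]^56 -> sigma_hat in [0,1]^3409`, trained in two stages:

1. **Pretraining** — minimize `|| sigma - G(V) ||^2` plus an L2 weight
   penalty with Adam (this stage alone is the BPNN baseline);
2. **Adversarial fine-tuning** — a discriminator `D` judges generator
   outputs against the real conductivity images under the minimax value
   `min_G max_D  E log D(sigma) + E log(1 - D(G(V)))`, while the
   generator keeps its paired fidelity term; training stops by a
   validation-MSE rule and the best-validation generator is returned.

Reconstructions are scored by RMSE, global SSIM, PSNR
(`PSNR = -20 log10 RMSE` on unit-range images) and Pearson correlation,
averaged over freshly generated test phantoms at SNR ∞/80/40/20 dB.

## Worked example

The scaled-down (`desk`) profile runs the full pipeline — corpus
generation on a 33 x 33 grid, BPNN pretraining, adversarial fine-tuning,
Tikhonov baseline, noise-sweep evaluation on 200 fresh phantoms — in
about two minutes on one CPU:

```r
library(mitgan)
study <- run_study(mit_profile("desk", seed = 1), quiet = FALSE)
study$evaluation
#>       model snr_db      rmse      ssim     psnr        cc   n
#> 1  Tikhonov    Inf 0.1753199 0.6556553 15.24879 0.6928243 200
#> 2      BPNN    Inf 0.1730200 0.6573191 15.60860 0.7100516 200
#> 3       GAN    Inf 0.1607071 0.7157607 16.47509 0.7494748 200
#> ...
#> 10 Tikhonov     20 0.2562212 0.4918892 12.31165 0.5039284 200
#> 11     BPNN     20 0.1734597 0.6558505 15.58744 0.7083595 200
#> 12      GAN     20 0.1613873 0.7137706 16.43339 0.7473762 200
```

At every noise level the two-stage reconstructor attains the lowest RMSE
and the highest correlation, the supervised-only network sits between it
and the one-step Tikhonov inverse, and all models degrade as the SNR
drops — the qualitative ordering the method is designed to produce.
Single reconstructions work frame by frame:

```r
grid  <- mit_grid(67, 0.1)
sens  <- build_sensitivity(grid, mit_coils())
truth <- place_anomalies(grid, list(anomaly(0.04, 30)))
frame <- add_noise(forward_project(sens, truth), snr_db = 40, seed = 7)
img   <- reconstruct(study$models$GAN, frame)   # conductivity in S/m
```

The `paper` profile (`mit_profile("paper")`) keeps the full-scale
settings — 67 x 67 grid, 0.1 cm/9° sweep (2840 single-anomaly
placements), the {56 128 256 512 1024 2048 4096 3409} generator, 1000
pretraining epochs — and takes hours on one CPU.

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/cli/mitgan.R generate --profile desk --seed 1 --out out/
Rscript inst/cli/mitgan.R train    --profile desk --seed 1 --out out/
Rscript inst/cli/mitgan.R evaluate --profile desk --seed 1 --out out/
Rscript inst/cli/mitgan.R render   --profile desk --seed 1 --out out/
```

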