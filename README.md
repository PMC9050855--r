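# flowunwrap

Velocity anti-aliasing for 4D-flow MRI in R.

## The problem

Phase-contrast MRI encodes velocity in signal phase, so every scan fixes a
velocity-encoding sensitivity (venc): only velocities in `[-venc, +venc)`
are representable. A true velocity `V_T` beyond that range *aliases* —
the scanner reports

```
V_A = ((V_T + venc) mod 2·venc) − venc
```

i.e. `V_T` shifted by a multiple of `2·venc` (for a single wrap,
`V_A = V_T − 2·venc`). In aortic 4D-flow (three-directional velocity over
a 3-D volume across the cardiac cycle), aliased voxels corrupt peak
velocity, net flow, and peak flow, so they must be detected and shifted
back before quantification.

`flowunwrap` provides the complete workflow for people developing or
validating anti-aliasing methods:

* **Phantoms** — seeded pulsatile Poiseuille tube / tilted U-bend
  ("candy-cane") velocity fields with a vessel mask, venc-proportional
  Gaussian noise (`σ_v = √2·venc/(π·SNR)`), and known true velocities.
* **Wrap simulation** — retrospective venc reduction with an exact binary
  ground-truth mask; mask-driven correction that restores the field
  **bit-exactly** where the wrap direction is identifiable
  (`|V_T| ≤ 2·venc_sim`).
* **Two detectors** — the conventional automatic spatio-temporal
  phase-jump algorithm (nearest-neighbor difference arrays on each
  `[X, Y, time]` slice, jumps > venc, sign-consistent correction), and a
  trainable dense-block U-Net voxel classifier (3-D encoder-decoder with
  dense blocks, composite softmax cross-entropy + Dice loss, Adam,
  batch size 1) implemented from the ground up in RcppArmadillo.
* **Evaluation** — Dice with the `1e-5` empty-mask stabilization,
  Hausdorff distance in mm (early-exit scan verified against a
  brute-force oracle), vessel-restricted aliased-voxel counts, plane-based
  net/peak flow and peak velocity, Bland–Altman bias and limits of
  agreement.

## Worked example

```r
library(flowunwrap)

# an aortic-like U-bend phantom: venc 150 cm/s, peak velocity 150 cm/s,
# SNR 15, 10 cardiac frames
ph <- generate_phantom(phantom_spec(grid_shape = c(64, 48, 16),
                                    n_frames = 10, frame_interval = 80,
                                    seed = 1))

# simulate a scan at 50% of the original venc
w <- wrap_velocity(ph$field, wrap_spec(venc_fraction = 0.5, venc = 150))
count_aliased(w$truth, ph$vessel)
#> [1] 736

# conventional spatio-temporal baseline
conv <- conventional_unwrap(w$aliased)
dice_score(conv$detected, w$truth, ph$vessel)
#> [1] 0.9716655

# dense U-Net: train the tiny preset on three phantoms, predict held out
train <- lapply(2:4, function(s)
  generate_phantom(phantom_spec(grid_shape = c(64, 48, 16), n_frames = 10,
                                frame_interval = 80, seed = s)))
cfg <- cnn_tiny_config(epochs = 20, seed = 11)
model <- train_unet(build_unet(cfg), train, cfg)
pred <- predict_unet(model, w$aliased)
dice_score(pred, w$truth, ph$vessel)
#> [1] 0.9202614

# correct and quantify flow at the ascending-limb plane
corr <- unwrap_with_mask(w$aliased, pred)
plane <- phantom_planes(ph)$aao
plane_flow(corr, plane, ph$vessel)
#> <flow_report> net 24.6 ml | peak 125.8 ml/s | peak velocity 1.47 m/s
plane_flow(ph$truth, plane, ph$vessel)
#> <flow_report> net 27.4 ml | peak 150.9 ml/s | peak velocity 1.47 m/s
plane_flow(w$aliased, plane, ph$vessel)
#> <flow_report> net 9.4 ml | peak 34.0 ml/s | peak velocity 0.75 m/s
```

The Dice scores read as overlap between detected and truly aliased
voxels inside the vessel (1 is perfect). The uncorrected aliased field
underestimates net flow by two thirds (9.4 vs 27.4 ml) and halves the
apparent peak velocity; after CNN-based correction the plane flow is
within about 10% of the truth, with the residual coming from missed
voxels at the systolic core — the reason aliasing must be corrected
before any hemodynamic analysis, and why detection quality is scored
per voxel.

A command-line interface over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "flowunwrap.R", package = "flowunwrap"))')
Rscript $CLI simulate --out phantom --seed 1
Rscript $CLI wrap --in phantom --venc-fraction 0.5 --out aliased --truth truth.nii.gz
Rscript $CLI unwrap-conventional --in aliased --out corrected --mask-out detected.nii.gz
Rscript $CLI evaluate --detected detected.nii.gz --truth truth.nii.gz \
        --vessel phantom_vessel.nii.gz --spacing 2.4,2.4,2.6
```

Subcommands `train`, `predict`, `flow`, `agree`, and `run` (full YAML
pipeline) follow the same pattern; see `?cli_main`.

## Further reading

The methods vignette (`vignettes/velocity-antialiasing.Rmd`) documents
the wrap algebra and its exactness guarantees, the phantom's assumptions
and what it does not model, both detectors' design decisions, metric
conventions, and known limitations.
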