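---
title: "Velocity anti-aliasing for 4D-flow MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Velocity anti-aliasing for 4D-flow MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phase-contrast MRI encodes velocity in the phase of the complex signal.
Because phase is only defined modulo $2\pi$, every acquisition fixes a
velocity-encoding sensitivity — the venc — and represents velocities on the
half-open interval $[-v_{enc}, +v_{enc})$. A true velocity $V_T$ outside
that interval *aliases*: the measured value is

$$V_A = \big((V_T + v_{enc}) \bmod 2 v_{enc}\big) - v_{enc},$$

i.e. $V_T$ shifted by an integer multiple of $2 v_{enc}$. In the
single-wrap regime ($v_{enc} < V_T < 3 v_{enc}$) this reduces to
$V_A = V_T - 2 v_{enc}$, and the mirrored rule for negative velocities. In
aortic 4D-flow (three-directional velocity over a 3-D volume across the
cardiac cycle) aliasing corrupts peak-velocity, net-flow, and peak-flow
measurements, so aliased voxels must be found and shifted back before any
hemodynamic quantity is read off.

`flowunwrap` implements the full workflow: simulate aliasing with exact
ground truth, detect it with either a conventional spatio-temporal
phase-jump algorithm or a trainable dense-block U-Net, correct the detected
voxels, and quantify both detection quality (Dice, Hausdorff, in-vessel
counts) and downstream flow agreement (Bland–Altman).

## Wrap simulation and its exactness guarantees

`wrap_velocity()` applies the symmetric modular wrap above to the whole
field, across all frames and directions, and returns the exact binary
ground-truth mask (voxels whose wrapped value differs from the true value).
Two conventions matter and are fixed once:

* **Half-open boundary.** $V_T = +v_{enc}$ wraps to $-v_{enc}$, matching
  the $2\pi$ periodicity of phase. Consequently, on noise-free data the
  truth mask equals $\{|V_T| \ge v_{enc}\}$.
* **Floating-point exactness.** The wrap is implemented as a single shift
  by $2v_{enc}$ whenever $|V_T| < 3v_{enc}$. By the Sterbenz lemma
  ($x - y$ is exact when $y/2 \le x \le 2y$), that shift is exact in IEEE
  arithmetic, and so is the inverse shift. Mask-driven correction therefore
  restores the original field *bit-exactly* wherever the correction
  direction is identifiable — a property the test suite asserts with
  `identical()`, not a tolerance. Identifiability sets the domain: a binary
  mask carries no wrap direction, so the sign rule below is the inverse
  only for $|V_T| \le 2 v_{enc}$. For $V_T \in (2v_{enc}, 3v_{enc})$ the
  aliased value lands back on the true sign and *no* mask-driven
  single-shift corrector can recover it; exact-restoration tests therefore
  run with the peak velocity at or below $2 v_{enc,sim}$.

`unwrap_with_mask()` corrects each masked voxel by
$-\operatorname{sign}(V_A)\,2v_{enc}$ (a negative aliased value is shifted
up, and vice versa). A masked voxel with $V_A = 0$ carries no sign
information; it is corrected upward and counted in an attribute so callers
can audit the choice. Multi-wrap correction ($|V_T| > 3v_{enc}$) is out of
scope by design: a binary mask carries no wrap count.

## The phantom generator

No clinical data ship with the package; all inputs come from
`generate_phantom()`, which emulates the features of an aortic 4D-flow scan
that matter for anti-aliasing and nothing more:

* **Geometry.** A straight tube (for analytic checks) or a U-bend
  "candy-cane" — ascending limb, 180° arch, descending limb — in a plane
  tilted about the z axis (default 20°) so that all three velocity
  components carry flow and alias independently.
* **Velocity profile.** Parabolic (Poiseuille) through-vessel profile,
  decomposed along the local centerline tangent; static (zero-velocity)
  tissue outside. The analytic flow through a cross-section,
  $Q = \pi R^2 v_{max}/2$, anchors the flow-quantification tests.
* **Pulsatility.** A raised-cosine systolic pulse over the first ~35% of
  the cycle on a 5% diastolic plateau, sampled at frame centers and
  normalized to peak exactly 1. Diastolic factors stay below 0.15, so
  late frames are nearly free of aliasing, as in real aortic scans.
* **Noise.** Zero-mean Gaussian velocity noise with
  $\sigma_v = \sqrt{2}\,v_{enc}/(\pi\,\mathrm{SNR})$, the standard
  phase-contrast relation in which velocity noise is proportional to the
  selected venc. The default SNR of 15 is a typical magnitude SNR for
  thoracic 4D-flow.
* **Defaults.** 64×48×24 voxels at 2.4×2.4×2.6 mm, 20 frames at 40 ms,
  venc 150 cm/s with peak velocity 150 cm/s — so the unreduced scan is
  alias-free and any reduced venc in the training range (40–70%) wraps.
  Heavier slice-thickness anisotropy is left to configuration.

The generator is seeded and bit-reproducible. What passing tests on these
phantoms do **not** show: robustness to partial-volume voxels at the vessel
wall (wraps by less than $2\pi$), eddy-current phase offsets, background
tissue motion, or multi-wrap aliasing — all absent from the phantom by
construction.

## The conventional baseline

`conventional_unwrap()` re-implements the automatic spatio-temporal
phase-jump method: per slice and velocity direction it scans the
`[X, Y, time]` sub-array with nearest-neighbor difference arrays along
time, x, and y, flags pairs whose difference exceeds the venc, and corrects
the flagged voxel by $-\operatorname{sign}(V)\,2v_{enc}$. Three design
choices the method's description leaves open are fixed as follows:

* **Pass order and references.** Temporal pass first (the first cardiac
  frame is trusted — diastolic frames rarely alias), then spatial passes
  trusting the field border, iterated up to `max_iterations` (10).
* **Disambiguation.** A flagged pair cannot tell by itself which of its two
  voxels wrapped. A voxel is corrected only when the jump sign agrees with
  the sign-based correction (jump down *and* negative value → shift up;
  jump up *and* positive value → shift down); inconsistent voxels are left
  unchanged.
* **Convergence and arithmetic.** The true in-plane gradient at the vessel
  wall can itself exceed the venc at clinical resolution, so within one
  sweep a wall voxel may be shifted by one pass and shifted back by the
  next. What must be stationary is the *sweep map*: convergence is
  declared when a full temporal+spatial sweep either changes nothing or
  reproduces the previous sweep's state. Corrections are stored as integer
  shift counts applied to the original values, so a do/undo cycle leaves a
  voxel bit-identical and a single net shift stays exact in floating
  point.
* **Consequence.** The method is exact where $|V_T| < 2 v_{enc}$ and
  smooth enough that jumps identify wraps — the idempotence and exactness
  tests run there. Beyond $2 v_{enc}$, a wrapped value lands back on the
  sign of its true value, presents no sign-consistent jump, and is missed;
  each miss leaves a stale temporal reference that degrades later frames.
  Two real failure modes follow and are visible on phantoms: undercounting
  at severe venc reductions (the published direction at 40% venc), and
  *camouflaged* wraps — when systolic acceleration between frames is
  comparable to $2v_{enc}$ minus the threshold, the apparent temporal jump
  of a genuinely wrapped voxel falls below the venc and no threshold rule
  can see it; spatial jumps then carry the rescue. The degradation test
  asserts the direction of the published finding (detected count at or
  below truth, Dice below the mask oracle and well below the mild-aliasing
  Dice), not any clinical value.

## The dense-block U-Net

`build_unet()` constructs a 3-D encoder–decoder in which each resolution
level is a *dense block*: a sequence of small 3×3×3 convolutions whose
outputs are concatenated onto their inputs, followed by a 1×1×1
compression back to the base width. Levels are linked by 2×2 in-plane max
pooling and nearest-neighbor upsampling with skip concatenation; a 1×1×1
transition compresses each `[upsampled, skip]` concatenation back to the
base width before the decoder block (the DenseNet compression idea applied
to the skip joins, which keeps decoder cost equal to encoder cost). The
head is a voxelwise two-channel softmax; its untrained bias favors
background, so a fresh model predicts an empty mask — the right prior for
a task where aliased voxels are a small minority.

The network and its training loop are implemented directly in
RcppArmadillo (im2col as tap-shifted block copies + single-precision GEMM,
hand-written backprop, Adam). All randomness — He initialization, dropout,
wrap draws — flows from one seed, so training is bit-reproducible on a
given platform.

**Training scheme.** Every (frame, direction) volume is a separate sample,
center-cropped in-plane and normalized to $[-1, 1)$ by division by its
venc (one model thus serves all vencs; predictions are invariant to
scaling field and venc together). Per epoch, each training field is
re-wrapped four times at venc fractions drawn uniformly from
$[0.40, 0.70]$, so the network sees a fresh aliasing pattern every pass.
The loss is softmax cross-entropy plus a soft-Dice term
$1 - (2\sum p t + \varepsilon)/(\sum p + \sum t + \varepsilon)$ with
$\varepsilon = 10^{-5}$ — the same constant as the evaluation Dice, so
empty-truth volumes are well defined. Optimization is Adam at batch size 1.

**Scales.** The published recipe (crop [128, 96, Z], learning rate
$10^{-4}$, dropout 0.1, 400 epochs) is the `cnn_config()` default
territory and is configuration-selectable. The package's test and example
path is `cnn_tiny_config()`: 2 levels, 1 dense layer per block, growth 4,
base width 4, crop [48, 32], learning rate $10^{-3}$, 30 epochs. Two
considerations fixed the tiny preset. First, capacity: on phantoms the
detection task is dominated by local velocity structure, and this
~2,000-parameter network reaches held-out Dice well above 0.9 at venc
fraction 0.5, while a further-halved variant (width 2) does not learn the
boundary cases. Second, the crop: [48, 32] on a 64×48 phantom plays the
same role the [128, 96] crop plays on a clinical matrix — it discards
noisy background while containing the whole vessel, and it reduces
training cost by half. The desk-scale experiment in the test suite — four
64×48×16×10 phantoms, 30 epochs, fixed seed, evaluated on a fifth held-out
phantom — is the package's parameter-recovery reference: held-out Dice at
least 0.85 at fraction 0.5, and the monotone trend of easier detection at
lower fractions (0.4 vs 0.7).

**Prediction.** Per (frame, direction) volume with the training crop and
normalization, channel argmax, re-embedded into the full geometry with
cropped-away regions reported non-aliased.

## Metrics

* **Dice** uses the $\varepsilon = 10^{-5}$ stabilization in numerator and
  denominator, so two empty masks score 1 — the convention needed for
  per-frame curves where diastole has no aliasing. When a vessel mask is
  supplied, only in-vessel voxels are compared.
* **Hausdorff distance** is the symmetric max-of-directed-min Euclidean
  distance between voxel-center point sets in physical mm (0-based voxel
  indices scaled by spacing). It is computed per (frame, direction) volume;
  the dataset value is the maximum over volumes, with the per-volume table
  retained (the aggregation is a package choice; published tables report mm
  without stating one). An empty mask makes the distance an explicit
  error/NA, never a silent 0. The default path uses an early-exit scan and
  is verified against a brute-force dense-matrix oracle.
* **Counts** are vessel-restricted sums over all frames and directions.

## Flow quantification and agreement

`plane_flow()` integrates $Q = \sum_{ROI} (\mathbf v \cdot \mathbf n)\,
\Delta A$ per frame (ml/s), sums the series times the frame interval for
net flow (ml; the rectangle rule is exact for a periodic series), takes
the series maximum for peak flow, and reports peak velocity as the maximum
vector magnitude over ROI and frames in m/s (regions of interest read
velocity, not flux). Axis-aligned planes are evaluated on the voxel slice;
oblique planes (the arch) are resampled on a regular in-plane grid at the
finest voxel spacing with nearest-neighbor lookup — manual clinical plane
placement cannot be reproduced, so `phantom_planes()` standardizes
ascending-limb, arch, and descending-limb planes from the phantom
geometry. `bland_altman()` reports bias, limits of agreement
$1.96\,\mathrm{SD}$ of the differences (sample SD, $n-1$), and the LOA as
a percentage of the reference mean (flagged undefined when that mean is 0).

`dual_venc_truth()` derives ground truth for paired acquisitions of the
same flow: a voxel is aliased in the low-venc scan where the per-direction
difference to the high-venc scan exceeds the low venc. On simulated
noise-free pairs this is provably identical to the wrap simulator's mask
(any wrap changes the value by at least $2v_{enc}$), and the test suite
asserts that equivalence exactly. Per-direction differences (not speed
magnitudes) are compared, matching the four-point encoding in which each
direction aliases independently.

## Numerical and degenerate-input choices

* Velocities are cm/s everywhere internally; m/s only at reporting
  boundaries. Lengths mm, times ms.
* Wrap counts in `wrap_velocity()` are clamped so boundary rounding in the
  modular division can never leave a value outside $[-v_{enc}, v_{enc})$.
* `conventional_unwrap()` caps repeated shifts per comparison (multi-wrap
  jumps converge across iterations instead) and reports non-convergence.
* `center_crop()` puts the extra voxel of an odd margin on the low side,
  records offsets and padding, and `embed_crop()` inverts the geometry
  exactly; padded regions are forced to background in predictions.
* Empty training sets, single-frame fields (temporal differences
  undefined), missing venc metadata (normalization and unwrapping
  undefined), degenerate ROIs, and zero-norm plane normals are hard
  errors, not warnings.

## Problem sizes

Desk-scale defaults keep every experiment on one CPU core: phantoms of
64×48×16 voxels with 10 frames for training/evaluation experiments
(~1.5 M velocity samples each), 32×24×12 for property tests, the tiny
U-Net preset for all learning tests, and 20–30 training epochs. The
acceptance script trains on three phantoms for 20 epochs; the test suite's
parameter-recovery experiment uses four phantoms for 30 epochs. The
full-scale configuration (crop [128, 96, Z], 400 epochs, deeper blocks) is
expressible but is a multi-hour GPU-class computation and is not exercised
by the tests.

## Known limitations

* Single-wrap correction only; multi-wrap voxels are a documented failure
  mode of both detectors and of the binary-mask representation itself.
* The phantom has sharp vessel walls: no partial-volume "partial wraps",
  which real scans show at the lumen boundary.
* Poiseuille profiles only; no Womersley dynamics, turbulence, or k-space
  effects.
* The conventional baseline follows the published description plus the
  documented disambiguation rules; the original implementation may differ
  in unstated preprocessing (e.g. median filtering), which is deliberately
  not added.
* Oblique-plane flow uses nearest-neighbor sampling; trilinear
  interpolation is a configuration option left out of the default path.
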