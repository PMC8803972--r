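---
title: "Forecasting tumor microenvironment maps under combination therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting tumor microenvironment maps under combination therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dent)
```

## The problem

Antiangiogenic agents transiently *normalize* the chaotic tumor
vasculature; chemotherapy delivered inside that window reaches the tumor
far better.  Finding good schedules and dosages is hard because the
coupled dynamics — tumor growth, angiogenesis, interstitial fluid pressure
(IFP), and drug transport — are nonlinear and patient-specific.  `dent`
implements a two-part program:

1. a **mechanistic simulator**: five coupled dimensionless PDE fields on a
   151 x 151 pixel grid — tumor cell density `n`, vasculature `m`, IFP
   `P`, antiangiogenic agent `A`, chemotherapy drug `d` — integrated at
   30-minute resolution through eight days of scheduled combination
   therapy, producing synthetic "patients";
2. a **convolutional surrogate** trained on those cases: two conditional
   drug-insertion CNNs (the *Diffuser*) and five per-channel one-day
   forecasters (the *Elapser*), composed into a single step that is rolled
   out autoregressively for a week, with scheduled dose scalars injected
   along the way.

The surrogate is scored against held-out simulated patients with
framewise SSIM and PSNR plus the error of a thresholded tumor-cell-density
summary `C`.

## The mechanistic model

Tumor density follows reaction-diffusion growth with logistic saturation
at the carrying capacity `n_lim`, vessel-assisted proliferation
(`alpha_mn n m`) and chemotherapy kill (`d_r n d`):

$$\partial_t n = D_n \nabla^2 n + r_n n (1 - n/n_{lim})
  + \alpha_{mn} n m - d_r\, n d.$$

Vasculature combines diffusion, a bistable island-forming reaction
`m(alpha + beta m + gamma m^2)`, outward drift along the tumor gradient
`beta_nm div(m grad n)`, tumor-induced angiogenesis
`alpha_nm n (1 - n/n_lim) m`, and pruning by the antiangiogenic agent
(`A_r m A`).  The reaction is parameterised as `alpha = -a`,
`beta = 1 + a`, `gamma = -1`, giving stable states at `m = 0` (avascular)
and `m = 1` (vascularised) with an unstable knee at `m = a`.

IFP solves an elliptic balance between Starling filtration from vessels
and lymphatic drainage,

$$-K \nabla^2 P = \lambda_b m\,[P_v - P - \sigma_v(\pi_c - \pi_i)]
  - \lambda_l P,$$

and the two drug fields are quasi-steady (transport is fast relative to
growth): diffusion + transvascular exchange + lymphatic drainage + decay
for `A`; the same plus interstitial convection `div(k_E d K grad P)`,
Starling-filtration influx `Gamma_b (1 - sigma_d) d_v` and the tumor
reaction sink `d_r d n` for the large-particle chemotherapy drug.  Plasma
levels after a bolus decay as `c0 * exp(-t / t_half)` (the decay constant
is an e-folding time, implemented exactly as the model states it).  All
fields carry no-flux boundaries.

### Parameter values

The source model's coefficient values are not printed in the text this
package was built from; they live in an earlier simulation study that was
not available.  `default_params()` therefore ships a named dimensionless
set chosen **once** so the simulator reproduces the qualitative features
the model family is validated on, and never adjusted afterwards:

* IFP rises near the microvascular plateau across the tumor interior and
  drops sharply at the rim (core mean ~0.74 of `P_v` vs ~0.58 in the far
  tissue under the defaults);
* vessel density decreases toward the tumor center relative to the rim
  (core ~0.9, rim ~1.6, background ~0.5);
* large-particle chemotherapy accumulates in the tumor periphery
  (post-bolus rim mean exceeds the core mean by ~70%);
* chemotherapy shrinks the thresholded density summary relative to an
  untreated case of the same patient.

Three tuning lessons are recorded here because they shape the defaults.
First, the bistable knee is `a = 0.5` rather than a smaller value: with
the initial vasculature drawn i.i.d. from `U(0.2, 0.8)`, a knee below
~0.45 sends nearly every background pixel to the vascularised state and
erases the core-vs-background IFP contrast.  Second, vessel-assisted
proliferation must stay small (`alpha_mn = 0.01`): it pushes `n` above
`n_lim` wherever vessels are dense, which flips the angiogenesis term
negative and — through the bistable dynamics — collapses the tumor core
to the avascular state.  Third, the outward vessel drift `beta_nm` is kept
moderate (2): at larger values the invasion front pushes island pixels
below the knee and the tumor wake de-vascularises permanently.

Lengths are in pixels (`h = 1`), times in days, densities relative to
`n_lim = 1`.  Every coefficient can be overridden through
`default_params(...)` and the config's `params` block.

### Numerics

* 5-point flux-form Laplacian and divergence stencils; boundary faces
  carry zero flux, so the discrete operators annihilate constants exactly
  (asserted in the tests).  No-flux is stated for the drugs and adopted
  for `n`, `m`, `P` as a closed-domain assumption.
* Explicit forward Euler for `n` and `m` with automatic sub-stepping when
  the recording step violates `dt <= 0.9 h^2 / (4 max(D_n, D_m))`; the
  user-facing step functions refuse unstable steps with a sub-stepping
  hint instead.
* The elliptic systems are solved sparsely (`Matrix`); the two symmetric
  positive-definite systems (P, A) reuse a cached symbolic Cholesky
  factorisation across the thousands of per-case solves.  The
  convection-diffusion system for `d` is nonsymmetric (central flux-form
  convection) and takes a sparse LU each solve.
* `Gamma_b` is not defined in the source text.  The default is the
  Starling filtration form `lambda_b m (P_v - P - sigma_v(pi_c - pi_i))`
  clamped at zero — consistent with "convection of drugs through the
  vessels" and with peripheral accumulation — with a plain `Gamma_b0 * m`
  alternative (`params$gamma_b_form = "constant"`).
* Negative values created by discretisation are clipped to zero after
  every explicit step and linear solve; a warning fires when clipped mass
  exceeds `1e-6` of the field total, so instabilities cannot hide.
* Bolus plasma levels are additive when a new injection arrives before
  the previous one has decayed.

### Case design

A *patient* is a vasculature realisation (one seed); a *case* is eight
therapy days recorded daily from a given initiation day with a given
`(A, d)` dose pair.  The antiangiogenic bolus lands at the end of therapy
steps 0, 2, 4, 6 and the chemotherapy bolus at steps 2, 4, 6; "end of
step t" means right after step t's daily frame is recorded.  Drug maps
recorded one hour (two 30-minute steps) after each insertion become the
Diffuser targets.  The default design — 5 training patients x 5
initiation days (14, 16, 18, 20, 21; the exact five are not printed in
the source, so five values spanning the stated range were fixed) x a
3 x 3 dose grid {0.4, 0.6, 0.8}^2 — yields 45 cases per patient, 225
training cases, and 135 test cases from 3 more patients.  Count
identities: 4 Diffuser pairs and 7 Elapser pairs per case, hence 900 and
1575 at the full design.

## Datasets and scaling

Min-max scaling (`z = (x - min)/(max - min)`) is fitted per channel over
all training pixels pooled across cases, and per drug over the training
insertion doses; the statistics are the only thing later stages may carry
(no leakage; asserted).  Two pooling choices are deliberate: drug
channels also pool the one-hour post-insertion maps (they are the
Diffuser targets and exceed every pre-insertion frame), and dose
statistics come from insertion events only, because a zero dose never
reaches a Diffuser network — the insertion stage is conditional and
passes untouched drug channels through bit-identically.  Values outside
the training range scale outside [0, 1] and are not clipped.

## The surrogate

Every submodel is a plain stack of 5 x 5, stride-1, padding-2
convolutions (spatial shape preserved), batch norm + ReLU after every
layer except the last.  Hidden channel ladders: Diffuser heads
`128, 64, 32, 16, 8, 1` (7 input channels: five maps plus two tiled dose
planes); Elapser 1-3 `128, 64, 32, 16, 8, 4, 1`; Elapser 4-5
`256, 128, 64, 32, 16, 8, 4, 1` (5 input channels each).  Three choices
the source leaves open: padding 2 ("same") preserves the 151 x 151 shape;
the smaller Elapser stacks serve the slowly-varying channels `n`, `m`,
`P` and the larger ones the sharply-changing drug channels (configurable
via `dent_model(arch = ...)`); batch norm uses inference statistics
during rollout and validation.  Weights are fan-in uniform initialised
from recorded seeds.  The composed step replaces the drug channels with
the Diffuser outputs (or passes them through when the day's dose is zero)
and applies the five Elapsers; the rollout feeds each prediction back for
an arbitrary number of days, entirely in scaled space.

Because no deep-learning framework for R is available in this
environment, the convolution/batch-norm/Adam engine is implemented in the
package itself (RcppArmadillo, single precision, one GEMM per layer per
mini-batch via a shift-copy im2col).  Its forward pass and every gradient
are tested against an independent double-precision reference network and
finite differences.

## Training protocol

MSE loss, Adam at learning rate 1e-4, batch size 10, up to 200 epochs
with early stopping, 5-fold leave-one-patient-out cross-validation; the
seven submodels train independently.  Two details are this package's
choices: early-stopping patience is 10 epochs (the protocol names early
stopping but no patience), and the delivered checkpoint is the
best-validation fold's seven submodels (ensembling across folds was
considered and rejected as unstated).  Mini-batch order reshuffles each
epoch from the run seed; everything is bit-reproducible given the seed.

## Evaluation

SSIM and PSNR are computed per day per channel on *scaled* maps — a
common scale is what makes the five-channel average meaningful — then
averaged over channels and cases; the density summary `C` (mean of pixels
above `0.05 n_lim`; the threshold follows the 5%-of-capacity convention,
the source defers the number to its predecessor study) is computed on
inverse-scaled maps, and its absolute percentage error is aggregated as
mean +/- sample standard deviation across cases.  SSIM uses a 7 x 7
uniform window, sample (n-1) covariance normalisation, stabilizers
`(0.01 L)^2` and `(0.03 L)^2` with `L` the per-frame ground-truth range.
PSNR uses the ground-truth dynamic range and is undefined for constant
references: exact reproductions (infinite PSNR) and constant-truth
channel-days (e.g. the chemo map before the first chemo bolus) are
excluded from averages and counted; SSIM falls back to the scaled-space
range `L = 1` there.  One printed-value discrepancy is resolved in favour
of the stated convention: the aggregation example "{1, 3} -> sd 1.0"
matches the population formula, but the declared convention is *sample*
sd, so `stats::sd` ({1, 3} -> 1.414) is used throughout.

## What the tests do and do not establish

The full protocol — 360 simulated 151 x 151 cases, seven Table-sized
submodels, 200 epochs x 5 folds — is an hours-to-days computation on one
CPU (a single Elapser epoch over 1260 full-size pairs costs a few
TFLOPs).  The packaged test-suite therefore runs the *same code paths* at
reduced scale and asserts properties, not headline numbers:

* solver correctness is checked against dense loop-assembled oracles and
  closed forms at tolerances 1e-8 to 1e-10;
* the qualitative microenvironment features above are asserted on a full
  151 x 151 default-parameter case;
* learning checks run the published architecture on a 31 x 31 world with
  the full 40-case two-patient design.  One caveat is structural: with
  batch size 10 and learning rate 1e-4, a 30-epoch run over 140 training
  pairs performs only ~420 Adam steps *regardless of image size*, which
  bounds how far any stack can move from initialisation; reaching
  SSIM > 0.9 one-day-ahead needs the step counts of the full protocol
  (hundreds of pairs x hundreds of epochs).  The desk-scale expectation
  is therefore descent and trend behaviour, not the published headline
  SSIM — the acceptance suite states this distinction explicitly.
* the rollout-degradation trend (SSIM non-increasing, density-error
  non-decreasing over the forecast week) is asserted on a reduced-width
  composed model trained at desk scale.

A green desk-scale suite establishes that the simulator reproduces the
intended physics, that the learning machinery descends and generalises
across patients, and that composed rollouts degrade gracefully — it does
not certify the published full-scale metric values, which require the
full computation and, independently, the unpublished coefficient set.

## Known limitations

2D maps only; a single-exponential plasma model; a fixed insertion
schedule (the source flags schedule variation as future work); no
data augmentation; no uncertainty quantification; the HDF5/PNG artifact
formats of a Python deployment are replaced by RDS containers and base-R
PNG panels behind the same function surface.
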