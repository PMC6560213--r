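---
title: "Transient-state imaging with qti: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient-state imaging with qti: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qti)
```

This vignette is the package's own account of its science: the signal
model and its assumptions, the parameters that matter and why their
defaults were chosen, what the synthetic data generator does and does
not emulate, and where the implementation had to make choices that the
method description leaves open.

## 1. The transient-state signal model

A transient-state acquisition plays an inversion pulse followed by a
train of `N` excitations whose flip angle changes every repetition, so
the magnetization never settles into a steady state. `qti` simulates
this with the Extended Phase Graph (EPG) formalism: the voxel state is a
matrix of configuration states over dephasing orders `k` — dephasing
transverse `F_k`, rephasing transverse `F*_k`, longitudinal `Z_k` —
on which each sequence event acts as a simple linear operator:

* **RF pulse** (`epg_rf`): the standard 3×3 rotation mixing
  `(F_k, F*_k, Z_k)` within each order; no mixing across orders.
* **Relaxation** (`epg_relax`): `exp(-dt/T2)` on transverse states,
  `exp(-dt/T1)` on longitudinal ones, recovery of `Z_0` toward
  equilibrium.
* **Gradient dephasing** (`epg_shift`): one unit of unbalanced gradient
  area per repetition advances every transverse state by one order, with
  conjugation where rephasing states cross `k = 0`. The retained-order
  cap defaults to `K = N + 1`, which is lossless for one shift per
  repetition; smaller caps trigger a truncation warning when populated.
* **Flow washout** (`epg_flow`): plug flow perpendicular to the slice at
  speed `v` through thickness `d` replaces a fraction of the slice
  content per repetition. The retained fraction is
  `h = max(0, 1 - TR·v/d)`; the state is scaled by `h` and `(1 - h)` of
  fresh, fully polarized magnetization enters `Z_0`.

The recorded signal is `ρ·F_0` at the echo time of every repetition.
Event order within a repetition is RF → relax(TE) → readout →
relax(TR−TE) → gradient shift → flow. The echo must be read at TE after
excitation; the placement of the shift and flow operators inside the
remaining interval does not change `F_0` at the echo.

Two modeling decisions deserve emphasis. First, washout is applied as a
**constant per-repetition fraction** rather than a cumulative function
of total elapsed time: compounding the cumulative form would count the
same outflow twice, whereas per-TR replacement reproduces classic
plug-flow washout and has the correct fixed points (`h = 1` stationary,
`h = 0` complete replacement every TR, under which the signal collapses
to `ρ·sin(α_t)·exp(-TE/T2)` exactly — a closed form the tests check to
1e-9). Second, the flow operator is realized **entirely by the scalar
washout**; no additional velocity-dependent phase is modeled, which
matches a sequence that only uses unbalanced gradients and makes the
model agnostic to flow direction.

Assumptions inherited from this model: no diffusion, no magnetization
transfer, no B0/B1 inhomogeneity, ideal rectangular slice profile, no
in-plane motion, constant velocity within a voxel. RF phase is constant
(0°) by default since the sequence relies on gradient spoiling, but a
phase train can be supplied.

**Validation strategy.** The compiled EPG engine is checked against an
independent oracle: a brute-force isochromat ensemble (256 uniformly
dephased Bloch spins per voxel, same event schedule). With 256 spins the
discrete dephasing average is exact for trains up to 64 repetitions
(aliasing of configuration orders cannot occur below the spin count), so
the two implementations agree to rounding, and the suite enforces
relative L2 error below 1e-6 over randomized designs and tissues.

## 2. Bayesian experimental design

The design variables are the two control points `(α_a, α_b)` of a linear
flip-angle ramp; the remaining acquisition variables are fixed at the
reference protocol (N = 260, TE/TR = 2/14 ms, 2 mm slice, inversion
prepared, 20 ms inversion event — 3.66 s per slice). The cost combines:

* an **information utility** `u(η;θ)`: the determinant of the Fisher
  information of the complex signal with respect to θ = (T1, T2, ρ)
  under Gaussian noise, assembled from first-derivative sensitivities
  (central finite differences, relative step 1e-3; the ρ column is
  analytically the signal itself). The first-derivative (Gauss–Newton)
  form is used deliberately: it is the standard Fisher information for a
  Gaussian likelihood and is guaranteed non-negative, which a
  Hessian-style second-derivative determinant is not. Marginalizing
  `log u` over the tissue prior by Monte Carlo (200 draws by default,
  shared across all candidate designs so the landscape is smooth) gives
  `U(η)`; singular information matrices contribute `log(1e-300)`.
* a **contrast term** per tissue class: the worst case over competing
  classes of the best separation over echoes,
  `min_{d≠c} max_t |s_t(θ_c) − s_t(θ_d)|`, evaluated at the class means
  with unit proton density and no flow (stationary blood is a lower
  bound for flowing blood here). Complex differences are used because
  the model signal is complex; the worst-case aggregation is the
  conservative choice (a mean-over-competitors variant is available).

The default prior has four classes — GM 1450/85, WM 900/60,
CSF 3600/1750, SB (stationary blood) 1740/275 ms — with contrast weights
μ = (0.05, 0.05, 0.1, 0.3) and, the "broad Gaussian" being otherwise
unquantified, a 10% coefficient of variation per parameter, truncated
at zero. The total cost is
`C(η) = −((1−Σμ)·U(η) + Σ_c μ_c·contrast_c)`, minimized by exhaustive
grid search with ties broken toward smaller `α_a`, then smaller `α_b`.

**What the landscape actually looks like.** Under these conditions this
implementation finds a cost landscape whose utility term increases
monotonically in both control points, while the contrast terms prefer
small initial flip angles (the contrast-only minimizer has `α_a = 1°`,
and the stationary-blood contrast peaks at `α_b ≈ 65–70°`). Because the
utility is a log-determinant (scale-free spread of ≈ 3 nats across the
grid) and the contrast is a linear signal amplitude (weighted spread
≈ 0.01 on unit-ρ signals), the combined minimum sits at the largest
admissible control points, (15°, 90°) on the default grid, rather than
at an interior point: no single relative scaling of the two
incommensurate terms moves the minimizer to the interior, because the
CSF contrast grows monotonically with `α_b` and overrides the
stationary-blood peak. The per-term structure (contrast favoring small
`α_a`; utility favoring large flips; blood best separated late in the
train) is robust and is what the acceptance suite asserts; the location
of the combined minimum should be read together with the exported
landscape (`scripts/acceptance.R` writes it as CSV) rather than as a
single headline pair. Velocity is deliberately excluded from the
utility parameters: the ramp encodes relaxation, and flow enters the
design through the contrast term only.

## 3. The synthetic acquisition

`make_phantom("brain2d")` builds a single-slice head: a grey-matter
ellipse with a white-matter interior, two CSF ventricles, and four small
vessel disks carrying blood relaxation times and a through-plane speed
(50 mm/s by default — a mid-range arterial value that produces a
washout fraction of 0.65 per 14 ms repetition through a 2 mm slice).
Proton densities are 0.8/0.7/1.0/0.9 for GM/WM/CSF/blood, typical
relative values. The default study geometry is 64² voxels over a 225 mm
field of view; this keeps a full acquisition–reconstruction–inference
cycle at minutes on one CPU while leaving every algorithmic ingredient
(undersampling, coil combination, subspace conditioning) intact.

Sampling is an analytic variable-density Archimedean spiral: 89
interleaves, of which 18 suffice to cover the inner 20% of k-space; the
azimuthal pitch follows `dφ/dk = 2π/ν(k)` with `ν(k)` the effective arm
count, so consecutive turns of the rotated arm set are Nyquist-spaced in
each regime. One arm is played per repetition, rotated continuously by
the golden angle (111.246°); a golden-ratio permutation of the interleaf
set is available instead. Gradient-hardware constraints, off-resonance
blurring and slice-profile effects are not modeled — the sampling
geometry, not gradient physics, is what drives the reconstruction
problem.

The forward model evaluates the phantom's instantaneous image (signals
cached exactly per unique (T1, T2, v) tuple — no interpolation), weights
it by each coil map (smooth Gaussian-lobe sensitivities, RSS-normalized)
and samples it with a Kaiser–Bessel gridding NUFFT (oversampling 2,
kernel width 8, numerically integrated deapodization; accuracy against
direct Fourier summation is below 1e-6 relative, and forward/adjoint are
exact transposes by construction). Noise is circular complex Gaussian
per sample; the 30 dB SNR used in the acceptance study is defined on the
RMS of the noiseless data.

What this generator does **not** emulate about real data: coil
calibration errors (sensitivities are known exactly), static field
inhomogeneity and spiral blurring, physiological motion and pulsatile
flow, partial-volume mixtures at tissue boundaries (labels are crisp),
and Rician magnitude statistics (all processing stays complex). Passing
tests on these phantoms therefore demonstrates correctness of the
algorithms, not robustness to scanner non-idealities.

## 4. Subspace reconstruction with local low rank

Signal evolutions drawn from the tissue prior (including a 20% fraction
of flowing spins with v uniform up to 100 mm/s, since blood must be
representable) are highly correlated; the top 10 left singular vectors
of a 1000-draw ensemble form the temporal basis Φ. Rank 10 keeps the
median projection error of held-out prior draws below 1%, which the
suite asserts. Reconstruction then solves

  min_c ½‖E Φ c − y‖² + λ Σ_patches ‖P c‖_*

by ADMM: conjugate-gradient data consistency, singular-value
soft-thresholding on 8×8 spatial patches of the coefficient images, dual
update. Thresholding the (voxels × R) coefficient matrix of a patch is
equivalent to thresholding its full (voxels × N) temporal matrix
restricted to the subspace — identical singular values at a fraction of
the cost — which is how the nominal 8×8×(full time) patch is realized in
a single-slice geometry.

Numerical choices that matter (all exposed in `recon_config()`):

* **Operator normalization.** The encoding operator is scaled to unit
  spectral norm (power iteration) before ADMM. Without this, λ and the
  penalty ρ would have to track the operator's squared norm (≈ 5·10⁴ on
  the default geometry); referencing the threshold to the raw adjoint
  image annihilates the solution entirely.
* **λ = 0.005**, expressed relative to the largest patch singular value
  of the normalized adjoint reconstruction, and **ρ = 0.05**: chosen so
  the data-consistency step dominates early iterations while the
  low-rank proximal step suppresses the incoherent aliasing of
  one-arm-per-TR sampling. With ρ on the order of 1 the x-update is
  over-damped and the solver stalls far from the data.
* **10 outer × 6 CG iterations** reach class-median T1 errors ≤ 2% and
  T2 errors ≤ 7% on the 64² study; the objective is logged per
  iteration and decreases monotonically when the patch partition is
  fixed. Random cyclic patch shifts (the default) avoid blocking
  artifacts at the price of a slightly jittering objective; disable
  `random_shifts` to observe textbook monotone ADMM.
* **No density compensation** in the objective: CG handles the Gram
  structure. The spiral's uniform-in-radius sampling makes the normal
  operator center-weighted, which costs CG iterations but no accuracy.
  One consequence worth knowing: spiral arms sample the inscribed disk
  of k-space only, so image content in the unsampled corner frequencies
  is invisible to the operator — exact-recovery experiments must
  band-limit their ground truth accordingly.

## 5. Probabilistic inference

Per voxel, the posterior over (T1, T2) is sampled under a uniform prior
(bounds 100–5000 / 10–3000 ms) with the complex proton density profiled
analytically inside the Gaussian likelihood — a linear nuisance
parameter, so `ρ̂ = ⟨f(θ), s⟩/‖f(θ)‖²` maximizes the likelihood exactly
and the sampled space stays two-dimensional (velocity can be added but
is off by default: the ramp has little sensitivity to it). The sampler
is a transitional MCMC: particles start from the prior, move through a
quadratic tempering schedule (8 stages × 500 particles by default) via
importance reweighting, systematic resampling and covariance-scaled
Metropolis moves, with extra decorrelation sweeps at the target
temperature; the maximum-likelihood point is polished by bounded
quasi-Newton from the best particle. Summaries are the posterior mean,
sd, central 95% interval, ML point, profiled ρ̂, relative fit residual
and an effective sample size; low acceptance (< 5%) or ESS (< 50) are
flagged, not fatal. The suite checks the sampler against a dense-grid
numerical posterior and recovers noiseless truths to 1%; posterior
widths grow from WM-like to CSF-like tissues, reflecting the weaker
encoding of long relaxation times by a 3.66 s train.

Baselines: fingerprint-style dictionary matching (log-spaced grid,
unit-norm atoms, matching invariant to complex scale — the default
100×100 grid has ≈ 4% steps, so studies asserting ≤ 2% accuracy build
denser grids) and bounded nonlinear least squares initialized from the
match. Noise, when not supplied, is estimated from the residuals of a
coarse dictionary fit.

## 6. Angiographic projections

Flow washout leaves vessel voxels hyperintense late in the train (fresh
magnetization keeps entering while stationary tissue saturates), so
summing the magnitudes of the last 160 of 260 reconstructed frames
(0-based indices 100–259, inclusive; `combine_frames()`) produces an
angiographic image, and a maximum-intensity projection (`mip()`)
collapses a slice stack for display — summation first, then projection.
Frame combination is monotone in the range and the MIP idempotent, both
tested.

## 7. Problem sizes and I/O

The shipped studies use: 165-point design grids with 200 Monte-Carlo
draws; 64² phantoms with 260 repetitions, 256-sample arms and 4 coils
for reconstruction; 32² geometries with short trains for operator-level
checks; a handful of voxels for full posterior sampling. These sizes
were chosen so a complete run of every study stays within minutes on a
single CPU while exercising each algorithm at full fidelity; all of
them scale up by argument.

Maps and frame stacks are written as NIfTI with FOV-derived voxel
spacing (magnitude only — complex arrays stay in the serialized
exports). Raw k-space and subspace coefficients are complex-valued and
are serialized with R's native format via `export_qti()`/`import_qti()`,
there being no HDF5 bindings among the package's dependencies; designs
travel as YAML, landscapes as CSV, and `run_pipeline()` writes a JSON
manifest with seeds and stage timings.

## 8. Known limitations

* The flow model is plug flow, direction-agnostic, with a single
  constant speed per voxel; it produces inflow contrast but is not a
  velocity-quantification model.
* The design study's combined cost mixes a log-determinant with a linear
  amplitude; its global minimizer on the default grid sits at the grid
  corner (§2), so design conclusions should be drawn from the per-term
  landscape, which is exported alongside.
* Vessel-class relaxometry from the map-fitting baselines is biased by
  construction: the fitted model excludes velocity while vessel signals
  are flow-perturbed. Stationary-class accuracy is the meaningful
  recovery metric.
* Reconstruction and inference assume exactly known coil sensitivities
  and complex Gaussian noise; neither holds exactly on a scanner.
* Single-slice (x, y, t) geometry; multi-slice stacks are handled by
  iteration, not by 3D encoding.
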