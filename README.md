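# qti — quantitative transient-state imaging

`qti` is an R toolbox for simulating, designing, reconstructing and
inverting **quantitative transient-state MRI** experiments of the
fingerprinting family. In a transient-state acquisition the flip angle
changes every repetition, so the magnetization never reaches a steady
state; the resulting signal evolution encodes the tissue relaxation
times T1 and T2, while through-plane flow continuously replaces
saturated spins with fresh magnetization and leaves flowing blood
hyperintense. The package covers the full in-silico pipeline:

* **Flow-aware EPG engine** — Extended Phase Graph simulation of the
  configuration states `(F_k, F*_k, Z_k)` under RF rotation, relaxation,
  unit gradient dephasing per TR, and a plug-flow washout operator that
  rescales the state by the retained fraction
  `h = max(0, 1 − TR·v/d)` and feeds `1 − h` of fresh longitudinal
  magnetization into `Z_0`.
* **Bayesian experimental design** — a Fisher-information utility
  `u(η;θ) = det Σ_t Re[∂s_t/∂θ_i · conj(∂s_t/∂θ_j)]/σ²` marginalized as
  `U(η) = E_π[log u]` over a Gaussian tissue-class prior, combined with
  per-class worst-case signal contrasts into the cost
  `C(η) = −((1−Σμ_c)·U(η) + Σ_c μ_c·min_{d≠c} max_t |s_t(θ_c) − s_t(θ_d)|)`,
  minimized exhaustively over flip-angle ramp control points.
* **Synthetic acquisition** — digital brain/tube phantoms,
  variable-density spiral trajectories (89 interleaves, 18 covering the
  dense core, golden-angle rotation), smooth RSS-normalized coil
  sensitivities, and a Kaiser–Bessel gridding NUFFT used to generate
  undersampled multi-coil k-space with complex Gaussian noise.
* **4D subspace reconstruction** — a rank-10 temporal basis from prior
  signal draws, and ADMM with local low-rank (singular-value
  soft-thresholding on 8×8 spatial patches of the coefficient images)
  solving `min_c ½‖E Φ c − y‖² + λ Σ_p ‖P_p c‖_*`.
* **Probabilistic inference** — per-voxel posterior over (T1, T2) under
  a uniform prior with the proton density profiled analytically,
  sampled by transitional (tempered) MCMC with uncertainty summaries,
  plus dictionary-matching and bounded least-squares baselines.
* **Angiography** — magnitude summation of late frames and
  maximum-intensity projection.

## Worked example

```r
library(qti)

## the reference acquisition: 7 -> 70 degree ramp, 260 repetitions,
## TE/TR = 2/14 ms, 2 mm slice, inversion-prepared
des <- make_ramp_design(ramp_spec(7, 70, N = 260))
design_duration(des)
#> [1] 3.66                        # seconds per slice

## signal of grey matter vs fast-flowing blood
gm    <- simulate_signal(des, tissue_params(1450, 85))
blood <- simulate_signal(des, tissue_params(1740, 275, v = 50))
mean(Mod(blood$s[200:260])) / mean(Mod(gm$s[200:260]))
#> [1] 8.441277                    # late-frame inflow hyperintensity

## end-to-end synthetic study (acquire -> reconstruct -> fit maps)
ph <- make_phantom("brain2d", 64, vessel_v = 50, seed = 1)
sp <- make_spiral(fov_mm = ph$fov_mm, resolution_mm = ph$fov_mm / 64)
co <- make_coils(64, 4, seed = 1)
y  <- acquire(ph, des, sp, co,
              noise_sd = noise_sd_for_snr(acquire(ph, des, sp, co, 0), 30),
              seed = 2)
basis <- build_subspace(des, tissue_class_prior(), n_signals = 1000,
                        R = 10, seed = 3)
rec    <- admm_reconstruct(y, sp, co, basis, recon_config(), seed = 4)
frames <- project_to_time(rec)
maps   <- fit_maps(frames, ph$rho > 0, des, method = "dict")
median(maps$T1[ph$labels == 2])   # white matter, true 900 ms
#> [1] 914.1838
```

The fitted white-matter T1 lands within about 2% of the phantom's
ground truth; grey matter and CSF behave similarly (see
`tests/testthat/test-acceptance.R` for the tolerances checked on every
run). Summing the magnitudes of the last 160 reconstructed frames with
`combine_frames()` and projecting with `mip()` yields an angiographic
image in which the flowing-vessel voxels are brighter than any
stationary tissue.

A complete configured run (design → simulate → reconstruct → infer →
angiography, with NIfTI/YAML/CSV/JSON artifacts) is available through
`run_pipeline()`; see `inst/extdata/pipeline_demo.yaml` and the thin
command-line wrapper `inst/cli/qti`.

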