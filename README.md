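# poremri

Pore size estimation from spherical-mean diffusion–relaxation MRI.

MRI cannot image micrometre-scale pores directly, but the signal from water
confined in narrow cylinders carries two size fingerprints. First, restricted
diffusion: the apparent diffusivity perpendicular to a cylinder of radius *r*
under a pulsed-gradient spin-echo (PGSE) experiment follows the van Gelderen
Gaussian-phase-distribution model, D⊥(r), which grows steeply with *r*.
Second, surface relaxation: collisions with the pore wall shorten the
transverse relaxation time according to the Brownstein–Tarr law

    1/T2i(r) = 1/T2b + 2 rho2 / r,

where T2b is the bulk-water T2 and rho2 the surface relaxivity of the pore
material. `poremri` implements the unified forward model for the
orientation-averaged (spherical-mean) signal of a whole *distribution* P(r)
of water-filled cylinders,

    S(b, TE) = k ∫ P(r) r² · exp(−TE/T2i(r)) · S̄_Diff(b, r) dr / ∫ P(r) r² dr,

with S̄_Diff the spherical-mean signal of an axisymmetric compartment
(√(π/4x²)·e^(−bD⊥)·erf(√x²), x² = b(D∥−D⊥)) and the r² factor expressing
that each cylinder contributes in proportion to its water volume. The two
practical estimators are special cases:

* **T2 branch** — at one high b-value and several echo times the diffusion
  factor is (nearly) constant: fit K·exp(−TE/T2i), convert T2i to a radius
  through rho2. Needs calibration of rho2 against a known radius sample,
  but only moderate gradients.
* **Diffusion branch (spherical-mean power law)** — at one echo time and
  several high b-values, fit β·S̄_Diff(b, r) with the van Gelderen D⊥(r).
  Needs ultra-strong gradients, no calibration.

Both report an *effective* radius: the single-cylinder radius whose signal
best matches the whole distribution. The package also computes the matching
ground-truth quantity from measured radii (e.g. electron-microscopy lists)
by synthesising the volume-weighted signal of the sample and fitting the
same one-cylinder models — a numerical definition that stays valid for
distributions with large pores, where the classical moment formula
(⟨r⁶⟩/⟨r²⟩)^(1/4) breaks down — plus the first-order moment approximation
⟨r²⟩/⟨r⟩ for the T2 branch.

A built-in simulator (five lognormal-mixture phantom presets with heavy
right tails, parallel or 90°-crossing fiber populations, 48-direction
acquisitions, Rician noise) lets every stage be validated end to end
without scanner data.

## Worked example

Simulate one phantom, calibrate its surface relaxivity against the known
radii, and estimate its effective radius from the noisy data:

```r
library(poremri)

prot  <- protocol_preset("t2_block")     # b = 5000 s/mm2, six TEs, 48 dirs
spec  <- phantom_preset("phantom1")      # mean radius 1.07 um, tail to ~10 um
radii <- sample_radii(spec, seed = 7)
radii
#> radius sample 'phantom1': 11618 pores, mean 1.077 um, range [0.247, 8.445]

ds     <- simulate_dwi(radii, spec, prot, snr = 34, n_voxels = 25, seed = 8)
series <- dataset_series(ds)$series      # spherical means, TE 51..250 ms

cal <- calibrate_rho2(series, radii, T2b = 3000)
cal
#> surface relaxivity calibration (phantom1): rho2 = 3.1967 nm/ms
#>   K = 0.2669, loss = 4.827e-07

t2    <- fit_monoexp_t2(series)          # intra-pore T2: 212.1 ms
relax <- relaxation_params(T2b = 3000, rho2 = cal$rho2)
radius_from_t2(t2$T2i, relax)            # MRI-side effective radius
#> [1] 1.459

fit_single_cylinder_relaxation(
  synth_relaxation_series(radii, prot$TE, relax), relax)
#> effective radius (relaxation model): r_eff = 1.4578 um
```

The MRI estimate (1.459 um) and the reference radius computed from the
generating distribution (1.458 um) agree to 0.1%: with a consistently
calibrated rho2 the T2 branch inverts its own forward model almost exactly,
even at SNR 34. Note that both are larger than the 1.08 um *mean* radius —
effective radii are volume-weighted, so the large-pore tail pulls them up.

The same workflow is available from the shell via the thin CLI in
`inst/exec/poremri` (`simulate`, `calibrate`, `fit-t2`, `fit-dmri`,
`sem-reff`, `compare`), which reads/writes CSV, NIfTI + bval/bvec and JSON
reports through `run_pipeline()`.

## Package layout

| Area | Functions |
|---|---|
| Signal physics | `b_value`, `radial_diffusivity_vg`, `radial_diffusivity_neuman`, `smt_diffusion`, `t2_intra`, `joint_signal` |
| Effective radii | `synth_relaxation_series`, `synth_diffusion_series`, `fit_single_cylinder_relaxation`, `fit_single_cylinder_diffusion`, `moment_ratio_radius`, `neuman_moment_radius` |
| Estimation pipelines | `spherical_mean`, `fit_monoexp_t2`, `radius_from_t2`, `fit_diffusion_radius`, `estimate_snr`, `compare_radii` |
| Calibration | `calibrate_rho2`, `pooled_relaxivity`, `estimate_t2b` |
| Synthetic phantoms | `phantom_preset`, `phantom_spec`, `sample_radii`, `simulate_dwi`, `add_rician`, `dmri_directions` |
| IO / orchestration | `read_radius_csv`, `read_series_csv`, `write_dataset`, `load_dataset`, `run_pipeline`, `phantom_study` |

The methods vignette (`vignettes/pore-size-estimation.Rmd`) documents the
model assumptions, unit conventions, numerical choices and the limits of
what the synthetic validation shows.
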