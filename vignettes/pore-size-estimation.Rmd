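---
title: "Estimating pore sizes from spherical-mean diffusion-relaxation MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pore sizes from spherical-mean diffusion-relaxation MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremri)
```

## The model

`poremri` models the spherical-mean (powder-average) MRI signal of water
confined in a distribution of parallel, impermeable cylindrical pores.
For a single cylinder of radius $r$ the signal under a rectangular PGSE
sequence factorises into a relaxation part and a diffusion part:

$$\bar S(b, TE; r) = e^{-TE/T_{2i}(r)}\; \bar S_{Diff}(b, r),$$

and for a whole radius distribution $P(r)$ the measured signal is the
volume-weighted mixture

$$\bar S(b, TE) = k\,
  \frac{\int P(r)\, r^2\, e^{-TE/T_{2i}(r)}\, \bar S_{Diff}(b,r)\, dr}
       {\int P(r)\, r^2\, dr},$$

the $r^2$ weight expressing that signal is proportional to water volume.
Three physical ingredients enter:

1. **Spherical mean of an axisymmetric compartment.** Averaging
   $\exp(-b[D_\perp + (D_\parallel - D_\perp)\cos^2\theta])$ over uniformly
   distributed orientations gives
   $\bar S_{Diff} = \sqrt{\pi/4x^2}\, e^{-b D_\perp}\,\mathrm{erf}(x)$ with
   $x^2 = b(D_\parallel - D_\perp)$ (`smt_diffusion()`). The average does
   not depend on how the fibers are oriented, which is what makes the
   technique usable in crossing-fiber geometries.
2. **Restricted radial diffusion.** $D_\perp(r)$ follows the van Gelderen
   Gaussian-phase-distribution series over the roots of $J_1'$
   (`radial_diffusivity_vg()`). Its wide-pulse (Neuman) limit
   $D_\perp = 7r^4/(48 D_0\,\delta(\Delta - \delta/3))$ is provided for
   comparison (`radial_diffusivity_neuman()`); at the default timings
   ($\delta/\Delta = 9/35$ ms, $D_0 = 2\ \mu m^2/ms$) it tracks the full
   series to ~2% below 1 µm but overshoots by tens of percent beyond
   ~2.5 µm, which is why all quantitative fits here use the full series.
   A medium-pulse closed form would sit between the two regimes; its
   expression is not implemented and the corresponding entry point
   (`radial_diffusivity_medium_pulse()`) signals a not-implemented
   condition rather than silently substituting the Neuman form.
3. **Surface relaxation.** $1/T_{2i}(r) = 1/T_{2b} + 2\rho_2/r$
   (`t2_intra()`), with $\rho_2$ the surface relaxivity of the pore
   material (nm/ms) — the material-dependent nuisance parameter of the T2
   branch.

### The two estimators

Each branch approximates the mixture by a *single* cylinder with an
effective radius:

* **T2 branch**: at fixed high $b$, $\bar S(TE) \approx K e^{-TE/T_{2i}(r_{eff})}$.
  `fit_monoexp_t2()` estimates $T_{2i}$; `radius_from_t2()` inverts the
  surface-relaxation law. This assumes the diffusion factor is constant
  across pores, which is only approximately true (see *Known
  approximations* below).
* **Diffusion branch**: at fixed TE,
  $\bar S(b) \approx \beta\, \bar S_{Diff}(b, r_{eff})$, fitted with the
  full erf expression and the van Gelderen $D_\perp(r)$
  (`fit_diffusion_radius()`). This neglects the $r$-dependence of
  relaxation, which inflates the apparent large-pore tail.

The matching ground truth for a measured radius list is computed
*numerically*: synthesise the volume-weighted decay of the whole sample
(`synth_relaxation_series()`, `synth_diffusion_series()`) and fit the same
one-cylinder models to it. This stays valid for distributions containing
large pores, where the classical moment formula
$(\langle r^6\rangle/\langle r^2\rangle)^{1/4}$ (kept as
`neuman_moment_radius()` for reference) fails together with the wide-pulse
approximation it is derived from. The first-order approximation
$\langle r^2\rangle/\langle r\rangle$ (`moment_ratio_radius()`) remains a
useful quick estimate for the T2 branch.

### Calibration

$\rho_2$ is estimated per phantom by minimising the mean squared difference
between a measured multi-TE series and the synthetic decay of the known
radius sample (`calibrate_rho2()`): a 200-point grid over 0.1–20 nm/ms
followed by golden-section refinement between the bracketing grid points,
with the scale $K$ profiled analytically at every candidate (this also
makes the calibration exactly invariant to rescaling of the data). The
grid-plus-refinement optimum matches a brute-force scan at 0.001 nm/ms
resolution, which the test suite checks. `pooled_relaxivity()` averages
per-phantom values with an explicit exclusion list, because a single
degraded phantom (altered surface chemistry) can carry a clearly deviating
relaxivity and both pooled conventions are worth reporting.

## Parameters and units

One canonical internal unit system avoids silent conversion errors:

| Quantity | Unit | Default | Notes |
|---|---|---|---|
| radius $r$ | µm | — | circular-equivalent radius $\sqrt{A/\pi}$ for SEM areas |
| times $\delta, \Delta, TE, T_2$ | ms | $\delta/\Delta$ = 9/35 | protocol presets |
| diffusivity $D_\parallel$ | µm²/ms | 2.0 | free water near room temperature; configurable |
| b-value | s/mm² (API), ms/µm² (internal) | — | factor $10^{-3}$ |
| gradient $G$ | mT/m | — | $\gamma = 2.6752218744\times10^8$ rad/s/T |
| $\rho_2$ | nm/ms | — | factor $10^{-3}$ to µm/ms inside $T_{2i}$ |
| $T_{2b}$ | ms | 3000 | free-water value measured on a control tube |
| series terms $m$ | — | 18 | matches the 200-term series to $10^{-6}$ relative |

Protocol presets store the b-value computed exactly from $G$ and the
timings ($b = 5161$ s/mm² for the nominal 5000, etc.): printed protocol
tables typically round $G$ and $b$ independently to a few percent, and the
simulator and the fitters must share identical physics. When a protocol is
built with both $G$ and $b$, their consistency is checked at a default 5%
tolerance.

## Numerical choices

* **Bessel roots.** Roots of $J_1'$ are bracketed by sign change on a fine
  grid and polished with `uniroot()` to ~$10^{-13}$, cached, and extended
  on demand so that high-order oracle series are available to the tests.
* **Guarded limits.** `smt_diffusion()` switches to a Taylor expansion of
  $\mathrm{erf}(x)/x$ when $x^2 < 10^{-12}$ (isotropic limit), and
  $D_\perp$ is clamped to $[0, D_\parallel]$.
* **Fitting.** All one-dimensional radius fits profile the scale
  analytically and run bounded L-BFGS-B from 10 log-spaced starts in
  $r \in [0.05, 15]$ µm, followed by a golden-section polish; ties are
  broken toward the smaller radius, and an optimum within 1% of a bound
  sets a `bounds_hit` flag instead of raising an error. Synthetic
  reference signals are evaluated on the acquisition grids themselves (six
  TEs; five b-values), since calibration compares synthetic and measured
  curves point by point.
* **SNR estimation.** The voxelwise mean/SD ratio over repeated b0 images
  is biased upward with few repeats ($E[1/s] > 1/\sigma$; the factor is
  $\approx 1.25$ for 5 repeats). `estimate_snr()` divides this
  chi-distribution factor out by default and keeps the raw convention
  behind `correct = FALSE`.
* **Regression.** Radius sets are compared by unweighted OLS with the
  two-sided t-distribution p-value ($n-2$ df) and no multiple-testing
  correction; per-point uncertainties are reported as error bars only.

## The synthetic phantoms

`phantom_preset()` defines five stand-in phantoms as truncated lognormal
mixtures: a bulk component (log-SD 0.30–0.42) carrying >99% of the pores
and a sparse large-pore tail (0.2–0.6% of pores around 4–5.5 µm, truncated
at 10 µm). The bulk log-mean is *solved* from the truncated-lognormal mean
formula so the population mean radius matches the catalogued value of each
phantom (1.07, 1.07, 0.70, 1.18, 1.21 µm) exactly by construction;
phantoms 1 and 2 share a distribution, with phantom 2 split into two fiber
populations crossing at 90°. Tail fractions were fixed once so that the
volume-weighted tail share stays modest and the first-order moment ratio
$\langle r^2\rangle/\langle r\rangle$ tracks the relaxation-side effective
radius within ~15%, the regime reported for real microfiber phantoms;
heavier tails would push most of the signal into the tail and describe a
different kind of sample. Per-preset surface relaxivities
{3.5, 4.3, 2.0, 3.2, 3.8} nm/ms are distinct on purpose, with phantom 3 as
the low outlier.

`simulate_dwi()` evaluates the exact forward model per fiber and gradient
direction (48-direction electrostatically optimised set, plus one b0 per
shell) and applies Rician noise with $\sigma = S_{b0}(\min TE)/SNR$
independently to every measurement of every voxel; all voxels share the
same ground truth. The default study conditions used by `phantom_study()`
and the acceptance script are the full catalogued fiber counts
(7246–11827 per phantom), 25 voxels, SNR 34; most unit tests run the same
machinery at 300–4000 fibers, which leaves all qualitative behaviour
unchanged.

What the simulator deliberately does **not** contain: an extra-fiber water
compartment (assumed suppressed at $b \ge 5000$ s/mm²), exchange, myelin
water, non-circular cross-sections, beading or undulation, per-voxel
heterogeneity of the radius distribution, and any denoising or Rician bias
correction. Passing the end-to-end tests therefore demonstrates internal
consistency of models, estimators and calibration under the stated noise
model — not robustness to the tissue-level confounds absent from the
simulation.

## Known approximations, and what the validation shows

Two deviations are intrinsic to the estimators, and the package's tests
assert them rather than hide them:

* **The T2 branch is exact only under its own convention.** At
  $b = 5000$ s/mm² the diffusion factor $e^{-bD_\perp(r)}$ is not quite
  constant across pores: it suppresses the large-pore tail, so with the
  *true* $\rho_2$ the noiseless MRI-side radius deviates by a few percent
  from the reference radius of the full distribution. The practical
  procedure never uses the true value: it calibrates $\rho_2$ on the
  measured curve and uses the calibrated value on both sides, under which
  the estimated and reference radii are fits of the same one-cylinder
  family to essentially the same curve and agree to well under 1% — the
  mechanism behind the near-unit regression slope that
  `scripts/acceptance.R` reproduces. The Rician floor at long TE biases
  the calibrated $\rho_2$ itself a few percent low at SNR 34, but this
  cancels in the comparison for the same reason.
* **The diffusion branch inflates radii when relaxation is active.**
  Because small pores relax faster, the $r$-dependent T2 weighting at
  TE = 51 ms shifts volume weight toward large pores; the pure-diffusion
  fit consequently overestimates the effective radius relative to the
  relaxation-free reference. Together with the lower resolution limit of
  the T2 contrast this also implies the ordering
  $r_{eff,D} \ge r_{eff,R}$ for heavy-tailed samples, which the tests
  check on three presets.

A further numerical caveat: a 48-point direction set carries an intrinsic
powder-average quadrature error (a few tenths of a percent in the signal,
growing with $b$), worth up to ~2–3% in the fitted diffusion-branch radius
at these pore sizes. The loop-closure test therefore isolates the
estimator with a dense 240-direction quadrature (agreement to <1%) and
bounds the 48-direction case separately. For the T2 branch the quadrature
factor is TE-independent at fixed $b$ and cancels into the scale exactly.

## Limitations

The phantom-study validation is a *self-consistency* study on synthetic
phantoms whose distribution shapes are stand-ins constrained by catalogued
means, tail extent and reported moment relationships — not the unpublished
per-phantom SEM lists. Real acquisitions add confounds listed above
(extra-pore water, irregular cross-sections, distribution heterogeneity)
that the estimators do not model; conclusions about real tissue or real
phantom hardware require the corresponding measured data, for which the
package provides the NIfTI/bval/bvec/TE-table readers (`load_dataset()`)
and the same fitting pipeline.
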