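---
title: "Modelling electron backscatter from internal lead shielding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling electron backscatter from internal lead shielding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ebftools)
library(dplyr)
```

## The physical picture

When a high-Z slab such as lead sits inside tissue during an electron beam
treatment, electrons backscatter from the slab and enhance the dose on its
upstream side. Two quantities describe the effect on the central axis:

* the **electron backscatter factor** `EBF`, the ratio of dose at the
  interface with the slab present to the dose at the same point without
  it, under saturation conditions (the slab thick enough that adding more
  material changes nothing); and
* the decay of that enhancement with **upstream distance** `t` (mm),
  historically called the electron backscatter intensity.

Both depend on the **mean electron energy at the interface**, `Em`, which
falls approximately linearly with depth,

$$E_m \approx E_0\,(1 - z/R_p),$$

where `E0 = 2.33 × R50` (R50 in cm) is the mean surface energy and `Rp`
the practical range. `ebftools` models the combined quantity as

$$\mathrm{EBF}(E_m, t) = 1 + \bigl(\mathrm{EBF}(E_m) - 1\bigr)\,
  e^{-k(E_m)\,t},$$

with the interface factor and the decay coefficient

$$\mathrm{EBF}(E_m) = 1 + C_1 e^{-C_2 E_m} - C_3 e^{-C_4 E_m},
\qquad k(E_m) = -C_5 \ln E_m + C_6 .$$

The two-exponential interface form captures the behaviour that a single
exponential misses: the enhancement *decreases* again below a peak energy
(about 3.5 MeV with the default coefficients), because very low-energy
electrons backscatter efficiently but are also absorbed before they can
deposit dose upstream.

Two structural choices deserve a note, because the combined expression can
be written several ways:

* **the decay applies to the enhancement** `EBF − 1`, not to the whole
  factor. Applying it to the whole factor would drive the dose *below*
  its unperturbed value far upstream, which is unphysical; our form tends
  to exactly 1.
* **`k` decreases with energy** (the minus sign on `C5 ln Em`): more
  energetic backscattered electrons travel further upstream. This is the
  form consistent with the monotone trends the decay data show; with the
  defaults `k` would cross zero near 24 MeV, far outside the validated
  window, and is clamped at zero there (with a warning).

## Coefficients, parameters and units

All depths and distances are in mm, energies in MeV. The packaged default
coefficient set (also in
`system.file("extdata", "default_coefficients.json", package = "ebftools")`)
is

```{r}
ebf_coefficients()
```

`C1`, `C3` are dimensionless amplitudes, `C2`, `C4` energy rates (MeV⁻¹),
`C5`, `C6` the decay-model slope and intercept (mm⁻¹). The interface model
is validated for `Em` in 0.2–14 MeV and the legacy single-exponential
relation (`ebf_klevenhagen()`) for 3–35 MeV; evaluations outside these
windows still compute but warn, and `strict = TRUE` (or the CLI `--strict`
flag) turns the warnings into errors. These coefficients are
machine-specific: they were determined for one accelerator family, and
refitting with `fit_full()` is the intended route for any other machine.

```{r}
peak_enhancement_energy()          # energy of maximum interface enhancement
enhancement_range(1, 0.05)         # mm upstream until only 5% enhancement is left
```

Both solvers are closed forms; the test suite cross-checks them against a
dense grid argmax and `uniroot()` bisection, two routes that share no code
with the implementation.

## Extraction conventions

Observations come from paired central-axis depth-dose curves scored with
and without the slab, as voxel-wise dose ratios at the voxel centers
upstream of the interface. Two conventions matter on a discrete grid:

* **interface attribution.** The interface EBF is a point quantity, but on
  a grid it is scored at the center of the first upstream voxel (half a
  voxel away). We follow that convention throughout: the generator and
  `predict_perturbed_pdd()` place the `t = 0` interface value at the first
  upstream voxel center (switchable with `interface_attribution = FALSE`),
  `extract_backscatter()` flags the smallest-`t` observation, and the
  fitting stage treats flagged observations as `t = 0` samples of the
  interface model. Whether a given dataset used `t = 0` or the geometric
  half-voxel offset for its interface values is often unknowable;
  `fit_full(interface_t = "geometric")` covers the other reading by
  fitting the interface model to the per-energy `t = 0` extrapolations of
  the decay fits instead.
* **grid alignment.** Ratio extraction requires identical grids. An
  explicit `resample = TRUE` linearly interpolates the *reference* curve
  onto the Pb-curve grid — never the Pb curve, whose sharp interface a
  linear interpolant would smear.

Doses at and beyond the interface are set to zero: a saturation-thickness
slab shields the distal side almost completely, and transmission through
the slab is out of scope.

## The staged fit

`fit_full()` mirrors the structure of the model rather than attempting a
six-parameter nonlinear fit in one shot:

1. **Interface stage** (`fit_interface_model()`): bounded
   Levenberg–Marquardt least squares (via `minpack.lm::nlsLM`) of the
   two-exponential form on the interface-flagged observations, with
   positivity bounds, starting point `(1.0, 0.05, 0.5, 0.4)` chosen from
   the magnitudes of the legacy relation, and a small set of deterministic
   perturbed restarts on non-convergence. At least 8 observations spanning
   at least 5 MeV are required — two exponentials are barely identifiable
   below that. The two terms have opposite signs, so they are not freely
   exchangeable; a fit that nevertheless lands with `c2 ≥ c4` is reported
   with a warning rather than silently reordered.
2. **Per-energy decay stage** (`fit_decay_per_energy()`): for each mean
   energy with at least three usable upstream points, an ordinary linear
   regression of `ln(EBF − 1)` on `t`. The negated slope is `k`; the
   exponentiated intercept is the implied interface enhancement.
3. **Decay-model stage** (`fit_decay_model()`): ordinary least squares of
   the per-energy `k` values on `ln Em`.

95% confidence half-widths are asymptotic (Jacobian- or
design-matrix-based) with t quantiles, matching the usual reporting style
for this kind of fit; they are *per-stage* intervals and do not propagate
uncertainty between stages. A caveat worth knowing: at realistic noise
levels the interface-stage estimator is median-unbiased but heavy-tailed
(occasional draws inflate `c1` and `c3` together with compensating rates),
so individual estimates can stray outside nominal intervals more often in
the upper tail than a Gaussian intuition suggests, while the CI *coverage*
stays nominal — the test suite checks coverage over 200 seeded replicates.

The log-linear decay fits use only points whose *observed* enhancement
exceeds `min_enhancement = 0.01`. With voxel noise of relative standard
deviation 0.002 on each of two curves, the ratio noise is ~0.3%; points
with enhancement below ~1% are noise-dominated and their logarithms would
corrupt the slope. The 1% floor is roughly five times that noise floor.
Points with `ebf ≤ 1` carry no usable enhancement at all and are dropped
(with a warning when no explicit floor was requested).

## Beam-quality characterisation

`beam_quality()` derives `R50` as the distal 50% crossing by linear
interpolation, and the practical range `Rp` by the standard construction:
the tangent at the steepest distal gradient (central differences),
intersected with the extrapolated bremsstrahlung-tail level, estimated as
the mean dose over the last 10% of the grid (configurable). A
non-monotone distal falloff warns and proceeds with the steepest-descent
point. `E0` follows as `2.33 × R50` (R50 in cm).

## What the synthetic generator emulates — and what it does not

The generator stands in for Monte Carlo-scored curves so the entire
pipeline is testable without transport simulations. It emulates their
*statistical structure*: values at voxel centers on a 1 mm grid,
normalized to 100 at the depth of maximum dose, with independent
multiplicative Gaussian noise of relative standard deviation 0.002 per
voxel (the sub-0.2% statistical level typical of well-converged MC
scoring), and a backscatter imprint that is exactly the package's own
model evaluated with known ground-truth coefficients.

The depth-dose shape itself is an invented parametric stand-in, not
physics: a sinusoidal build-up from a surface fraction to the maximum,
times a logistic distal falloff, plus a small constant bremsstrahlung
tail. Its midpoint and width are solved (by a short fixed-point
iteration) so that `beam_quality()` recovers each preset's `R50` and `Rp`
to well within half a voxel — the property the pipeline actually relies
on. Four presets (6/9/12/15 MeV classes) use typical clinical ranges,
with `Rp` placed just beyond the deepest slab position of the standard
simulation schedule (27 + 22 + 20 + 19 = 88 interface depths) so that
every scheduled interface sees a positive mean energy; across presets the
interface energies span ~0.19–14 MeV. The preset values live in
`inst/extdata/beam_presets.json`, not in code.

Consequently, passing tests on synthetic data demonstrate
*self-consistency* of extraction, fitting and prediction — they cannot
validate the two-exponential form against nature. Real MC or measured
curves carry features the generator deliberately omits: voxel-to-voxel
noise correlation, photon contamination, angular and off-axis effects,
energy-spectrum differences between machines, and any mismatch between
the true backscatter physics and the fitted functional form.

```{r}
obs <- synth_observation_set(presets = "12", noise_relative_sd = 0)
fit <- fit_full(obs)
glance(fit)
```

## Numerical choices and degenerate inputs

* `Em` clamps to 0 at and beyond `Rp`; a slab there produces no
  backscatter (no electrons reach it), and `predict_perturbed_pdd()`
  leaves upstream doses unchanged with a warning.
* `k` clamps to 0 above `exp(C6/C5)` MeV (warning); `enhancement_range()`
  refuses a clamped `k` (the range would be infinite).
* `peak_enhancement_energy()` errors on `c2 = c4` (degenerate) and on
  coefficient sets with no interior peak.
* Curve files are written with 17 significant digits and read with a
  correctly rounded parser, so write/read round-trips are bit-exact.
* All randomness flows through explicit seeds (`withr::with_seed`);
  fitting itself uses deterministic restarts and is seed-free.

## Problem sizes

The test suite and the acceptance script run, on one CPU in well under a
minute each: the full 88-pair synthetic observation set (~2,350
observations) for the noise-free recovery and the noisy end-to-end
agreement checks; 200 seeded replicates of the 60-point interface fit for
CI coverage; and five 20-point noise-free profiles for the
decay-regression recovery. These sizes were chosen as the smallest that
exercise every stage at the study's own schedule; the statistics they
produce are computed at run time, never stored.

## Known limitations

* Coefficients are specific to one accelerator family and to lead;
  other shield materials, field sizes or machines require refitting.
* Central-axis, 1-D curves only; no off-axis or 2-D/3-D dose modelling.
* No slab-transmission model (distal dose is zeroed under the saturation
  assumption) and no photon-contamination physics.
* Stage-wise confidence intervals do not propagate between stages, and
  the interface-stage estimator is heavy-tailed at realistic noise.
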