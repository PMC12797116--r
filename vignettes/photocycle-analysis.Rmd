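---
title: "Global lifetime analysis of multi-window TR-IR photocycle data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global lifetime analysis of multi-window TR-IR photocycle data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocyclekit)
```

## The measurement and the model

Time-resolved infrared difference spectroscopy of LOV photoreceptors
produces a matrix $\Delta A(t, \tilde\nu)$: difference absorbance (mOD)
versus pump–probe delay (seconds, here spanning picoseconds to hours) and
wavenumber (cm$^{-1}$, the amide I region around 1600–1760 cm$^{-1}$).
Negative bands (*bleaches*) are dark-state modes depleted by excitation;
positive bands (*transients*) belong to photocycle intermediates.

The photocycle itself is modelled as a unidirectional sequential scheme
with branching losses. Compartment $i$ decays with time constant $\tau_i$;
a fraction $\phi_i \in (0,1]$ of that decay proceeds forward and $1-\phi_i$
returns directly to the ground state. Populations follow the Bateman
closed form implemented in `concentration_profiles()`; a photoproduct that
is stable on the observation window is handled as the $k\to 0$ limit of
the same formula. Excitation is treated as a delta pulse at $t=0$: the
fastest process the model is asked to fit (~2 ns intersystem crossing) is
four orders of magnitude slower than a femtosecond pump, so
instrument-response convolution is deliberately omitted. Reversible steps,
parallel branches and stretched-exponential (dispersive) kinetics are out
of scope — monoexponential steps in a single chain describe these data.

Two numerical choices matter here:

* **Degenerate rates.** The Bateman denominators $(k_l - k_i)$ are
  ill-conditioned for nearly equal time constants.
  `resolve_degenerate_rates()` perturbs the later member of any pair agreeing
  to better than $10^{-9}$ (relative) by $10^{-6}$, keeping the closed form
  within about $10^{-6}$ of the exact confluent solution — verified against
  Runge–Kutta integration in the test suite. We chose perturbation over
  confluent special-case formulas for simplicity; fitted constants this
  degenerate are scientifically meaningless anyway.
* **Ascending $\tau$.** The chain is parameterized as
  $\log\tau_1=\theta_1$, $\log\tau_i=\log\tau_{i-1}+\mathrm{softplus}(\theta_i)$,
  so ordering is structural rather than a constraint; the photocycle is a
  strictly slowing cascade and compartment identity stays unambiguous.

## Variable-projection fitting

`fit_sequential()` minimizes the root-mean-square residual of
$\Delta A = C(\tau)\,S$ over the time constants only: for any candidate
$\tau$ the EADS matrix $S$ (one difference spectrum per compartment) is the
exact linear least-squares solution, computed by QR decomposition in
`solve_eads()`. Eliminating the (large) linear block inside the (tiny)
nonlinear search is what makes global fitting across ~46 wavenumber
channels cheap and reliable.

The nonlinear search is a Nelder–Mead simplex followed by a cyclic
coordinate-wise Brent line search, which sharpens the optimum to machine
precision on noiseless data and certifies convergence (stationarity under
the line search). With `tau_init = "auto"`, a coarse logarithmic grid of
ascending $\tau$ tuples (half-decade steps for up to two constants, decade
steps beyond) seeds the simplex — multiexponential residual surfaces have
local minima, and the grid scan removes the initialization sensitivity we
observed with single-point heuristics.

Branching yields are *not* fitted: in a single bilinear dataset they are
exactly confounded with EADS amplitudes. The fit therefore uses $\phi = 1$
and the yields are recovered afterwards from the EADS themselves (below).

The fits run per instrument window (`fit_windows()`), matching how the
data are recorded; the assumption that no kinetic step falls inside the
acquisition gaps (40 ms–40 ms boundary, 15 s boundary) lets each window be
fitted with the sub-chain of compartments alive there, on the absolute
time axis. The terminal compartment of one window is the decaying head of
the next. An optional spectrally flat component with heating-rise kinetics
$1-e^{-t/\tau_\mathrm{heat}}$ ($\tau_\mathrm{heat}$ = 1 ms default) can be
appended to absorb the unspecific sample-heating offset seen on the
millisecond scale; it is off by default because heating is an artifact,
not a photocycle species. A kinetically *constant* offset would be
unusable here: it is exactly collinear with a population-conserving chain.

`bootstrap_tau()` adds residual-resampling confidence intervals
(residuals resampled with replacement onto the fitted surface, refit,
2.5/97.5 percentiles), with residuals inflated by $\sqrt{N/(N-p)}$ to undo
the shrinkage from the fitted parameters. Residuals are resampled per
*pixel* by default — the nonparametric analogue of the
independent-per-pixel detector noise — because our coverage studies showed
per-row resampling to run measurably below nominal coverage while
per-pixel resampling calibrates; `resample = "rows"` remains available for
data with within-spectrum noise correlation. These intervals are a
convenience of this implementation, not a claim about the original
analysis.

## Data reduction

Three operations mirror the standard reduction chain:

* `stitch_batches()` — replicate batches of one window are matched on
  shared time points, rescaled by the least-squares scalar
  $s = \langle\mathrm{ref},b\rangle/\langle b,b\rangle$ against the growing
  stitched average (reference = earliest-starting batch, ties broken by
  batch id, so the result is input-order invariant), then averaged per
  time point. Only *relative* scales are recoverable; the absolute scale
  of the reference batch remains, as it does in any real measurement.
* `subtract_linear_baseline()` — per spectrum, a straight line through the
  means of the first and last $q=3$ points is removed. "Endpoints" without
  a stated width is ambiguous; $q=3$ averages enough pixels to be robust
  to noise while staying inside the band-free edges of the amide I window.
  The operation is idempotent.
* `svd_rotate()` / `remove_drift_components()` — the slow (minutes–hours)
  window is truncated to its leading $m$ singular triplets and an
  orthogonal rotation, built from pairwise Jacobi 2×2 steps, maximizes
  $\sum_j w_j^2\,\mathrm{AC}_1(u_j)$ (weighted lag-1 autocorrelation of
  the temporal vectors — the Henry–Hofrichter objective). The rank-$m$
  reconstruction is exactly invariant under the rotation, so no signal is
  lost by rotating. A pair is only rotated when the objective gain exceeds
  $10^{-9}$ relative: along flat directions (two equally smooth
  components) the identity is kept, so a drift component already isolated
  by the SVD is not re-mixed.

Drift components are then deleted, either by explicit index or by the
`"auto"` rule: temporal net-displacement/total-variation $\geq 0.5$
(a magnitude-weighted monotonicity measure — $\approx 1$ for a ramp,
$\approx n^{-1/2}$ for noise; a raw count of same-sign differences proved
too fragile near its threshold) *and* spectral correlation with a straight
line in $\tilde\nu$ of $|r| \geq 0.9$. Structured difference spectra fail
the linearity test, noise fails both. **Known limitation:** component
deletion can only remove drift that occupies its own singular direction.
When the drift's time course is strongly collinear with the kinetics
(e.g. a log-linear ramp against a comparable-timescale decay), the SVD
mixes the two and no per-component criterion can separate them; the auto
rule then correctly removes nothing, and the drift must be handled by
measurement design or manual inspection. The test suite constructs its
drift-removal cases in the separable regime (drift factors orthogonalized
against the signal factors) because that is the regime in which the
operation is well-posed.

## Derived quantities

* **Φ_ISC from bleach ratios** (`estimate_isc_yield()`): ground-state
  bleaches measure how many molecules left the ground state, so the ratio
  of bleach intensity in the triplet EADS to the singlet EADS estimates
  the intersystem-crossing yield. Intensity is the trapezoidal integral of
  $\max(0,-\Delta A)$ over fixed bands (defaults 1660–1675 and 1683–1695
  cm$^{-1}$, bracketing the two amide-I ground-state bleaches); integrating
  only negative signal over fixed bands is robust to the transient-band
  differences between the two states, which is why band-shape fitting was
  not used. Estimates above 1.5 trigger an "unphysical" warning.
* **Double differences** (`double_difference()`): construct minus isolated
  domain, after interpolating the second dataset onto the first's grids —
  linear in wavenumber, linear in $\log t$ (the data are log-sampled;
  linear-in-$t$ interpolation would distort early times). The default
  scale is 1 because difference amplitudes per excited molecule are
  directly comparable; bleach-integral scaling is available as an option.
* **Peak picking and shifts** (`pick_peaks()`, `peak_shift()`): local
  extrema above a prominence threshold, refined by three-point parabolic
  interpolation for sub-grid accuracy on the ~4 cm$^{-1}$ detector grid
  (recovers sub-grid shifts to better than 0.3 cm$^{-1}$ in the tests).
  Band-shift measurement requires exactly one extremum of the requested
  sign in the search interval and errs otherwise rather than guessing.
* **Computed spectra** (`scale_wavenumbers()`, `broaden_sticks()`):
  harmonic frequencies from electronic-structure calculations are scaled
  by the empirical factor 0.966 and broadened with 16 cm$^{-1}$ FWHM
  Gaussians whose peak height equals the line intensity — the standard
  post-processing for comparing computed normal modes with measured
  difference spectra. The quantum-chemistry calculations themselves are
  outside this package.

## What the synthetic generator emulates — and what it does not

`preset_truth()` fixes the study conditions. Three presets encode the
published photocycles:

| preset | chain | $\tau$ | $\Phi_\mathrm{ISC}$ |
|---|---|---|---|
| `bslov` | ¹FMN\* → ³FMN\* → A390 → ground | 2 ns, 6.1 µs, 3800 s | 0.65 |
| `yf1`   | ¹FMN\* → ³FMN\* → A390 → ground | 2 ns, 8.7 µs, 3800 s | 0.65 |
| `pal`   | ¹FMN\* → ³FMN\* → A390 → SIG → ground | 3 ns, 8 µs, 3 s, $\sqrt{370\cdot 3800}\approx 1186$ s | 0.75 |

The PAL adduct-formation constant (8 µs) sits inside the published 6–10 µs
range (no PAL-specific value is printed); the yields are the midpoints of
the published per-protein ranges; the dark-recovery default for PAL is the
geometric midpoint of the published 370–3800 s span, while BsLOV/YF1 use
the upper value.

Band tables (`default_band_tables()`) transcribe the published amide-I
inventories per state. The sources fix band *positions and signs* only, so
relative amplitudes are order-one choices and the width defaults to
12 cm$^{-1}$ FWHM, which reproduces the visual overlap of measured EADS.
Two amplitude choices deserve explanation:

* The **triplet row of the ground truth is the unscaled singlet table**
  (species spectra): every excited molecule depletes one ground-state
  molecule, so the species bleach content of ¹FMN\* and ³FMN\* is
  identical. The published "decrease in intensity of all features" of the
  *observed* triplet EADS then emerges from the branching loss in the
  kinetics — and this is precisely what makes the bleach-ratio estimator
  consistent: with a $\phi=1$ fitting chain, the fitted triplet EADS comes
  out scaled by exactly $\Phi_\mathrm{ISC}$. Scaling the species spectrum
  *as well* would double-count the yield. The standalone
  `default_band_tables(..., "T1")` still returns the yield-scaled
  (observed-EADS) table, as its own contract states. The
  `realistic_triplet` flag perturbs the triplet's transient bands (±15%
  amplitude, ±2 cm$^{-1}$ position) to break the exact spectral identity;
  bleach bands are never perturbed, and the perturbation moves the
  integrated bleach by only a few percent.
* The **SIG table's 1640 cm$^{-1}$ transient is weaker (0.3) than its
  A390 counterpart (0.8)**. The published observable is a ~3 cm$^{-1}$
  blue-shift of the 1629 cm$^{-1}$ bleach upon SIG formation. With equal
  neighbor amplitudes, band overlap pulls the observed minimum and
  compresses the apparent shift to ~2.2 cm$^{-1}$; the weaker 1640
  amplitude — unconstrained by the sources — was calibrated once, at
  design time, so the rendered default spectra exhibit the published
  observed shift.

Instrument artifacts (`add_instrument_effects()`) split the simulation at
40 ms and 15 s into the three instrument windows, duplicate each into
batches with lognormal scale jitter ($\sigma$ = 0.05) and fresh pixel
noise (default $\sigma$ = 0.02 mOD, i.e. 2% of the ~1 mOD maximum signal),
add per-spectrum linear baselines to the rapid-scan and static windows
(intercept/slope $\sigma$ = 0.03 mOD), a rank-1 log-time ramp × linear-in-ν
drift (0.1 mOD) to the static window, and a spectrally flat heating offset
rising as $1-e^{-t/1\,\mathrm{ms}}$ (0.05 mOD — the published description
calls the offset "unspecific" and minor, and gives it no shape). Noise
levels and batch-scale variation are not quantified in the sources; these
defaults are the package's calibration of "realistic", chosen once. The
default time grid is log-spaced, $10^{-12}$–$10^{4}$ s at 8 points per
decade (16 decades; the measurements span 15).

Not emulated: shot noise or detector physics, correlated noise,
polarization/anisotropy, instrument response convolution, and
non-monotone drift. Passing recovery tests on this generator therefore
demonstrates correctness of the *analysis chain* under the stated noise
model — not robustness to every pathology of real spectrometers.

## Problem sizes and tolerances

The recovery studies in the tests and the acceptance script use the
default grids (129 time points × 46 wavenumbers, three windows) with 20
noise seeds per preset (10 for the slow window) — sizes chosen so the full
suite completes in minutes on one CPU while leaving the medians' Monte
Carlo error far below the 5–10% recovery tolerances. The bootstrap
coverage study uses a compact two-constant fixture (30 × 6) with 150
resamples per interval at nominal 95%. Key numerical tolerances: Bateman
vs ODE $10^{-8}$; noiseless EADS recovery $10^{-10}$; rotation
orthogonality and reconstruction invariance $10^{-10}$; baseline
idempotence $10^{-12}$; simplex convergence $10^{-6}$ in $\theta$ with at
most 2000 iterations.

## A minimal run

```{r example, eval = FALSE}
truth <- preset_truth("yf1", noise_sigma = 0.02, rng_seed = 42)
sim <- simulate_windows(truth)
windows <- preprocess_windows(sim$batches)
fits <- fit_windows(windows, list(
  run_config(n_compartments = 3, terminal_decays = FALSE),
  run_config(n_compartments = 1, terminal_decays = TRUE),
  run_config(n_compartments = 1, terminal_decays = TRUE)
))
fits[[1]]$scheme_hat$tau     # ~2 ns, ~8.7 us
estimate_isc_yield(fits[[1]]$eads_hat$spectra[1, ],
                   fits[[1]]$eads_hat$spectra[2, ], windows[[1]]$wn)$value
```

## Known limitations

* Drift removal is well-posed only for drift separable from the kinetics
  (see above).
* The sequential chain cannot represent parallel branches, reversible
  steps, or dispersive kinetics; `fit_sequential` will still return its
  best sequential approximation, so model adequacy must be judged from
  the residual matrix.
* The number of compartments per window is a user decision; an automatic
  model-order choice is intentionally not provided (inspect rmse vs n and
  the EADS).
* Yield estimation assumes the chosen bleach bands contain ground-state
  depletion only; strongly overlapping transients inside the bands bias
  the ratio.
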