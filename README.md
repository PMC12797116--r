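# photocyclekit

Global lifetime analysis of time-resolved infrared (TR-IR) difference
spectroscopy for LOV-domain photoreceptor proteins.

Blue-light LOV photoreceptors run a photocycle that spans fifteen decades in
time: the flavin chromophore (FMN) is excited to its singlet state
(¹FMN\*), crosses to the triplet (³FMN\*) in ~2 ns, forms a cysteinyl
thioadduct (A390) in microseconds, may relax further to a metastable
signaling state (SIG) on the seconds scale, and finally recovers the
dark-adapted ground state over minutes to hours. TR-IR difference spectra in
the amide I region (~1600–1760 cm⁻¹) watch every one of these steps at once
— if you can stitch together data from three different instruments, remove
their baselines and drifts, and fit a kinetic model globally across the
whole wavenumber axis. `photocyclekit` implements that entire chain for
people analyzing (or simulating) such measurements.

## The model

The photocycle is a unidirectional sequential scheme with branching losses,

```
c1 --(phi_1 / tau_1)--> c2 --(phi_2 / tau_2)--> ... --> ground
```

whose populations have the closed Bateman form

    c_1(t) = exp(-k_1 t),
    c_j(t) = (prod_{i<j} phi_i k_i) * sum_{i<=j} exp(-k_i t) / prod_{l!=i} (k_l - k_i)

with rates `k_i = 1/tau_i` and forward yields `phi_i` (the fraction of each
decay that proceeds along the cycle; `1 - phi_i` returns directly to the
ground state — `phi_1` is the intersystem-crossing quantum yield Φ_ISC). The
measured difference-absorbance matrix is bilinear in populations and
spectra, `ΔA(t, ν) = C(τ, φ) · S`, and fitting is by **variable
projection**: a derivative-free simplex searches the time constants while
the evolution-associated difference spectra (EADS) `S` are solved linearly
by QR decomposition at every step. Ascending τ is built into the
parameterization (`log τ_i = log τ_{i-1} + softplus(θ_i)`), matching the
strictly slowing cascade of the photocycle.

Around the fit, the package provides the standard reduction chain for
multi-window measurements — overlap-scaled batch stitching, per-spectrum
linear baseline subtraction, and Henry–Hofrichter rotated-SVD deletion of
slow baseline drifts — plus the derived-quantity estimators: Φ_ISC from
EADS bleach-band ratios, construct-minus-domain double-difference spectra,
sub-grid peak picking and band-shift measurement, and Gaussian broadening /
empirical frequency scaling of computed stick spectra.

A first-class synthetic generator (`preset_truth()`, `simulate_windows()`)
produces TR-IR datasets with the band structures, time constants,
instrument windows (gaps at 40 ms and 15 s), batch-scale jitter, baselines,
drifts, heating offsets and pixel noise of real measurements, so every
pipeline stage is testable by parameter recovery.

## Worked example

Simulate a YF1-like measurement (ISC in 2 ns with yield 0.65, adduct
formation in 8.7 µs, dark recovery in 3800 s; 2% pixel noise plus the full
instrument-artifact set), reduce it, and fit each instrument window:

```r
library(photocyclekit)

truth <- preset_truth("yf1", noise_sigma = 0.02, rng_seed = 42)
sim <- simulate_windows(truth)              # 3 windows x 2 batches
windows <- preprocess_windows(sim$batches)  # stitch + baseline + de-drift

fits <- fit_windows(windows, list(
  run_config(n_compartments = 3, terminal_decays = FALSE),  # ps-40 ms
  run_config(n_compartments = 1, terminal_decays = TRUE),   # 40 ms-15 s
  run_config(n_compartments = 1, terminal_decays = TRUE)    # 15 s-hours
))
fits[[1]]
#> <fit_result> 2 time constants, rmse 0.01782 mOD, converged
#>   tau_hat [s]: 2.0555e-09, 8.9116e-06
fits[[3]]
#> <fit_result> 1 time constants, rmse 0.01144 mOD, converged
#>   tau_hat [s]: 3820.4

estimate_isc_yield(fits[[1]]$eads_hat$spectra[1, ],
                   fits[[1]]$eads_hat$spectra[2, ], windows[[1]]$wn)
#> <quantum_yield> Phi_ISC estimate = 0.6493
```

The fast window recovers the singlet decay (2.06 ns vs the generating
2 ns) and the adduct-formation constant (8.91 µs vs 8.7 µs, ~2% high under
this noise realization); the slow window recovers the dark recovery
(3820 s vs 3800 s); and the bleach-ratio estimator returns the generating
intersystem-crossing yield (0.649 vs 0.65) because ground-state bleaches
measure exactly the population that left the ground state.

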