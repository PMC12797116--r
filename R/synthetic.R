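#' Default wavenumber and time grids for simulated measurements
#'
#' The wavenumber grid covers the amide I region at the instrument's ~4
#' cm\eqn{^{-1}} per-pixel resolution; the time grid is logarithmically
#' spaced from 1 ps to 10^4 s (16 decades), matching the multi-decade
#' sampling of a pump--probe + rapid-scan + static-cell measurement chain.
#'
#' @param from,to,by wavenumber range and spacing in cm\eqn{^{-1}}.
#' @return numeric axis vector.
#' @export
default_wavenumber_axis <- function(from = 1580, to = 1760, by = 4) {
  seq(from, to, by = by)
}

#' @rdname default_wavenumber_axis
#' @param t_min,t_max time range in seconds.
#' @param per_decade log-spaced samples per decade.
#' @export
default_time_grid <- function(t_min = 1e-12, t_max = 1e4, per_decade = 8) {
  n <- round(log10(t_max / t_min) * per_decade) + 1
  10^seq(log10(t_min), log10(t_max), length.out = n)
}

#' Build a difference spectrum from a Gaussian band inventory
#'
#' Difference spectra in the amide I region are modelled as sums of Gaussian
#' bands: positive amplitudes are transients (newly populated modes),
#' negative amplitudes are bleaches (depleted dark-state modes).
#'
#' @param bands data frame with columns \code{center} (cm\eqn{^{-1}}),
#'   \code{amplitude} (signed, mOD) and \code{fwhm} (cm\eqn{^{-1}}, > 0).
#' @param wn wavenumber axis.
#' @return numeric spectrum vector on \code{wn}, in mOD.
#' @export
make_eads_from_bands <- function(bands, wn) {
  bands <- as.data.frame(bands)
  stopifnot(nrow(bands) >= 1, all(c("center", "amplitude", "fwhm") %in%
                                    names(bands)))
  if (any(bands$fwhm <= 0)) stop("band fwhm must be > 0", call. = FALSE)
  spec <- numeric(length(wn))
  for (i in seq_len(nrow(bands))) {
    sigma <- bands$fwhm[i] / (2 * sqrt(2 * log(2)))
    spec <- spec + bands$amplitude[i] *
      exp(-(wn - bands$center[i])^2 / (2 * sigma^2))
  }
  spec
}

#' Amide-I band inventories of the photocycle intermediates
#'
#' Hard-coded Gaussian band tables for the difference spectra of the singlet
#' (S1) and triplet (T1) excited flavin, the cysteinyl adduct (A390) and,
#' for PAL, the late signaling state (SIG), for the three studied systems:
#' the isolated Bacillus subtilis LOV domain (BsLOV), the engineered
#' LOV--histidine-kinase fusion YF1, and the natural PAS--ANTAR--LOV receptor
#' PAL. Band positions are the published amide-I inventories; relative
#' amplitudes are order-one values with the published signs (the source data
#' fix positions and signs, not absolute intensities), and the default width
#' of 12 cm\eqn{^{-1}} FWHM reproduces the visual band overlap of measured
#' EADS. The T1 table is the S1 table with all amplitudes scaled by the
#' triplet yield: in the amide I region the singlet-to-triplet transition
#' appears chiefly as a uniform intensity decrease.
#'
#' @param protein one of \code{"BsLOV"}, \code{"YF1"}, \code{"PAL"}
#'   (case-insensitive).
#' @param state one of \code{"S1"}, \code{"T1"}, \code{"A390"}, \code{"SIG"}
#'   (SIG exists only for PAL).
#' @param triplet_yield scale factor applied for \code{state = "T1"}
#'   (the intersystem-crossing quantum yield of the preset).
#' @param fwhm default band width in cm\eqn{^{-1}}.
#' @return data frame with columns \code{center}, \code{amplitude},
#'   \code{fwhm}.
#' @export
default_band_tables <- function(protein, state, triplet_yield = 0.65,
                                fwhm = 12) {
  protein <- toupper(protein)
  protein <- match.arg(protein, c("BSLOV", "YF1", "PAL"))
  state <- match.arg(toupper(state), c("S1", "T1", "A390", "SIG"))
  band <- function(center, amplitude, width = fwhm) {
    data.frame(center = center, amplitude = amplitude, fwhm = width)
  }
  s1_bslov <- rbind(
    band(1613, 1), band(1631, 1), band(1650, 0.45),      # transients+shoulder
    band(1667, -1, 2 * fwhm),                            # broad bleach
    band(1688, -0.4), band(1700, -0.35)                  # minor bleaches
  )
  # PAL singlet: transients/shoulder/broad bleach blue-shifted by ~6 cm^-1,
  # 1688 bleach unaltered, highest bleach blue-shifted by ~20 cm^-1
  s1_pal <- rbind(
    band(1619, 1), band(1637, 1), band(1656, 0.45),
    band(1674, -1, 2 * fwhm),
    band(1688, -0.4), band(1720, -0.35)
  )
  tbl <- switch(
    paste(protein, state, sep = "."),
    "BSLOV.S1" = s1_bslov,
    "YF1.S1"   = s1_bslov,
    "PAL.S1"   = s1_pal,
    "BSLOV.A390" = rbind(
      band(1620, 0.9), band(1630, 0.4), band(1664, 1), band(1677, 0.8),
      band(1718, 0.5), band(1642, -0.6), band(1693, -1)
    ),
    "YF1.A390" = rbind(
      band(1620, 0.9), band(1664, 1), band(1677, 0.8), band(1718, 0.5),
      band(1630, -0.7), band(1642, -0.25), band(1690, -1)
    ),
    "PAL.A390" = rbind(
      band(1614, 0.7), band(1640, 0.8), band(1657, 0.9), band(1693, 0.7),
      band(1723, 0.5),
      band(1629, -1), band(1664, -0.9), band(1685, -0.8)
    ),
    # SIG: 1629 bleach blue-shifted by 3 cm^-1, the 1657 transient bleached
    # away, and a new transient formed at 1677. The weaker 1640 amplitude is
    # calibrated so the rendered spectra reproduce the *observed* ~3 cm^-1
    # shift of the bleach minimum despite band overlap.
    "PAL.SIG" = rbind(
      band(1614, 0.7), band(1640, 0.3), band(1677, 0.7), band(1693, 0.7),
      band(1723, 0.5),
      band(1632, -1), band(1664, -0.9), band(1685, -0.8)
    )
  )
  if (is.null(tbl)) {
    if (state == "T1") {
      tbl <- default_band_tables(protein, "S1", fwhm = fwhm)
      tbl$amplitude <- tbl$amplitude * triplet_yield
    } else {
      stop("no band table for ", protein, " in state ", state, call. = FALSE)
    }
  }
  tbl
}

#' Ground-truth parameter sets for the synthetic generator
#'
#' Bundles everything that determines a simulated measurement: the kinetic
#' scheme, the true per-compartment difference spectra (EADS), the noise
#' level and the instrument-artifact amplitudes, plus the seed. Presets:
#' \describe{
#'   \item{bslov}{S1 -> T1 -> A390 -> ground; tau = 2 ns, 6.1 us, 3800 s;
#'     ISC yield 0.65.}
#'   \item{yf1}{S1 -> T1 -> A390 -> ground; tau = 2 ns, 8.7 us, 3800 s;
#'     ISC yield 0.65.}
#'   \item{pal}{S1 -> T1 -> A390 -> SIG -> ground; tau = 3 ns, 8 us, 3 s,
#'     sqrt(370 x 3800) ~ 1185.8 s; ISC yield 0.75.}
#' }
#' Time constants and yields are the published photocycle values (the PAL
#' adduct-formation constant sits inside the published 6--10 us range; the
#' dark-recovery default is the geometric midpoint of the published
#' 370--3800 s span, except for BsLOV/YF1 where the upper value is used).
#'
#' @param preset \code{"bslov"}, \code{"yf1"} or \code{"pal"}.
#' @param wn wavenumber axis the true EADS are rendered on.
#' @param noise_sigma i.i.d. Gaussian noise level in mOD per (t, wn) pixel.
#' @param rng_seed integer seed; the simulation is bit-reproducible given it.
#' @param realistic_triplet when TRUE the triplet EADS is not an exact scaled
#'   copy of the singlet EADS: its transient (positive) bands get seeded
#'   random amplitude (±15\%) and position (±2 cm\eqn{^{-1}}) perturbations,
#'   emulating the real spectral differences between the states. Bleach bands
#'   are never perturbed, so bleach-ratio yield estimation stays meaningful.
#' @param sigma_scale lognormal sd of the per-batch multiplicative scale
#'   jitter ("slight variations between batches").
#' @param baseline_sigma sd (mOD) of per-spectrum linear-baseline intercept
#'   and slope in the rapid-scan and static windows.
#' @param drift_amplitude amplitude (mOD) of the slow rank-1 baseline drift
#'   added to the minutes-to-hours window.
#' @param heating_amplitude amplitude (mOD) of the spectrally flat heating
#'   offset; 0 disables it.
#' @param tau_heat rise time (s) of the heating offset,
#'   \eqn{1 - e^{-t/\tau}}.
#' @param fwhm band width passed to [default_band_tables()].
#' @return An object of class \code{"ground_truth"} with elements
#'   \code{scheme}, \code{eads_true} (compartments x wavenumbers),
#'   \code{wn}, \code{states}, \code{protein} and the artifact parameters.
#' @export
preset_truth <- function(preset = c("bslov", "yf1", "pal"),
                         wn = default_wavenumber_axis(),
                         noise_sigma = 0.02,
                         rng_seed = 1L,
                         realistic_triplet = FALSE,
                         sigma_scale = 0.05,
                         baseline_sigma = 0.03,
                         drift_amplitude = 0.1,
                         heating_amplitude = 0.05,
                         tau_heat = 1e-3,
                         fwhm = 12) {
  preset <- match.arg(preset)
  spec_of <- function(protein, state, yield) {
    make_eads_from_bands(default_band_tables(protein, state,
                                             triplet_yield = yield,
                                             fwhm = fwhm), wn)
  }
  if (preset == "pal") {
    protein <- "PAL"
    phi_isc <- 0.75
    scheme <- kinetic_scheme(
      tau = c(3e-9, 8e-6, 3, sqrt(370 * 3800)),
      phi = c(phi_isc, 1, 1),
      names = c("1FMN*", "3FMN*", "A390", "SIG"),
      terminal_decays = TRUE
    )
    states <- c("S1", "T1", "A390", "SIG")
  } else {
    protein <- if (preset == "yf1") "YF1" else "BsLOV"
    phi_isc <- 0.65
    scheme <- kinetic_scheme(
      tau = c(2e-9, if (preset == "yf1") 8.7e-6 else 6.1e-6, 3800),
      phi = c(phi_isc, 1),
      names = c("1FMN*", "3FMN*", "A390"),
      terminal_decays = TRUE
    )
    states <- c("S1", "T1", "A390")
  }
  # True spectra are *species* spectra: the triplet row reuses the singlet
  # band table unscaled (every excited molecule depletes one ground-state
  # molecule, so the species bleach content is identical). The published
  # "decrease in intensity of all features" of the observed triplet EADS then
  # emerges from the branching loss in the kinetics, which is exactly what
  # makes the bleach-ratio yield estimator consistent.
  eads <- t(vapply(states, function(st) {
    spec_of(protein, if (st == "T1") "S1" else st, phi_isc)
  }, numeric(length(wn))))
  if (realistic_triplet) {
    tbl <- default_band_tables(protein, "S1", fwhm = fwhm)
    set.seed(as.integer(rng_seed %% .Machine$integer.max))
    pos <- tbl$amplitude > 0
    tbl$amplitude[pos] <- tbl$amplitude[pos] *
      (1 + stats::runif(sum(pos), -0.15, 0.15))
    tbl$center[pos] <- tbl$center[pos] + stats::runif(sum(pos), -2, 2)
    eads[2, ] <- make_eads_from_bands(tbl, wn)
  }
  rownames(eads) <- scheme$names
  structure(
    list(scheme = scheme, eads_true = eads, wn = wn, states = states,
         protein = protein, phi_isc = phi_isc,
         noise_sigma = noise_sigma, sigma_scale = sigma_scale,
         baseline_sigma = baseline_sigma, drift_amplitude = drift_amplitude,
         heating_amplitude = heating_amplitude, tau_heat = tau_heat,
         rng_seed = as.integer(rng_seed)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> preset ", x$protein, ", seed ", x$rng_seed, "\n",
      sep = "")
  print(x$scheme)
  cat("  noise sigma ", x$noise_sigma, " mOD; heating ", x$heating_amplitude,
      " mOD\n", sep = "")
  invisible(x)
}

#' Simulate a clean or noisy photocycle measurement
#'
#' Forward model of the measurement: the difference-absorbance matrix is the
#' bilinear product of the sequential-model concentration profiles with the
#' true EADS, \eqn{\Delta A = C(\tau, \phi)\, S}, plus (optionally) i.i.d.
#' Gaussian pixel noise. Deterministic given \code{truth$rng_seed}.
#'
#' @param truth a [preset_truth()] object.
#' @param t time axis in seconds (default [default_time_grid()]).
#' @param noise logical; add Gaussian noise of sd \code{truth$noise_sigma}?
#' @return A [spectral_dataset()] spanning the full time grid.
#' @export
simulate_photocycle <- function(truth, t = default_time_grid(),
                                noise = TRUE) {
  stopifnot(inherits(truth, "ground_truth"))
  cmat <- concentration_profiles(truth$scheme, t)
  if (ncol(cmat) != nrow(truth$eads_true)) {
    stop("scheme has ", ncol(cmat), " compartments but eads_true has ",
         nrow(truth$eads_true), " rows", call. = FALSE)
  }
  dA <- cmat %*% truth$eads_true
  if (noise && truth$noise_sigma > 0) {
    set.seed(truth$rng_seed)
    dA <- dA + matrix(stats::rnorm(length(dA), sd = truth$noise_sigma),
                      nrow = nrow(dA))
  }
  pk_log("simulate_photocycle: %d x %d, max|dA| = %.3f mOD", nrow(dA),
         ncol(dA), max(abs(dA)))
  spectral_dataset(truth$wn, t, dA, window_id = "full", batch_id = "truth")
}

#' Split a simulation into instrument windows and add measurement artifacts
#'
#' Emulates the three-instrument measurement chain: the time axis is split at
#' 40 ms (pump--probe vs rapid-scan FTIR) and 15 s (rapid-scan vs static
#' cell). Each window is duplicated into \code{n_batches} batches which each
#' receive an independent multiplicative scale jitter (lognormal,
#' \code{truth$sigma_scale}) and fresh Gaussian pixel noise
#' (\code{truth$noise_sigma}). Windows 2 and 3 additionally get per-spectrum
#' linear baselines; window 3 gets a slow rank-1 drift (monotone in time,
#' linear in wavenumber); and a spectrally flat heating offset rising as
#' \eqn{1 - e^{-t/\tau_{heat}}} is added everywhere when
#' \code{truth$heating_amplitude > 0}. The input should be a noiseless
#' simulation (\code{simulate_photocycle(truth, noise = FALSE)}); noise is
#' drawn here, independently per batch.
#'
#' @param ds full-time-range [spectral_dataset()].
#' @param truth the [preset_truth()] that generated \code{ds}.
#' @param n_batches batches per window (>= 1).
#' @return List of [spectral_dataset()] objects, window ids \code{w1, w2,
#'   w3}, batch ids \code{b1, b2, ...}.
#' @export
add_instrument_effects <- function(ds, truth, n_batches = 2) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(truth, "ground_truth"))
  bounds <- c(0.04, 15)
  win_of <- findInterval(ds$t, bounds) + 1L  # 1, 2, 3
  wn <- ds$wn
  nu <- (wn - mean(wn)) / (diff(range(wn)) / 2)  # normalized [-1, 1]
  out <- list()
  set.seed(truth$rng_seed + 1L)
  for (w in sort(unique(win_of))) {
    rows <- which(win_of == w)
    tw <- ds$t[rows]
    base <- ds$dA[rows, , drop = FALSE]
    if (truth$heating_amplitude > 0) {
      heat <- truth$heating_amplitude * (1 - exp(-tw / truth$tau_heat))
      base <- base + heat %o% rep(1, length(wn))
    }
    for (b in seq_len(n_batches)) {
      m <- base
      if (w >= 2 && truth$baseline_sigma > 0) {
        a0 <- stats::rnorm(length(tw), sd = truth$baseline_sigma)
        b0 <- stats::rnorm(length(tw), sd = truth$baseline_sigma)
        m <- m + a0 %o% rep(1, length(wn)) + b0 %o% nu
      }
      if (w == 3 && truth$drift_amplitude > 0) {
        trend <- log(tw / min(tw)) / log(max(tw) / min(tw))
        m <- m + truth$drift_amplitude * trend %o% nu
      }
      scale <- exp(stats::rnorm(1, sd = truth$sigma_scale))
      m <- m * scale
      if (truth$noise_sigma > 0) {
        m <- m + matrix(stats::rnorm(length(m), sd = truth$noise_sigma),
                        nrow = nrow(m))
      }
      out[[length(out) + 1L]] <- spectral_dataset(
        wn, tw, m, window_id = paste0("w", w), batch_id = paste0("b", b),
        meta = list(scale_true = scale)
      )
    }
  }
  pk_log("add_instrument_effects: %d windows x %d batches",
         length(unique(win_of)), n_batches)
  out
}

#' One-call simulation of a full multi-window measurement
#'
#' Convenience wrapper: noiseless forward model, then
#' [add_instrument_effects()].
#'
#' @inheritParams add_instrument_effects
#' @inheritParams simulate_photocycle
#' @return list with elements \code{truth}, \code{clean} (noiseless
#'   full-range dataset) and \code{batches} (per-window batch list).
#' @export
simulate_windows <- function(truth, t = default_time_grid(), n_batches = 2) {
  clean <- simulate_photocycle(truth, t, noise = FALSE)
  list(truth = truth, clean = clean,
       batches = add_instrument_effects(clean, truth, n_batches = n_batches))
}
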