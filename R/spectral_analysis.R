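#' Bleach-ratio estimate of the intersystem-crossing quantum yield
#'
#' The ground-state bleaches measure how much dark-state population is
#' missing, so the ratio of bleach intensity in the triplet EADS to that in
#' the singlet EADS estimates the fraction of excited molecules that crossed
#' to the triplet, \eqn{\Phi_{ISC}}. Bleach intensity is quantified as the
#' trapezoidal integral of the negative-going signal,
#' \eqn{\int \max(0, -\Delta A)\, d\tilde\nu}, over fixed bleach bands —
#' robust against the transient-band differences between the two states,
#' which fall outside the bands.
#'
#' @param eads_singlet,eads_triplet spectra (mOD) on \code{wn}.
#' @param wn wavenumber axis.
#' @param bands list of \code{c(low, high)} intervals in cm\eqn{^{-1}};
#'   default [default_bleach_bands()].
#' @return An object of class \code{"quantum_yield"}: list with
#'   \code{value}, \code{bands_used}, \code{bleach_singlet},
#'   \code{bleach_triplet} (mOD cm\eqn{^{-1}}). A value above 1.5 triggers a
#'   warning (unphysical ratio).
#' @export
estimate_isc_yield <- function(eads_singlet, eads_triplet, wn,
                               bands = default_bleach_bands()) {
  stopifnot(length(eads_singlet) == length(wn),
            length(eads_triplet) == length(wn))
  bs <- bleach_integral(eads_singlet, wn, bands)
  bt <- bleach_integral(eads_triplet, wn, bands)
  if (bs == 0) stop("singlet bleach integral is zero over the given bands",
                    call. = FALSE)
  phi <- bt / bs
  if (phi > 1.5) {
    warning("bleach ratio ", format(phi, digits = 3),
            " > 1.5: unphysical quantum-yield estimate", call. = FALSE)
  }
  pk_log("estimate_isc_yield: phi = %.4f (triplet %.4g / singlet %.4g)",
         phi, bt, bs)
  structure(
    list(value = phi, bands_used = bands, bleach_singlet = bs,
         bleach_triplet = bt),
    class = "quantum_yield"
  )
}

#' @export
print.quantum_yield <- function(x, ...) {
  cat("<quantum_yield> Phi_ISC estimate = ", format(x$value, digits = 4),
      "\n", sep = "")
  invisible(x)
}

# trapezoidal integral of max(0, -spec) over the union of wavenumber bands
bleach_integral <- function(spec, wn, bands) {
  inside <- Reduce(`|`, lapply(bands, function(b) wn >= b[1] & wn <= b[2]))
  if (!any(inside)) stop("no wavenumber points inside the bleach bands",
                         call. = FALSE)
  y <- pmax(0, -spec)
  y[!inside] <- 0
  trapz_int(wn, y)
}

trapz_int <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Construct-minus-domain double-difference dataset
#'
#' Subtracts a second difference-spectroscopy dataset from a first,
#' isolating the contribution absent from the second (e.g. a full construct
#' minus its isolated photosensor domain leaves the effector-domain
#' response). \code{b} is interpolated onto \code{a}'s grids — linear in
#' wavenumber and linear in log-time, appropriate for log-sampled kinetics —
#' and the result is restricted to the overlapping axis ranges.
#'
#' @param a,b [spectral_dataset()] objects.
#' @param scale scalar multiplier for \code{b}, or \code{"bleach"} to match
#'   the earliest-time bleach integrals over \code{bands}. The default 1
#'   reflects that difference amplitudes per excited molecule are directly
#'   comparable when measurement conditions match.
#' @param bands bleach bands for \code{scale = "bleach"}.
#' @return A [spectral_dataset()] holding \eqn{a - s\,b} on the overlap.
#' @export
double_difference <- function(a, b, scale = 1,
                              bands = default_bleach_bands()) {
  stopifnot(inherits(a, "spectral_dataset"), inherits(b, "spectral_dataset"))
  wn_keep <- a$wn >= min(b$wn) & a$wn <= max(b$wn)
  t_keep <- a$t >= min(b$t) & a$t <= max(b$t)
  if (!any(wn_keep) || !any(t_keep)) {
    stop("datasets have no overlapping axis range", call. = FALSE)
  }
  wn <- a$wn[wn_keep]
  tt <- a$t[t_keep]
  b_interp <- interp_grid(b, wn, tt)
  a_block <- a$dA[t_keep, wn_keep, drop = FALSE]
  s <- if (identical(scale, "bleach")) {
    ba <- bleach_integral(a_block[1, ], wn, bands)
    bb <- bleach_integral(b_interp[1, ], wn, bands)
    if (bb == 0) stop("cannot bleach-scale: zero bleach in b", call. = FALSE)
    ba / bb
  } else {
    as.numeric(scale)
  }
  pk_log("double_difference: overlap %d x %d, scale = %.4g", length(tt),
         length(wn), s)
  spectral_dataset(wn, tt, a_block - s * b_interp,
                   window_id = a$window_id,
                   batch_id = paste0(a$batch_id, "-minus-", b$batch_id),
                   meta = list(scale = s))
}

# bilinear interpolation: linear in wavenumber, linear in log10(t)
interp_grid <- function(ds, wn_out, t_out) {
  step1 <- t(apply(ds$dA, 1, function(row) {
    stats::approx(ds$wn, row, xout = wn_out, rule = 2)$y
  }))
  if (length(wn_out) == 1) step1 <- matrix(step1, ncol = 1)
  out <- apply(step1, 2, function(col) {
    stats::approx(log10(ds$t), col, xout = log10(t_out), rule = 2)$y
  })
  matrix(out, nrow = length(t_out), ncol = length(wn_out))
}

#' Locate bands in a difference spectrum
#'
#' Finds local extrema with absolute amplitude at least
#' \code{min_prominence} and refines each center by three-point parabolic
#' interpolation, giving sub-grid accuracy on the ~4 cm\eqn{^{-1}} detector
#' grid. Minima with negative value are reported as bleaches, maxima with
#' positive value as transients.
#'
#' @param spectrum numeric vector on \code{wn}.
#' @param wn wavenumber axis (>= 3 points).
#' @param min_prominence amplitude threshold in mOD (default 0).
#' @return data frame with columns \code{center} (cm\eqn{^{-1}}),
#'   \code{amplitude} (mOD, signed) and \code{sign} (\code{"bleach"} or
#'   \code{"transient"}); zero rows when nothing qualifies.
#' @export
pick_peaks <- function(spectrum, wn, min_prominence = 0) {
  stopifnot(length(spectrum) == length(wn), length(wn) >= 3)
  out <- data.frame(center = numeric(0), amplitude = numeric(0),
                    sign = character(0))
  for (i in 2:(length(wn) - 1)) {
    y0 <- spectrum[i]
    # left-strict comparison so a band centered exactly between two grid
    # points (equal-value pair) is still picked up, exactly once
    is_max <- y0 > spectrum[i - 1] && y0 >= spectrum[i + 1] && y0 > 0
    is_min <- y0 < spectrum[i - 1] && y0 <= spectrum[i + 1] && y0 < 0
    if (!is_max && !is_min) next
    if (abs(y0) < min_prominence) next
    ref <- parabolic_vertex(wn[(i - 1):(i + 1)], spectrum[(i - 1):(i + 1)])
    out <- rbind(out, data.frame(
      center = ref$x, amplitude = ref$y,
      sign = if (is_min) "bleach" else "transient"
    ))
  }
  out[order(out$center), , drop = FALSE]
}

# vertex of the parabola through three (x, y) points (x need not be uniform)
parabolic_vertex <- function(x, y) {
  X <- cbind(1, x - x[2], (x - x[2])^2)
  ab <- solve(X, y)
  if (ab[3] == 0) return(list(x = x[2], y = y[2]))
  xv <- -ab[2] / (2 * ab[3])
  list(x = x[2] + xv, y = ab[1] + ab[2] * xv + ab[3] * xv^2)
}

#' Measure a band shift between two spectra
#'
#' Compares the parabolic-refined center of one band between two spectra.
#' Exactly one extremum of the requested sign must fall inside \code{band}
#' in each spectrum; positive return values are blue-shifts (toward higher
#' wavenumber).
#'
#' @param spec_a,spec_b spectra on \code{wn} (\code{a} = earlier state).
#' @param wn wavenumber axis.
#' @param band \code{c(low, high)} interval in cm\eqn{^{-1}}.
#' @param sign \code{"bleach"}, \code{"transient"}, or \code{"any"}.
#' @param min_prominence passed to [pick_peaks()].
#' @return shift in cm\eqn{^{-1}} (center of \code{b} minus center of
#'   \code{a}).
#' @export
peak_shift <- function(spec_a, spec_b, wn, band,
                       sign = c("any", "bleach", "transient"),
                       min_prominence = 0) {
  sign <- match.arg(sign)
  center_of <- function(spec, which_spec) {
    pk <- pick_peaks(spec, wn, min_prominence)
    pk <- pk[pk$center >= band[1] & pk$center <= band[2], , drop = FALSE]
    if (sign != "any") pk <- pk[pk$sign == sign, , drop = FALSE]
    if (nrow(pk) != 1) {
      stop("ambiguous band: spectrum ", which_spec, " has ", nrow(pk),
           if (sign == "any") " extrema" else paste0(" ", sign, " extrema"),
           " in [", band[1], ", ", band[2], "] cm^-1 (need exactly 1)",
           call. = FALSE)
    }
    pk$center
  }
  center_of(spec_b, "b") - center_of(spec_a, "a")
}

#' Stick spectra from vibrational-frequency calculations
#'
#' A stick spectrum is the raw output of a normal-mode calculation: discrete
#' (wavenumber, intensity) lines awaiting empirical-scaling and broadening
#' before comparison with measured spectra.
#'
#' @param wavenumber positive line positions in cm\eqn{^{-1}}.
#' @param intensity non-negative intensities (arbitrary units).
#' @return An object of class \code{"stick_spectrum"}.
#' @export
stick_spectrum <- function(wavenumber, intensity) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  stopifnot(length(wavenumber) == length(intensity))
  if (any(wavenumber <= 0)) stop("line wavenumbers must be positive",
                                 call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  ord <- order(wavenumber)
  structure(
    list(wavenumber = wavenumber[ord], intensity = intensity[ord]),
    class = "stick_spectrum"
  )
}

#' Read a stick spectrum from two-column delimited text
#'
#' Columns: wavenumber (cm\eqn{^{-1}}), intensity; \code{#} starts a
#' comment. Whitespace or comma separated.
#' @param path file path.
#' @return A [stick_spectrum()].
#' @export
read_stick_spectrum <- function(path) {
  tab <- utils::read.table(path, comment.char = "#", sep = "",
                           col.names = c("wavenumber", "intensity"))
  stick_spectrum(tab$wavenumber, tab$intensity)
}

#' Apply an empirical frequency-scaling factor
#'
#' Harmonic frequencies from electronic-structure calculations
#' systematically overestimate observed fundamentals; multiplying the
#' wavenumber axis by an empirical factor (0.966 for the B3LYP/6-311G*
#' level used here) corrects for this. Intensities are unchanged and line
#' ordering is preserved.
#'
#' @param s a [stick_spectrum()].
#' @param alpha positive scale factor.
#' @return scaled [stick_spectrum()].
#' @export
scale_wavenumbers <- function(s, alpha = 0.966) {
  stopifnot(inherits(s, "stick_spectrum"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    stop("alpha must be a positive scalar", call. = FALSE)
  }
  stick_spectrum(s$wavenumber * alpha, s$intensity)
}

#' Broaden a stick spectrum into a continuous IR spectrum
#'
#' Convolves the lines with a Gaussian of fixed FWHM (default 16
#' cm\eqn{^{-1}}): each line becomes a Gaussian whose peak height equals the
#' line intensity. An empty stick list yields the zero spectrum.
#'
#' @param s a [stick_spectrum()].
#' @param wn output wavenumber axis.
#' @param fwhm Gaussian full width at half maximum in cm\eqn{^{-1}}.
#' @return numeric spectrum on \code{wn}.
#' @export
broaden_sticks <- function(s, wn, fwhm = 16) {
  stopifnot(inherits(s, "stick_spectrum"))
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  if (length(s$wavenumber) == 0) return(numeric(length(wn)))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  spec <- numeric(length(wn))
  for (i in seq_along(s$wavenumber)) {
    spec <- spec + s$intensity[i] *
      exp(-(wn - s$wavenumber[i])^2 / (2 * sigma^2))
  }
  spec
}
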