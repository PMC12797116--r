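test_that("EADS are recovered exactly from exact bilinear data", {
  wn <- default_wavenumber_axis()
  t <- 10^seq(-6, 1, length.out = 40)
  sc <- kinetic_scheme(tau = c(1e-4, 1e-1), terminal_decays = FALSE,
                       names = c("a", "b", "c"))
  s0 <- rbind(make_eads_from_bands(data.frame(center = 1640, amplitude = 1,
                                              fwhm = 12), wn),
              make_eads_from_bands(data.frame(center = 1660, amplitude = -1,
                                              fwhm = 12), wn),
              make_eads_from_bands(data.frame(center = 1690, amplitude = 0.5,
                                              fwhm = 12), wn))
  cmat <- concentration_profiles(sc, t)
  ds <- spectral_dataset(wn, t, cmat %*% s0)
  fit <- solve_eads(ds, sc)
  expect_lt(max(abs(fit$spectra - s0)), 1e-10)
  # single compartment: one decay times one spectrum
  sc1 <- kinetic_scheme(tau = 1e-3, names = "only")
  c1 <- concentration_profiles(sc1, t)
  ds1 <- spectral_dataset(wn, t, c1 %*% s0[1, , drop = FALSE])
  expect_lt(max(abs(solve_eads(ds1, sc1)$spectra - s0[1, ])), 1e-12)
})

test_that("EADS error shrinks with the noise level", {
  wn <- default_wavenumber_axis()
  t <- 10^seq(-6, 1, length.out = 60)
  sc <- kinetic_scheme(tau = c(1e-4, 1e-1), terminal_decays = FALSE)
  s0 <- rbind(make_eads_from_bands(data.frame(center = 1640, amplitude = 1,
                                              fwhm = 12), wn),
              make_eads_from_bands(data.frame(center = 1660, amplitude = -1,
                                              fwhm = 12), wn),
              make_eads_from_bands(data.frame(center = 1690, amplitude = 0.5,
                                              fwhm = 12), wn))
  cmat <- concentration_profiles(sc, t)
  err_at <- vapply(c(0.1, 0.01, 0.001), function(sigma) {
    set.seed(99)
    ds <- spectral_dataset(wn, t, cmat %*% s0 +
                             matrix(rnorm(length(t) * length(wn),
                                          sd = sigma), length(t)))
    max(abs(solve_eads(ds, sc)$spectra - s0))
  }, numeric(1))
  expect_true(all(diff(err_at) < 0))
})

test_that("ill-conditioned concentration matrices are reported, not solved", {
  ds <- tiny_dataset(n_t = 10)
  # both time constants far below the sampled window -> zero columns
  sc <- kinetic_scheme(tau = c(1e-9, 2e-9), names = c("fast1", "fast2"))
  expect_error(solve_eads(ds, sc), "ill-conditioned")
})

test_that("noiseless time constants are recovered to high precision", {
  # exact two-compartment data: the model can represent it perfectly
  wn <- seq(1600, 1700, 4)
  t <- 10^seq(-5, 1, length.out = 60)
  sc <- kinetic_scheme(tau = c(1e-3, 1))
  s0 <- rbind(make_eads_from_bands(data.frame(center = 1630, amplitude = 1,
                                              fwhm = 12), wn),
              make_eads_from_bands(data.frame(center = 1665, amplitude = -1,
                                              fwhm = 12), wn))
  ds <- spectral_dataset(wn, t, concentration_profiles(sc, t) %*% s0)
  f0 <- fit_sequential(ds, run_config(n_compartments = 2,
                                      tau_init = c(1e-3, 1),
                                      terminal_decays = TRUE))
  expect_lt(max(abs(f0$scheme_hat$tau / c(1e-3, 1) - 1)), 1e-6)
  expect_lt(f0$rmse, 1e-10)
  # full preset, noiseless, init off by x3 per constant: recovery to 0.1%
  # (a tiny residual remains because the terminal photoproduct of the truth
  # decays on the hours scale, outside the fitted window's model)
  tr <- preset_truth("yf1", noise_sigma = 0)
  w1 <- window_slice(simulate_photocycle(tr, noise = FALSE), 0, 0.04)
  f3 <- fit_sequential(w1, run_config(n_compartments = 3,
                                      tau_init = c(6e-9, 26.1e-6),
                                      terminal_decays = FALSE))
  expect_lt(max(abs(f3$scheme_hat$tau / c(2e-9, 8.7e-6) - 1)), 1e-3)
})

test_that("rmse field is recomputable and the fit never beats its init", {
  tr <- preset_truth("bslov", noise_sigma = 0.02, rng_seed = 3)
  w1 <- window_slice(simulate_photocycle(tr), 0, 0.04)
  cfg <- run_config(n_compartments = 3, tau_init = c(1e-8, 3e-5),
                    terminal_decays = FALSE)
  fit <- fit_sequential(w1, cfg)
  expect_equal(fit$rmse, sqrt(mean(fit$residual^2)), tolerance = 1e-12)
  expect_true(fit$converged)
  # rmse at the returned optimum <= rmse at the user-supplied start
  rmse_at <- function(tau) {
    sc <- kinetic_scheme(tau = tau, terminal_decays = FALSE)
    e <- solve_eads(w1, sc)
    sqrt(mean((w1$dA - concentration_profiles(sc, w1$t) %*% e$spectra)^2))
  }
  expect_lte(fit$rmse, rmse_at(c(1e-8, 3e-5)))
})

test_that("flat offset component absorbs the heating artifact", {
  tr <- preset_truth("yf1", noise_sigma = 0.005, heating_amplitude = 0.08)
  ds <- simulate_photocycle(tr, noise = FALSE)
  heat <- tr$heating_amplitude * (1 - exp(-ds$t / tr$tau_heat))
  ds$dA <- ds$dA + heat %o% rep(1, length(ds$wn))
  w1 <- window_slice(ds, 0, 0.04)
  plain <- fit_sequential(w1, run_config(n_compartments = 3,
                                         terminal_decays = FALSE))
  offs <- fit_sequential(w1, run_config(n_compartments = 3,
                                        terminal_decays = FALSE,
                                        fit_offset_component = TRUE))
  expect_lt(offs$rmse, plain$rmse)
  # the fitted offset spectrum is flat at roughly the heating amplitude
  off_row <- offs$eads_hat$spectra[nrow(offs$eads_hat$spectra), ]
  expect_lt(diff(range(off_row)), 0.02)
})

test_that("windowed fits recover each preset constant from its own window", {
  tr <- preset_truth("yf1", noise_sigma = 0)
  ds <- simulate_photocycle(tr, noise = FALSE)
  wins <- split_windows(ds)
  cfgs <- list(
    run_config(n_compartments = 3, terminal_decays = FALSE),  # S1, T1 -> A390
    run_config(n_compartments = 1, terminal_decays = TRUE),   # A390 tail
    run_config(n_compartments = 1, terminal_decays = TRUE)    # dark recovery
  )
  fits <- fit_windows(wins, cfgs)
  expect_lt(max(abs(fits[[1]]$scheme_hat$tau / c(2e-9, 8.7e-6) - 1)), 1e-3)
  expect_lt(abs(fits[[3]]$scheme_hat$tau / 3800 - 1), 1e-3)
  expect_error(fit_windows(list(), cfgs), "empty")
})

test_that("single-window and windowed fits agree on shared constants", {
  tr <- preset_truth("bslov", noise_sigma = 0.02, rng_seed = 17)
  ds <- simulate_photocycle(tr)
  w1 <- window_slice(ds, 0, 0.04)
  fit_w <- fit_windows(list(w1), run_config(n_compartments = 3,
                                            terminal_decays = FALSE))[[1]]
  fit_s <- fit_sequential(w1, run_config(n_compartments = 3,
                                         terminal_decays = FALSE))
  expect_equal(fit_w$scheme_hat$tau, fit_s$scheme_hat$tau, tolerance = 1e-12)
})

test_that("bootstrap intervals are seeded, narrow when noiseless, and cover", {
  wn <- seq(1600, 1700, 4)
  t <- 10^seq(-5, 0, length.out = 60)
  sc <- kinetic_scheme(tau = c(1e-3, 1e-1), terminal_decays = FALSE)
  s0 <- rbind(make_eads_from_bands(data.frame(center = 1630, amplitude = 1,
                                              fwhm = 12), wn),
              make_eads_from_bands(data.frame(center = 1660, amplitude = -1,
                                              fwhm = 12), wn),
              make_eads_from_bands(data.frame(center = 1685, amplitude = 0.6,
                                              fwhm = 12), wn))
  surface <- concentration_profiles(sc, t) %*% s0
  cfg <- run_config(n_compartments = 3, tau_init = c(1e-3, 1e-1),
                    terminal_decays = FALSE, rng_seed = 7)
  # noiseless: degenerate residuals give essentially zero-width intervals
  ds0 <- spectral_dataset(wn, t, surface)
  b0 <- bootstrap_tau(ds0, cfg, n_boot = 20)
  expect_lt(max((b0$tau_ci[, "hi"] - b0$tau_ci[, "lo"]) / sc$tau), 1e-6)
  expect_error(bootstrap_tau(ds0, cfg, n_boot = 5), "n_boot")
  # same seed -> identical intervals
  set.seed(1)
  ds <- spectral_dataset(wn, t, surface + matrix(rnorm(length(surface),
                                                       sd = 0.02),
                                                 nrow = length(t)))
  b1 <- bootstrap_tau(ds, cfg, n_boot = 30)
  b2 <- bootstrap_tau(ds, cfg, n_boot = 30)
  expect_identical(b1$tau_ci, b2$tau_ci)
})
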