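test_that("linear baseline subtraction removes lines and keeps bands", {
  wn <- default_wavenumber_axis()
  t <- 10^seq(-1, 1, length.out = 5)
  # pure lines vanish
  lines <- outer(seq_along(t), wn, function(i, v) 0.3 * i + 0.002 * i * v)
  ds <- spectral_dataset(wn, t, lines)
  out <- subtract_linear_baseline(ds)
  expect_lt(max(abs(out$dA)), 1e-12)
  # a mid-axis Gaussian band with flat edges is untouched at its center
  band <- make_eads_from_bands(
    data.frame(center = 1670, amplitude = -1, fwhm = 10), wn)
  ds2 <- spectral_dataset(wn, t, matrix(band, length(t), length(wn),
                                        byrow = TRUE))
  out2 <- subtract_linear_baseline(ds2)
  j <- which(wn == 1670)
  expect_equal(out2$dA[, j], ds2$dA[, j], tolerance = 1e-12)
  # band + line -> pure band recovered where edges are line-dominated
  ds3 <- spectral_dataset(wn, t, ds2$dA + lines)
  out3 <- subtract_linear_baseline(ds3)
  expect_equal(out3$dA[, j], ds2$dA[, j], tolerance = 1e-10)
})

test_that("baseline subtraction is idempotent and validates q", {
  ds <- tiny_dataset(n_wn = 12)
  once <- subtract_linear_baseline(ds, q = 3)
  twice <- subtract_linear_baseline(once, q = 3)
  expect_equal(twice$dA, once$dA, tolerance = 1e-12)
  expect_error(subtract_linear_baseline(ds, q = 7), "2q")
  expect_error(subtract_linear_baseline(ds, q = 0), ">= 1")
})

test_that("overlap scale closed-form cases are exact", {
  ds <- tiny_dataset(seed = 2)
  expect_equal(compute_overlap_scale(ds, ds), 1)
  half <- ds
  half$dA <- 2 * ds$dA
  expect_equal(compute_overlap_scale(ds, half), 0.5)
  zero <- ds
  zero$dA <- 0 * ds$dA
  expect_error(compute_overlap_scale(ds, zero), "degenerate")
  far <- ds
  far$t <- ds$t * 1e3
  expect_error(compute_overlap_scale(ds, far), "no overlapping")
})

test_that("overlap scale estimate is unbiased within least-squares noise", {
  set.seed(14)
  wn <- seq(1600, 1660, 4)
  t <- 10^seq(-3, 0, length.out = 20)
  u <- matrix(rnorm(length(t) * 3), ncol = 3)
  v <- matrix(rnorm(length(wn) * 3), ncol = 3)
  truth <- u %*% t(v)  # random rank-3 reference
  ests <- replicate(100, {
    ref <- spectral_dataset(wn, t, truth)
    noisy <- spectral_dataset(wn, t,
                              0.8 * truth + matrix(rnorm(length(truth),
                                                         sd = 0.01),
                                                   nrow = length(t)))
    compute_overlap_scale(ref, noisy)
  })
  # estimator recovers 1/0.8 = 1.25 within 2 %
  expect_lt(abs(median(ests) - 1.25) / 1.25, 0.02)
})

test_that("stitching averages, rescales to the reference, and is order-invariant", {
  ds <- tiny_dataset(seed = 4)
  # identical batches average to themselves
  out <- stitch_batches(list(ds, ds))
  expect_equal(out$dA, ds$dA, tolerance = 1e-12)
  # relative scales (1, 2, 4) collapse onto the reference scale
  b2 <- ds; b2$dA <- 2 * ds$dA; b2$batch_id <- "b2"
  b4 <- ds; b4$dA <- 4 * ds$dA; b4$batch_id <- "b4"
  out2 <- stitch_batches(list(ds, b2, b4))
  expect_equal(out2$dA, ds$dA, tolerance = 1e-10)
  # input order does not matter (same earliest-start reference rule)
  out3 <- stitch_batches(list(b4, ds, b2))
  expect_equal(out3$dA, out2$dA, tolerance = 1e-10)
})

test_that("stitching k noisy replicates shrinks noise like 1/sqrt(k)", {
  set.seed(21)
  wn <- seq(1600, 1700, 4)
  t <- 10^seq(-3, 0, length.out = 15)
  clean <- matrix(rnorm(length(t) * length(wn)), length(t))
  sigma <- 0.1
  resid_sd <- function(k) {
    mean(replicate(30, {
      batches <- lapply(seq_len(k), function(i) {
        spectral_dataset(wn, t, clean + matrix(rnorm(length(clean),
                                                     sd = sigma),
                                               nrow = length(t)),
                         batch_id = paste0("b", i))
      })
      sd(stitch_batches(batches)$dA - clean)
    }))
  }
  expect_equal(resid_sd(4) / resid_sd(1), 0.5, tolerance = 0.2)
})

test_that("stitching refuses a disconnected overlap chain", {
  ds <- tiny_dataset(seed = 6)
  far <- spectral_dataset(ds$wn, ds$t + 100, ds$dA, batch_id = "far")
  expect_error(stitch_batches(list(ds, far)), "disconnected|no overlapping")
})

test_that("rotation is orthogonal and preserves the rank-m reconstruction", {
  ds <- tiny_dataset(n_t = 30, n_wn = 20, seed = 8)
  for (m in c(1, 3, 5)) {
    r <- svd_rotate(ds, m = m)
    expect_lt(max(abs(crossprod(r$rotation) - diag(m))), 1e-10)
    sv <- svd(ds$dA)
    trunc <- sv$u[, 1:m, drop = FALSE] %*%
      diag(sv$d[1:m], m) %*% t(sv$v[, 1:m, drop = FALSE])
    expect_lt(max(abs(reconstruct(r)$dA - trunc)), 1e-10)
    if (m == 1) expect_equal(r$rotation, diag(1))
  }
  expect_error(svd_rotate(ds, m = 25), "must lie in")
})

test_that("rotation concentrates a smooth kinetic component against noise", {
  set.seed(31)
  n_t <- 80
  tt <- 10^seq(-6, 2, length.out = n_t)
  wn <- seq(1600, 1756, 4)
  u_s <- exp(-tt / 1e-3); u_s <- u_s / sqrt(sum(u_s^2))
  u_n <- rnorm(n_t)
  u_n <- u_n - u_s * sum(u_n * u_s); u_n <- u_n / sqrt(sum(u_n^2))
  v1 <- dnorm(wn, 1660, 8); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- dnorm(wn, 1700, 10); v2 <- v2 / sqrt(sum(v2^2))
  ds <- spectral_dataset(wn, tt, u_s %o% v1 + 0.9 * u_n %o% v2)
  r <- svd_rotate(ds, m = 2)
  acs <- apply(r$temporal, 2, function(u) {
    sum(head(u, -1) * tail(u, -1)) / sum(u^2)
  })
  j <- which.max(acs)
  smooth <- u_s %o% v1
  captured <- sum((r$temporal[, j] %o%
                     drop(crossprod(r$temporal[, j], smooth)))^2)
  expect_gte(captured / sum(smooth^2), 0.95)
  # oracle: exhaustive 2x2 angle scan at 0.001 rad resolution
  sv <- svd(ds$dA, nu = 2, nv = 2)
  u0 <- sv$u; w0 <- sv$v %*% diag(sv$d[1:2])
  obj <- function(th) {
    G <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    u2 <- u0 %*% G; w2 <- w0 %*% G
    sum(colSums(w2^2) * apply(u2, 2, function(u) {
      sum(head(u, -1) * tail(u, -1)) / sum(u^2)
    }))
  }
  scan_best <- max(vapply(seq(-pi / 4, pi / 4, 0.001), obj, numeric(1)))
  expect_equal(tail(r$objective, 1), scan_best, tolerance = 1e-6)
  # objective trace is non-decreasing across sweeps
  expect_true(all(diff(r$objective) >= -1e-12))
})

test_that("drift removal deletes injected drift and spares clean signal", {
  # rank-2 back-reaction-like signal plus a rank-1 monotone, linear-in-nu
  # drift. The drift factors are orthogonalized against the signal factors
  # (known mixing) so the drift occupies its own singular direction, which
  # is the regime where component deletion can work at all; temporally
  # overlapping drift is a documented limitation.
  wn <- default_wavenumber_axis()
  tt <- 10^seq(1.2, 4, length.out = 40)
  nu <- (wn - mean(wn)) / (diff(range(wn)) / 2)
  spec1 <- make_eads_from_bands(default_band_tables("YF1", "A390"), wn)
  spec2 <- make_eads_from_bands(default_band_tables("YF1", "S1"), wn)
  u1 <- exp(-tt / 3)
  u2 <- exp(-tt / 20)
  S <- cbind(spec1, spec2)
  U <- cbind(u1, u2)
  trend <- log(tt / min(tt)) / log(max(tt) / min(tt))
  trend_p <- as.vector(trend - U %*% solve(crossprod(U),
                                           crossprod(U, trend)))
  nu_p <- as.vector(nu - S %*% solve(crossprod(S), crossprod(S, nu)))
  signal <- u1 %o% spec1 + u2 %o% spec2
  sigma <- 0.01
  rmse_after <- vapply(1:20, function(seed) {
    set.seed(seed)
    noisy <- signal + 0.3 * trend_p %o% nu_p +
      matrix(rnorm(length(signal), sd = sigma), nrow = length(tt))
    ds <- spectral_dataset(wn, tt, noisy)
    cleaned <- remove_drift_components(svd_rotate(ds, m = 3), "auto")
    sqrt(mean((cleaned$dA - signal)^2))
  }, numeric(1))
  expect_lt(median(rmse_after), 1.5 * sigma)

  # specificity: no component removed from drift-free data
  removed <- vapply(1:20, function(seed) {
    set.seed(seed + 100)
    noisy <- signal + matrix(rnorm(length(signal), sd = sigma),
                             nrow = length(tt))
    cleaned <- remove_drift_components(
      svd_rotate(spectral_dataset(wn, tt, noisy), m = 3), "auto")
    length(cleaned$meta$drift_removed)
  }, integer(1))
  expect_true(all(removed == 0))

  # explicit empty index list reproduces the rank-m truncation
  ds <- tiny_dataset(n_t = 20, n_wn = 15)
  r <- svd_rotate(ds, m = 4)
  expect_equal(remove_drift_components(r, integer(0))$dA,
               reconstruct(r)$dA, tolerance = 1e-12)
  expect_error(remove_drift_components(r, 1:4), "all")
})
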