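# shared fixtures: small deterministic datasets built in code

tiny_dataset <- function(n_t = 12, n_wn = 8, seed = 1) {
  set.seed(seed)
  wn <- seq(1600, by = 4, length.out = n_wn)
  t <- 10^seq(-6, 0, length.out = n_t)
  spectral_dataset(wn, t, matrix(rnorm(n_t * n_wn), n_t, n_wn))
}

# slice a full-range simulation to one instrument window
window_slice <- function(ds, t_min = 0, t_max = Inf) {
  sel <- ds$t > t_min & ds$t <= t_max
  spectral_dataset(ds$wn, ds$t[sel], ds$dA[sel, , drop = FALSE],
                   window_id = ds$window_id, batch_id = ds$batch_id)
}

# independent ODE oracle for the sequential chain with branching:
# dc1/dt = -k1 c1;  dcj/dt = phi_{j-1} k_{j-1} c_{j-1} - kj cj
ode_concentrations <- function(scheme, t, rtol = 1e-10) {
  n <- n_compartments(scheme)
  k <- 1 / scheme$tau
  if (!scheme$terminal_decays) k <- c(k, 0)
  phi <- scheme$phi
  rhs <- function(time, y, parms) {
    d <- numeric(n)
    d[1] <- -k[1] * y[1]
    if (n > 1) {
      for (j in 2:n) d[j] <- phi[j - 1] * k[j - 1] * y[j - 1] - k[j] * y[j]
    }
    list(d)
  }
  # integrate on a log-friendly grid including 0
  out <- deSolve::ode(y = c(1, numeric(n - 1)), times = c(0, t), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = 1e-14)
  unname(out[-1, -1, drop = FALSE])
}
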