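#' Subtract a per-spectrum linear baseline anchored at the endpoints
#'
#' For every time slice, a straight line through the means of the first and
#' last \code{q} spectral points is fitted and subtracted — the standard
#' correction for rapid-scan FTIR difference spectra whose band-free edges
#' should sit at zero. The operation is idempotent.
#'
#' @param ds a [spectral_dataset()].
#' @param q endpoint-region width in points (default 3).
#' @return Baseline-corrected [spectral_dataset()].
#' @export
subtract_linear_baseline <- function(ds, q = 3) {
  stopifnot(inherits(ds, "spectral_dataset"))
  q <- as.integer(q)
  n_wn <- length(ds$wn)
  if (q < 1) stop("q must be >= 1", call. = FALSE)
  if (n_wn < 2 * q) {
    stop("need at least 2q = ", 2 * q, " spectral points, have ", n_wn,
         call. = FALSE)
  }
  i_lo <- seq_len(q)
  i_hi <- seq(n_wn - q + 1L, n_wn)
  x_lo <- mean(ds$wn[i_lo])
  x_hi <- mean(ds$wn[i_hi])
  y_lo <- rowMeans(ds$dA[, i_lo, drop = FALSE])
  y_hi <- rowMeans(ds$dA[, i_hi, drop = FALSE])
  slope <- (y_hi - y_lo) / (x_hi - x_lo)
  icept <- y_lo - slope * x_lo
  corrected <- ds$dA - (icept %o% rep(1, n_wn) + slope %o% ds$wn)
  pk_log("subtract_linear_baseline: q = %d, mean |baseline| = %.4g mOD", q,
         mean(abs(ds$dA - corrected)))
  ds$dA <- corrected
  ds
}

#' Least-squares scale between overlapping batches
#'
#' Finds the scalar \eqn{s} minimizing \eqn{\|ref - s \cdot batch\|^2} over
#' the block of time points the two batches share (matched within a relative
#' tolerance; batches are expected to share grid points exactly, as the
#' generator guarantees): \eqn{s = \langle ref, batch\rangle /
#' \langle batch, batch\rangle}.
#'
#' @param ref,batch [spectral_dataset()] objects on the same wavenumber axis.
#' @param t_tol relative tolerance for matching time points.
#' @return scalar scale to apply to \code{batch}.
#' @export
compute_overlap_scale <- function(ref, batch, t_tol = 1e-6) {
  stopifnot(inherits(ref, "spectral_dataset"),
            inherits(batch, "spectral_dataset"))
  if (length(ref$wn) != length(batch$wn) ||
      max(abs(ref$wn - batch$wn)) > 1e-9 * max(ref$wn)) {
    stop("batches must share the wavenumber axis", call. = FALSE)
  }
  idx <- match_times(batch$t, ref$t, t_tol)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no overlapping time points between batches",
                       call. = FALSE)
  a <- ref$dA[idx[keep], , drop = FALSE]
  b <- batch$dA[keep, , drop = FALSE]
  bb <- sum(b * b)
  if (bb == 0) stop("degenerate overlap: batch block is identically zero",
                    call. = FALSE)
  s <- sum(a * b) / bb
  pk_log("compute_overlap_scale: %d overlap times, s = %.6g", sum(keep), s)
  s
}

# index of each element of t_query in t_ref within relative tolerance, NA if
# absent
match_times <- function(t_query, t_ref, t_tol) {
  vapply(t_query, function(tq) {
    d <- abs(t_ref - tq) / tq
    j <- which.min(d)
    if (d[j] <= t_tol) j else NA_integer_
  }, integer(1))
}

#' Stitch replicate batches by overlap scaling and averaging
#'
#' Implements the measurement-averaging rule: batches are ordered by their
#' earliest time point (ties broken by batch id); the earliest batch is the
#' scale reference; each subsequent batch is rescaled by
#' [compute_overlap_scale()] against the growing stitched result and the
#' matrices are then averaged per time point on the union time grid.
#'
#' @param batches list of [spectral_dataset()] objects sharing a wavenumber
#'   axis, with a connected chain of time overlaps.
#' @param t_tol relative time-matching tolerance.
#' @return One stitched [spectral_dataset()]; \code{meta$scales} records the
#'   applied per-batch factors.
#' @export
stitch_batches <- function(batches, t_tol = 1e-6) {
  if (length(batches) == 0) stop("no batches to stitch", call. = FALSE)
  stopifnot(all(vapply(batches, inherits, logical(1), "spectral_dataset")))
  starts <- vapply(batches, function(b) min(b$t), numeric(1))
  ids <- vapply(batches, function(b) b$batch_id, character(1))
  ord <- order(starts, ids)
  batches <- batches[ord]
  wn <- batches[[1]]$wn
  # union time grid (tolerance-deduplicated)
  t_all <- sort(unique(unlist(lapply(batches, function(b) b$t))))
  if (length(t_all) > 1) {
    keep <- c(TRUE, diff(t_all) / t_all[-1] > t_tol)
    t_all <- t_all[keep]
  }
  acc <- matrix(0, length(t_all), length(wn))
  cnt <- integer(length(t_all))
  scales <- numeric(length(batches))
  running <- NULL
  for (i in seq_along(batches)) {
    b <- batches[[i]]
    s <- if (is.null(running)) 1 else compute_overlap_scale(running, b, t_tol)
    scales[i] <- s
    idx <- match_times(b$t, t_all, t_tol)
    if (anyNA(idx)) stop("internal: time grid mismatch", call. = FALSE)
    acc[idx, ] <- acc[idx, , drop = FALSE] + s * b$dA
    cnt[idx] <- cnt[idx] + 1L
    if (any(cnt == 0)) {
      # not all times covered yet; running average over covered block
      covered <- cnt > 0
    } else {
      covered <- rep(TRUE, length(t_all))
    }
    if (i < length(batches) && !any(!is.na(match_times(batches[[i + 1]]$t,
                                                       t_all[cnt > 0],
                                                       t_tol)))) {
      stop("disconnected overlap chain: batch '", batches[[i + 1]]$batch_id,
           "' shares no time points with the batches stitched so far",
           call. = FALSE)
    }
    running <- spectral_dataset(
      wn, t_all[cnt > 0],
      acc[cnt > 0, , drop = FALSE] / cnt[cnt > 0],
      window_id = b$window_id, batch_id = "stitched"
    )
  }
  names(scales) <- vapply(batches, function(b) b$batch_id, character(1))
  pk_log("stitch_batches: %d batches -> %d times, scales [%s]",
         length(batches), length(t_all),
         paste(format(scales, digits = 4), collapse = ", "))
  running$meta$scales <- scales
  running
}

#' Rotated truncated SVD of a spectral dataset
#'
#' Truncates the dataset to its leading \code{m} singular triplets and then
#' applies the Henry--Hofrichter rotation: an orthogonal \code{m x m} matrix
#' R, built from iterative pairwise Jacobi-style 2x2 rotations, that
#' maximizes \eqn{\sum_j w_j^2 \, AC_{lag}(u_j)}, the weighted lag
#' autocorrelation of the temporal vectors. Smoothly evolving kinetic
#' components concentrate into high-autocorrelation vectors while noise and
#' erratic drift separate out, yet the rank-m reconstruction (and hence the
#' retained orthonormal basis) is exactly preserved.
#'
#' @param ds a [spectral_dataset()].
#' @param m number of retained components.
#' @param lag autocorrelation lag (default 1).
#' @param max_sweeps,tol Jacobi sweep limit and objective-improvement
#'   stopping tolerance.
#' @return An object of class \code{"rotated_svd"} with fields
#'   \code{temporal} (n_t x m, orthonormal, rotated), \code{spectral}
#'   (n_wn x m, amplitude-carrying: column j is the spectrum of component j),
#'   \code{weights} (rotated component weights = column norms of
#'   \code{spectral}), \code{rotation}, \code{d} (original singular values),
#'   \code{objective} (per-sweep trace) and \code{source}.
#' @references Henry, E. R. and Hofrichter, J. (1992) Singular value
#'   decomposition: application to analysis of experimental data.
#'   Methods in Enzymology 210, 129--192.
#' @export
svd_rotate <- function(ds, m, lag = 1, max_sweeps = 100, tol = 1e-10) {
  stopifnot(inherits(ds, "spectral_dataset"))
  m <- as.integer(m)
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be >= 1", call. = FALSE)
  if (m < 1 || m > min(dim(ds$dA))) {
    stop("m must lie in 1..min(n_t, n_wn) = ", min(dim(ds$dA)),
         call. = FALSE)
  }
  sv <- svd(ds$dA, nu = m, nv = m)
  u <- sv$u                       # n_t x m
  w <- sv$v %*% diag(sv$d[seq_len(m)], m)  # n_wn x m, amplitude-carrying
  rot <- diag(m)
  objective <- sum(vapply(seq_len(m), function(j) {
    sum(w[, j]^2) * ac_lag(u[, j], lag)
  }, numeric(1)))
  trace <- objective
  if (m > 1) {
    for (sweep in seq_len(max_sweeps)) {
      for (p in seq_len(m - 1)) {
        for (q in seq(p + 1, m)) {
          th <- best_pair_angle(u, w, p, q, lag)
          if (th != 0) {
            G <- rotation_2x2(th)
            u[, c(p, q)] <- u[, c(p, q)] %*% G
            w[, c(p, q)] <- w[, c(p, q)] %*% G
            rot[, c(p, q)] <- rot[, c(p, q)] %*% G
          }
        }
      }
      new_obj <- sum(vapply(seq_len(m), function(j) {
        sum(w[, j]^2) * ac_lag(u[, j], lag)
      }, numeric(1)))
      trace <- c(trace, new_obj)
      if (new_obj - objective < tol) {
        objective <- new_obj
        break
      }
      objective <- new_obj
    }
  }
  weights <- sqrt(colSums(w^2))
  pk_log("svd_rotate: m = %d, %d sweeps, objective %.6g", m,
         length(trace) - 1, objective)
  structure(
    list(temporal = u, spectral = w, weights = weights, rotation = rot,
         d = sv$d, lag = lag, objective = trace, source = ds),
    class = "rotated_svd"
  )
}

rotation_2x2 <- function(th) {
  matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
}

# lag-autocorrelation of a vector (normalized by its energy)
ac_lag <- function(v, lag) {
  n <- length(v)
  if (n <= lag) return(0)
  sum(v[seq_len(n - lag)] * v[seq(lag + 1, n)]) / sum(v * v)
}

# best rotation angle for the (p, q) component pair: 1-D maximization of the
# weighted-autocorrelation objective restricted to that pair
best_pair_angle <- function(u, w, p, q, lag) {
  obj <- function(th) {
    G <- rotation_2x2(th)
    u2 <- u[, c(p, q)] %*% G
    w2 <- w[, c(p, q)] %*% G
    sum(colSums(w2^2) * c(ac_lag(u2[, 1], lag), ac_lag(u2[, 2], lag)))
  }
  opt <- stats::optimize(obj, interval = c(-pi / 4, pi / 4), maximum = TRUE,
                         tol = 1e-10)
  # rotate only on a meaningful gain: along near-flat directions of the
  # objective (two equally smooth components) the identity is kept, so an
  # already-separated drift component is not re-mixed
  base <- obj(0)
  if (opt$objective - base > 1e-9 * max(abs(base), 1e-12)) opt$maximum else 0
}

#' Reconstruct a dataset from a rotated SVD
#' @param r a [svd_rotate()] result.
#' @param keep integer indices of components to retain (default all).
#' @return A [spectral_dataset()] rebuilt from the retained components.
#' @export
reconstruct <- function(r, keep = seq_along(r$weights)) {
  stopifnot(inherits(r, "rotated_svd"))
  dA <- r$temporal[, keep, drop = FALSE] %*% t(r$spectral[, keep,
                                                          drop = FALSE])
  ds <- r$source
  ds$dA <- dA
  ds
}

#' Delete slow baseline-drift components from a rotated SVD
#'
#' Removes the components identified as instrumental drift and reconstructs
#' the dataset from the rest. With \code{drift_idx = "auto"} a component is
#' flagged as drift when its temporal trace drifts monotonically — net
#' displacement over total variation >= 0.5, a magnitude-weighted
#' monotonicity statistic that is ~1 for a monotone ramp and
#' ~\eqn{n^{-1/2}} for white noise — \emph{and} its spectral trace is close
#' to a straight line in wavenumber (|Pearson r| >= 0.9 against \code{wn}).
#' That combination is the signature of the minutes-to-hours baseline wander
#' of long static-cell measurements; structured kinetic difference spectra
#' fail the linearity test and noise fails both.
#'
#' @param r a [svd_rotate()] result.
#' @param drift_idx integer indices of drift components, or \code{"auto"}.
#' @return A [spectral_dataset()] reconstructed without the drift
#'   components; \code{meta$drift_removed} lists them.
#' @export
remove_drift_components <- function(r, drift_idx = "auto") {
  stopifnot(inherits(r, "rotated_svd"))
  m <- length(r$weights)
  if (identical(drift_idx, "auto")) {
    drift_idx <- which(vapply(seq_len(m), function(j) {
      is_drift_component(r$temporal[, j], r$spectral[, j], r$source$wn)
    }, logical(1)))
  } else {
    drift_idx <- as.integer(drift_idx)
    if (length(drift_idx) && (min(drift_idx) < 1 || max(drift_idx) > m)) {
      stop("drift indices must lie in 1..", m, call. = FALSE)
    }
  }
  if (length(drift_idx) >= m) {
    stop("refusing to delete all ", m, " components as drift", call. = FALSE)
  }
  pk_log("remove_drift_components: removing [%s] of %d",
         paste(drift_idx, collapse = ", "), m)
  ds <- reconstruct(r, keep = setdiff(seq_len(m), drift_idx))
  ds$meta$drift_removed <- drift_idx
  ds
}

is_drift_component <- function(temporal, spectral, wn,
                               mono_frac = 0.5, r_line = 0.9) {
  # monotonicity as net displacement over total variation: 1 for a strictly
  # monotone trace, ~n^-1/2 for white noise. Magnitude weighting makes the
  # statistic robust to tiny sign flips on near-flat stretches, where a raw
  # count of same-sign first differences chatters.
  d <- diff(temporal)
  tv <- sum(abs(d))
  mono <- if (tv == 0) TRUE else abs(sum(d)) / tv >= mono_frac
  lin <- abs(stats::cor(spectral, wn)) >= r_line
  mono && lin
}
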