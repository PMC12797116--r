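#' Run the full data-reduction chain on multi-window batch data
#'
#' Mirrors the published reduction protocol: per window, replicate batches
#' are overlap-scaled and averaged ([stitch_batches()]); the rapid-scan and
#' static windows (all but the first) get a per-spectrum linear baseline
#' subtraction ([subtract_linear_baseline()]); and the slowest window is
#' cleaned of minutes-to-hours baseline drift through a rotated truncated
#' SVD ([svd_rotate()], [remove_drift_components()]).
#'
#' @param batches list of [spectral_dataset()] objects carrying
#'   \code{window_id} labels (as produced by [add_instrument_effects()]).
#' @param baseline_q endpoint width for the baseline line.
#' @param baseline_windows window indices (by time order) that receive the
#'   baseline correction; default all but the first.
#' @param svd_m SVD truncation rank for drift removal (capped at the window
#'   size).
#' @param drift \code{"auto"}, integer indices, or \code{NULL} to skip drift
#'   removal.
#' @return list of stitched, corrected [spectral_dataset()] objects, one per
#'   window, ordered by start time.
#' @export
preprocess_windows <- function(batches, baseline_q = 3,
                               baseline_windows = NULL, svd_m = 6,
                               drift = "auto") {
  stopifnot(all(vapply(batches, inherits, logical(1), "spectral_dataset")))
  wids <- vapply(batches, function(b) b$window_id, character(1))
  groups <- split(batches, wids)
  starts <- vapply(groups, function(g) min(g[[1]]$t), numeric(1))
  groups <- groups[order(starts)]
  if (is.null(baseline_windows) && length(groups) > 1) {
    baseline_windows <- seq(2, length(groups))
  }
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    w <- stitch_batches(groups[[i]])
    if (i %in% baseline_windows) {
      w <- subtract_linear_baseline(w, q = baseline_q)
    }
    if (i == length(groups) && length(groups) > 1 && !is.null(drift)) {
      m <- min(svd_m, dim(w$dA))
      r <- svd_rotate(w, m = m)
      w <- remove_drift_components(r, drift_idx = drift)
    }
    out[[i]] <- w
  }
  names(out) <- names(groups)
  out
}

#' Cut a dataset into instrument time windows
#'
#' Splits along the time axis at the given boundaries (defaults: 40 ms
#' between the pump--probe and rapid-scan instruments, 15 s between
#' rapid-scan and the static cell).
#'
#' @param ds a [spectral_dataset()].
#' @param boundaries ascending split times in seconds.
#' @return list of [spectral_dataset()] objects labelled \code{w1, w2, ...};
#'   empty windows are dropped.
#' @export
split_windows <- function(ds, boundaries = c(0.04, 15)) {
  stopifnot(inherits(ds, "spectral_dataset"))
  win <- findInterval(ds$t, sort(boundaries)) + 1L
  lapply(split(seq_along(ds$t), paste0("w", win)), function(rows) {
    spectral_dataset(ds$wn, ds$t[rows], ds$dA[rows, , drop = FALSE],
                     window_id = paste0("w", win[rows[1]]),
                     batch_id = ds$batch_id, meta = ds$meta)
  })
}
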