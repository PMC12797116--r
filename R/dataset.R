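#' Construct a time-resolved spectral dataset
#'
#' The universal data container of the pipeline: a difference-absorbance
#' matrix \eqn{\Delta A(t, \tilde\nu)} in mOD on a wavenumber axis (cm\eqn{^{-1}},
#' columns) and a pump--probe delay axis (seconds, rows). Axes are validated
#' and stored strictly ascending; the matrix is reordered to match.
#'
#' @param wn numeric vector of wavenumbers in cm\eqn{^{-1}} (positive,
#'   length >= 2, no duplicates).
#' @param t numeric vector of pump--probe delays in seconds (positive, no
#'   duplicates).
#' @param dA numeric matrix of difference absorbance in mOD with
#'   \code{length(t)} rows and \code{length(wn)} columns; all entries finite.
#' @param window_id,batch_id character labels identifying the instrument
#'   window and measurement batch the data came from.
#' @param meta named list of free-form metadata (written to the file header
#'   by [write_dataset()]).
#'
#' @return An object of class \code{"spectral_dataset"}: a list with elements
#'   \code{wn}, \code{t}, \code{dA}, \code{window_id}, \code{batch_id},
#'   \code{meta}.
#' @seealso [read_dataset()], [write_dataset()]
#' @export
spectral_dataset <- function(wn, t, dA, window_id = "w1", batch_id = "b1",
                             meta = list()) {
  wn <- as.numeric(wn)
  t <- as.numeric(t)
  dA <- as.matrix(dA)
  if (anyDuplicated(wn)) stop("duplicate wavenumbers in axis", call. = FALSE)
  if (anyDuplicated(t)) {
    stop("duplicate time points within one batch (averaging across batches ",
         "is stitch_batches' job, not the container's)", call. = FALSE)
  }
  if (nrow(dA) != length(t) || ncol(dA) != length(wn)) {
    stop("dA must be length(t) x length(wn) = ", length(t), " x ", length(wn),
         ", got ", nrow(dA), " x ", ncol(dA), call. = FALSE)
  }
  ow <- order(wn)
  ot <- order(t)
  wn <- wn[ow]
  t <- t[ot]
  dA <- dA[ot, ow, drop = FALSE]
  validate_wavenumber_axis(wn)
  validate_time_axis(t)
  if (!all(is.finite(dA))) stop("non-finite entries in dA", call. = FALSE)
  storage.mode(dA) <- "double"
  dimnames(dA) <- NULL
  structure(
    list(wn = wn, t = t, dA = dA,
         window_id = as.character(window_id),
         batch_id = as.character(batch_id),
         meta = meta),
    class = "spectral_dataset"
  )
}

validate_wavenumber_axis <- function(wn) {
  if (length(wn) < 2) stop("wavenumber axis needs >= 2 points", call. = FALSE)
  if (!all(is.finite(wn)) || any(wn <= 0)) {
    stop("wavenumbers must be finite and positive", call. = FALSE)
  }
  if (any(diff(wn) <= 0)) {
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  }
  invisible(wn)
}

validate_time_axis <- function(t) {
  if (length(t) < 1) stop("time axis is empty", call. = FALSE)
  if (!all(is.finite(t)) || any(t <= 0)) {
    stop("times must be finite and positive (seconds)", call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop("time axis must be strictly increasing", call. = FALSE)
  }
  invisible(t)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("<spectral_dataset> ", length(x$t), " times x ", length(x$wn),
      " wavenumbers\n", sep = "")
  cat("  t:  ", format(min(x$t), digits = 3), " .. ",
      format(max(x$t), digits = 3), " s\n", sep = "")
  cat("  wn: ", format(min(x$wn), digits = 6), " .. ",
      format(max(x$wn), digits = 6), " cm^-1\n", sep = "")
  cat("  window ", x$window_id, ", batch ", x$batch_id,
      ", max|dA| = ", format(max(abs(x$dA)), digits = 4), " mOD\n", sep = "")
  invisible(x)
}

#' Read a csv_matrix difference-absorbance file
#'
#' The on-disk dialect is plain UTF-8 CSV: optional \code{#}-prefixed comment
#' lines carrying \code{key=value} metadata, a header row
#' \code{wavenumber,<t1>,<t2>,...} with times in seconds, and one row per
#' wavenumber. Axes may be stored in any order; the returned dataset is
#' always sorted ascending in both axes.
#'
#' @param path path to the file.
#' @param dialect currently only \code{"csv_matrix"}.
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(path, dialect = "csv_matrix") {
  dialect <- match.arg(dialect, "csv_matrix")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^\\s*#", lines)
  meta <- parse_meta_comments(lines[is_comment])
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) < 2) {
    stop("malformed csv_matrix file: need a header and at least one data row",
         call. = FALSE)
  }
  header <- strsplit(body[[1]], ",", fixed = TRUE)[[1]]
  if (tolower(trimws(header[[1]])) != "wavenumber" || length(header) < 2) {
    stop("malformed header: expected 'wavenumber,<t1>,<t2>,...', got '",
         body[[1]], "'", call. = FALSE)
  }
  t <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(t)) stop("malformed header: times do not parse as numbers",
                     call. = FALSE)
  cells <- strsplit(body[-1], ",", fixed = TRUE)
  ncol_ok <- vapply(cells, length, integer(1)) == length(header)
  if (!all(ncol_ok)) {
    stop("malformed row(s): ", paste(which(!ncol_ok) + 1, collapse = ", "),
         " (wrong number of cells)", call. = FALSE)
  }
  num <- suppressWarnings(vapply(cells, as.numeric, numeric(length(header))))
  # num is (1 + n_t) x n_wn: row 1 the wavenumbers, remaining rows the
  # dA values at t[1], t[2], ... for each wavenumber column
  wn <- num[1, ]
  dA <- num[-1, , drop = FALSE]
  if (anyNA(wn)) stop("wavenumber column does not parse as numbers",
                      call. = FALSE)
  if (anyNA(dA)) stop("NaN or unparseable cells in data block", call. = FALSE)
  ds <- spectral_dataset(
    wn = wn, t = t, dA = dA,
    window_id = meta$window_id %||% "w1",
    batch_id = meta$batch_id %||% "b1",
    meta = meta[setdiff(names(meta), c("window_id", "batch_id"))]
  )
  pk_log("read_dataset: %s -> %d x %d (t x wn)", path, length(ds$t),
         length(ds$wn))
  ds
}

#' Write a spectral dataset as a csv_matrix file
#'
#' Inverse of [read_dataset()]; metadata, window and batch labels are stored
#' in \code{#}-prefixed \code{key=value} comment lines. Values are written
#' with full double precision so that a read/write round trip is lossless to
#' better than 1e-12 relative.
#'
#' @param ds a [spectral_dataset()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (length(ds$dA) == 0) stop("refusing to write an empty matrix",
                               call. = FALSE)
  meta <- c(list(window_id = ds$window_id, batch_id = ds$batch_id), ds$meta)
  hdr <- vapply(names(meta), function(k) {
    sprintf("# %s=%s", k,
            paste(format(meta[[k]], digits = 17), collapse = ","))
  }, character(1))
  header <- paste(c("wavenumber", format_num(ds$t)), collapse = ",")
  rows <- vapply(seq_along(ds$wn), function(j) {
    paste(c(format_num(ds$wn[j]), format_num(ds$dA[, j])), collapse = ",")
  }, character(1))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(hdr, header, rows), con)
  invisible(path)
}

format_num <- function(x) {
  formatC(x, digits = 17, format = "g")
}

parse_meta_comments <- function(lines) {
  meta <- list()
  for (ln in lines) {
    ln <- sub("^\\s*#\\s*", "", ln)
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Package-level diagnostic logging
#'
#' Every pipeline stage reports input shapes, parameters and residual/scale
#' summaries through this hook. Enable with
#' \code{options(photocyclekit.verbose = TRUE)}.
#'
#' @param fmt sprintf format string.
#' @param ... values interpolated into \code{fmt}.
#' @return \code{NULL}, invisibly.
#' @keywords internal
pk_log <- function(fmt, ...) {
  if (isTRUE(getOption("photocyclekit.verbose", FALSE))) {
    message(sprintf(paste0("[photocyclekit] ", fmt), ...))
  }
  invisible(NULL)
}
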