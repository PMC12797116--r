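#' Read a run configuration from a TOML file
#'
#' Supports the flat TOML subset the pipeline uses: top-level
#' \code{key = value} lines with string, number, boolean, flat-array and
#' array-of-pair values (nested tables are not supported). Keys mirror the
#' [run_config()] arguments; \code{bleach_bands} is written as an array of
#' \code{[low, high]} pairs.
#'
#' @param path path to the TOML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- parse_flat_toml(path)
  args <- list()
  for (key in c("n_compartments", "tau_init", "terminal_decays",
                "fit_offset_component", "bleach_bands", "rng_seed")) {
    if (!is.null(vals[[key]])) args[[key]] <- vals[[key]]
  }
  if (!is.null(args$bleach_bands) && !is.list(args$bleach_bands)) {
    # flat array low1, high1, low2, high2, ...
    bb <- args$bleach_bands
    args$bleach_bands <- split(bb, ceiling(seq_along(bb) / 2))
  }
  do.call(run_config, args)
}

#' Serialize a run configuration to TOML
#' @param cfg a [run_config()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  fmt <- function(v) {
    if (is.logical(v)) return(if (v) "true" else "false")
    if (is.character(v)) return(sprintf('"%s"', v))
    if (length(v) > 1) {
      return(paste0("[", paste(format(v, digits = 17), collapse = ", "), "]"))
    }
    format(v, digits = 17)
  }
  lines <- c(
    paste0("n_compartments = ", fmt(cfg$n_compartments)),
    paste0("tau_init = ", if (identical(cfg$tau_init, "auto")) "\"auto\""
           else fmt(cfg$tau_init)),
    paste0("terminal_decays = ", fmt(cfg$terminal_decays)),
    paste0("fit_offset_component = ", fmt(cfg$fit_offset_component)),
    paste0("bleach_bands = [",
           paste(vapply(cfg$bleach_bands, fmt, character(1)),
                 collapse = ", "), "]"),
    paste0("rng_seed = ", fmt(cfg$rng_seed))
  )
  writeLines(lines, path)
  invisible(path)
}

# minimal flat TOML: key = value; strings, numbers, booleans, [a, b, ...],
# [[a, b], [c, d]]
parse_flat_toml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      stop("TOML tables are not supported by this reader: '", ln, "'",
           call. = FALSE)
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed TOML line: '", ln, "'", call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- parse_toml_value(val)
  }
  out
}

parse_toml_value <- function(val) {
  if (val == "true") return(TRUE)
  if (val == "false") return(FALSE)
  if (grepl("^\\[\\s*\\[", val)) {
    # array of arrays: pull out the innermost bracket groups
    groups <- regmatches(val, gregexpr("\\[[^][]*\\]", val))[[1]]
    return(lapply(groups, parse_toml_value))
  }
  if (grepl("^\\[", val)) {
    inner <- sub("^\\[", "", sub("\\]$", "", val))
    items <- trimws(strsplit(inner, ",")[[1]])
    items <- items[nzchar(items)]
    return(vapply(items, function(x) parse_toml_value(x), numeric(1),
                  USE.NAMES = FALSE))
  }
  if (grepl('^"', val)) return(gsub('^"|"$', "", val))
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) stop("cannot parse TOML value: '", val, "'", call. = FALSE)
  num
}

#' Serialize a ground truth to TOML (for simulation provenance)
#' @param truth a [preset_truth()] object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth_toml <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  num <- function(v) paste0("[", paste(format(v, digits = 17),
                                       collapse = ", "), "]")
  lines <- c(
    sprintf('protein = "%s"', truth$protein),
    paste0("tau_s = ", num(truth$scheme$tau)),
    paste0("phi = ", num(truth$scheme$phi)),
    sprintf('names = [%s]',
            paste(sprintf('"%s"', truth$scheme$names), collapse = ", ")),
    sprintf("terminal_decays = %s",
            if (truth$scheme$terminal_decays) "true" else "false"),
    paste0("noise_sigma = ", format(truth$noise_sigma, digits = 17)),
    paste0("sigma_scale = ", format(truth$sigma_scale, digits = 17)),
    paste0("heating_amplitude = ",
           format(truth$heating_amplitude, digits = 17)),
    paste0("rng_seed = ", truth$rng_seed)
  )
  writeLines(lines, path)
  invisible(path)
}
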