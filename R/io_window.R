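## Umbrella-window time series: GROMACS pullx-style two-column text
## (time ps, position nm), "#"/"@" comment lines tolerated, with a JSON
## sidecar (<file>.json) carrying the window center and force constant.
## Force series use the same dialect with force (kJ mol^-1 nm^-1) in the
## second column.

#' Construct an umbrella window series
#'
#' @param center window center (nm).
#' @param force_constant harmonic bias force constant (kJ mol^-1 nm^-2),
#'   >= 0.
#' @param time sample times (ps).
#' @param z sampled reaction-coordinate positions (nm).
#' @param force optional force samples (kJ mol^-1 nm^-1).
#' @return An object of class `window_series`.
#' @export
window_series <- function(center, force_constant, time, z, force = NULL) {
  if (force_constant < 0) ox_stop("force_constant must be >= 0")
  if (length(z) == 0L) ox_stop("window series has no samples")
  stopifnot(length(time) == length(z))
  if (!is.null(force)) stopifnot(length(force) == length(z))
  structure(list(center = as.numeric(center),
                 force_constant = as.numeric(force_constant),
                 time = as.numeric(time), z = as.numeric(z),
                 force = force),
            class = "window_series")
}

#' @export
print.window_series <- function(x, ...) {
  cat(sprintf("window_series: center %.3f nm, k = %g kJ/mol/nm^2, %d samples\n",
              x$center, x$force_constant, length(x$z)))
  invisible(x)
}

#' Write window series to pullx-style files with JSON sidecars
#'
#' @param windows list of `window_series`.
#' @param dir output directory.
#' @param prefix file-name prefix; files are `<prefix>_<i>.xvg` plus
#'   `<prefix>_<i>.xvg.json`.
#' @return Invisibly, the data-file paths.
#' @export
write_window_series <- function(windows, dir, prefix = "window") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    path <- file.path(dir, sprintf("%s_%03d.xvg", prefix, i))
    hdr <- c("# pull coordinate position", "@ xaxis label \"Time (ps)\"",
             "@ yaxis label \"Position (nm)\"")
    writeLines(c(hdr, sprintf("%g %.8g", w$time, w$z)), path)
    jsonlite::write_json(list(center = w$center,
                              force_constant = w$force_constant),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    paths[i] <- path
  }
  invisible(paths)
}

#' Read pullx-style window series
#'
#' @param paths character vector of data-file paths; each must have a
#'   `<path>.json` sidecar with `center` and `force_constant`.
#' @param dialect only `"pullx"` is understood.
#' @return List of `window_series`.
#' @export
read_window_series <- function(paths, dialect = "pullx") {
  if (!identical(dialect, "pullx")) ox_stop("unknown dialect: ", dialect)
  lapply(paths, function(path) {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^[#@]", lines) & nzchar(trimws(lines))
    idx <- which(keep)
    if (!length(idx)) ox_stop("no data lines in ", path)
    fields <- strsplit(trimws(lines[idx]), "\\s+")
    ncol <- lengths(fields)
    if (any(ncol < 2L)) {
      ox_stop("parse error in ", path, " at line ", idx[which(ncol < 2L)[1]],
              ": expected >= 2 columns")
    }
    vals <- suppressWarnings(lapply(fields, as.numeric))
    bad <- which(vapply(vals, function(v) any(is.na(v[1:2])), TRUE))
    if (length(bad)) {
      ox_stop("parse error in ", path, " at line ", idx[bad[1]],
              ": non-numeric payload")
    }
    time <- vapply(vals, `[`, 0, 1L)
    z <- vapply(vals, `[`, 0, 2L)
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      ox_stop("missing sidecar ", sidecar, " (center, force_constant)")
    }
    meta <- jsonlite::read_json(sidecar)
    if (is.null(meta$center) || is.null(meta$force_constant)) {
      ox_stop("sidecar ", sidecar, " must define center and force_constant")
    }
    window_series(meta$center, meta$force_constant, time, z)
  })
}
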