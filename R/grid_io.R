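#' Read a dose grid from file
#'
#' Dispatches on `format`: `"portable-grid"` is the package's JSON grid format
#' (see [write_dose_grid()]); `"rtdose"` is a DICOM RT Dose object (explicit
#' VR little endian) with uniform grid-frame offsets.
#'
#' @param path input file path.
#' @param format `"portable-grid"` or `"rtdose"` (default guesses from the
#'   file extension: `.dcm` means RTDOSE).
#' @return a [dose_grid()]; RTDOSE values are scaled to Gy via the
#'   dose-grid-scaling attribute and axes normalised to `(z, y, x)`.
#' @export
read_dose_grid <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.dcm$", path, ignore.case = TRUE)) "rtdose"
              else "portable-grid"
  }
  format <- match.arg(format, c("portable-grid", "rtdose"))
  if (format == "rtdose") read_rtdose(path) else read_portable_grid(path)
}

#' Write a dose grid to file
#'
#' @param grid a [dose_grid()].
#' @param path output file path.
#' @param format `"portable-grid"` (JSON, lossless) or `"rtdose"` (minimal
#'   DICOM RT Dose; values quantised by the chosen dose-grid scaling).
#' @param ... passed to the format writer (e.g. `scaling` for RTDOSE).
#' @return `path`, invisibly.
#' @export
write_dose_grid <- function(grid, path, format = NULL, ...) {
  if (is.null(format)) {
    format <- if (grepl("\\.dcm$", path, ignore.case = TRUE)) "rtdose"
              else "portable-grid"
  }
  format <- match.arg(format, c("portable-grid", "rtdose"))
  if (format == "rtdose") write_rtdose(grid, path, ...)
  else write_portable_grid(grid, path)
}

# Portable grid: one JSON object with axes, shape, spacing_mm, origin_mm,
# is_relative and row-major (last axis fastest) flat dose values.
read_portable_grid <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (k in c("axes", "shape", "spacing_mm", "origin_mm", "values")) {
    if (is.null(j[[k]])) stop("portable-grid file missing field '", k, "'")
  }
  shape <- as.integer(j$shape)
  if (length(j$values) != prod(shape)) {
    stop("portable-grid values length ", length(j$values),
         " does not match shape ", paste(shape, collapse = "x"))
  }
  # row-major on disk -> fill reversed dims then transpose back
  v <- array(as.numeric(j$values), dim = rev(shape))
  v <- aperm(v, rev(seq_along(shape)))
  if (length(shape) == 1L) v <- array(as.numeric(j$values), dim = shape)
  dose_grid(v, spacing = as.numeric(j$spacing_mm),
            origin = as.numeric(j$origin_mm), axes = as.character(j$axes),
            is_relative = isTRUE(j$is_relative))
}

write_portable_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  nd <- grid_ndim(grid)
  v <- grid$values
  flat <- if (nd == 1L) as.vector(v) else as.vector(aperm(v, rev(seq_len(nd))))
  obj <- list(
    format = "gammaspc-portable-grid-v1",
    axes = grid$axes,
    shape = dim(grid$values),
    spacing_mm = grid$spacing,
    origin_mm = grid$origin,
    is_relative = grid$is_relative,
    values = flat
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}
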