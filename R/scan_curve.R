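#' Water-tank scan curve
#'
#' A 1D [dose_grid()] carrying beam-scan metadata: a depth-dose curve (DDC),
#' an off-centre ratio (OCR) at fixed depth, or a cross-plane profile.
#' DDC positions are depths in mm with 0 at the water surface; OCR positions
#' are off-axis distances in mm.
#'
#' @param positions strictly increasing, uniformly spaced positions (mm).
#' @param dose dose values (Gy for DDCs; relative units allowed for OCRs).
#' @param curve_kind one of `"DDC"`, `"OCR"`, `"crossplane-profile"`.
#' @param collimator one of `"fixed"`, `"iris"`, `"mlc"`.
#' @param field_size_mm nominal field size in mm; checked against
#'   `field_size_table` unless that is `NULL`.
#' @param depth_mm measurement depth in mm (OCR / cross profiles; `NA` for DDC).
#' @param machine_id machine identifier string.
#' @param is_relative logical, relative-dose flag (DDCs must be absolute).
#' @param field_size_table numeric vector of allowed nominal field sizes, or
#'   `NULL` to skip the check. Defaults to [cyberknife_field_sizes()] for the
#'   curve's collimator.
#'
#' @return object of class `c("scan_curve", "dose_grid")`.
#' @export
scan_curve <- function(positions, dose,
                       curve_kind = c("DDC", "OCR", "crossplane-profile"),
                       collimator = c("fixed", "iris", "mlc"),
                       field_size_mm, depth_mm = NA_real_,
                       machine_id = "CK1", is_relative = FALSE,
                       field_size_table = NULL) {
  curve_kind <- match.arg(curve_kind)
  collimator <- match.arg(collimator)
  positions <- as.numeric(positions)
  if (length(positions) < 2L) stop("a scan curve needs at least 2 points")
  dp <- diff(positions)
  if (any(dp <= 0)) stop("positions must be strictly increasing")
  if (max(dp) - min(dp) > 1e-6 * max(dp)) {
    stop("positions must be uniformly spaced")
  }
  if (curve_kind == "DDC" && isTRUE(is_relative)) {
    stop("DDC curves carry absolute dose (is_relative must be FALSE)")
  }
  if (is.null(field_size_table)) {
    field_size_table <- cyberknife_field_sizes()[[collimator]]
  }
  if (length(field_size_table) &&
      min(abs(field_size_table - field_size_mm)) > 1e-6) {
    stop("field_size_mm ", field_size_mm,
         " is not in the declared field-size table for collimator '",
         collimator, "'")
  }
  g <- dose_grid(dose, spacing = mean(dp), origin = positions[1L],
                 axes = if (curve_kind == "DDC") "depth" else "offaxis",
                 is_relative = is_relative)
  g$curve_kind <- curve_kind
  g$collimator <- collimator
  g$field_size_mm <- as.numeric(field_size_mm)
  g$depth_mm <- as.numeric(depth_mm)
  g$machine_id <- as.character(machine_id)
  class(g) <- c("scan_curve", "dose_grid")
  g
}

#' @export
print.scan_curve <- function(x, ...) {
  cat(sprintf(
    "<scan_curve> %s %s FS %g mm%s, %d points [%g..%g mm], machine %s\n",
    x$curve_kind, x$collimator, x$field_size_mm,
    if (is.finite(x$depth_mm)) sprintf(" @ depth %g mm", x$depth_mm) else "",
    length(x$values), x$origin,
    x$origin + (length(x$values) - 1) * x$spacing, x$machine_id
  ))
  invisible(x)
}

#' Nominal CyberKnife field sizes per collimator system
#'
#' The default field-size tables: 12 nominal sizes for the fixed cones and
#' the Iris variable aperture, and 11 nominal MLC field widths (leaf-travel
#' direction).
#'
#' @return named list with numeric vectors `fixed`, `iris`, `mlc` (mm).
#' @export
cyberknife_field_sizes <- function() {
  fixed <- c(5, 7.5, 10, 12.5, 15, 20, 25, 30, 35, 40, 50, 60)
  list(
    fixed = fixed,
    iris = fixed,
    mlc = c(7.6, 15.4, 23.0, 30.8, 38.4, 46.2, 53.8, 69.2, 84.6, 100.0, 115.0)
  )
}

# ---- scan CSV dialect ------------------------------------------------------
# Header lines `# key: value` (keys: kind, collimator, field_size_mm,
# depth_mm, machine, is_relative), then `position_mm,dose` rows; multiple
# curve blocks separated by one or more blank lines.

#' Read scan curves from a scan CSV file
#'
#' @param path path to a scan CSV file (see Details).
#' @details The dialect: each curve block starts with header lines of the form
#'   `# key: value` with required keys `kind` (`DDC`/`OCR`/
#'   `crossplane-profile`), `collimator` (`fixed`/`iris`/`mlc`) and
#'   `field_size_mm`, optional keys `depth_mm`, `machine` and `is_relative`;
#'   then one `position_mm,dose` row per sample. Blocks are separated by blank
#'   lines. Positions must be strictly increasing within a block.
#' @return a list of [scan_curve()] objects.
#' @export
read_scan_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur_header <- character()
  cur_rows <- character()
  cur_row_lines <- integer()
  flush <- function() {
    if (length(cur_header) == 0L && length(cur_rows) == 0L) return(NULL)
    parse_scan_block(cur_header, cur_rows, cur_row_lines)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") {
      b <- flush()
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur_header <- character(); cur_rows <- character(); cur_row_lines <- integer()
    } else if (startsWith(ln, "#")) {
      if (length(cur_rows) > 0L) {
        stop("line ", i, ": header line after data rows")
      }
      cur_header <- c(cur_header, ln)
    } else {
      cur_rows <- c(cur_rows, ln)
      cur_row_lines <- c(cur_row_lines, i)
      attr(cur_header, "start") <- attr(cur_header, "start") %||% i
    }
  }
  b <- flush()
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  if (length(blocks) == 0L) stop("no curve blocks found in ", path)
  blocks
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_scan_block <- function(header, rows, row_lines) {
  keys <- list()
  for (h in header) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1L]]
    if (length(m) != 3L) {
      stop("malformed header line: '", h, "'")
    }
    keys[[m[2L]]] <- trimws(m[3L])
  }
  for (req in c("kind", "collimator", "field_size_mm")) {
    if (is.null(keys[[req]])) {
      stop("missing required header key '", req, "' in curve block",
           if (length(row_lines)) paste0(" before line ", row_lines[1L]) else "")
    }
  }
  if (length(rows) < 2L) stop("curve block needs at least 2 data rows")
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("line ", row_lines[bad[1L]], ": expected 'position_mm,dose'")
  }
  pos <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  dose <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(pos) || anyNA(dose)) {
    i <- which(is.na(pos) | is.na(dose))[1L]
    stop("line ", row_lines[i], ": non-numeric value")
  }
  if (any(diff(pos) <= 0)) {
    i <- which(diff(pos) <= 0)[1L] + 1L
    stop("line ", row_lines[i], ": positions must be strictly increasing")
  }
  scan_curve(
    positions = pos, dose = dose,
    curve_kind = keys$kind, collimator = keys$collimator,
    field_size_mm = as.numeric(keys$field_size_mm),
    depth_mm = if (is.null(keys$depth_mm)) NA_real_ else as.numeric(keys$depth_mm),
    machine_id = keys$machine %||% "CK1",
    is_relative = identical(tolower(keys$is_relative %||% "false"), "true")
  )
}

#' Write scan curves to a scan CSV file
#'
#' Inverse of [read_scan_csv()]; values are written with enough digits for a
#' faithful round trip.
#'
#' @param curves a [scan_curve()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(curves, path) {
  if (inherits(curves, "scan_curve")) curves <- list(curves)
  out <- character()
  for (cv in curves) {
    stopifnot(inherits(cv, "scan_curve"))
    hdr <- c(
      sprintf("# kind: %s", cv$curve_kind),
      sprintf("# collimator: %s", cv$collimator),
      sprintf("# field_size_mm: %.10g", cv$field_size_mm),
      if (is.finite(cv$depth_mm)) sprintf("# depth_mm: %.10g", cv$depth_mm),
      sprintf("# machine: %s", cv$machine_id),
      sprintf("# is_relative: %s", tolower(as.character(cv$is_relative)))
    )
    pos <- grid_axis_coords(cv, 1L)
    rows <- sprintf("%.10g,%.10g", pos, as.vector(cv$values))
    out <- c(out, hdr, rows, "")
  }
  writeLines(out, path)
  invisible(path)
}
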