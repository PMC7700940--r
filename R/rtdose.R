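# Minimal DICOM RT Dose I/O, written for this package: explicit VR little
# endian only, uniform grid-frame offsets only, 32-bit unsigned pixel data.
# Covers the grid/scaling subset of the RT Dose IOD that dose comparison
# needs; it is not a general DICOM implementation.

RTDOSE_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.481.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# one explicit-VR element as a raw vector; pads string values to even length
dcm_element <- function(group, elem, vr, value) {
  if (vr %in% c("UI", "CS", "DS", "IS", "LO", "SH")) {
    s <- as.character(value)
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    body <- charToRaw(s)
    if (length(body) %% 2L == 1L) body <- c(body, pad)
  } else if (vr == "US") {
    body <- u16le(value)
  } else if (vr == "UL") {
    body <- u32le(value)
  } else if (vr %in% c("OB", "OW")) {
    body <- value  # raw
    if (length(body) %% 2L == 1L) body <- c(body, as.raw(0L))
  } else stop("unsupported VR ", vr)
  head <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "UT", "UN", "SQ", "OF")) {
    c(head, as.raw(c(0L, 0L)), u32le(length(body)), body)
  } else {
    if (length(body) > 65534L) stop("element too long for short VR")
    c(head, u16le(length(body)), body)
  }
}

ds_join <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

#' Write a dose grid as a minimal DICOM RT Dose file
#'
#' Explicit VR little endian, 32-bit pixel data. Dose values are quantised to
#' integer multiples of `scaling`; the round-trip error is bounded by half the
#' scaling quantum.
#'
#' @param grid a 2D (`y`,`x`) or 3D (`z`,`y`,`x`) [dose_grid()] of absolute dose.
#' @param path output path (conventionally `.dcm`).
#' @param scaling dose-grid scaling in Gy per integer unit; default scales the
#'   maximum dose to 1e8 integer units.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(grid, path, scaling = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  nd <- grid_ndim(grid)
  if (nd < 2L) stop("RTDOSE supports 2D planes and 3D volumes only")
  v <- grid$values
  if (is.null(scaling)) {
    scaling <- if (max(v) > 0) max(v) / 1e8 else 1e-8
  }
  ints <- round(v / scaling)
  if (max(ints) > 2^31 - 1) stop("scaling too fine for 32-bit pixel data")

  if (nd == 2L) {
    nframes <- 1L; nrow_ <- dim(v)[1L]; ncol_ <- dim(v)[2L]
    sp_row <- grid$spacing[1L]; sp_col <- grid$spacing[2L]
    ipp <- c(grid$origin[2L], grid$origin[1L], 0)
    gfov <- 0
    flat <- as.vector(t(ints))                    # x fastest, then y
  } else {
    nframes <- dim(v)[1L]; nrow_ <- dim(v)[2L]; ncol_ <- dim(v)[3L]
    sp_row <- grid$spacing[2L]; sp_col <- grid$spacing[3L]
    ipp <- c(grid$origin[3L], grid$origin[2L], grid$origin[1L])
    gfov <- (seq_len(nframes) - 1) * grid$spacing[1L]
    flat <- as.vector(aperm(ints, c(3L, 2L, 1L))) # x, then y, then z
  }

  uid <- function(suffix) paste0("1.2.826.0.1.3680043.9.7225.", suffix)
  inst <- uid(paste0(format(round(stats::runif(1) * 1e8)), ".",
                     format(round(as.numeric(Sys.time())))))
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_element(0x0002, 0x0002, "UI", RTDOSE_SOP_CLASS),
    dcm_element(0x0002, 0x0003, "UI", inst),
    dcm_element(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", uid("1"))
  )
  pix <- writeBin(as.integer(flat), raw(), size = 4, endian = "little")
  data <- c(
    dcm_element(0x0008, 0x0016, "UI", RTDOSE_SOP_CLASS),
    dcm_element(0x0008, 0x0018, "UI", inst),
    dcm_element(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_element(0x0020, 0x0032, "DS", ds_join(ipp)),
    dcm_element(0x0020, 0x0037, "DS", ds_join(c(1, 0, 0, 0, 1, 0))),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0008, "IS", as.character(nframes)),
    dcm_element(0x0028, 0x0010, "US", nrow_),
    dcm_element(0x0028, 0x0011, "US", ncol_),
    dcm_element(0x0028, 0x0030, "DS", ds_join(c(sp_row, sp_col))),
    dcm_element(0x0028, 0x0100, "US", 32L),
    dcm_element(0x0028, 0x0101, "US", 32L),
    dcm_element(0x0028, 0x0102, "US", 31L),
    dcm_element(0x0028, 0x0103, "US", 0L),
    dcm_element(0x3004, 0x0002, "CS", "GY"),
    dcm_element(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_element(0x3004, 0x000A, "CS", "PLAN"),
    dcm_element(0x3004, 0x000C, "DS", ds_join(gfov)),
    dcm_element(0x3004, 0x000E, "DS", sprintf("%.12g", scaling)),
    dcm_element(0x7FE0, 0x0010, "OW", pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(dcm_element(0x0002, 0x0000, "UL", length(meta)), meta), con)
  writeBin(data, con)
  invisible(path)
}

read_u16 <- function(r, at) {
  readBin(r[at:(at + 1L)], integer(), size = 2, endian = "little", signed = FALSE)
}
read_u32 <- function(r, at) {
  readBin(r[at:(at + 3L)], integer(), size = 4, endian = "little")
}

#' Read a DICOM RT Dose file into a dose grid
#'
#' Supports explicit VR little endian RT Dose objects with uniform
#' grid-frame offsets and 16- or 32-bit unsigned pixel data. Dose values are
#' scaled to Gy by the dose-grid-scaling attribute; 3D axes are normalised to
#' `(z, y, x)`, 2D (single frame) to `(y, x)`.
#'
#' @param path path to a `.dcm` RT Dose file.
#' @return a [dose_grid()] in Gy.
#' @export
read_rtdose <- function(path) {
  r <- readBin(path, raw(), file.info(path)$size)
  if (length(r) < 140L || rawToChar(r[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path)
  }
  pos <- 133L
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(r)) {
    group <- read_u16(r, pos); elem <- read_u16(r, pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- read_u32(r, pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- read_u16(r, pos + 6L)
      vstart <- pos + 8L
    }
    if (len < 0 || vstart + len - 1L > length(r)) {
      stop("corrupt element length at byte ", pos)
    }
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, raw = if (len > 0) r[vstart:(vstart + len - 1L)] else raw(0))
    pos <- vstart + len
  }
  getstr <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$raw[t$raw != as.raw(0L)]))
  }
  getds <- function(key) {
    s <- getstr(key)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\", fixed = TRUE)[[1L]])
  }
  getus <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    read_u16(t$raw, 1L)
  }
  ts <- getstr("0002,0010")
  if (!is.null(ts) && ts != TS_EXPLICIT_LE) {
    stop("unsupported transfer syntax ", ts,
         " (only explicit VR little endian is supported)")
  }
  scaling <- getds("3004,000E")
  if (is.null(scaling)) stop("missing DoseGridScaling (3004,000E): not a usable RT Dose")
  nrow_ <- getus("0028,0010"); ncol_ <- getus("0028,0011")
  if (is.null(nrow_) || is.null(ncol_)) stop("missing Rows/Columns")
  nframes <- as.integer(getstr("0028,0008") %||% "1")
  bits <- getus("0028,0100") %||% 32L
  sp <- getds("0028,0030")
  if (is.null(sp) || length(sp) != 2L) stop("missing or malformed PixelSpacing")
  ipp <- getds("0020,0032") %||% c(0, 0, 0)
  pix <- tags[["7FE0,0010"]]
  if (is.null(pix)) stop("missing PixelData")
  n <- as.integer(nframes) * nrow_ * ncol_
  if (bits == 32L) {
    ints <- readBin(pix$raw, integer(), n, size = 4, endian = "little")
    if (any(ints < 0)) stop("pixel values exceed signed 32-bit range")
  } else if (bits == 16L) {
    ints <- readBin(pix$raw, integer(), n, size = 2, endian = "little",
                    signed = FALSE)
  } else stop("unsupported BitsAllocated ", bits)
  if (length(ints) != n) stop("pixel data truncated")
  dose <- ints * scaling

  if (nframes > 1L) {
    gfov <- getds("3004,000C")
    if (is.null(gfov) || length(gfov) != nframes) {
      stop("missing or malformed GridFrameOffsetVector")
    }
    dz <- diff(gfov)
    if (any(dz <= 0) || max(dz) - min(dz) > 1e-6 * max(abs(dz))) {
      stop("non-uniform slice spacing is unsupported")
    }
    v <- array(dose, dim = c(ncol_, nrow_, nframes))  # x fastest on disk
    v <- aperm(v, c(3L, 2L, 1L))
    dose_grid(v, spacing = c(mean(dz), sp[1L], sp[2L]),
              origin = c(ipp[3L], ipp[2L], ipp[1L]), axes = c("z", "y", "x"))
  } else {
    v <- t(matrix(dose, nrow = ncol_, ncol = nrow_))
    dose_grid(v, spacing = c(sp[1L], sp[2L]),
              origin = c(ipp[2L], ipp[1L]), axes = c("y", "x"))
  }
}
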