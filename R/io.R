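# Volume I/O: multi-page TIFF (8/16-bit integer, 32-bit float) through the
# tiff package, and MRC2014 through a minimal readBin/writeBin implementation
# (modes 0 = int8, 1 = int16, 2 = float32, 6 = uint16). Slice order on disk
# is acquisition order (z); in memory arrays are (z, y, x).

#' Read a volumetric stack
#'
#' @param path multi-page TIFF (`.tif`/`.tiff`) or MRC2014 (`.mrc`) file.
#' @param spacing voxel spacing `(c, b, a)` nm. Required for TIFF (the format
#'   carries no nm metadata here); for MRC it overrides the header cell
#'   dimensions when given.
#' @param origin nm offset, default zero.
#' @param name identifier; defaults to the file name.
#' @return a [voxel_grid()]; float data give `depth = "float"`.
#' @export
read_stack <- function(path, spacing = NULL, origin = c(0, 0, 0), name = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (is.null(name)) name <- basename(path)
  if (ext %in% c("tif", "tiff")) {
    info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
    # 32 bits per sample marks floating-point storage
    is_float <- any(info$bits.per.sample >= 32) ||
      identical(info$sample.format[1], "float")
    slices <- tiff::readTIFF(path, all = TRUE, as.is = !is_float)
    if (!is.list(slices)) slices <- list(slices)
    shp <- lapply(slices, dim)
    if (length(unique(vapply(shp, paste, "", collapse = "x"))) != 1L)
      stop("inconsistent slice shapes in ", path)
    if (length(shp[[1]]) != 2L)
      stop("expected single-channel (grayscale) TIFF slices")
    if (is.null(spacing))
      stop("missing spacing: TIFF carries no nm metadata, pass `spacing`")
    nz <- length(slices)
    ny <- shp[[1]][1]
    nx <- shp[[1]][2]
    vals <- array(0, c(nz, ny, nx))
    for (k in seq_len(nz)) vals[k, , ] <- slices[[k]]
    storage.mode(vals) <- "double"
    voxel_grid(vals, spacing, origin = origin, name = name)
  } else if (ext == "mrc") {
    read_mrc(path, spacing = spacing, origin = origin, name = name)
  } else {
    stop("unsupported extension: .", ext, " (use .tif/.tiff or .mrc)")
  }
}

#' Write a volumetric stack
#'
#' Round trips are value-exact for the supported bit depths. 8-bit grids go
#' to 8-bit TIFF pages or MRC mode 6; float grids (TIFF: values in `[0, 1]`)
#' to 32-bit float; label volumes to 16-bit.
#'
#' @param grid a `VoxelGrid`, `ProbabilityMap` or `LabelVolume`.
#' @param path destination; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  ext <- tolower(tools::file_ext(path))
  vals <- grid_values(grid)
  kind <- if (inherits(grid, "LabelVolume")) "label"
          else if (inherits(grid, "ProbabilityMap")) "float"
          else grid$depth
  if (ext %in% c("tif", "tiff")) {
    nz <- dim(vals)[1]
    slices <- vector("list", nz)
    if (kind == "8bit") {
      for (k in seq_len(nz)) slices[[k]] <- vals[k, , ] / 255
      tiff::writeTIFF(slices, path, bits.per.sample = 8L)
    } else if (kind == "label") {
      if (max(vals) > 65535) stop("label ids exceed 16-bit TIFF range")
      for (k in seq_len(nz)) slices[[k]] <- vals[k, , ] / 65535
      tiff::writeTIFF(slices, path, bits.per.sample = 16L)
    } else {
      if (min(vals) < 0 || max(vals) > 1)
        stop("float TIFF expects values in [0, 1]")
      for (k in seq_len(nz)) {
        m <- vals[k, , ]
        storage.mode(m) <- "double"
        slices[[k]] <- m
      }
      tiff::writeTIFF(slices, path, bits.per.sample = 32L)
    }
  } else if (ext == "mrc") {
    mode <- switch(kind, "8bit" = 6L, "label" = 6L, 1L)
    if (kind == "float") mode <- 2L
    write_mrc(vals, path, spacing = grid$spacing, mode = mode)
  } else {
    stop("unsupported extension: .", ext)
  }
  invisible(path)
}

# -- MRC2014 ---------------------------------------------------------------

read_mrc <- function(path, spacing = NULL, origin = c(0, 0, 0), name = "") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  cella <- {
    seek(con, 40)
    readBin(con, "double", n = 3, size = 4, endian = "little")
  }
  nsymbt <- {
    seek(con, 92)
    readBin(con, "integer", n = 1, size = 4, endian = "little")
  }
  if (is.null(spacing)) {
    if (all(cella > 0)) {
      # cella is the cell dimension in Angstrom; spacing nm = cella/dim/10
      spacing <- rev(c(cella[1] / nx, cella[2] / ny, cella[3] / nz) / 10)
    } else {
      stop("missing spacing: MRC header has no cell dimensions, pass `spacing`")
    }
  }
  seek(con, 1024 + nsymbt)
  n <- as.numeric(nx) * ny * nz
  raw_vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode: ", mode))
  if (length(raw_vals) < n) stop("truncated MRC data in ", path)
  # on disk x is fastest, then y, then section (z)
  vals <- aperm(array(as.double(raw_vals), c(nx, ny, nz)), c(3, 2, 1))
  voxel_grid(vals, spacing, origin = origin, name = name,
             depth = if (mode == 2) "float" else NULL)
}

write_mrc <- function(vals, path, spacing, mode = 2L) {
  d <- dim(vals) # (nz, ny, nx)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d[3], d[2], d[1], mode, 0, 0, 0, d[3], d[2], d[1])),
           con, size = 4, endian = "little")
  # cell dimensions in Angstrom (spacing nm * 10 * n)
  writeBin(as.numeric(c(d[3] * spacing[3], d[2] * spacing[2],
                        d[1] * spacing[1]) * 10),
           con, size = 4, endian = "little")
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 2, 3)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(vals), max(vals), mean(vals))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(0, 0)), con, size = 4, endian = "little") # ispg, nsymbt
  writeBin(raw(100), con) # extra
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little") # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # little-endian stamp
  writeBin(as.numeric(sd(as.numeric(vals))), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little") # nlabl
  writeBin(raw(800), con) # labels
  x_fastest <- aperm(vals, c(3, 2, 1))
  if (mode == 2L) {
    writeBin(as.numeric(x_fastest), con, size = 4, endian = "little")
  } else if (mode %in% c(1L, 6L)) {
    iv <- as.integer(x_fastest)
    if (mode == 6L) iv <- ifelse(iv > 32767L, iv - 65536L, iv)
    writeBin(iv, con, size = 2, endian = "little")
  } else if (mode == 0L) {
    writeBin(as.integer(x_fastest), con, size = 1, endian = "little")
  } else stop("unsupported MRC mode: ", mode)
  invisible(path)
}
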