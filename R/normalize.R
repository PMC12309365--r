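# Intensity normalization. CLAHE is computed as a pseudo-3D combination of
# three orthogonal 2D passes (front XY, top XZ, side YZ). Window sizes are
# derived from a *physical* tile size, so anisotropic voxels give rectangular
# sliding windows: the XZ/YZ passes see fewer pixels along z than in-plane.
# The three passes are combined voxel-wise (mean by default) and rounded back
# to 8-bit.

#' Per-axis CLAHE window sizes in pixels
#'
#' `round(tile_nm / spacing_axis)` for each axis `(z, y, x)`. With the FIB-SEM
#' spacing (10, 3.255, 3.255) nm and a 260.4-nm tile this gives (26, 80, 80):
#' an 80x80 px window in XY but 26x80 px in XZ/YZ.
#'
#' @param spacing `(c, b, a)` nm.
#' @param tile_nm physical window size.
#' @return integer window sizes `(z, y, x)` in pixels.
#' @export
clahe_window_px <- function(spacing, tile_nm) {
  w <- round(tile_nm / spacing)
  names(w) <- c("z", "y", "x")
  w
}

# single-region CLAHE: histogram clipped at `limit` times the uniform level,
# excess redistributed, then equalized - the window-larger-than-plane limit
equalize_clipped <- function(mat, limit, bins) {
  n <- length(mat)
  idx <- pmin(floor(mat / 256 * bins), bins - 1)
  h <- tabulate(idx + 1, nbins = bins)
  clip <- max(limit * n / bins, 1)
  excess <- sum(pmax(h - clip, 0))
  h <- pmin(h, clip) + excess / bins
  cdf <- cumsum(h)
  cdf_min <- cdf[which(h > 0)[1]]
  map <- (cdf - cdf_min) / max(n - cdf_min, 1) * 255
  matrix(map[idx + 1], nrow(mat), ncol(mat))
}

# one padded 2D CLAHE pass; mat values in [0,255], windows (w1, w2) px along
# (rows, cols)
clahe2d <- function(mat, w1, w2, limit, bins) {
  n1 <- nrow(mat); n2 <- ncol(mat)
  t1 <- max(1L, round(n1 / w1))
  t2 <- max(1L, round(n2 / w2))
  if (t1 < 2 || t2 < 2) return(equalize_clipped(mat, limit, bins))
  p1 <- ceiling(n1 / t1) * t1
  p2 <- ceiling(n2 / t2) * t2
  if (p1 != n1) {
    extra <- pmin(n1, (p1 - n1))
    mat <- rbind(mat, mat[n1:(n1 - extra + 1), , drop = FALSE])
  }
  if (p2 != n2) {
    extra <- pmin(n2, (p2 - n2))
    mat <- cbind(mat, mat[, n2:(n2 - extra + 1), drop = FALSE])
  }
  out <- EBImage::clahe(mat / 255, nx = t1, ny = t2, bins = bins,
                        limit = limit)
  out[seq_len(n1), seq_len(n2), drop = FALSE] * 255
}

#' Anisotropy-aware pseudo-3D CLAHE
#'
#' Contrast-limited adaptive histogram equalization computed from the front
#' (XY), top (XZ) and side (YZ) of the volume and combined voxel-wise. The
#' per-axis window is `round(tile_nm / spacing_axis)` pixels, so the physical
#' window is (approximately) `tile_nm` on every axis regardless of voxel
#' anisotropy.
#'
#' @param grid 8-bit [voxel_grid()].
#' @param tile_nm physical sliding-window size, nm. Default 416 nm (about
#'   128 px in-plane at 3.255 nm).
#' @param clip_limit histogram clip factor (1 = no equalization limit
#'   changes nothing; larger allows stronger equalization). Default 3.
#' @param combine how the three passes merge: `"mean"` (default), `"min"` or
#'   `"max"`.
#' @param bins histogram bins, default 256.
#' @return 8-bit `VoxelGrid` of the same shape and spacing.
#' @export
clahe_anisotropic <- function(grid, tile_nm = 416, clip_limit = 3,
                              combine = c("mean", "min", "max"), bins = 256) {
  stopifnot(inherits(grid, "VoxelGrid"))
  if (grid$depth != "8bit") stop("clahe_anisotropic expects an 8-bit grid")
  combine <- match.arg(combine)
  w <- clahe_window_px(grid$spacing, tile_nm)
  d <- dim(grid$values)
  if (any(pmin(w, d) < 2))
    stop("tile_nm smaller than 2 px on some axis at this spacing")
  w <- pmin(w, d)
  v <- grid$values
  xy <- array(0, d); xz <- array(0, d); yz <- array(0, d)
  for (k in seq_len(d[1])) # front: rows y, cols x
    xy[k, , ] <- clahe2d(v[k, , ], w["y"], w["x"], clip_limit, bins)
  for (j in seq_len(d[2])) # top: rows z, cols x
    xz[, j, ] <- clahe2d(v[, j, ], w["z"], w["x"], clip_limit, bins)
  for (i in seq_len(d[3])) # side: rows z, cols y
    yz[, , i] <- clahe2d(v[, , i], w["z"], w["y"], clip_limit, bins)
  out <- switch(combine,
                mean = (xy + xz + yz) / 3,
                min = pmin(xy, xz, yz),
                max = pmax(xy, xz, yz))
  voxel_grid(as_8bit(out), grid$spacing, origin = grid$origin,
             name = grid$name, depth = "8bit")
}

#' Median denoising with a physical radius
#'
#' Median filter with per-axis half-widths `round(radius_nm / spacing_axis)`,
#' used to suppress detector shot noise before voxel extraction. The dtype
#' and value range are preserved.
#'
#' @param grid a [voxel_grid()].
#' @param radius_nm physical radius, nm; must reach at least one voxel on
#'   every axis (window of 3 or more voxels).
#' @return a `VoxelGrid` of the same shape, spacing and depth.
#' @export
median_denoise <- function(grid, radius_nm) {
  stopifnot(inherits(grid, "VoxelGrid"))
  h <- round(radius_nm / grid$spacing)
  if (any(h < 1))
    stop("radius too small to cover >= 3 voxels on axis ",
         paste(c("z", "y", "x")[h < 1], collapse = ","))
  v <- cpp_median3d(grid$values, dim(grid$values), as.integer(h))
  voxel_grid(v, grid$spacing, origin = grid$origin, name = grid$name,
             depth = grid$depth)
}
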