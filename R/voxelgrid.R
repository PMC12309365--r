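# Core voxel containers.
#
# Axis convention (fixed package-wide): arrays are indexed (z, y, x) with
# dim = c(nz, ny, nx) and spacing = c(c, b, a) nm. Voxel indices are 0-based
# in physical conversions and a voxel's physical position is its center:
# position(k, j, i) = origin + (k*c, j*b, i*a). Point sets that interact with
# meshes (vertices, probes) use (x, y, z) nm columns.

#' Construct a voxel grid
#'
#' A scalar 3D image with physical anisotropic spacing. The canonical
#' intensity depth is 8-bit (integers 0-255); float grids are accepted and
#' converted with round-half-up where an operation requires 8-bit.
#'
#' @param values numeric 3D array, indexed `(z, y, x)`.
#' @param spacing numeric length-3, voxel spacing `(c, b, a)` in nm per axis
#'   `(z, y, x)`; all positive.
#' @param origin numeric length-3 nm offset `(z, y, x)`.
#' @param name free-text identifier.
#' @param depth `"8bit"` or `"float"`; guessed from the values when `NULL`.
#' @return an object of class `VoxelGrid`.
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0), name = "",
                       depth = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array indexed (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (c, b, a) in nm")
  if (is.null(depth)) {
    depth <- if (all(values == round(values)) && min(values) >= 0 &&
                 max(values) <= 255) "8bit" else "float"
  }
  depth <- match.arg(depth, c("8bit", "float"))
  if (depth == "8bit" &&
      (any(values != round(values)) || min(values) < 0 || max(values) > 255))
    stop("8-bit grids may contain only integers in [0, 255]")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         name = name, depth = depth),
    class = "VoxelGrid")
}

#' Construct a per-class probability map
#'
#' Per-voxel class probability in `[0, 1]`, as produced by an AI segmenter
#' (classes such as Memb, Matter, Sol, Void, Vesc).
#'
#' @inheritParams voxel_grid
#' @param class_name class label text, e.g. `"Memb"`.
#' @return an object of class `ProbabilityMap`.
#' @export
probability_map <- function(values, spacing, class_name = "Memb",
                            origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array indexed (z, y, x)")
  if (min(values) < 0 || max(values) > 1)
    stop("probability values must lie in [0, 1]")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive values (c, b, a) in nm")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin),
         class_name = class_name),
    class = "ProbabilityMap")
}

#' Construct a label volume
#'
#' Non-negative integer instance/class labels (0 = unassigned) with a label
#' table mapping each id to an organelle class, an instance index and a
#' clipped-by-boundary flag.
#'
#' @param labels integer 3D array indexed `(z, y, x)`.
#' @param table data.frame with columns `label`, `class`, `instance`,
#'   `clipped`; built automatically (class `"organelle"`, clipped from border
#'   contact) when `NULL`.
#' @inheritParams voxel_grid
#' @return an object of class `LabelVolume`.
#' @export
label_volume <- function(labels, spacing, table = NULL, origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array indexed (z, y, x)")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (is.null(table)) {
    clipped <- vapply(ids, function(id) {
      touches_border(labels == id)
    }, logical(1))
    table <- data.frame(label = ids, class = rep("organelle", length(ids)),
                        instance = seq_along(ids), clipped = clipped,
                        stringsAsFactors = FALSE)
  } else {
    missing <- setdiff(ids, table$label)
    if (length(missing))
      stop("labels without a table entry: ", paste(missing, collapse = ", "))
    dup <- stats::aggregate(table$instance,
                            by = list(class = table$class), FUN = anyDuplicated)
    if (any(dup$x > 0))
      stop("instance indices must be unique within a class")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive values (c, b, a) in nm")
  structure(
    list(labels = labels, table = table, spacing = spacing,
         origin = as.numeric(origin)),
    class = "LabelVolume")
}

#' @export
print.VoxelGrid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<VoxelGrid %s> %d x %d x %d (z,y,x), spacing %s nm, %s\n",
              x$name, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "x"), x$depth))
  invisible(x)
}

#' @export
print.ProbabilityMap <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ProbabilityMap '%s'> %d x %d x %d (z,y,x), spacing %s nm\n",
              x$class_name, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<LabelVolume> %d x %d x %d (z,y,x), %d labels\n",
              d[1], d[2], d[3], nrow(x$table)))
  invisible(x)
}

#' Physical coordinates of voxel indices
#'
#' All nm/voxel conversions go through this pair of helpers. Voxel indices
#' are 0-based; a voxel's physical position is its center.
#'
#' @param grid a `VoxelGrid`, `ProbabilityMap` or `LabelVolume`.
#' @param vox integer matrix with columns `(k, j, i)` = `(z, y, x)`, 0-based.
#' @return numeric matrix with columns `(z, y, x)` in nm.
#' @export
vox_to_nm <- function(grid, vox) {
  vox <- rbind(vox)
  sweep(sweep(vox, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' @rdname vox_to_nm
#' @param nm numeric matrix with columns `(z, y, x)` in nm.
#' @return for `nm_to_vox`, the nearest 0-based voxel indices.
#' @export
nm_to_vox <- function(grid, nm) {
  nm <- rbind(nm)
  round(sweep(sweep(nm, 2, grid$origin, "-"), 2, grid$spacing, "/"))
}

# round-half-up 8-bit conversion
as_8bit <- function(values) {
  v <- floor(values + 0.5)
  v[v < 0] <- 0
  v[v > 255] <- 255
  v
}

grid_values <- function(x) {
  if (inherits(x, "LabelVolume")) x$labels else x$values
}

same_geometry <- function(a, b) {
  identical(dim(grid_values(a)), dim(grid_values(b))) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9))
}

touches_border <- function(mask) {
  d <- dim(mask)
  any(mask[1, , ]) || any(mask[d[1], , ]) ||
    any(mask[, 1, ]) || any(mask[, d[2], ]) ||
    any(mask[, , 1]) || any(mask[, , d[3]])
}

# coordinate arrays (x, y, z nm) for every voxel of a grid, recycled shape
coord_arrays <- function(dim, spacing, origin = c(0, 0, 0)) {
  z <- origin[1] + (seq_len(dim[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(dim[2]) - 1) * spacing[2]
  x <- origin[3] + (seq_len(dim[3]) - 1) * spacing[3]
  list(
    z = array(z, dim),
    y = array(rep(y, each = dim[1]), dim),
    x = array(rep(x, each = dim[1] * dim[2]), dim)
  )
}
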