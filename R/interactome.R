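# Organelle-organelle separation analysis: per-vertex surface-to-surface
# distance maps, closest approach, contact fractions at the standard <35-nm
# membrane-contact-site criterion, area-weighted separation histograms, and
# probe-based consistency benchmarking. All distances are Euclidean in nm;
# anisotropy is handled by working in physical coordinates throughout.

#' Surface-to-surface distance map
#'
#' For every vertex of the query mesh, the distance to the nearest point on
#' any reference triangle (point-to-triangle, not vertex-to-vertex). The
#' unsigned separation is reported; the side of the nearest triangle is
#' retained for containment queries.
#'
#' @param query,reference non-empty [surface_mesh()]es.
#' @return a `DistanceMap`: `distance` (nm, per query vertex), `signed`,
#'   `vertex_area`, plus query/reference ids.
#' @export
surface_distance <- function(query, reference) {
  stopifnot(inherits(query, "SurfaceMesh"), inherits(reference, "SurfaceMesh"))
  if (!nrow(query$vertices) || !nrow(reference$triangles))
    stop("empty mesh")
  res <- cpp_mesh_distance(query$vertices, reference$vertices,
                           reference$triangles)
  structure(list(distance = res$distance,
                 signed = res$distance * res$side,
                 vertex_area = query$vertex_area,
                 query = query$name, reference = reference$name,
                 query_label = query$label, reference_label = reference$label),
            class = "DistanceMap")
}

#' @export
print.DistanceMap <- function(x, ...) {
  cat(sprintf("<DistanceMap %s -> %s> %d vertices, min %.3g nm\n",
              x$query, x$reference, length(x$distance), min(x$distance)))
  invisible(x)
}

#' Closest approach between two organelles
#'
#' The minimum separation distance over all query vertices of a distance map.
#'
#' @param dm a [surface_distance()] result.
#' @return nm.
#' @export
closest_approach <- function(dm) {
  stopifnot(inherits(dm, "DistanceMap"))
  if (!length(dm$distance)) stop("empty distance map")
  min(dm$distance)
}

#' Fraction of a population in membrane contact
#'
#' The percentage of distance maps whose closest approach falls below the
#' separation threshold (default 35 nm, the standard membrane-contact-site
#' criterion).
#'
#' @param population list of `DistanceMap`s (one per organelle).
#' @param threshold_nm contact criterion, nm.
#' @return percentage in `[0, 100]`.
#' @export
contact_fraction <- function(population, threshold_nm = 35) {
  if (!length(population)) stop("empty population")
  ca <- vapply(population, closest_approach, numeric(1))
  mean(ca < threshold_nm) * 100
}

#' Area-weighted separation histogram of a surface
#'
#' Groups per-vertex separation distances into fixed brackets (default 5-nm
#' bins over 0-250 nm) and reports the percentage of the query surface area
#' in each bracket. Bins are half-open `[lo, lo + bin)`; distances at or
#' beyond the range maximum pool into an overflow bin, so the percentages
#' always total 100.
#'
#' @param dm a [surface_distance()] result.
#' @param bin_nm bracket width, nm.
#' @param range_nm two-element range, nm.
#' @return data.frame `lo`, `hi`, `area_pct` (last row is the overflow bin).
#' @export
surface_histogram <- function(dm, bin_nm = 5, range_nm = c(0, 250)) {
  stopifnot(inherits(dm, "DistanceMap"))
  if (bin_nm <= 0) stop("bin width must be positive")
  lo <- seq(range_nm[1], range_nm[2] - bin_nm, by = bin_nm)
  hi <- lo + bin_nm
  total <- sum(dm$vertex_area)
  idx <- findInterval(dm$distance, c(lo, range_nm[2]))
  # idx 0 = below range (cannot happen for range starting at 0), k+1 overflow
  area <- vapply(seq_along(lo), function(b)
    sum(dm$vertex_area[idx == b]), numeric(1))
  overflow <- sum(dm$vertex_area[idx > length(lo) | idx == 0])
  data.frame(lo = c(lo, range_nm[2]), hi = c(hi, Inf),
             area_pct = c(area, overflow) / total * 100)
}

#' Place random distance probes near membranes
#'
#' Samples voxel-center probe coordinates uniformly from the eligibility
#' shell: within `dilation_nm` of a membrane but not inside one (and, when a
#' constraint mask is given, within `dilation_nm` of that mask as well) -
#' the same filtering the probe benchmark uses with 30 probes and the 35-nm
#' contact criterion.
#'
#' @param membrane_mask binary/logical [voxel_grid()] of membrane voxels.
#' @param n number of distinct probes.
#' @param dilation_nm shell thickness, nm.
#' @param constraint_mask optional binary [voxel_grid()] (e.g. a dilated
#'   organelle label).
#' @param seed integer; the draw is deterministic for a fixed seed.
#' @return a `ProbeSet`: `coords` (n x 3, `(x, y, z)` nm), `voxel` (0-based
#'   `(z, y, x)` indices), and the eligibility parameters.
#' @export
place_probes <- function(membrane_mask, n, dilation_nm = 35,
                         constraint_mask = NULL, seed = 1) {
  stopifnot(inherits(membrane_mask, "VoxelGrid"))
  mask <- grid_values(membrane_mask) > 0
  if (!any(mask)) stop("membrane mask is empty")
  d <- dim(mask)
  edt <- cpp_edt3d(mask, d, membrane_mask$spacing)
  shell <- edt > 0 & edt <= dilation_nm
  if (!is.null(constraint_mask)) {
    cmask <- grid_values(constraint_mask) > 0
    cedt <- cpp_edt3d(cmask, d, membrane_mask$spacing)
    shell <- shell & cedt <= dilation_nm
  }
  cand <- which(shell)
  if (length(cand) < n)
    stop("eligibility shell too small to host ", n, " distinct probes (",
         length(cand), " candidate voxels)")
  picked <- with_seed(seed, sample(cand, n))
  zyx <- arrayInd(picked, d) - 1L
  nm <- vox_to_nm(membrane_mask, zyx)
  coords <- cbind(x = nm[, 3], y = nm[, 2], z = nm[, 1])
  structure(list(coords = coords, voxel = zyx, n = n,
                 dilation_nm = dilation_nm, seed = seed,
                 constrained = !is.null(constraint_mask)),
            class = "ProbeSet")
}

#' @export
print.ProbeSet <- function(x, ...) {
  cat(sprintf("<ProbeSet> %d probes, %g-nm shell, seed %d\n",
              x$n, x$dilation_nm, x$seed))
  invisible(x)
}

#' Distance of probes to the nearest surface
#'
#' @param probes a [place_probes()] result (or an n x 3 `(x, y, z)` nm
#'   matrix).
#' @param mesh a [surface_mesh()].
#' @return numeric vector of nm distances, one per probe.
#' @export
probe_distances <- function(probes, mesh) {
  coords <- if (inherits(probes, "ProbeSet")) probes$coords else probes
  if (!nrow(mesh$triangles)) stop("empty mesh")
  cpp_mesh_distance(coords, mesh$vertices, mesh$triangles)$distance
}

#' Consistency of repeated probe measurements
#'
#' For each probe measured under several conditions (e.g. the same location
#' against surfaces from different AI models): the range (max - min) and the
#' relative absolute deviation, RAD = mean(|x_i - mean|) / mean, a scale-free
#' consistency metric.
#'
#' @param measurements numeric matrix, rows = probes, columns = conditions
#'   (at least 2).
#' @return data.frame `probe`, `range`, `rad`; probes with zero mean get
#'   `NA` RAD and are flagged in the `zero_mean` column.
#' @export
probe_consistency <- function(measurements) {
  m <- as.matrix(measurements)
  if (ncol(m) < 2) stop("need at least two measurements per probe")
  rng <- apply(m, 1, max) - apply(m, 1, min)
  mu <- rowMeans(m)
  rad <- rowMeans(abs(m - mu)) / mu
  zero <- mu == 0
  rad[zero] <- NA_real_
  data.frame(probe = seq_len(nrow(m)), range = rng, rad = rad,
             zero_mean = zero)
}

# evaluate expr under a fixed RNG seed without disturbing the global stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
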