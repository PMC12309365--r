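# The AIVE core: Gaussian smoothing of AI probability maps, voxel-wise
# multiplication with normalized EM intensities, label masking, organelle
# filling, and inter-model disagreement (delta-V) quantification.

#' Smooth a probability map with a physical Gaussian
#'
#' Gaussian blur with per-axis sigma `sigma_nm / spacing_axis` voxels
#' (anisotropy-corrected), the standard 10-nm pre-blur applied to AI
#' predictions before voxel extraction.
#'
#' @param pmap a [probability_map()].
#' @param sigma_nm physical standard deviation, nm (default 10; 0 = identity).
#' @return a `ProbabilityMap`; values stay in `[0, 1]` and total probability
#'   mass is conserved away from the volume border.
#' @export
smooth_probability <- function(pmap, sigma_nm = 10) {
  stopifnot(inherits(pmap, "ProbabilityMap"))
  if (sigma_nm < 0) stop("sigma_nm must be >= 0")
  if (sigma_nm == 0) return(pmap)
  sig <- sigma_nm / pmap$spacing
  v <- cpp_gaussian3d(pmap$values, dim(pmap$values), sig)
  v[v < 0] <- 0
  v[v > 1] <- 1
  probability_map(v, pmap$spacing, class_name = pmap$class_name,
                  origin = pmap$origin)
}

#' Voxel extraction: probability times electron signal
#'
#' The defining AIVE operation: each output voxel is `round(p * I)` on the
#' 8-bit scale, so a 50% membrane probability over a mid-range intensity of
#' 128 yields 64 - the product of two independent dynamic ranges whose
#' common center is 25%, not 50%. Voxels where either input is zero are
#' excluded from the output.
#'
#' @param pmap a [probability_map()].
#' @param em 8-bit [voxel_grid()] of normalized EM intensities, same shape
#'   and spacing.
#' @return 8-bit `VoxelGrid`.
#' @export
voxel_extract <- function(pmap, em) {
  stopifnot(inherits(pmap, "ProbabilityMap"), inherits(em, "VoxelGrid"))
  if (!same_geometry(pmap, em)) stop("shape/spacing mismatch between inputs")
  if (em$depth != "8bit") stop("EM grid must be 8-bit")
  out <- as_8bit(pmap$values * em$values)
  voxel_grid(out, em$spacing, origin = em$origin,
             name = paste0(pmap$class_name, "_aive"), depth = "8bit")
}

#' Mask a probability map by an organelle label
#'
#' The binary mask of the target label is blurred with a physical Gaussian
#' (10 nm by default) and multiplied voxel-wise into the probability map:
#' classification labels identify an organelle without defining its boundary.
#'
#' @param pmap a [probability_map()].
#' @param labels a [label_volume()].
#' @param target label id present in the label table.
#' @param sigma_nm mask blur, nm.
#' @return a `ProbabilityMap` restricted to the target's neighborhood.
#' @export
mask_by_label <- function(pmap, labels, target, sigma_nm = 10) {
  stopifnot(inherits(pmap, "ProbabilityMap"), inherits(labels, "LabelVolume"))
  if (!target %in% labels$table$label) stop("unknown label id: ", target)
  mask <- (labels$labels == target) * 1.0
  if (sigma_nm > 0) {
    mask <- cpp_gaussian3d(mask, dim(mask), sigma_nm / labels$spacing)
    mask[mask < 0] <- 0
    mask[mask > 1] <- 1
  }
  probability_map(pmap$values * mask, pmap$spacing,
                  class_name = paste0(pmap$class_name, "_label", target),
                  origin = pmap$origin)
}

#' Fill an organelle interior
#'
#' Multiplies the Matter class with the organelle's label mask, extracts the
#' matching electron signal, and adds the result to the AIVE membrane output
#' (saturating at 255), imputing the matrix of e.g. a mitochondrion.
#'
#' @param matter Matter-class [probability_map()].
#' @param labels a [label_volume()].
#' @param target label id.
#' @param membrane_aive 8-bit membrane AIVE [voxel_grid()].
#' @param em 8-bit normalized EM [voxel_grid()].
#' @param sigma_nm mask blur, nm.
#' @return 8-bit `VoxelGrid`; never below `membrane_aive` anywhere.
#' @export
fill_organelle <- function(matter, labels, target, membrane_aive, em,
                           sigma_nm = 10) {
  stopifnot(inherits(membrane_aive, "VoxelGrid"), inherits(em, "VoxelGrid"))
  if (!same_geometry(matter, em) || !same_geometry(membrane_aive, em))
    stop("shape/spacing mismatch between inputs")
  filling <- voxel_extract(mask_by_label(matter, labels, target, sigma_nm), em)
  out <- pmin(membrane_aive$values + filling$values, 255)
  voxel_grid(out, em$spacing, origin = em$origin,
             name = paste0("filled_label", target), depth = "8bit")
}

#' Merge membrane subclass probability maps
#'
#' Membrane subclasses (e.g. Memb and Vesc) are combined by voxel-wise
#' probability maximum, which keeps the result in `[0, 1]`.
#'
#' @param ... two or more [probability_map()]s with identical geometry.
#' @return a merged `ProbabilityMap`.
#' @export
merge_membrane_maps <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && is.list(maps[[1]]) &&
      !inherits(maps[[1]], "ProbabilityMap")) maps <- maps[[1]]
  if (length(maps) < 2L) stop("need at least two maps to merge")
  for (m in maps[-1]) if (!same_geometry(maps[[1]], m))
    stop("shape/spacing mismatch between maps")
  v <- Reduce(pmax, lapply(maps, function(m) m$values))
  probability_map(v, maps[[1]]$spacing, class_name = "Memb_merged",
                  origin = maps[[1]]$origin)
}

#' Inter-model disagreement (delta-V)
#'
#' The absolute difference in voxel values between each pair of co-registered
#' predictions, expressed as a percentage of each grid's own dynamic range
#' (0-255 for 8-bit, 0-1 for probabilities), summarized per z-slice for every
#' two-way comparison and averaged per model over all its pairs.
#'
#' @param maps list of two or more `VoxelGrid`/`ProbabilityMap` objects (or
#'   plain arrays) with identical shape.
#' @param names model names; defaults to `model1`, `model2`, ...
#' @return a `DisagreementReport`: `per_slice` (data.frame model_a, model_b,
#'   slice, dv_pct), `per_pair` (mean over slices), and `per_model` (each
#'   model against all others), all in percent.
#' @export
delta_v_compare <- function(maps, names = NULL) {
  if (length(maps) < 2L) stop("need at least two grids to compare")
  arrs <- lapply(maps, function(m) {
    if (inherits(m, "VoxelGrid")) {
      if (m$depth == "8bit") m$values / 255 * 100 else m$values * 100
    } else if (inherits(m, "ProbabilityMap")) {
      m$values * 100
    } else if (is.array(m)) {
      if (max(m) > 1) m / 255 * 100 else m * 100
    } else stop("unsupported input to delta_v_compare")
  })
  d <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), d)) stop("shape mismatch")
  if (is.null(names)) names <- paste0("model", seq_along(arrs))
  k <- length(arrs)
  per_slice <- NULL
  pair_means <- NULL
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      dv <- abs(arrs[[i]] - arrs[[j]])
      slice_means <- apply(dv, 1, mean)
      per_slice <- rbind(per_slice, data.frame(
        model_a = names[i], model_b = names[j],
        slice = seq_len(d[1]), dv_pct = slice_means,
        stringsAsFactors = FALSE))
      pair_means <- rbind(pair_means, data.frame(
        model_a = names[i], model_b = names[j], dv_pct = mean(dv),
        stringsAsFactors = FALSE))
    }
  }
  per_model <- vapply(names, function(nm) {
    mean(pair_means$dv_pct[pair_means$model_a == nm |
                             pair_means$model_b == nm])
  }, numeric(1))
  structure(list(per_slice = per_slice, per_pair = pair_means,
                 per_model = per_model),
            class = "DisagreementReport")
}

#' @export
print.DisagreementReport <- function(x, ...) {
  cat("<DisagreementReport>\n per-model mean delta-V (% of dynamic range):\n")
  print(round(x$per_model, 3))
  invisible(x)
}
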