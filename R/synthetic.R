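# Synthetic phantom volumes: membranous shells, tubes, dumbbells and
# intruded sphere pairs rendered on an anisotropic grid with 8-bit intensity
# plus Gaussian and shot noise, noise-free ground-truth membership maps, and
# simulated "AI model" probability maps that agree in object interiors but
# disagree at boundaries. Defaults emulate the FIB-SEM acquisition regime
# the pipeline targets: 3.255 x 3.255 x 10 nm voxels, membrane rendered
# brighter than matrix (osmium contrast polarity), moderate detector noise.

#' Phantom specification
#'
#' @param shape grid dimensions `(nz, ny, nx)`.
#' @param spacing voxel spacing `(c, b, a)` nm; default the FIB-SEM
#'   (10, 3.255, 3.255).
#' @param objects list of objects; each a list with `type` (`"ball"`,
#'   `"shell"`, `"tube"`, `"dumbbell"`), a center `center` (`(x, y, z)` nm;
#'   tubes/dumbbells use `p1`, `p2`), `radius_nm`, and optional `class`.
#' @param membrane_nm membrane shell thickness, default 20 nm.
#' @param intensity named levels (0-255) for `membrane`, `matrix`,
#'   `cytosol`; membrane brightest by default.
#' @param noise list: `gaussian_sd` (8-bit units) and `shot_fraction`
#'   (salt-and-pepper voxel fraction).
#' @param label_margin_nm how far instance labels extend beyond the object
#'   surface, default 30 nm: classification labels identify an approximate
#'   region around an organelle (annotators draw them generously) and never
#'   define its boundary. Overlapping margins are resolved to the nearest
#'   object.
#' @param seed RNG seed; generation is deterministic per seed.
#' @return a `PhantomSpec`.
#' @export
phantom_spec <- function(shape, spacing = c(10, 3.255, 3.255),
                         objects = list(), membrane_nm = 20,
                         intensity = c(membrane = 200, matrix = 140,
                                       cytosol = 60),
                         noise = list(gaussian_sd = 8, shot_fraction = 0.005),
                         label_margin_nm = 30, seed = 1) {
  if (any(intensity < 0) || any(intensity > 255))
    stop("intensity levels must lie in [0, 255]")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 objects = objects, membrane_nm = membrane_nm,
                 intensity = intensity, noise = noise,
                 label_margin_nm = label_margin_nm, seed = seed),
            class = "PhantomSpec")
}

# signed distance (nm) from every voxel center to an object's mid-surface;
# negative inside the enclosed volume
object_sdist <- function(obj, co) {
  if (obj$type %in% c("ball", "shell")) {
    ctr <- obj$center # (x, y, z) nm
    sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2) -
      obj$radius_nm
  } else if (obj$type == "tube") {
    seg_dist(co, obj$p1, obj$p2) - obj$radius_nm
  } else {
    stop("unknown object type: ", obj$type)
  }
}

seg_dist <- function(co, p1, p2) {
  v <- p2 - p1
  len2 <- sum(v^2)
  t <- ((co$x - p1[1]) * v[1] + (co$y - p1[2]) * v[2] +
          (co$z - p1[3]) * v[3]) / max(len2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  sqrt((co$x - (p1[1] + t * v[1]))^2 + (co$y - (p1[2] + t * v[2]))^2 +
         (co$z - (p1[3] + t * v[3]))^2)
}

# fractional membership with a one-voxel linear ramp at the boundary
ramp_inside <- function(sdist, width) pmin(pmax(0.5 - sdist / width, 0), 1)

#' Render a phantom volume
#'
#' Builds the noise-free membership functions for membrane (a band of
#' `membrane_nm` around each object's mid-surface; for solid balls the outer
#' shell) and matter (the enclosed interior; hollow objects such as shells
#' and dumbbell necks have none), renders an 8-bit EM image from the
#' intensity levels plus Gaussian and shot noise, and assigns instance
#' labels over each object's solid extent.
#'
#' @param spec a [phantom_spec()].
#' @return list `em` ([voxel_grid()]), `truth_membrane`, `truth_matter`
#'   ([probability_map()]s), `labels` ([label_volume()]).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$shape
  sp <- spec$spacing
  co <- coord_arrays(d, sp)
  width <- min(sp) # ramp width
  memb <- array(0, d)
  matter <- array(0, d)
  labels <- array(0L, d)
  table <- NULL
  half <- spec$membrane_nm / 2
  expand_objects <- function(objs) {
    out <- list()
    for (obj in objs) {
      if (identical(obj$type, "dumbbell")) {
        r_neck <- if (!is.null(obj$neck_radius_nm)) obj$neck_radius_nm
                  else obj$radius_nm / 4
        out <- c(out, list(
          list(type = "shell", center = obj$p1, radius_nm = obj$radius_nm,
               class = obj$class, hollow = FALSE),
          list(type = "shell", center = obj$p2, radius_nm = obj$radius_nm,
               class = obj$class, group = TRUE, hollow = FALSE),
          list(type = "tube", p1 = obj$p1, p2 = obj$p2, radius_nm = r_neck,
               class = obj$class, group = TRUE, hollow = TRUE)))
      } else out <- c(out, list(obj))
    }
    out
  }
  objs <- expand_objects(spec$objects)
  inst <- 0L
  margin <- if (is.null(spec$label_margin_nm)) 30 else spec$label_margin_nm
  best_sdist <- array(Inf, d)
  for (oi in seq_along(objs)) {
    obj <- objs[[oi]]
    sdist <- object_sdist(obj, co)
    band <- ramp_inside(abs(sdist) - half, width)
    memb <- pmax(memb, band)
    interior <- ramp_inside(sdist + half, width)
    if (!isTRUE(obj$hollow)) matter <- pmax(matter, interior)
    if (!isTRUE(obj$group)) {
      inst <- inst + 1L
      table <- rbind(table, data.frame(
        label = inst,
        class = if (is.null(obj$class)) "organelle" else obj$class,
        stringsAsFactors = FALSE))
    }
    # generous label region, nearest object wins where margins overlap
    claim <- sdist <= half + margin & sdist < best_sdist
    labels[claim] <- inst
    best_sdist[claim] <- sdist[claim]
  }
  base <- spec$intensity["cytosol"]
  em <- base + matter * (spec$intensity["matrix"] - base)
  em <- em + memb * (spec$intensity["membrane"] - em)
  em <- with_seed(spec$seed, {
    v <- em + rnorm(length(em), sd = spec$noise$gaussian_sd)
    nshot <- round(spec$noise$shot_fraction * length(v))
    if (nshot > 0) {
      at <- sample(length(v), nshot)
      v[at] <- sample(c(0, 255), nshot, replace = TRUE)
    }
    v
  })
  em <- array(as_8bit(em), d)
  tbl <- if (is.null(table)) NULL else
    data.frame(label = table$label, class = table$class,
               instance = stats::ave(table$label, table$class,
                                     FUN = seq_along),
               clipped = vapply(table$label, function(id)
                 touches_border(labels == id), logical(1)),
               stringsAsFactors = FALSE)
  list(
    em = voxel_grid(em, sp, name = "phantom_em", depth = "8bit"),
    truth_membrane = probability_map(memb, sp, class_name = "Memb"),
    truth_matter = probability_map(matter, sp, class_name = "Matter"),
    labels = label_volume(labels, sp, table = tbl)
  )
}

#' Intruded or tangent sphere-pair phantom
#'
#' Two spheres of equal diameter (default 128 voxels). In `"intruded"` mode
#' sphere 2 extends into a matching invagination of sphere 1 separated by a
#' uniform seam; in `"tangent"` mode the spheres touch externally with the
#' same seam gap. The anomalous 0-5 unit peak in the surface-separation
#' histogram distinguishes the two geometries.
#'
#' @param diameter_vox sphere diameter in voxels, default 128.
#' @param intrusion_depth how far sphere 2 penetrates sphere 1 (same units
#'   as `spacing`); 0 reduces to tangency.
#' @param seam_gap surface-to-surface seam, default 1 unit.
#' @param mode `"intruded"` or `"tangent"`.
#' @param spacing voxel spacing, default isotropic 1 (distances then in
#'   voxel units, as in the simulated-contact benchmark).
#' @return list of two scalar [voxel_grid()]s (`sphere1`, `sphere2`, values
#'   0-255 with a one-voxel boundary ramp; mesh at isovalue 127.5), plus the
#'   geometry (`centers`, `radius`).
#' @export
intruded_spheres <- function(diameter_vox = 128, intrusion_depth = 0,
                             seam_gap = 1, mode = c("intruded", "tangent"),
                             spacing = c(1, 1, 1)) {
  mode <- match.arg(mode)
  if (mode == "tangent") intrusion_depth <- 0
  R <- diameter_vox / 2
  if (intrusion_depth >= diameter_vox)
    stop("intrusion depth must be smaller than the sphere diameter")
  gap <- seam_gap
  sep <- 2 * R + gap - intrusion_depth # center-to-center along x
  margin <- 4
  nx <- ceiling(2 * R + sep + 2 * margin)
  ny <- nz <- ceiling(2 * R + 2 * margin + 2 * gap)
  d <- c(nz, ny, nx)
  co <- coord_arrays(d, spacing)
  cy <- (ny - 1) * spacing[2] / 2
  cz <- (nz - 1) * spacing[3] / 2
  c1 <- c(margin + R, cy, cz)
  c2 <- c(margin + R + sep, cy, cz)
  d1 <- sqrt((co$x - c1[1])^2 + (co$y - c1[2])^2 + (co$z - c1[3])^2) - R
  d2 <- sqrt((co$x - c2[1])^2 + (co$y - c2[2])^2 + (co$z - c2[3])^2) - R
  w <- min(spacing)
  # sphere 1 = ball 1 minus (ball 2 grown by the seam): the invagination
  mu1 <- ramp_inside(pmax(d1, -(d2 + gap)), w)
  mu2 <- ramp_inside(d2, w)
  list(sphere1 = voxel_grid(array(as_8bit(mu1 * 255), d), spacing,
                            name = "sphere1", depth = "8bit"),
       sphere2 = voxel_grid(array(as_8bit(mu2 * 255), d), spacing,
                            name = "sphere2", depth = "8bit"),
       centers = rbind(c1, c2), radius = R, mode = mode)
}

#' Simulate disagreeing AI model predictions
#'
#' Generates `k` probability maps that agree in object interiors (value
#' `interior_conf`) but displace object boundaries by an independent smooth
#' random warp of physical amplitude `boundary_jitter_nm` per variant,
#' emulating the inter-model variability of AI membrane segmenters: models
#' disagree about where a boundary runs, not whether the membrane exists, so
#' thin structures are translated locally rather than eroded, and variants
#' differ only near value transitions.
#'
#' @param truth ground-truth [probability_map()] (membership function).
#' @param k number of model variants, `>= 2`.
#' @param boundary_jitter_nm per-axis displacement scale (standard
#'   deviation), nm; 0 returns `truth * interior_conf` for every variant.
#' @param interior_conf interior confidence level, default 0.9.
#' @param prediction_noise per-voxel confidence noise (sd on the probability
#'   scale) riding on each variant, emulating the graininess of raw model
#'   predictions; default 0.05.
#' @param clutter_rate rate of isolated false-positive voxels (confidence
#'   drawn from U(0.5, 1)), the speckle that makes raw prediction surfaces
#'   unreliable and that the 10-nm pre-blur suppresses; default 0.002.
#'   Zero jitter, noise and clutter return exact scaled copies of the truth.
#' @param seed RNG seed; deterministic per seed.
#' @param field_sigma_nm correlation length of the boundary-disagreement
#'   displacement field, default 5 nm: disagreement between independently
#'   trained models is localized at the scale of individual image features.
#' @return list of `k` [probability_map()]s.
#' @export
simulate_ai_variants <- function(truth, k, boundary_jitter_nm = 10,
                                 interior_conf = 0.9, prediction_noise = 0.05,
                                 clutter_rate = 0.002, seed = 1,
                                 field_sigma_nm = 5) {
  stopifnot(inherits(truth, "ProbabilityMap"))
  if (k < 2) stop("need k >= 2 variants")
  d <- dim(truth$values)
  sp <- truth$spacing
  if (boundary_jitter_nm == 0 && prediction_noise == 0 && clutter_rate == 0) {
    return(lapply(seq_len(k), function(v)
      probability_map(truth$values * interior_conf, sp,
                      class_name = paste0(truth$class_name, "_model", v),
                      origin = truth$origin)))
  }
  sig_vox <- field_sigma_nm / sp
  smooth_field <- function() {
    eta <- array(rnorm(prod(d)), d)
    cpp_gaussian3d(eta, d, sig_vox)
  }
  # central difference along one axis, in 1/nm
  ddx <- function(f, axis) {
    n <- d[axis]
    idx_hi <- c(2:n, n)
    idx_lo <- c(1, 1:(n - 1))
    g <- switch(axis,
                f[idx_hi, , , drop = FALSE] - f[idx_lo, , , drop = FALSE],
                f[, idx_hi, , drop = FALSE] - f[, idx_lo, , drop = FALSE],
                f[, , idx_hi, drop = FALSE] - f[, , idx_lo, drop = FALSE])
    array(g, d) / (2 * sp[axis])
  }
  with_seed(seed, lapply(seq_len(k), function(v) {
    if (boundary_jitter_nm > 0) {
      # divergence-free displacement u = curl(A): boundaries move but thin
      # structures are not locally compressed or stretched
      az <- smooth_field(); ay <- smooth_field(); ax <- smooth_field()
      uz <- ddx(ax, 2) - ddx(ay, 3)
      uy <- ddx(az, 3) - ddx(ax, 1)
      ux <- ddx(ay, 1) - ddx(az, 2)
      nrm <- function(u) u / stats::sd(u) * boundary_jitter_nm
      # displacement in voxel units per axis
      mu <- cpp_warp3d(truth$values, d, nrm(uz) / sp[1], nrm(uy) / sp[2],
                       nrm(ux) / sp[3])
    } else {
      mu <- truth$values
    }
    if (prediction_noise > 0)
      mu <- mu + array(rnorm(prod(d), sd = prediction_noise), d)
    if (clutter_rate > 0) {
      nfp <- round(clutter_rate * prod(d))
      at <- sample(prod(d), nfp)
      mu[at] <- pmax(mu[at], runif(nfp, 0.5, 1))
    }
    mu <- pmin(pmax(mu, 0), 1)
    probability_map(mu * interior_conf, sp,
                    class_name = paste0(truth$class_name, "_model", v),
                    origin = truth$origin)
  }))
}
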