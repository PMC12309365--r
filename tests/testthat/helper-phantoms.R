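# Shared fixtures, all generated in code.

# antialiased ball scalar grid (values 0-255, one-voxel boundary ramp);
# mesh at isovalue 127.5 to place the surface at the analytic radius
ball_grid <- function(radius, dim = rep(ceiling(2 * radius) + 11, 3),
                      spacing = c(1, 1, 1),
                      center = (dim[c(3, 2, 1)] - 1) * spacing[c(3, 2, 1)] / 2) {
  co <- aive:::coord_arrays(dim, spacing)
  sdist <- sqrt((co$x - center[1])^2 + (co$y - center[2])^2 +
                  (co$z - center[3])^2) - radius
  mu <- pmin(pmax(0.5 - sdist / min(spacing), 0), 1)
  voxel_grid(array(aive:::as_8bit(mu * 255), dim), spacing, depth = "8bit")
}

# binary mask of a ball (voxel-center membership)
ball_mask <- function(radius, dim = rep(ceiling(2 * radius) + 11, 3),
                      spacing = c(1, 1, 1),
                      center = (dim[c(3, 2, 1)] - 1) * spacing[c(3, 2, 1)] / 2) {
  co <- aive:::coord_arrays(dim, spacing)
  array(sqrt((co$x - center[1])^2 + (co$y - center[2])^2 +
               (co$z - center[3])^2) <= radius, dim)
}

# axis-aligned tube (cylinder) mask from p1 to p2 (x,y,z physical)
tube_mask <- function(p1, p2, radius, dim, spacing = c(1, 1, 1)) {
  co <- aive:::coord_arrays(dim, spacing)
  array(aive:::seg_dist(co, p1, p2) <= radius, dim)
}

# two parallel square plate meshes separated by `gap` along z
plate_meshes <- function(side = 10, gap = 7, n = 6) {
  s <- seq(0, side, length.out = n)
  gpts <- expand.grid(x = s, y = s)
  tri_grid <- function() {
    idx <- matrix(seq_len(n * n), n, n)
    tris <- NULL
    for (i in 1:(n - 1)) for (j in 1:(n - 1)) {
      tris <- rbind(tris,
                    c(idx[i, j], idx[i + 1, j], idx[i, j + 1]),
                    c(idx[i + 1, j], idx[i + 1, j + 1], idx[i, j + 1]))
    }
    tris
  }
  a <- surface_mesh(cbind(gpts$x, gpts$y, 0), tri_grid(), name = "plateA")
  b <- surface_mesh(cbind(gpts$x, gpts$y, gap), tri_grid(), name = "plateB")
  list(a = a, b = b)
}

# brute-force point-to-triangle distances (independent oracle, pure R)
brute_mesh_distance <- function(points, verts, tris) {
  pt_tri <- function(p, a, b, c_) {
    # distance to the plane patch: min over projection (if inside) and edges
    seg <- function(p, u, v) {
      w <- v - u
      t <- sum((p - u) * w) / max(sum(w^2), 1e-300)
      t <- min(max(t, 0), 1)
      sqrt(sum((p - (u + t * w))^2))
    }
    n <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
           (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
           (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]))
    d <- min(seg(p, a, b), seg(p, b, c_), seg(p, c_, a))
    nn <- sum(n^2)
    if (nn > 1e-300) {
      proj <- p - sum((p - a) * n) / nn * n
      # barycentric test
      v0 <- c_ - a; v1 <- b - a; v2 <- proj - a
      d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
      d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
      den <- d00 * d11 - d01 * d01
      if (den > 1e-300) {
        u <- (d11 * d20 - d01 * d21) / den
        v <- (d00 * d21 - d01 * d20) / den
        if (u >= 0 && v >= 0 && u + v <= 1)
          d <- min(d, sqrt(sum((p - proj)^2)))
      }
    }
    d
  }
  apply(points, 1, function(p) {
    min(apply(tris, 1, function(tr)
      pt_tri(p, verts[tr[1], ], verts[tr[2], ], verts[tr[3], ])))
  })
}

# small shell phantom spec on the anisotropic FIB-SEM grid
shell_phantom_spec <- function(seed = 7, shape = c(44L, 120L, 120L),
                               radius_nm = 120) {
  spacing <- c(10, 3.255, 3.255)
  center <- (rev(shape) - 1) * rev(spacing) / 2 # (x, y, z) nm
  phantom_spec(
    shape = shape, spacing = spacing,
    objects = list(list(type = "shell", center = center,
                        radius_nm = radius_nm, class = "mito")),
    membrane_nm = 20, seed = seed)
}

# normalized EM for a phantom (CLAHE + median), as the pipeline applies it
normalize_em <- function(em) {
  median_denoise(clahe_anisotropic(em, tile_nm = 416, clip_limit = 3),
                 max(em$spacing))
}
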