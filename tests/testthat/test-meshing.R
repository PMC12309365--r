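# Isosurface extraction, mesh measures, measurable-distance limit, Feret.

test_that("grids entirely on one side of the isovalue give an empty mesh", {
  g <- voxel_grid(array(10, c(4, 4, 4)), c(1, 1, 1))
  m <- marching_cubes(g, isovalue = 64)
  expect_equal(nrow(m$vertices), 0)
  expect_equal(nrow(m$triangles), 0)
  expect_error(marching_cubes(voxel_grid(array(0, c(1, 3, 3)), c(1, 1, 1))),
               "at least 2 voxels")
})

test_that("a digitized ball meshes to one closed sphere-topology component", {
  g <- ball_grid(14)
  m <- marching_cubes(g, isovalue = 127.5)
  expect_true(m$watertight)
  mm <- mesh_measures(m)
  expect_equal(mm$euler, 2) # one component with sphere topology
  expect_true(mm$closed)
})

test_that("enclosed volume of a radius-40 ball is within 2% of analytic", {
  g <- ball_grid(40)
  m <- marching_cubes(g, isovalue = 127.5)
  mm <- mesh_measures(m)
  expect_equal(mm$volume_nm3, 4 / 3 * pi * 40^3, tolerance = 0.02)
  # per-vertex areas sum to the total triangle area
  expect_equal(sum(m$vertex_area), mm$area_nm2, tolerance = 1e-9)
})

test_that("sphericity behaves like the analytic oracle under refinement", {
  # analytic lat-long sphere mesh: sphericity -> 1 with refinement
  sphere_mesh <- function(R, n) {
    th <- seq(0, pi, length.out = n)
    ph <- seq(0, 2 * pi, length.out = 2 * n + 1)[-1]
    v <- rbind(c(0, 0, R), c(0, 0, -R))
    for (t in th[-c(1, n)]) for (p in ph)
      v <- rbind(v, R * c(sin(t) * cos(p), sin(t) * sin(p), cos(t)))
    ring <- function(i) 2 + (i - 1) * length(ph) + seq_along(ph)
    tris <- NULL
    r1 <- ring(1)
    for (j in seq_along(ph)) {
      jn <- if (j == length(ph)) 1 else j + 1
      tris <- rbind(tris, c(1, r1[j], r1[jn]))
    }
    for (i in 1:(n - 3)) {
      ra <- ring(i); rb <- ring(i + 1)
      for (j in seq_along(ph)) {
        jn <- if (j == length(ph)) 1 else j + 1
        tris <- rbind(tris, c(ra[j], rb[j], rb[jn]), c(ra[j], rb[jn], ra[jn]))
      }
    }
    rl <- ring(n - 2)
    for (j in seq_along(ph)) {
      jn <- if (j == length(ph)) 1 else j + 1
      tris <- rbind(tris, c(2, rl[jn], rl[j]))
    }
    surface_mesh(v, tris)
  }
  s_coarse <- mesh_measures(sphere_mesh(10, 12))$sphericity
  s_fine <- mesh_measures(sphere_mesh(10, 40))$sphericity
  expect_gt(s_fine, s_coarse)
  expect_gt(s_fine, 0.995)
  expect_lte(s_fine, 1 + 1e-9)

  # voxelized ball (after faceting relaxation) approaches 1; the 2:1:1
  # ellipsoid at the same resolution is strictly less spherical
  mb <- smooth_mesh(marching_cubes(ball_grid(20), isovalue = 127.5))
  sb <- mesh_measures(mb)$sphericity
  expect_gt(sb, 0.95)
  expect_lte(sb, 1 + 1e-6)
  d <- c(31L, 31L, 61L)
  co <- aive:::coord_arrays(d, c(1, 1, 1))
  sd_ell <- sqrt(((co$x - 30) / 2)^2 + ((co$y - 15))^2 + ((co$z - 15))^2) - 10
  mu <- pmin(pmax(0.5 - sd_ell, 0), 1)
  ge <- voxel_grid(array(aive:::as_8bit(mu * 255), d), c(1, 1, 1))
  se <- mesh_measures(smooth_mesh(marching_cubes(ge, isovalue = 127.5)))$sphericity
  expect_lt(se, sb)
})

test_that("open meshes get area but flagged-invalid volume", {
  pm <- plate_meshes()
  mm <- mesh_measures(pm$a)
  expect_false(mm$closed)
  expect_true(is.na(mm$volume_nm3) && is.na(mm$sphericity))
  expect_equal(mm$area_nm2, 100, tolerance = 1e-9)
})

test_that("minimum measurable distance uses the two smallest spacings", {
  expect_equal(round(min_measurable_distance(c(10, 3.255, 3.255)), 1), 2.3)
  expect_equal(min_measurable_distance(c(1, 1, 1)), 1 / sqrt(2))
  expect_equal(min_measurable_distance(c(100, 2, 2)), sqrt(2))
  expect_equal(min_measurable_distance(c(2, 100, 2)), sqrt(2)) # order-free
  expect_error(min_measurable_distance(c(0, 1, 1)), "positive")
})

test_that("Feret diameters match caliper geometry", {
  # disk of diameter 21 px
  n <- 25
  xy <- expand.grid(r = 1:n, c = 1:n)
  disk <- matrix((xy$r - 13)^2 + (xy$c - 13)^2 <= 10.5^2, n, n)
  expect_equal(feret_diameter(disk), 21, tolerance = 1.5 / 21)
  # axis-aligned square of side s: diagonal s * sqrt(2)
  sq <- matrix(FALSE, 20, 20)
  sq[5:14, 3:12] <- TRUE
  expect_equal(feret_diameter(sq), 10 * sqrt(2), tolerance = 1e-9)
  # anisotropic spacing scales the answer
  expect_equal(feret_diameter(sq, spacing = c(2, 1)),
               sqrt(20^2 + 10^2), tolerance = 1e-9)
  # 3:1 digital ellipse: major axis, against a brute-force point-pair oracle
  ell <- matrix((xy$r - 13)^2 / 12^2 + (xy$c - 13)^2 / 4^2 <= 1, n, n)
  pts <- which(ell, arr.ind = TRUE)
  corners <- rbind(cbind(pts[, 1] - 1.5, pts[, 2] - 1.5),
                   cbind(pts[, 1] - 1.5, pts[, 2] - 0.5),
                   cbind(pts[, 1] - 0.5, pts[, 2] - 1.5),
                   cbind(pts[, 1] - 0.5, pts[, 2] - 0.5))
  oracle <- max(dist(corners))
  expect_equal(feret_diameter(ell), oracle, tolerance = 1e-9)
  expect_error(feret_diameter(matrix(FALSE, 3, 3)), "empty")
})

test_that("scalar grids escape the binary vertex-position lattice", {
  # binary ball: only midpoint crossings (fractional offsets 0 and 0.5);
  # the antialiased scalar ball populates many distinct edge offsets
  gb <- voxel_grid(array(ball_mask(10) * 255, dim(ball_mask(10))),
                   c(1, 1, 1))
  mb <- marching_cubes(gb, isovalue = 127.5)
  offs_bin <- unique(round(as.vector(mb$vertices) %% 1, 6))
  gs <- ball_grid(10)
  ms <- marching_cubes(gs, isovalue = 127.5)
  offs_scalar <- unique(round(as.vector(ms$vertices) %% 1, 6))
  expect_lte(length(offs_bin), 2)
  expect_gt(length(offs_scalar), 10 * length(offs_bin))
})

test_that("PLY and STL export round-trip geometry", {
  m <- marching_cubes(ball_grid(6), isovalue = 127.5)
  fp <- tempfile(fileext = ".ply")
  write_ply(m, fp, scalar = m$vertex_area)
  back <- read_ply(fp)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-6)
  expect_equal(back$triangles, m$triangles)
  expect_equal(attr(back, "scalar"), m$vertex_area, tolerance = 1e-6)
  fs <- tempfile(fileext = ".stl")
  write_stl(m, fs)
  expect_equal(readBin(fs, "integer", n = 1, size = 4, endian = "little",
                       signed = TRUE) * 0 + file.size(fs),
               84 + 50 * nrow(m$triangles))
})

test_that("cube corner configurations reduce to the small canonical sets", {
  cc <- cube_config_classes()
  expect_equal(unname(cc["rotation"]), 23)
  # the classically cited count of 15 unique cases
  expect_true(15 %in% cc)
})
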