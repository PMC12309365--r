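# Distance maps, closest approach, contact fractions, histograms, probes.

test_that("surface distance is zero to self and the gap between plates", {
  pm <- plate_meshes(side = 10, gap = 7)
  self <- surface_distance(pm$a, pm$a)
  expect_true(all(self$distance == 0))
  dm <- surface_distance(pm$a, pm$b)
  expect_true(all(abs(dm$distance - 7) < 1e-9))
  expect_equal(closest_approach(dm), 7)
  expect_error(surface_distance(pm$a, surface_mesh(matrix(0, 0, 3),
                                                   matrix(0L, 0, 3))),
               "empty mesh")
})

test_that("exact agreement with the brute-force point-to-triangle oracle", {
  set.seed(4)
  m1 <- marching_cubes(ball_grid(5, dim = c(17L, 17L, 17L)), 127.5)
  m2 <- marching_cubes(ball_grid(2, dim = c(11L, 11L, 11L),
                                 center = c(7, 4, 5)), 127.5)
  expect_lte(nrow(m2$triangles), 500)
  keep <- sample(nrow(m1$vertices), 120)
  q <- surface_mesh(m1$vertices[keep, ], matrix(c(1L, 2L, 3L), 1))
  dm <- surface_distance(q, m2)
  oracle <- brute_mesh_distance(q$vertices, m2$vertices, m2$triangles)
  expect_lt(max(abs(dm$distance - oracle)), 1e-6)
  # random free points as well
  pts <- cbind(runif(40, -5, 25), runif(40, -5, 25), runif(40, -5, 25))
  got <- probe_distances(pts, m2)
  expect_lt(max(abs(got - brute_mesh_distance(pts, m2$vertices,
                                              m2$triangles))), 1e-6)
})

test_that("meshed ball pairs recover the analytic gap symmetrically", {
  r1 <- 10; r2 <- 7; D <- 25
  d <- c(30L, 30L, 50L)
  g1 <- ball_grid(r1, dim = d, center = c(10, 15, 15))
  g2 <- ball_grid(r2, dim = d, center = c(10 + D, 15, 15))
  m1 <- marching_cubes(g1, 127.5)
  m2 <- marching_cubes(g2, 127.5)
  gap <- D - r1 - r2
  half_diag <- sqrt(3) / 2
  ca12 <- closest_approach(surface_distance(m1, m2))
  ca21 <- closest_approach(surface_distance(m2, m1))
  expect_equal(ca12, gap, tolerance = half_diag / gap)
  # symmetry within about a mesh edge
  expect_lt(abs(ca12 - ca21), 1.1)
})

test_that("contact fraction counts members under the 35-nm criterion", {
  mk_dm <- function(d) structure(list(distance = d, vertex_area = rep(1,
    length(d)), query = "q", reference = "r"), class = "DistanceMap")
  pop <- c(lapply(c(0, 3, 34.9), function(x) mk_dm(c(x, x + 50))),
           lapply(rep(1000, 9), mk_dm))
  expect_equal(contact_fraction(pop), 3 / 12 * 100)
  expect_equal(contact_fraction(lapply(rep(0, 5), mk_dm)), 100)
  expect_equal(contact_fraction(lapply(rep(1e3, 5), mk_dm)), 0)
  expect_error(contact_fraction(list()), "empty")
})

test_that("surface histograms are area-weighted, half-open and total 100%", {
  mk_dm <- function(d, a) structure(list(distance = d, vertex_area = a,
    query = "q", reference = "r"), class = "DistanceMap")
  h <- surface_histogram(mk_dm(rep(2, 4), rep(1, 4)))
  expect_equal(h$area_pct[1], 100)
  expect_equal(sum(h$area_pct), 100)
  # plates at 103 nm fall entirely in the 100-105 bin
  pm <- plate_meshes(side = 10, gap = 103)
  dmp <- surface_distance(pm$a, pm$b)
  hp <- surface_histogram(dmp)
  expect_equal(hp$area_pct[hp$lo == 100], 100)
  # half-open binning: a distance exactly at a bin edge joins the upper bin
  hb <- surface_histogram(mk_dm(c(5, 5), c(1, 3)))
  expect_equal(hb$area_pct[hb$lo == 5], 100)
  # overflow pooling keeps the total at 100
  ho <- surface_histogram(mk_dm(c(2, 400), c(1, 1)))
  expect_equal(ho$area_pct[nrow(ho)], 50)
  expect_equal(sum(ho$area_pct), 100)
  expect_error(surface_histogram(mk_dm(1, 1), bin_nm = 0), "positive")
})

test_that("probes land in the eligibility shell, deterministically", {
  d <- c(20L, 24L, 24L)
  mask <- array(FALSE, d)
  mask[10, , ] <- TRUE # single plane membrane
  g <- voxel_grid(array(mask * 255, d), c(10, 3.255, 3.255))
  ps <- place_probes(g, 30, dilation_nm = 35, seed = 42)
  expect_equal(nrow(ps$coords), 30)
  # all probes within 35 nm of the plane but never on it
  dz <- abs(ps$coords[, 3] - 9 * 10)
  expect_true(all(dz > 0 & dz <= 35))
  ps2 <- place_probes(g, 30, dilation_nm = 35, seed = 42)
  expect_identical(ps$coords, ps2$coords)
  ps3 <- place_probes(g, 30, dilation_nm = 35, seed = 43)
  expect_false(identical(ps$coords, ps3$coords))
  # a membrane filling the whole grid leaves no shell
  gfull <- voxel_grid(array(255, d), c(10, 3.255, 3.255))
  expect_error(place_probes(gfull, 5), "shell too small|empty")
  # constrained variant respects both masks
  cmask <- array(FALSE, d)
  cmask[1:10, 1:8, ] <- TRUE
  gc2 <- voxel_grid(array(cmask * 255, d), c(10, 3.255, 3.255))
  psc <- place_probes(g, 10, constraint_mask = gc2, seed = 1)
  cedt <- aive:::cpp_edt3d(cmask, d, g$spacing)
  at <- psc$voxel
  for (r in seq_len(nrow(at)))
    expect_lte(cedt[at[r, 1] + 1, at[r, 2] + 1, at[r, 3] + 1], 35)
})

test_that("probe consistency implements range and RAD", {
  m <- rbind(c(2, 4), c(3, 3), c(10, 30))
  pc <- probe_consistency(m)
  expect_equal(pc$range, c(2, 0, 20))
  expect_equal(pc$rad[1], (1 + 1) / 2 / 3) # {2,4}: mad 1, mean 3
  expect_equal(pc$rad[2], 0)
  # scale invariance of RAD
  pc10 <- probe_consistency(m * 10)
  expect_equal(pc10$rad, pc$rad)
  expect_equal(pc10$range, pc$range * 10)
  # zero mean flagged
  pz <- probe_consistency(rbind(c(0, 0)))
  expect_true(pz$zero_mean[1] && is.na(pz$rad[1]))
  expect_error(probe_consistency(matrix(1, 3, 1)), "at least two")
})
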