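# Shape analytics: ellipsoid fits, skeleton paths, nanotunnels, cavities,
# and the Poisson occurrence model.

test_that("equivalent ellipsoid recovers box and spheroid geometry", {
  # 8 x 2 x 2 voxel box: axes 4:1:1 from the closed-form box moments
  m <- array(FALSE, c(12, 6, 6))
  m[2:9, 2:3, 2:3] <- TRUE
  ee <- equivalent_ellipsoid(m, c(1, 1, 1))
  expect_equal(ee$axes[1] / ee$axes[2], 4, tolerance = 1e-9)
  expect_equal(ee$axes[2] / ee$axes[3], 1, tolerance = 1e-9)
  expect_equal(ee$elongation, 4, tolerance = 1e-9)
  # digitized ball: elongation 1 within 2%
  eb <- equivalent_ellipsoid(ball_mask(10), c(1, 1, 1))
  expect_equal(eb$elongation, 1, tolerance = 0.02)
  # 4:1 prolate spheroid within 5%
  d <- c(25L, 25L, 90L)
  co <- aive:::coord_arrays(d, c(1, 1, 1))
  sph <- ((co$x - 44) / 40)^2 + ((co$y - 12) / 10)^2 + ((co$z - 12) / 10)^2 <= 1
  es <- equivalent_ellipsoid(array(sph, d), c(1, 1, 1))
  expect_equal(es$elongation, 4, tolerance = 0.05)
  # anisotropic spacing is honored: a cube of voxels with (2,1,1) nm spacing
  cube <- array(TRUE, c(4, 8, 8))
  ec <- equivalent_ellipsoid(cube, c(2, 1, 1))
  expect_equal(ec$elongation, 1, tolerance = 1e-9)
  expect_error(equivalent_ellipsoid(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("skeleton longest path measures tubes and collapses balls", {
  # straight tube along x, length 40, radius 3
  d <- c(11L, 11L, 52L)
  tm <- tube_mask(c(6, 5, 5), c(46, 5, 5), 3, d)
  sk <- skeleton_longest_path(tm, c(1, 1, 1))
  expect_equal(sk$length_nm, 40, tolerance = 2 * sqrt(3) / 40)
  # L-shaped tube: arms 30 and 25
  dL <- c(11L, 42L, 42L)
  tl <- tube_mask(c(5, 5, 5), c(35, 5, 5), 3, dL) |
    tube_mask(c(35, 5, 5), c(35, 30, 5), 3, dL)
  skl <- skeleton_longest_path(tl, c(1, 1, 1))
  expect_equal(skl$length_nm, 55, tolerance = 4 * sqrt(3) / 55)
  # ball: the skeleton collapses far below the diameter
  skb <- skeleton_longest_path(ball_mask(10), c(1, 1, 1))
  expect_lt(skb$length_nm, 20)
  # disconnected solids give per-component results
  two <- array(FALSE, c(5L, 5L, 30L))
  two[2:4, 2:4, 2:8] <- TRUE
  two[2:4, 2:4, 20:29] <- TRUE
  skt <- skeleton_longest_path(two, c(1, 1, 1))
  expect_equal(skt$n_components, 2)
  expect_length(skt$per_component, 2)
  expect_error(skeleton_longest_path(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("skeleton length is stable under 90-degree grid rotation", {
  d <- c(11L, 11L, 52L)
  tm <- tube_mask(c(6, 5, 5), c(46, 5, 5), 3, d)
  rot <- aperm(tm, c(3, 2, 1)) # swap z and x
  a <- skeleton_longest_path(tm, c(1, 1, 1))$length_nm
  b <- skeleton_longest_path(rot, c(1, 1, 1))$length_nm
  # directional sub-iterations make thinning only near-equivariant; the
  # endpoints can shift by about a voxel at each end
  expect_lt(abs(a - b), 2 * sqrt(3))
})

test_that("nanotunnels are flagged by matrix separation in one solid", {
  sp <- c(10, 3.255, 3.255)
  shape <- c(30L, 60L, 150L)
  ctr_y <- (shape[2] - 1) * sp[2] / 2
  ctr_z <- (shape[1] - 1) * sp[1] / 2
  spec <- phantom_spec(
    shape = shape, spacing = sp,
    objects = list(list(type = "dumbbell",
                        p1 = c(90, ctr_y, ctr_z), p2 = c(380, ctr_y, ctr_z),
                        radius_nm = 70, neck_radius_nm = 25, class = "mito")),
    membrane_nm = 20, seed = 5,
    noise = list(gaussian_sd = 0, shot_fraction = 0))
  ph <- make_phantom(spec)
  memb <- voxel_extract(ph$truth_membrane, ph$em)
  mat <- voxel_extract(ph$truth_matter, ph$em)
  inst <- organelle_instance(1L, memb, mat)
  nt <- nanotunnel_flag(inst)
  expect_true(nt$flag)
  expect_equal(nt$n_matrix_components, 2)
  # a single blob has one matrix volume: no nanotunnel
  spec2 <- shell_phantom_spec(seed = 6, shape = c(24L, 60L, 60L),
                              radius_nm = 60)
  spec2$noise <- list(gaussian_sd = 0, shot_fraction = 0)
  ph2 <- make_phantom(spec2)
  inst2 <- organelle_instance(1L, voxel_extract(ph2$truth_membrane, ph2$em),
                              voxel_extract(ph2$truth_matter, ph2$em))
  expect_false(nanotunnel_flag(inst2)$flag)
  # two disjoint solids are rejected outright
  v <- array(0, c(6, 6, 20))
  v[2:5, 2:5, 2:6] <- 200
  v[2:5, 2:5, 12:18] <- 200
  g <- voxel_grid(v, c(1, 1, 1))
  inst3 <- organelle_instance(1L, g, g)
  expect_error(nanotunnel_flag(inst3), "one connected component")
})

test_that("a drilled blind channel is detected and measured as a cavity", {
  # ball radius 20 with a channel of radius 5, depth 30 drilled along +x
  dim3 <- c(45L, 45L, 45L)
  ctr <- c(22, 22, 22)
  ball <- ball_mask(20, dim = dim3, center = ctr)
  channel <- tube_mask(c(ctr[1] - 20, 22, 22), c(ctr[1] - 20 + 30, 22, 22),
                       5, dim3)
  solid <- ball & !channel
  g <- voxel_grid(array(solid * 255, dim3), c(1, 1, 1))
  inst <- organelle_instance(1L, g, g, isovalue = 127)
  cav <- detect_cavities(inst, closing_radius_nm = 12, min_depth_nm = 10)
  expect_length(cav, 1)
  rec <- cav[[1]]
  expect_equal(rec$category, "empty")
  # parameter recovery: depth within 2 voxel diagonals, radius within 1 vox
  expect_equal(rec$depth_nm, 30, tolerance = 2 * sqrt(3) / 30)
  expect_equal(rec$inscribed_radius_nm, 5, tolerance = 1 / 5)
  cyl_vol <- pi * 25 * 30
  expect_equal(rec$volume_nm3, cyl_vol, tolerance = 0.25)
  # solid ball alone has no cavities
  gb <- voxel_grid(array(ball * 255, dim3), c(1, 1, 1))
  instb <- organelle_instance(1L, gb, gb, isovalue = 127)
  expect_length(detect_cavities(instb, closing_radius_nm = 12,
                                min_depth_nm = 10), 0)
})

test_that("an occupied channel is categorized by the intruding label", {
  dim3 <- c(45L, 45L, 45L)
  ctr <- c(22, 22, 22)
  ball <- ball_mask(20, dim = dim3, center = ctr)
  channel <- tube_mask(c(2, 22, 22), c(ctr[1] - 20 + 30, 22, 22), 5, dim3)
  solid <- ball & !channel
  tube_in <- tube_mask(c(2, 22, 22), c(ctr[1] - 20 + 28, 22, 22), 4, dim3)
  labs <- array(0L, dim3)
  labs[tube_in] <- 7L
  lv <- label_volume(labs, c(1, 1, 1),
                     table = data.frame(label = 7L, class = "ER",
                                        instance = 1L, clipped = TRUE))
  g <- voxel_grid(array(solid * 255, dim3), c(1, 1, 1))
  inst <- organelle_instance(1L, g, g, isovalue = 127)
  cav <- detect_cavities(inst, closing_radius_nm = 12, min_depth_nm = 10,
                         other_labels = lv)
  expect_length(cav, 1)
  expect_equal(cav[[1]]$category, "ER")
})

test_that("cavity metrics match analytic cylinders and single voxels", {
  # flat-ended cylinder radius 5, length 50 along x
  d <- c(13L, 13L, 60L)
  co <- aive:::coord_arrays(d, c(1, 1, 1))
  cyl <- co$x >= 4 & co$x <= 53 & (co$y - 6)^2 + (co$z - 6)^2 <= 25
  rec <- structure(list(voxels = which(array(cyl, d), arr.ind = TRUE) - 1L),
                   class = "CavityRecord")
  rec <- cavity_metrics(rec, spacing = c(1, 1, 1))
  expect_equal(rec$inscribed_radius_nm, 5, tolerance = 0.1)
  expect_equal(rec$major_axis_nm, 50, tolerance = 0.05)
  expect_equal(rec$volume_nm3, pi * 25 * 50, tolerance = 0.1)
  one <- structure(list(voxels = matrix(c(1L, 1L, 1L), 1)),
                   class = "CavityRecord")
  expect_equal(cavity_metrics(one, spacing = c(10, 3.255, 3.255))$volume_nm3,
               10 * 3.255^2)
  # spherical cavity: inscribed radius equals the sphere radius
  sph <- structure(list(voxels = which(ball_mask(8), arr.ind = TRUE) - 1L),
                   class = "CavityRecord")
  expect_equal(cavity_metrics(sph, spacing = c(1, 1, 1))$inscribed_radius_nm,
               8, tolerance = 0.15)
})

test_that("the Poisson model reproduces the intrusion statistics", {
  counts <- c(rep(0, 149), rep(1, 26), rep(2, 9), rep(3, 2)) # 50 over 186
  expect_length(counts, 186)
  expect_equal(sum(counts), 50)
  fit <- intrusion_poisson(counts)
  expect_equal(round(fit$lambda, 3), 0.269)
  expect_equal(fit$table$expected[1], exp(-fit$lambda))
  expect_equal(round(fit$table$expected[1], 3), 0.764)
  # all-zero counts degenerate cleanly
  f0 <- intrusion_poisson(rep(0, 10))
  expect_equal(f0$lambda, 0)
  expect_equal(f0$table$expected[f0$table$k == 0], 1)
  # the pmf over all k sums to one
  expect_equal(sum(dpois(0:50, fit$lambda)), 1, tolerance = 1e-12)
  expect_error(intrusion_poisson(integer(0)), "empty")
  expect_error(intrusion_poisson(c(1, -2)), "non-negative")
})

test_that("membrane and matrix volumes track each other on phantoms", {
  sp <- c(10, 3.255, 3.255)
  vols <- vapply(c(50, 70, 90, 110), function(r) {
    shape <- c(30L, 90L, 90L)
    spec <- shell_phantom_spec(seed = r, shape = shape, radius_nm = r)
    ph <- make_phantom(spec)
    memb <- voxel_extract(smooth_probability(ph$truth_membrane, 10), ph$em)
    mat <- voxel_extract(smooth_probability(ph$truth_matter, 10), ph$em)
    inst <- organelle_instance(1L, memb, mat)
    c(sum(inst$membrane$values > 64), sum(inst$matrix_grid$values > 64))
  }, numeric(2))
  expect_gt(cor(vols[1, ], vols[2, ]), 0.99)
})
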