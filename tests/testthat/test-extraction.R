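# The AIVE core: smoothing, multiplication, masking, filling, delta-V.

test_that("probability smoothing is anisotropy-corrected and conservative", {
  pm <- probability_map(array(0.3, c(5, 5, 5)), c(10, 3.255, 3.255))
  expect_identical(smooth_probability(pm, 0), pm)
  expect_error(smooth_probability(pm, -1), ">= 0")
  # per-axis sigma rule: 10 nm over (10, 3.255, 3.255) = (1, 3.073, 3.073) vox
  expect_equal(10 / pm$spacing, c(1, 3.0722, 3.0722), tolerance = 1e-4)
  # unit impulse conserves total probability mass
  v <- array(0, c(31, 31, 31))
  v[16, 16, 16] <- 1
  pm2 <- probability_map(v, c(2, 1, 1))
  sm <- smooth_probability(pm2, 3)
  expect_equal(sum(sm$values), 1, tolerance = 1e-6)
  expect_true(all(sm$values >= 0 & sm$values <= 1))
})

test_that("voxel extraction multiplies the two dynamic ranges", {
  d <- c(2L, 2L, 2L)
  em <- voxel_grid(array(128, d), c(1, 1, 1))
  pm <- probability_map(array(0.5, d), c(1, 1, 1))
  expect_equal(unique(as.vector(voxel_extract(pm, em)$values)), 64)
  # p = 1 is the identity; p = 0 annihilates any intensity
  em2 <- voxel_grid(array(173, d), c(1, 1, 1))
  expect_equal(voxel_extract(probability_map(array(1, d), c(1, 1, 1)),
                             em2)$values, array(173, d))
  expect_equal(voxel_extract(probability_map(array(0, d), c(1, 1, 1)),
                             em2)$values, array(0, d))
  expect_error(voxel_extract(pm, voxel_grid(array(1, c(3, 2, 2)), c(1, 1, 1))),
               "mismatch")
})

test_that("extraction is monotone and bounded by both inputs", {
  set.seed(9)
  d <- c(4L, 6L, 6L)
  p <- array(runif(prod(d)), d)
  i <- array(sample(0:255, prod(d), TRUE), d)
  out <- voxel_extract(probability_map(p, c(1, 1, 1)),
                       voxel_grid(i, c(1, 1, 1)))$values
  expect_true(all(out <= i + 0.5))
  expect_true(all(out <= 255 * p + 0.5))
  p2 <- pmin(p + 0.2, 1)
  out2 <- voxel_extract(probability_map(p2, c(1, 1, 1)),
                        voxel_grid(i, c(1, 1, 1)))$values
  expect_true(all(out2 >= out))
})

test_that("label masking zeroes outside the masked region", {
  d <- c(4L, 4L, 8L)
  p <- array(0.8, d)
  labs <- array(0L, d)
  labs[, , 1:4] <- 1L # half-space
  lv <- label_volume(labs, c(1, 1, 1))
  pm <- probability_map(p, c(1, 1, 1))
  m0 <- mask_by_label(pm, lv, 1, sigma_nm = 0)
  expect_equal(m0$values[, , 1:4], p[, , 1:4])
  expect_true(all(m0$values[, , 5:8] == 0))
  expect_error(mask_by_label(pm, lv, 9), "unknown label")
  # all-one mask with zero blur is the identity
  lv1 <- label_volume(array(1L, d), c(1, 1, 1))
  expect_equal(mask_by_label(pm, lv1, 1, sigma_nm = 0)$values, p)
})

test_that("organelle filling adds matter inside and saturates at 255", {
  spec <- shell_phantom_spec(seed = 2, shape = c(20L, 56L, 56L),
                             radius_nm = 60)
  spec$noise <- list(gaussian_sd = 0, shot_fraction = 0)
  ph <- make_phantom(spec)
  em <- ph$em
  memb_aive <- voxel_extract(ph$truth_membrane, em)
  filled <- fill_organelle(ph$truth_matter, ph$labels, 1, memb_aive, em,
                           sigma_nm = 0)
  # never decreases relative to the membrane output
  expect_true(all(filled$values >= memb_aive$values))
  interior <- ph$truth_matter$values == 1
  expect_true(all(filled$values[interior] > 0))
  exterior <- ph$truth_matter$values == 0 & ph$truth_membrane$values == 0
  expect_equal(filled$values[exterior], memb_aive$values[exterior])
  # matter identically zero leaves the membrane output untouched
  zero_mat <- probability_map(array(0, dim(em$values)), em$spacing)
  same <- fill_organelle(zero_mat, ph$labels, 1, memb_aive, em)
  expect_equal(same$values, memb_aive$values)
  # saturation
  hot <- voxel_grid(array(200, c(2, 2, 2)), c(1, 1, 1))
  mat1 <- probability_map(array(1, c(2, 2, 2)), c(1, 1, 1))
  lv <- label_volume(array(1L, c(2, 2, 2)), c(1, 1, 1))
  em1 <- voxel_grid(array(100, c(2, 2, 2)), c(1, 1, 1))
  expect_equal(unique(as.vector(
    fill_organelle(mat1, lv, 1, hot, em1, sigma_nm = 0)$values)), 255)
})

test_that("membrane subclass merging takes the probability maximum", {
  d <- c(2L, 3L, 3L)
  a <- probability_map(array(runif(prod(d)), d), c(1, 1, 1), "Memb")
  b <- probability_map(array(runif(prod(d)), d), c(1, 1, 1), "Vesc")
  m <- merge_membrane_maps(a, b)
  expect_equal(m$values, pmax(a$values, b$values))
  expect_error(merge_membrane_maps(a), "at least two")
})

test_that("delta-V follows the percentage scale and averaging rules", {
  d <- c(3L, 4L, 4L)
  g0 <- voxel_grid(array(0, d), c(1, 1, 1))
  g255 <- voxel_grid(array(255, d), c(1, 1, 1))
  rep0 <- delta_v_compare(list(g0, g0))
  expect_true(all(rep0$per_slice$dv_pct == 0))
  rep1 <- delta_v_compare(list(g0, g255))
  expect_true(all(rep1$per_slice$dv_pct == 100))
  # synthetic pair deltas 10, 20, 30 percent -> per-model (15, 20, 25)
  a <- array(0, d)
  b <- array(0.10, d)
  c_ <- array(0.30, d)
  pm <- lapply(list(a, b, c_), probability_map, spacing = c(1, 1, 1))
  rep2 <- delta_v_compare(pm, names = c("A", "B", "C"))
  expect_equal(rep2$per_pair$dv_pct, c(10, 30, 20))
  expect_equal(unname(rep2$per_model), c(20, 15, 25))
  # mixed dynamic ranges are each rescaled to their own percentage
  rep3 <- delta_v_compare(list(
    voxel_grid(array(255, d), c(1, 1, 1)),
    probability_map(array(1, d), c(1, 1, 1))))
  expect_true(all(rep3$per_slice$dv_pct == 0))
  expect_error(delta_v_compare(list(g0)), "at least two")
})
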