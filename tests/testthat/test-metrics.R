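test_that("center of mass matches voxel-center enumeration", {
  sp <- c(1, 1, 3)
  one <- binary_mask(array(FALSE, c(9, 9, 5)), sp)
  one$data[3, 7, 2] <- TRUE
  expect_equal(unname(center_of_mass(one)), c(2.5, 6.5, 4.5))
  cube <- binary_mask(array(FALSE, c(9, 9, 5)), sp)
  cube$data[3:6, 3:6, 2:3] <- TRUE
  expect_equal(unname(center_of_mass(cube)), c(4, 4, 6))
  set.seed(41)
  m <- rand_mask(c(15, 12, 9), c(1.2, 0.8, 2.5), p = 0.1)
  expect_equal(unname(center_of_mass(m)), oracle_com(m), tolerance = 1e-12)
  empty <- binary_mask(array(FALSE, c(4, 4, 4)), sp)
  expect_error(center_of_mass(empty), "empty")
})

test_that("displacement vector follows the Euclidean formula", {
  set.seed(42)
  m <- rand_blob(c(20, 20, 14), c(1, 1, 1))
  expect_identical(displacement(m, m)$vector_v, 0)
  d1 <- displacement(shift_mask(m, c(3, 4, 0)), m)
  expect_equal(c(d1$dx_lr, d1$dy_ap, d1$dz_cc, d1$vector_v), c(3, 4, 0, 5))
  d2 <- displacement(shift_mask(m, c(1, 2, 2)), m)
  expect_equal(d2$vector_v, 3)
  other <- binary_mask(array(TRUE, c(5, 5, 5)), c(1, 1, 1))
  expect_error(displacement(m, other), "geometry")
})

test_that("overlap of offset cubes matches hand counts", {
  sp <- c(1, 1, 1)
  a <- binary_mask(array(FALSE, c(20, 14, 14)), sp)
  a$data[1:10, 3:12, 3:12] <- TRUE
  b <- shift_mask(a, c(5, 0, 0))
  ov <- overlap(a, b)
  expect_equal(ov$vol_intersection * 1000, 500)
  expect_equal(ov$ci, 1 / 3)
  expect_equal(ov$di_a_in_b, 0.5)
  expect_equal(ov$di_b_in_a, 0.5)
  expect_equal(ov$dice, 0.5)
  ident <- overlap(a, a)
  expect_equal(c(ident$ci, ident$di_a_in_b, ident$di_b_in_a, ident$dice),
               c(1, 1, 1, 1))
  expect_identical(ident$hausdorff, 0)
  disj <- shift_mask(a, c(10, 0, 0))
  ovd <- overlap(a, disj)
  expect_equal(c(ovd$ci, ovd$di_a_in_b, ovd$dice), c(0, 0, 0))
  empty <- binary_mask(array(FALSE, c(20, 14, 14)), sp)
  expect_warning(ove <- overlap(a, empty), "empty")
  expect_equal(c(ove$ci, ove$di_b_in_a), c(0, 0))
  expect_error(overlap(empty, empty), "undefined")
})

test_that("shape measures follow the stated conventions", {
  sp <- c(1, 1, 1)
  cube <- binary_mask(array(FALSE, c(14, 14, 14)), sp)
  cube$data[3:12, 3:12, 3:12] <- TRUE
  sh <- shape_measures(cube)
  expect_equal(sh$volume, 1.0)
  expect_equal(sh$length, 1.0)
  expect_equal(sh$max_transverse_diameter, (9 * sqrt(2) + 1) / 10)
  # phantom cylinder of radius 15 mm reads as about a 3 cm diameter
  spc <- phantom_spec(grid_shape = c(64, 64, 24), spacing = c(1, 1, 3),
                      tumor_length = 24, tumor_radius = 15,
                      noise_sd_hu = 0, noise_sd_suv = 0, seed = 1)
  pat <- make_phantom(spc)
  d <- shape_measures(pat$truth_mask)$max_transverse_diameter
  expect_lte(abs(d - 3.0), 0.1)
})

test_that("Hausdorff distance matches the all-pairs oracle", {
  sp <- c(1, 1, 1)
  a <- binary_mask(array(FALSE, c(12, 12, 12)), sp)
  a$data[2, 2, 2] <- TRUE
  b <- binary_mask(array(FALSE, c(12, 12, 12)), sp)
  b$data[9, 2, 2] <- TRUE
  expect_equal(hausdorff_distance(a, b), 7)
  expect_identical(hausdorff_distance(a, a), 0)
  set.seed(43)
  for (rep in 1:10) {
    m1 <- rand_mask(c(10, 10, 8), c(1.5, 1, 2), p = 0.12)
    m2 <- rand_mask(c(10, 10, 8), c(1.5, 1, 2), p = 0.12)
    if (sum(m1$data) == 0 || sum(m2$data) == 0) next
    expect_equal(hausdorff_distance(m1, m2), oracle_hausdorff(m1, m2),
                 tolerance = 1e-12)
  }
})

test_that("metric identities and invariances hold on random pairs", {
  set.seed(44)
  for (rep in 1:50) {
    a <- rand_mask(c(12, 10, 8), c(1, 1.5, 2), p = 0.25, margin = 2)
    b <- rand_mask(c(12, 10, 8), c(1, 1.5, 2), p = 0.25, margin = 2)
    if (sum(a$data) == 0 || sum(b$data) == 0) next
    ov <- overlap(a, b)
    rev <- overlap(b, a)
    expect_identical(ov$ci, rev$ci)
    expect_identical(ov$di_a_in_b, rev$di_b_in_a)
    expect_equal(ov$ci, ov$dice / (2 - ov$dice), tolerance = 1e-12)
    if (ov$di_a_in_b > 0 && ov$di_b_in_a > 0)
      expect_equal(ov$ci, 1 / (1 / ov$di_a_in_b + 1 / ov$di_b_in_a - 1),
                   tolerance = 1e-12)
    expect_lte(ov$ci, min(ov$di_a_in_b, ov$di_b_in_a) + 1e-15)
    # unnecessary-irradiation identity by direct voxel counting
    frac_outside <- sum(a$data & !b$data) / sum(a$data)
    expect_equal(frac_outside, 1 - ov$di_a_in_b, tolerance = 1e-12)
    # joint translation leaves overlap metrics unchanged, COM equivariant
    by <- c(2, 1, 1)
    ov2 <- overlap(shift_mask(a, by), shift_mask(b, by))
    expect_identical(ov2$ci, ov$ci)
    expect_identical(ov2$dice, ov$dice)
    expect_equal(unname(center_of_mass(shift_mask(a, by)) - center_of_mass(a)),
                 by * a$spacing, tolerance = 1e-12)
  }
})

test_that("comparing a GTV set reproduces the single-pair operations", {
  pat <- make_phantom(small_spec(seed = 26))
  gs <- derive_contour_variants(pat, list(
    gtv_3d = perturbation_spec(com_shift = c(1.5, 0, 0)),
    gtv_pet_ref = perturbation_spec(com_shift = c(0, 3, 0), length_delta = 6),
    gtv_pet_reg = perturbation_spec(com_shift = c(-3, 1.5, 3))))
  rec <- compare_gtv_set(gs)
  row <- as.data.frame(rec)
  d <- displacement(gs$gtv_pet_reg, gs$gtv_3d)
  ov <- overlap(gs$gtv_pet_ref, gs$gtv_3d)
  expect_identical(row$v_reg_3d, d$vector_v)
  expect_identical(row$ci_ref_3d, ov$ci)
  expect_identical(row$di_ref_in_3d, ov$di_a_in_b)
  expect_identical(row$di_3d_in_ref, ov$di_b_in_a)
  expect_identical(row$vol_3d, shape_measures(gs$gtv_3d)$volume)
  # three identical masks: all CI/DI 1, all V 0
  same <- list(gtv_3d = pat$truth_mask, gtv_pet_ref = pat$truth_mask,
               gtv_pet_reg = pat$truth_mask)
  r2 <- as.data.frame(compare_gtv_set(same))
  expect_equal(unname(unlist(r2[grep("^(ci|di)_", names(r2))])),
               rep(1, 9))
  expect_equal(unname(unlist(r2[grep("^v_", names(r2))])), rep(0, 3))
  # a pair with an empty mask is flagged while the rest is computed
  empty <- binary_mask(array(FALSE, dim(pat$truth_mask$data)),
                       pat$truth_mask$spacing)
  r3 <- compare_gtv_set(list(gtv_3d = empty, gtv_pet_ref = pat$truth_mask,
                             gtv_pet_reg = pat$truth_mask))
  expect_setequal(r3$flagged, c("reg_3d", "ref_3d"))
  expect_identical(r3$pairs$reg_ref$overlap$ci, 1)
})

test_that("resampling maps a mask onto a finer reference grid", {
  src <- binary_mask(array(FALSE, c(8, 8, 4)), c(2, 2, 4))
  src$data[3:6, 3:6, 2:3] <- TRUE
  ref <- binary_mask(array(FALSE, c(16, 16, 8)), c(1, 1, 2))
  out <- resample_mask(src, ref)
  expect_identical(sum(out$data), 8L * sum(src$data))
  expect_equal(unname(center_of_mass(out)), unname(center_of_mass(src)))
})
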