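make_point_pet <- function(suvmax, dm = c(11, 11, 11), bg = 1) {
  arr <- array(bg, dm)
  arr[6, 6, 6] <- suvmax
  voxel_volume(arr, c(1, 1, 1), unit = "SUV")
}

test_that("effective threshold is max(2.5, 0.2 * SUVmax within ROI)", {
  for (m in c(3.21, 10, 12.95, 20, 49.50)) {
    pet <- make_point_pet(m)
    msk <- suv_threshold(pet, threshold_spec(roi_center = c(5.5, 5.5, 5.5),
                                             roi_radius = 4))
    expect_equal(attr(msk, "threshold"), max(2.5, 0.2 * m))
    expect_equal(attr(msk, "suvmax"), m)
  }
  # single-criterion modes
  pet <- make_point_pet(20)
  sp <- threshold_spec(roi_center = c(5.5, 5.5, 5.5), roi_radius = 4)
  expect_equal(attr(suv_threshold(pet, sp, mode = "absolute"), "threshold"), 2.5)
  expect_equal(attr(suv_threshold(pet, sp, mode = "fraction"), "threshold"), 4)
})

test_that("SUVmax below 2 signals enrollment failure", {
  pet <- voxel_volume(array(1, c(8, 8, 8)), c(1, 1, 1), unit = "SUV")
  expect_error(
    suv_threshold(pet, threshold_spec(roi_center = c(4, 4, 4), roi_radius = 3)),
    class = "gtvconc_enrollment_error")
})

test_that("raising the threshold never grows the mask; 40% nests in 20%", {
  pat <- make_phantom(small_spec(seed = 21, tumor_suvmax = 10))
  sp0 <- threshold_spec(roi_center = pat$meta$tumor_center, roi_radius = 30)
  prev <- NULL
  for (f in c(0.15, 0.2, 0.3, 0.4, 0.6)) {
    sp <- threshold_spec(fraction_of_max = f, roi_center = sp0$roi_center,
                         roi_radius = sp0$roi_radius)
    m <- suv_threshold(pat$pet_suv, sp, mode = "fraction")
    if (!is.null(prev)) expect_true(all(prev$data | !m$data))  # m subset prev
    prev <- m
  }
  m20 <- suv_threshold(pat$pet_suv, threshold_spec(
    fraction_of_max = 0.2, roi_center = sp0$roi_center,
    roi_radius = sp0$roi_radius))
  m40 <- suv_threshold(pat$pet_suv, threshold_spec(
    fraction_of_max = 0.4, roi_center = sp0$roi_center,
    roi_radius = sp0$roi_radius))
  expect_true(all(m20$data | !m40$data))
})

test_that("noise-free recovery: SUV contour Dice vs truth is at least 0.90", {
  pat <- make_phantom(small_spec(seed = 22, tumor_suvmax = 10))
  m <- suv_threshold(pat$pet_suv,
                     threshold_spec(roi_center = pat$meta$tumor_center,
                                    roi_radius = 30))
  expect_gte(overlap(m, pat$truth_mask)$dice, 0.90)
})

test_that("heart repair subtracts exactly the overlapping voxels", {
  sp <- c(1, 1, 2)
  gtv <- binary_mask(array(FALSE, c(12, 12, 8)), sp)
  gtv$data[3:8, 3:8, 2:5] <- TRUE
  heart_far <- binary_mask(array(FALSE, c(12, 12, 8)), sp)
  heart_far$data[11:12, 11:12, 7:8] <- TRUE
  expect_identical(exclude_heart(gtv, heart_far)$data, gtv$data)
  heart_over <- binary_mask(array(FALSE, c(12, 12, 8)), sp)
  heart_over$data[3:7, 3:7, 2:5] <- TRUE  # 100-voxel overlap
  out <- exclude_heart(gtv, heart_over)
  expect_identical(sum(out$data), sum(gtv$data) - 100L)
  heart_all <- binary_mask(array(TRUE, c(12, 12, 8)), sp)
  expect_warning(out2 <- exclude_heart(gtv, heart_all), "entire GTV")
  expect_identical(sum(out2$data), 0L)
})

test_that("wall rule keeps thick walls and wide non-gas diameters only", {
  # 6 mm wall (thickness rule alone)
  p6 <- make_phantom(small_spec(seed = 23, tumor_radius = 8,
                                wall_thickness = 6))
  g6 <- ct_wall_rule(p6$planning_ct, patient_axis(p6),
                     ct_rule_spec(wall_diameter_min = 1000))
  expect_gt(length(attr(g6, "kept_slices")), 0)
  # 3 mm wall, 8 mm outer diameter: fails both
  p3 <- make_phantom(small_spec(seed = 23, tumor_radius = 4,
                                wall_thickness = 3, lumen_radius = 1))
  g3 <- ct_wall_rule(p3$planning_ct, patient_axis(p3))
  expect_length(attr(g3, "kept_slices"), 0)
  expect_identical(sum(g3$data), 0L)
})

test_that("diameter rule recovers a 36 mm 4 mm-wall tumor's CC extent", {
  sp <- small_spec(seed = 24, tumor_radius = 6, wall_thickness = 4,
                   spacing = c(1, 1, 3))
  pat <- make_phantom(sp)
  g <- ct_wall_rule(pat$planning_ct, patient_axis(pat))
  ks <- attr(g, "kept_slices")
  extent <- (max(ks) - min(ks) + 1) * sp$spacing[3]
  expect_lte(abs(extent - sp$tumor_length), sp$spacing[3])
  # the same tumor fails the thickness criterion alone
  g_thick <- ct_wall_rule(pat$planning_ct, patient_axis(pat),
                          ct_rule_spec(wall_diameter_min = 1000))
  expect_length(attr(g_thick, "kept_slices"), 0)
})

test_that("an axis outside the grid is rejected", {
  pat <- make_phantom(small_spec(seed = 25))
  expect_error(ct_wall_rule(pat$planning_ct,
                            cbind(1e4, 1e4, c(1, 10))), "outside grid")
})
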