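test_that("truth mask equals the analytic cylinder voxelization", {
  specs <- list(small_spec(seed = 3),
                small_spec(seed = 4, tumor_radius = 7, wall_thickness = 5))
  for (sp in specs) {
    pat <- make_phantom(sp)
    inner <- max(0, sp$tumor_radius - sp$wall_thickness)
    expect_identical(
      sum(pat$truth_mask$data),
      as.integer(oracle_cylinder_count(sp$grid_shape, sp$spacing,
                                       pat$meta$tumor_center,
                                       sp$tumor_radius, sp$tumor_length,
                                       inner)))
  }
})

test_that("identical spec and seed give bit-identical phantoms", {
  sp <- small_spec(seed = 9, noise_sd_hu = 12, noise_sd_suv = 0.2)
  p1 <- make_phantom(sp)
  p2 <- make_phantom(sp)
  expect_identical(p1$planning_ct$data, p2$planning_ct$data)
  expect_identical(p1$pet_suv$data, p2$pet_suv$data)
  expect_identical(p1$truth_mask$data, p2$truth_mask$data)
})

test_that("PET plateau reaches the requested SUVmax over the tumor", {
  pat <- make_phantom(small_spec(seed = 2, tumor_suvmax = 12.95))
  expect_equal(max(pat$pet_suv$data[pat$truth_mask$data]), 12.95,
               tolerance = 1e-10)
})

test_that("oversized tumors are rejected with a sizing error", {
  expect_error(phantom_spec(grid_shape = c(30, 30, 10), spacing = c(1, 1, 3),
                            tumor_length = 200),
               "exceeds grid bounds")
  expect_error(small_spec(tumor_suvmax = 60), "outside admissible range")
  expect_error(small_spec(tumor_radius = -1), "must be > 0")
})

test_that("zero perturbation reproduces the truth mask exactly", {
  pat <- make_phantom(small_spec(seed = 5))
  gs <- derive_contour_variants(pat)
  for (v in c("gtv_3d", "gtv_pet_ref", "gtv_pet_reg"))
    expect_identical(gs[[v]]$data, pat$truth_mask$data)
})

test_that("a 3-4-0 mm shift yields an exact 5 mm 3D vector on a 1 mm grid", {
  sp <- phantom_spec(grid_shape = c(48, 48, 36), spacing = c(1, 1, 3),
                     tumor_length = 30, tumor_radius = 8,
                     noise_sd_hu = 0, noise_sd_suv = 0, seed = 6)
  pat <- make_phantom(sp)
  gs <- derive_contour_variants(pat, list(
    gtv_3d = perturbation_spec(),
    gtv_pet_ref = perturbation_spec(com_shift = c(3, 4, 0)),
    gtv_pet_reg = perturbation_spec()))
  d <- displacement(gs$gtv_pet_ref, gs$gtv_3d)
  expect_identical(c(d$dx_lr, d$dy_ap, d$dz_cc), c(3, 4, 0))
  expect_identical(d$vector_v, 5)
})

test_that("a +10 mm length perturbation lengthens the variant accordingly", {
  pat <- make_phantom(small_spec(seed = 8))
  gs <- derive_contour_variants(pat, list(
    gtv_3d = perturbation_spec(length_delta = 10),
    gtv_pet_ref = perturbation_spec(),
    gtv_pet_reg = perturbation_spec()))
  d_mm <- (shape_measures(gs$gtv_3d)$length -
             shape_measures(pat$truth_mask)$length) * 10
  expect_lte(abs(d_mm - 10), pat$truth_mask$spacing[3])
})

test_that("off-grid perturbations are rejected", {
  pat <- make_phantom(small_spec(seed = 8))
  expect_error(derive_contour_variants(pat, list(
    gtv_3d = perturbation_spec(com_shift = c(0, 0, 100)),
    gtv_pet_ref = perturbation_spec(),
    gtv_pet_reg = perturbation_spec())), "off the grid")
})

test_that("applied COM shifts are recovered within half a voxel diagonal", {
  pat <- make_phantom(small_spec(seed = 13))
  half_diag <- sqrt(sum(pat$truth_mask$spacing^2)) / 2
  set.seed(31)
  for (rep in 1:25) {
    shift <- stats::runif(3, -4, 4)
    gs <- derive_contour_variants(pat, list(
      gtv_3d = perturbation_spec(com_shift = shift),
      gtv_pet_ref = perturbation_spec(),
      gtv_pet_reg = perturbation_spec()))
    d <- displacement(gs$gtv_3d, pat$truth_mask)
    expect_lt(max(abs(c(d$dx_lr, d$dy_ap, d$dz_cc) - shift)), half_diag)
    expect_lt(abs(d$vector_v - sqrt(sum(shift^2))), half_diag)
  }
})

test_that("cohort defaults give groups of 32/24/16 and SUVmax >= 2 holds", {
  base <- small_spec(grid_shape = c(48, 48, 64))
  coh <- make_cohort(seed = 2, base_spec = base, keep_volumes = FALSE)
  expect_length(coh, 72)
  grp <- vapply(coh, `[[`, "", "group")
  expect_equal(as.integer(table(grp)[c("A", "B", "C")]), c(32L, 24L, 16L))
  # per-patient SUVmax parameters honor enrollment and the admissible range
  suv <- vapply(coh, function(p) p$meta$spec$tumor_suvmax, 0)
  expect_true(all(suv >= base$suvmax_range[1] & suv <= base$suvmax_range[2]))
  expect_true(all(suv >= 2))
  # spot-check realized PET SUVmax over the truth mask on a fresh patient
  p1 <- gtvconc:::simulate_patient("A001", "upper", cohort_distributions(),
                                   2, base)
  expect_gte(max(p1$pet_suv$data[p1$truth_mask$data]), 2)
})

test_that("cohort patients are keyed by id: size changes do not reshuffle", {
  base <- small_spec(grid_shape = c(48, 48, 64))
  c1 <- make_cohort(n_a = 2, n_b = 1, n_c = 0, seed = 5, base_spec = base,
                    keep_volumes = FALSE)
  c2 <- make_cohort(n_a = 3, n_b = 1, n_c = 1, seed = 5, base_spec = base,
                    keep_volumes = FALSE)
  expect_identical(c1$A002$truth_mask$data, c2$A002$truth_mask$data)
  expect_identical(c1$B001$gtv_set$gtv_pet_reg$data,
                   c2$B001$gtv_set$gtv_pet_reg$data)
})

test_that("singleton and zero-perturbation cohorts behave as stated", {
  base <- small_spec(grid_shape = c(48, 48, 64))
  c1 <- make_cohort(n_a = 1, n_b = 0, n_c = 0, seed = 3, base_spec = base,
                    keep_volumes = FALSE)
  expect_length(c1, 1)
  expect_identical(c1[[1]]$group, "A")
  zero <- cohort_distributions(com_shift_sd = c(0, 0, 0), length_delta_mean = 0,
                               length_delta_sd = 0, radius_delta_sd = 0,
                               deformation_sd = 0)
  cz <- make_cohort(n_a = 1, n_b = 1, n_c = 1, distributions = zero, seed = 4,
                    base_spec = base, keep_volumes = FALSE)
  for (p in cz) {
    rec <- compare_gtv_set(p$gtv_set)
    row <- as.data.frame(rec)
    expect_equal(unlist(row[grep("^ci_", names(row))]), c(ci_reg_ref = 1,
                 ci_reg_3d = 1, ci_ref_3d = 1))
    expect_equal(unname(unlist(row[grep("^v_", names(row))])), c(0, 0, 0))
  }
})

test_that("distal-group perturbation draws are systematically larger", {
  d <- cohort_distributions()
  set.seed(77)
  wins <- 0L
  for (r in 1:200) {
    va <- mean(replicate(8, sqrt(sum(
      gtvconc:::draw_perturbations(d, "A")$gtv_pet_ref$com_shift^2))))
    vc <- mean(replicate(8, sqrt(sum(
      gtvconc:::draw_perturbations(d, "C")$gtv_pet_ref$com_shift^2))))
    if (vc > va) wins <- wins + 1L
  }
  expect_gte(wins / 200, 0.95)
})
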