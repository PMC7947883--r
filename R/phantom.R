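#' Phantom specification
#'
#' Parameters of a single digital thorax phantom: a cylindrical esophageal
#' tumor (a wall-thickened, usually lumen-occluding segment of an esophageal
#' tube) embedded in a lung-density background with a soft-tissue mediastinal
#' block and, for middle/distal tumors, a heart region. The paired PET volume
#' carries a smooth uptake plateau at `tumor_suvmax` inside the tumor with a
#' cosine taper across the tumor surface.
#'
#' @param grid_shape voxels per axis (LR, AP, CC); default 128 x 128 x 160.
#' @param spacing mm per voxel (LR, AP, CC); default 1 x 1 x 3 (3 mm planning
#'   CT slice thickness).
#' @param tumor_location one of "upper", "middle", "distal" (groups A/B/C).
#' @param tumor_length mm of tumor along CC.
#' @param tumor_radius mm outer tumor radius.
#' @param wall_thickness mm tumor wall thickness; values >= `tumor_radius`
#'   give a solid (lumen-occluding) tumor, the default.
#' @param lumen_radius,normal_wall mm lumen radius and wall thickness of the
#'   uninvolved esophagus (outer diameter 2*(lumen_radius+normal_wall), kept
#'   below the 10 mm rule by default).
#' @param background_hu,mediastinum_hu,tumor_hu,gap_hu,lumen_hu Hounsfield
#'   units of lung background, mediastinal soft tissue, esophageal wall/tumor,
#'   the fat/partial-volume gap separating the esophagus from the mediastinal
#'   block, and lumen gas.
#' @param background_suv,tumor_suvmax,heart_suv SUV of background tissue,
#'   tumor plateau, and heart.
#' @param suvmax_range admissible range for `tumor_suvmax`.
#' @param noise_sd_hu,noise_sd_suv additive Gaussian noise SD on CT (HU) and
#'   PET (SUV).
#' @param seed RNG seed; fully determines the phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 160),
                         spacing = c(1, 1, 3),
                         tumor_location = c("middle", "upper", "distal"),
                         tumor_length = 50,
                         tumor_radius = 12,
                         wall_thickness = tumor_radius,
                         lumen_radius = 2,
                         normal_wall = 2.5,
                         background_hu = -750,
                         mediastinum_hu = 40,
                         tumor_hu = 45,
                         gap_hu = -300,
                         lumen_hu = -1000,
                         background_suv = 1.0,
                         tumor_suvmax = 12.95,
                         heart_suv = 1.8,
                         suvmax_range = c(3.21, 49.50),
                         noise_sd_hu = 15,
                         noise_sd_suv = 0.2,
                         seed = 1L) {
  tumor_location <- match.arg(tumor_location)
  spec <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
               tumor_location = tumor_location, tumor_length = tumor_length,
               tumor_radius = tumor_radius, wall_thickness = wall_thickness,
               lumen_radius = lumen_radius, normal_wall = normal_wall,
               background_hu = background_hu, mediastinum_hu = mediastinum_hu,
               tumor_hu = tumor_hu, gap_hu = gap_hu, lumen_hu = lumen_hu,
               background_suv = background_suv, tumor_suvmax = tumor_suvmax,
               heart_suv = heart_suv, suvmax_range = as.numeric(suvmax_range),
               noise_sd_hu = noise_sd_hu, noise_sd_suv = noise_sd_suv,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  pos <- c("tumor_length", "tumor_radius", "wall_thickness", "lumen_radius",
           "normal_wall", "noise_sd_hu", "noise_sd_suv")
  for (f in pos[1:5]) if (spec[[f]] <= 0) stop(f, " must be > 0")
  for (f in pos[6:7]) if (spec[[f]] < 0) stop(f, " must be >= 0")
  if (any(spec$grid_shape <= 0) || any(spec$spacing <= 0))
    stop("grid_shape and spacing must be positive")
  if (spec$tumor_suvmax < spec$suvmax_range[1] ||
      spec$tumor_suvmax > spec$suvmax_range[2])
    stop(sprintf("tumor_suvmax %.2f outside admissible range [%.2f, %.2f]",
                 spec$tumor_suvmax, spec$suvmax_range[1], spec$suvmax_range[2]))
  ext <- spec$grid_shape * spec$spacing
  ctr <- phantom_centers(spec)
  if (ctr$tumor[3] - spec$tumor_length / 2 < 0 ||
      ctr$tumor[3] + spec$tumor_length / 2 > ext[3] ||
      spec$tumor_radius + 3 > min(ext[1], ext[2]) / 2)
    stop("tumor exceeds grid bounds: shrink the tumor or enlarge the grid")
  invisible(spec)
}

# tumor / heart centers in mm; CC position encodes the thoracic segment
phantom_centers <- function(spec) {
  ext <- spec$grid_shape * spec$spacing
  zc <- switch(spec$tumor_location,
               upper = 0.72, middle = 0.50, distal = 0.28) * ext[3]
  list(tumor = c(ext[1] / 2, ext[2] / 2, zc),
       heart = c(ext[1] / 2 - 10, ext[2] / 2 - 42, 0.32 * ext[3]),
       heart_radius = 24)
}

# cosine taper of the PET uptake profile over the signed distance to the
# tumor surface; asymmetric so that thresholds max(2.5, 0.2*SUVmax) cross
# near the true surface across SUVmax in [3.21, 49.50]
.taper_w_in <- 4.0
.taper_w_out <- 1.5
taper_profile <- function(d) {
  w <- .taper_w_in + .taper_w_out
  p <- 0.5 * (1 + cos(pi * (d + .taper_w_in) / w))
  p[d <= -.taper_w_in] <- 1
  p[d >= .taper_w_out] <- 0
  p
}

# signed distance (mm) from in-plane radius r and CC offset dz to the surface
# of a solid cylinder of radius R and half-length hl
cylinder_sdist <- function(r, dz, R, hl) {
  dr <- r - R
  dzs <- abs(dz) - hl
  out <- sqrt(pmax(dr, 0)^2 + pmax(dzs, 0)^2)
  inside <- dr <= 0 & dzs <= 0
  out[inside] <- pmax(dr, dzs)[inside]
  out
}

# voxelize a (possibly annular, possibly bent) CC-aligned cylinder.
# membership: voxel center satisfies inner_radius < r <= radius and
# |z - center_z| <= length/2. axis_offset, if given, is a function of z (mm)
# returning a 2-col matrix of (LR, AP) axis displacements.
cylinder_mask_array <- function(grid_shape, spacing, center, radius, length,
                                inner_radius = 0, axis_offset = NULL) {
  xc <- (seq_len(grid_shape[1]) - 0.5) * spacing[1]
  yc <- (seq_len(grid_shape[2]) - 0.5) * spacing[2]
  zc <- (seq_len(grid_shape[3]) - 0.5) * spacing[3]
  out <- array(FALSE, grid_shape)
  zin <- which(abs(zc - center[3]) <= length / 2)
  if (!length(zin)) return(out)
  if (is.null(axis_offset)) {
    r2 <- outer((xc - center[1])^2, (yc - center[2])^2, `+`)
    sl <- r2 <= radius^2 & r2 > inner_radius^2
    for (k in zin) out[, , k] <- sl
  } else {
    off <- axis_offset(zc)
    for (k in zin) {
      r2 <- outer((xc - center[1] - off[k, 1])^2,
                  (yc - center[2] - off[k, 2])^2, `+`)
      out[, , k] <- r2 <= radius^2 & r2 > inner_radius^2
    }
  }
  out
}

# in-plane squared-radius map about (x0, y0)
inplane_r2 <- function(grid_shape, spacing, x0, y0) {
  xc <- (seq_len(grid_shape[1]) - 0.5) * spacing[1]
  yc <- (seq_len(grid_shape[2]) - 0.5) * spacing[2]
  outer((xc - x0)^2, (yc - y0)^2, `+`)
}

#' Simulate one phantom patient
#'
#' Builds the paired planning-CT (HU) and PET (SUV) volumes, the ground-truth
#' tumor mask, and the heart mask. The planning CT renders the tumor at its
#' true geometry; the PET uptake plateaus at `tumor_suvmax` in the tumor core
#' and tapers smoothly across the surface. A heart region with `heart_suv` is
#' present for middle and distal tumors. Output is fully determined by the
#' spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @param pet_perturbation optional [perturbation_spec()] applied to the PET
#'   tumor geometry only, emulating residual misalignment of a deformably
#'   registered diagnostic PET against the planning frame.
#' @return object of class `synthetic_patient`: fields `id`, `group`,
#'   `planning_ct`, `pet_suv`, `truth_mask`, `heart_mask`, `meta`.
#' @export
make_phantom <- function(spec, pet_perturbation = NULL) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  gs <- spec$grid_shape; sp <- spec$spacing
  ctr <- phantom_centers(spec)
  x0 <- ctr$tumor[1]; y0 <- ctr$tumor[2]; z0 <- ctr$tumor[3]
  zc <- (seq_len(gs[3]) - 0.5) * sp[3]
  hl <- spec$tumor_length / 2
  tumor_inner <- max(0, spec$tumor_radius - spec$wall_thickness)
  in_tumor_slab <- abs(zc - z0) <= hl

  r2 <- inplane_r2(gs, sp, x0, y0)
  r <- sqrt(r2)
  eso_outer <- spec$lumen_radius + spec$normal_wall

  # -- planning CT ------------------------------------------------------------
  ct <- array(spec$background_hu, gs)
  xc <- (seq_len(gs[1]) - 0.5) * sp[1]
  yc <- (seq_len(gs[2]) - 0.5) * sp[2]
  med <- outer(abs(xc - x0) <= 45, yc >= y0 - 55 & yc <= y0 + 30, `&`)
  truth <- array(FALSE, gs)
  has_heart <- spec$tumor_location %in% c("middle", "distal")
  hr2c <- if (has_heart)
    inplane_r2(gs, sp, ctr$heart[1], ctr$heart[2]) else NULL
  heart_mask <- array(FALSE, gs)
  gap <- 2.5
  for (k in seq_len(gs[3])) {
    sl <- ct[, , k]
    sl[med] <- spec$mediastinum_hu
    if (has_heart) {
      dz2 <- (zc[k] - ctr$heart[3])^2
      hs <- hr2c + dz2 <= ctr$heart_radius^2
      sl[hs] <- spec$tumor_hu
      heart_mask[, , k] <- hs
    }
    if (in_tumor_slab[k]) {
      outer_r <- spec$tumor_radius; inner_r <- tumor_inner
    } else {
      outer_r <- eso_outer; inner_r <- spec$lumen_radius
    }
    sl[r > outer_r & r <= outer_r + gap] <- spec$gap_hu
    tis <- r <= outer_r & r > inner_r
    sl[tis] <- spec$tumor_hu
    if (inner_r > 0) sl[r <= inner_r] <- spec$lumen_hu
    ct[, , k] <- sl
    if (in_tumor_slab[k]) truth[, , k] <- tis
  }
  if (has_heart) heart_mask <- heart_mask & !truth

  # -- PET --------------------------------------------------------------------
  pp <- pet_perturbation
  if (is.null(pp)) pp <- perturbation_spec()
  pet_center <- c(x0, y0, z0) + pp$com_shift
  pet_R <- spec$tumor_radius + pp$radius_delta
  pet_hl <- hl + pp$length_delta / 2
  axis_off <- deformation_offsets(pp, spec, variant_tag = "pet")
  pet <- array(spec$background_suv, gs)
  if (has_heart) pet[heart_mask] <- spec$heart_suv
  if (is.null(axis_off)) {
    rp <- sqrt(inplane_r2(gs, sp, pet_center[1], pet_center[2]))
    for (k in seq_len(gs[3])) {
      d <- cylinder_sdist(rp, zc[k] - pet_center[3], pet_R, pet_hl)
      up <- spec$background_suv +
        (spec$tumor_suvmax - spec$background_suv) * taper_profile(d)
      pet[, , k] <- pmax(pet[, , k], up)
    }
  } else {
    off <- axis_off(zc)
    for (k in seq_len(gs[3])) {
      rp <- sqrt(inplane_r2(gs, sp, pet_center[1] + off[k, 1],
                            pet_center[2] + off[k, 2]))
      d <- cylinder_sdist(rp, zc[k] - pet_center[3], pet_R, pet_hl)
      up <- spec$background_suv +
        (spec$tumor_suvmax - spec$background_suv) * taper_profile(d)
      pet[, , k] <- pmax(pet[, , k], up)
    }
  }

  if (spec$noise_sd_hu > 0)
    ct <- ct + array(stats::rnorm(prod(gs), 0, spec$noise_sd_hu), gs)
  if (spec$noise_sd_suv > 0)
    pet <- pet + array(stats::rnorm(prod(gs), 0, spec$noise_sd_suv), gs)
  ct <- pmin(pmax(ct, -1000), 3000)
  pet <- pmax(pet, 0)

  grp <- c(upper = "A", middle = "B", distal = "C")[[spec$tumor_location]]
  structure(list(
    id = sprintf("%s-%08d", grp, spec$seed %% 1e8),
    group = grp,
    planning_ct = voxel_volume(ct, sp, unit = "HU"),
    pet_suv = voxel_volume(pet, sp, unit = "SUV"),
    truth_mask = binary_mask(truth, sp),
    heart_mask = binary_mask(heart_mask, sp),
    gtv_set = NULL,
    meta = list(spec = spec, tumor_center = c(x0, y0, z0),
                tumor_inner = tumor_inner,
                pet_perturbation = pp)
  ), class = "synthetic_patient")
}

#' Perturbation applied to a derived contour variant
#'
#' Encodes a known geometric difference between a contour variant and the
#' ground truth: a rigid COM shift, a change of cranio-caudal length and of
#' radius, and a smooth (sinusoidal) residual axis deformation emulating
#' imperfect deformable registration. Zero perturbation reproduces the truth
#' mask exactly.
#'
#' @param com_shift mm shift per axis (LR, AP, CC).
#' @param length_delta mm change of CC length (applied symmetrically).
#' @param radius_delta mm change of radius.
#' @param deformation_amplitude mm amplitude of a smooth axis bend.
#' @param deformation_phase radians; phase of the bend (set from the patient
#'   RNG stream when drawn in a cohort).
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(com_shift = c(0, 0, 0), length_delta = 0,
                              radius_delta = 0, deformation_amplitude = 0,
                              deformation_phase = 0) {
  stopifnot(length(com_shift) == 3)
  structure(list(com_shift = as.numeric(com_shift),
                 length_delta = length_delta, radius_delta = radius_delta,
                 deformation_amplitude = deformation_amplitude,
                 deformation_phase = deformation_phase),
            class = "perturbation_spec")
}

# axis-offset closure for a smooth residual deformation; NULL when amplitude 0
deformation_offsets <- function(pert, spec, variant_tag = "") {
  if (pert$deformation_amplitude == 0) return(NULL)
  A <- pert$deformation_amplitude
  lambda <- 200  # mm; slow bend over the thorax
  ph <- pert$deformation_phase
  function(z) cbind(A * sin(2 * pi * z / lambda + ph),
                    A * sin(2 * pi * z / lambda + ph + pi / 3))
}

#' Derive the three contour variants of a patient
#'
#' Produces the GTV_3D, GTV_PET-ref and GTV_PET-reg masks as the ground-truth
#' tumor shape translated/rescaled/deformed per each variant's
#' [perturbation_spec()], voxelized from the analytically shifted shape (not
#' by resampling the truth mask), so sub-voxel shifts are honored. Applied
#' perturbations are recorded for downstream recovery checks.
#'
#' @param patient a `synthetic_patient`.
#' @param perturbations named list with elements `gtv_3d`, `gtv_pet_ref`,
#'   `gtv_pet_reg`, each a [perturbation_spec()].
#' @return list of class `gtv_set`: the three `binary_mask`s, `truth`, and
#'   `applied` (the perturbations).
#' @export
derive_contour_variants <- function(patient,
                                    perturbations = list(
                                      gtv_3d = perturbation_spec(),
                                      gtv_pet_ref = perturbation_spec(),
                                      gtv_pet_reg = perturbation_spec())) {
  stopifnot(inherits(patient, "synthetic_patient"))
  if (n_voxels(patient$truth_mask) == 0) stop("truth mask is empty")
  need <- c("gtv_3d", "gtv_pet_ref", "gtv_pet_reg")
  if (!all(need %in% names(perturbations)))
    stop("perturbations must name gtv_3d, gtv_pet_ref, gtv_pet_reg")
  spec <- patient$meta$spec
  gs <- spec$grid_shape; sp <- spec$spacing
  ext <- gs * sp
  out <- list()
  for (v in need) {
    p <- perturbations[[v]]
    ctr <- patient$meta$tumor_center + p$com_shift
    R <- spec$tumor_radius + p$radius_delta
    L <- spec$tumor_length + p$length_delta
    if (R <= 0 || L <= 0)
      stop("perturbation collapses variant ", v, " to nothing")
    if (ctr[3] - L / 2 < 0 || ctr[3] + L / 2 > ext[3] ||
        ctr[1] - R < 0 || ctr[1] + R > ext[1] ||
        ctr[2] - R < 0 || ctr[2] + R > ext[2])
      stop("perturbation pushes variant ", v, " off the grid")
    inner <- max(0, R - spec$wall_thickness)
    arr <- cylinder_mask_array(gs, sp, ctr, R, L, inner_radius = inner,
                               axis_offset = deformation_offsets(p, spec, v))
    out[[v]] <- binary_mask(arr, sp)
  }
  structure(list(gtv_3d = out$gtv_3d, gtv_pet_ref = out$gtv_pet_ref,
                 gtv_pet_reg = out$gtv_pet_reg, truth = patient$truth_mask,
                 applied = perturbations),
            class = "gtv_set")
}

# stable 31-bit hash of a patient id, mixed with the global seed, so cohort
# size changes do not reshuffle existing patients' substreams
patient_seed <- function(global_seed, id) {
  h <- 17
  for (b in utf8ToInt(id)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(global_seed) * 1000003 + h) %% 2147483647)
}

#' Per-group perturbation distributions for a synthetic cohort
#'
#' Defines how the three contour variants deviate from the truth, per tumor
#' location group. Defaults emulate mm-scale inter-contour differences with
#' the distal group (C) systematically more displaced than A/B, and are
#' calibrated so the default image-based pipeline lands near a median
#' conformity index of 0.70.
#'
#' @param com_shift_sd mm SD per axis (LR, AP, CC) of each variant's COM shift.
#' @param length_delta_mean,length_delta_sd mm; applied to GTV_PET-ref
#'   (PET-referenced contours tend to run longer).
#' @param radius_delta_sd mm SD of radius change.
#' @param deformation_sd mm; half-normal amplitude of residual deformation of
#'   the registered PET frame (GTV_PET-reg only).
#' @param group_scale multipliers of all SDs per group (A, B, C).
#' @param variant_shift_scale multipliers of `com_shift_sd` per variant.
#' @export
cohort_distributions <- function(com_shift_sd = c(1.3, 1.7, 2.6),
                                 length_delta_mean = 3,
                                 length_delta_sd = 4,
                                 radius_delta_sd = 0.8,
                                 deformation_sd = 1.1,
                                 group_scale = c(A = 0.6, B = 1.0, C = 2.0),
                                 variant_shift_scale = c(gtv_3d = 1.0,
                                                         gtv_pet_ref = 1.0,
                                                         gtv_pet_reg = 1.0)) {
  list(com_shift_sd = com_shift_sd, length_delta_mean = length_delta_mean,
       length_delta_sd = length_delta_sd, radius_delta_sd = radius_delta_sd,
       deformation_sd = deformation_sd, group_scale = group_scale,
       variant_shift_scale = variant_shift_scale)
}

# draw the three variant perturbations for one patient (RNG must be seeded)
draw_perturbations <- function(dist, group) {
  gsc <- dist$group_scale[[group]]
  draw1 <- function(variant) {
    vs <- dist$variant_shift_scale[[variant]]
    shift <- stats::rnorm(3, 0, dist$com_shift_sd * gsc * vs)
    ld <- if (variant == "gtv_pet_ref")
      stats::rnorm(1, dist$length_delta_mean, dist$length_delta_sd * gsc)
    else stats::rnorm(1, 0, dist$length_delta_sd * gsc * 0.5)
    rd <- stats::rnorm(1, 0, dist$radius_delta_sd * gsc)
    def <- if (variant == "gtv_pet_reg")
      abs(stats::rnorm(1, 0, dist$deformation_sd * gsc)) else 0
    perturbation_spec(com_shift = shift, length_delta = ld, radius_delta = rd,
                      deformation_amplitude = def,
                      deformation_phase = stats::runif(1, 0, 2 * pi))
  }
  list(gtv_3d = draw1("gtv_3d"), gtv_pet_ref = draw1("gtv_pet_ref"),
       gtv_pet_reg = draw1("gtv_pet_reg"))
}

# draw per-patient tumor parameters (RNG must be seeded). Lengths and radii
# are additionally clamped so the tumor plus a perturbation allowance fits
# the grid at every location (no effect at the default grid size).
draw_tumor_params <- function(base_spec, suv_meanlog = log(11),
                              suv_sdlog = 0.5) {
  rng <- base_spec$suvmax_range
  repeat {
    s <- exp(stats::rnorm(1, suv_meanlog, suv_sdlog))
    if (s >= rng[1] && s <= rng[2]) break
  }
  ext <- base_spec$grid_shape * base_spec$spacing
  max_len <- 2 * (0.28 * ext[3] - 25)  # worst-case CC center fraction
  max_rad <- min(ext[1], ext[2]) / 2 - 20
  list(tumor_suvmax = s,
       tumor_length = min(max(stats::rnorm(1, 55, 14), 24), 90, max_len),
       tumor_radius = min(max(stats::rnorm(1, 12, 1.8), 8), 16, max_rad))
}

#' Simulate a cohort of phantom patients
#'
#' Generates `n_a`/`n_b`/`n_c` patients with upper/middle/distal tumors
#' (groups A/B/C; defaults 32/24/16, total 72), each with per-patient tumor
#' size and SUVmax drawn from realistic distributions (SUVmax log-normal,
#' truncated to the admissible range), three contour variants perturbed per
#' `distributions`, and a PET volume rendered at the GTV_PET-reg geometry
#' (the residual misalignment of the registered frame). A single global seed
#' expands into per-patient substreams keyed by patient id.
#'
#' @param n_a,n_b,n_c group sizes.
#' @param distributions a [cohort_distributions()] list.
#' @param seed global seed.
#' @param base_spec template [phantom_spec()]; per-patient fields are drawn on
#'   top of it.
#' @param keep_volumes if FALSE, drop the CT/PET volumes from each returned
#'   patient once the variants are derived (a full-grid 72-patient cohort of
#'   volumes is several GB; masks are kept either way).
#' @return list of `synthetic_patient`, each with `gtv_set` filled in.
#' @export
make_cohort <- function(n_a = 32, n_b = 24, n_c = 16,
                        distributions = cohort_distributions(),
                        seed = 1L, base_spec = phantom_spec(),
                        keep_volumes = TRUE) {
  stopifnot(n_a >= 0, n_b >= 0, n_c >= 0)
  ids <- c(if (n_a) sprintf("A%03d", seq_len(n_a)),
           if (n_b) sprintf("B%03d", seq_len(n_b)),
           if (n_c) sprintf("C%03d", seq_len(n_c)))
  locs <- c(rep("upper", n_a), rep("middle", n_b), rep("distal", n_c))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    out[[i]] <- simulate_patient(ids[i], locs[i], distributions, seed,
                                 base_spec, keep_volumes)
  }
  names(out) <- ids
  out
}

# bound a drawn perturbation so the variant stays on-grid and non-degenerate;
# the clamped values are what gets applied and recorded. No effect for
# typical draws at the default grid size.
clamp_perturbation <- function(p, spec) {
  p$length_delta <- max(p$length_delta, -(spec$tumor_length - 12))
  p$radius_delta <- max(p$radius_delta, -(spec$tumor_radius - 4))
  ext <- spec$grid_shape * spec$spacing
  ctr <- phantom_centers(spec)$tumor
  Lv <- spec$tumor_length + p$length_delta
  Rv <- spec$tumor_radius + p$radius_delta + p$deformation_amplitude
  zmar <- max(min(ctr[3] - Lv / 2, ext[3] - ctr[3] - Lv / 2) - 1.5, 0)
  xmar <- max(min(ctr[1] - Rv, ext[1] - ctr[1] - Rv) - 1.5, 0)
  ymar <- max(min(ctr[2] - Rv, ext[2] - ctr[2] - Rv) - 1.5, 0)
  p$com_shift <- pmin(pmax(p$com_shift, -c(xmar, ymar, zmar)),
                      c(xmar, ymar, zmar))
  p
}

# one patient of a cohort: deterministic given (seed, id)
simulate_patient <- function(id, location, distributions, seed, base_spec,
                             keep_volumes = TRUE) {
  ps <- patient_seed(seed, id)
  set.seed(ps)
  pars <- draw_tumor_params(base_spec)
  grp <- c(upper = "A", middle = "B", distal = "C")[[location]]
  perts <- draw_perturbations(distributions, grp)
  spec <- base_spec
  spec$tumor_location <- location
  spec$tumor_suvmax <- pars$tumor_suvmax
  spec$tumor_length <- pars$tumor_length
  spec$tumor_radius <- pars$tumor_radius
  spec$wall_thickness <- pars$tumor_radius  # solid tumor
  spec$seed <- ps
  perts <- lapply(perts, clamp_perturbation, spec = spec)
  pat <- make_phantom(spec, pet_perturbation = perts$gtv_pet_reg)
  pat$id <- id
  pat$gtv_set <- derive_contour_variants(pat, perts)
  if (!keep_volumes) {
    pat$planning_ct <- NULL
    pat$pet_suv <- NULL
  }
  pat
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> %s (group %s), tumor %s, %d truth voxels\n",
              x$id, x$group, x$meta$spec$tumor_location,
              sum(x$truth_mask$data)))
  invisible(x)
}
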