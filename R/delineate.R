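#' SUV threshold specification
#'
#' Auto-contouring rule for PET: a spherical region of interest (the sphere
#' the operator drags over the lesion) and two threshold criteria, an
#' absolute SUV floor (default 2.5) and a fraction of the SUVmax found within
#' the ROI (default 20%). The default mode combines them as a single
#' effective threshold `max(absolute_suv, fraction_of_max * SUVmax)`, so both
#' stated criteria act as floors; each criterion alone is also available.
#'
#' @param absolute_suv SUV floor, > 0.
#' @param fraction_of_max unitless in (0, 1).
#' @param roi_center sphere center, mm (LR, AP, CC).
#' @param roi_radius sphere radius, mm.
#' @export
threshold_spec <- function(absolute_suv = 2.5, fraction_of_max = 0.20,
                           roi_center, roi_radius) {
  stopifnot(absolute_suv > 0, fraction_of_max > 0, fraction_of_max < 1,
            length(roi_center) == 3, roi_radius > 0)
  structure(list(absolute_suv = absolute_suv, fraction_of_max = fraction_of_max,
                 roi_center = as.numeric(roi_center), roi_radius = roi_radius),
            class = "threshold_spec")
}

#' CT wall-rule specification
#'
#' Mediastinal window settings and the slice-keeping rule for CT-based
#' esophageal GTV delineation: a slice's wall segment is kept if the
#' estimated wall thickness exceeds `wall_thickness_min` (default 5 mm) or
#' the in-plane tissue diameter exceeds `wall_diameter_min` (default 10 mm).
#'
#' @param window_width,window_level HU; mediastinal window (defaults 400/40).
#' @param wall_thickness_min,wall_diameter_min mm rule thresholds.
#' @export
ct_rule_spec <- function(window_width = 400, window_level = 40,
                         wall_thickness_min = 5, wall_diameter_min = 10) {
  stopifnot(window_width > 0, window_level > 0, wall_thickness_min > 0,
            wall_diameter_min > 0)
  structure(list(window_width = window_width, window_level = window_level,
                 wall_thickness_min = wall_thickness_min,
                 wall_diameter_min = wall_diameter_min),
            class = "ct_rule_spec")
}

#' Condition signalled when the lesion fails the SUVmax >= 2 enrollment rule
#' @noRd
enrollment_error <- function(suvmax) {
  structure(class = c("gtvconc_enrollment_error", "error", "condition"),
            list(message = sprintf(
              "SUVmax within ROI is %.3f < 2; lesion fails enrollment", suvmax),
              call = NULL, suvmax = suvmax))
}

#' SUV-threshold auto-contour
#'
#' Segments the PET volume inside the ROI sphere at the effective threshold.
#' In mode "max" (default) the threshold is
#' `max(absolute_suv, fraction_of_max * SUVmax)` where SUVmax is taken within
#' the ROI sphere; modes "absolute" and "fraction" apply a single criterion.
#' Threshold comparison is inclusive (SUV >= T). If the ROI SUVmax is below
#' 2, an enrollment-failure error of class `gtvconc_enrollment_error` is
#' signalled; an empty result raises a warning and returns an empty mask.
#'
#' @param pet a `voxel_volume` in SUV units.
#' @param spec a [threshold_spec()].
#' @param mode threshold combination mode.
#' @return a `binary_mask` with attributes `threshold` (effective T, SUV) and
#'   `suvmax` (SUVmax within the ROI).
#' @export
suv_threshold <- function(pet, spec, mode = c("max", "absolute", "fraction")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pet, "voxel_volume"), inherits(spec, "threshold_spec"))
  gs <- dim(pet$data); sp <- pet$spacing
  ext <- gs * sp
  if (any(spec$roi_center < 0) || any(spec$roi_center > ext))
    stop("ROI center outside grid")
  roi <- sphere_mask_array(gs, sp, spec$roi_center, spec$roi_radius)
  if (!any(roi)) stop("ROI sphere contains no voxels")
  suvmax <- max(pet$data[roi])
  if (suvmax < 2) stop(enrollment_error(suvmax))
  thr <- switch(mode,
                max = max(spec$absolute_suv, spec$fraction_of_max * suvmax),
                absolute = spec$absolute_suv,
                fraction = spec$fraction_of_max * suvmax)
  sel <- roi & pet$data >= thr
  if (!any(sel)) warning("SUV threshold produced an empty contour")
  out <- binary_mask(array(sel, gs), sp)
  attr(out, "threshold") <- thr
  attr(out, "suvmax") <- suvmax
  out
}

sphere_mask_array <- function(grid_shape, spacing, center, radius) {
  xc <- (seq_len(grid_shape[1]) - 0.5) * spacing[1]
  yc <- (seq_len(grid_shape[2]) - 0.5) * spacing[2]
  zc <- (seq_len(grid_shape[3]) - 0.5) * spacing[3]
  r2xy <- outer((xc - center[1])^2, (yc - center[2])^2, `+`)
  out <- array(FALSE, grid_shape)
  for (k in seq_len(grid_shape[3])) {
    dz2 <- (zc[k] - center[3])^2
    if (dz2 <= radius^2) out[, , k] <- r2xy + dz2 <= radius^2
  }
  out
}

#' Heart repair: remove the heart from a GTV
#'
#' Subtracts the heart structure (its boundary taken from the supplied
#' CT-derived heart mask) from an SUV-based GTV, emulating the manual repair
#' applied when myocardial uptake reaches the threshold.
#'
#' @param gtv,heart `binary_mask`s on one grid.
#' @param ct optional CT `voxel_volume`; unused by the subtraction itself,
#'   accepted so callers can document the provenance of the heart boundary.
#' @return `binary_mask`: gtv minus heart.
#' @export
exclude_heart <- function(gtv, heart, ct = NULL) {
  stop_if_geometry_mismatch(gtv, heart)
  out <- binary_mask(gtv$data & !heart$data, gtv$spacing)
  if (n_voxels(gtv) > 0 && n_voxels(out) == 0)
    warning("heart repair removed the entire GTV")
  for (a in c("threshold", "suvmax"))
    if (!is.null(attr(gtv, a))) attr(out, a) <- attr(gtv, a)
  out
}

#' CT wall rule delineation
#'
#' Surrogate for manual mediastinal-window contouring on planning CT. Per
#' axial slice, soft-tissue voxels (HU strictly inside the mediastinal
#' window) connected to the esophageal axis point are segmented; the slice's
#' segment is kept iff the estimated wall thickness exceeds
#' `wall_thickness_min` or the in-plane tissue diameter (outer diameter of
#' the non-gas cross-section) exceeds `wall_diameter_min`. The union of kept
#' segments is the CT-based GTV surrogate.
#'
#' Wall thickness is estimated as the minimal radial soft-tissue extent from
#' the lumen: the smallest per-sector outer radius minus the component's
#' innermost (lumen-adjacent) radius. The diameter is the maximal outer
#' extent through the axis. Both use a full-width convention (one in-plane
#' voxel added to center-to-center extents).
#'
#' @param ct `voxel_volume` in HU.
#' @param esophagus_axis n x 3 matrix of (LR, AP, CC) mm points; the axis
#'   polyline is linearly interpolated in CC. Slices outside its CC range are
#'   not evaluated.
#' @param spec a [ct_rule_spec()].
#' @param seed_radius mm; soft tissue within this distance of the axis point
#'   seeds the connected component.
#' @param n_sectors angular sectors for the radial estimates.
#' @param crop_margin mm half-width of the in-plane working window.
#' @return a `binary_mask`; attribute `kept_slices` lists kept slice indices.
#' @export
ct_wall_rule <- function(ct, esophagus_axis, spec = ct_rule_spec(),
                         seed_radius = 6, n_sectors = 36, crop_margin = 30) {
  stopifnot(inherits(ct, "voxel_volume"), is.matrix(esophagus_axis),
            ncol(esophagus_axis) == 3, inherits(spec, "ct_rule_spec"))
  gs <- dim(ct$data); sp <- ct$spacing; ext <- gs * sp
  if (any(esophagus_axis < 0) || any(sweep(esophagus_axis, 2, ext, `>`)))
    stop("esophagus axis polyline outside grid")
  lo <- spec$window_level - spec$window_width / 2
  hi <- spec$window_level + spec$window_width / 2
  zc <- (seq_len(gs[3]) - 0.5) * sp[3]
  ax <- esophagus_axis[order(esophagus_axis[, 3]), , drop = FALSE]
  zr <- range(ax[, 3])
  xc <- (seq_len(gs[1]) - 0.5) * sp[1]
  yc <- (seq_len(gs[2]) - 0.5) * sp[2]
  half_sector <- if (n_sectors %% 2 == 0) n_sectors / 2 else
    stop("n_sectors must be even")
  vox_in <- mean(sp[1:2])
  out <- array(FALSE, gs)
  kept <- integer(0)
  for (k in seq_len(gs[3])) {
    if (zc[k] < zr[1] || zc[k] > zr[2]) next
    axy <- if (nrow(ax) == 1) ax[1, 1:2] else
      c(stats::approx(ax[, 3], ax[, 1], zc[k])$y,
        stats::approx(ax[, 3], ax[, 2], zc[k])$y)
    isel <- which(abs(xc - axy[1]) <= crop_margin)
    jsel <- which(abs(yc - axy[2]) <= crop_margin)
    sl <- ct$data[isel, jsel, k]
    soft <- sl > lo & sl < hi
    if (!any(soft)) next
    lab <- EBImage::bwlabel(soft)
    dx <- xc[isel] - axy[1]; dy <- yc[jsel] - axy[2]
    r2 <- outer(dx^2, dy^2, `+`)
    seed_labs <- setdiff(unique(lab[r2 <= seed_radius^2]), 0)
    if (!length(seed_labs)) next
    comp <- array(lab, dim(lab)) %in% seed_labs & soft
    dim(comp) <- dim(lab)
    pts <- which(comp, arr.ind = TRUE)
    px <- dx[pts[, 1]]; py <- dy[pts[, 2]]
    r <- sqrt(px^2 + py^2)
    sect <- (floor((atan2(py, px) + pi) / (2 * pi) * n_sectors) %%
               n_sectors) + 1
    rmax <- rep(NA_real_, n_sectors)
    agg_max <- tapply(r, sect, max)
    rmax[as.integer(names(agg_max))] <- agg_max
    nonempty <- !is.na(rmax)
    thickness <- min(rmax[nonempty]) - min(r) + vox_in
    rmax[!nonempty] <- 0
    opp <- ((seq_len(n_sectors) - 1 + half_sector) %% n_sectors) + 1
    diameter <- max(rmax + rmax[opp]) + vox_in
    if (thickness > spec$wall_thickness_min ||
        diameter > spec$wall_diameter_min) {
      out[isel, jsel, k] <- out[isel, jsel, k] | comp
      kept <- c(kept, k)
    }
  }
  res <- binary_mask(out, sp)
  attr(res, "kept_slices") <- kept
  res
}
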