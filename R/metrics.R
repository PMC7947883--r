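#' Center of mass of a binary contour
#'
#' Unweighted mean of member-voxel center coordinates in physical mm
#' (LR, AP, CC). Contours, not images, are compared, so no intensity
#' weighting is applied.
#'
#' @param mask a nonempty `binary_mask`.
#' @return numeric length-3, mm (LR, AP, CC).
#' @export
center_of_mass <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (n_voxels(mask) == 0) stop("center of mass of an empty mask is undefined")
  ctr <- colMeans(voxel_centers(mask))
  names(ctr) <- c("lr", "ap", "cc")
  ctr
}

#' COM displacement between two contours
#'
#' Signed per-axis difference of centers of mass (A minus B) and the 3D
#' vector V = sqrt(dx^2 + dy^2 + dz^2), in mm.
#'
#' @param a,b nonempty `binary_mask`s on one grid.
#' @return list of class `displacement_record`: `dx_lr`, `dy_ap`, `dz_cc`,
#'   `vector_v` (mm).
#' @export
displacement <- function(a, b) {
  stop_if_geometry_mismatch(a, b)
  ca <- center_of_mass(a); cb <- center_of_mass(b)
  d <- ca - cb
  structure(list(dx_lr = unname(d[1]), dy_ap = unname(d[2]),
                 dz_cc = unname(d[3]), vector_v = sqrt(sum(d^2))),
            class = "displacement_record")
}

#' Volumetric overlap of two contours
#'
#' Conformity index CI = |A intersect B| / |A union B| (the Jaccard
#' coefficient; 1 iff identical), degree of inclusion
#' DI(A in B) = |A intersect B| / |A| in both orders, Dice score, symmetric
#' Hausdorff distance, and the three volumes in cm^3. If treatment planning
#' used A while B is the truth, a fraction 1 - DI(A in B) of A is irradiated
#' unnecessarily.
#'
#' @param a,b `binary_mask`s on one grid; both empty is an error, one empty
#'   yields CI = 0 and DI of the empty side defined as 0, with a warning.
#' @return list of class `overlap_record`.
#' @export
overlap <- function(a, b) {
  stop_if_geometry_mismatch(a, b)
  na <- n_voxels(a); nb <- n_voxels(b)
  if (na == 0 && nb == 0) stop("overlap of two empty masks is undefined")
  if (na == 0 || nb == 0)
    warning("one mask is empty; its degree of inclusion is defined as 0")
  ni <- sum(a$data & b$data)
  nu <- na + nb - ni
  vcc <- voxel_cc(a)
  hd <- if (na > 0 && nb > 0) hausdorff_distance(a, b) else NA_real_
  structure(list(
    ci = ni / nu,
    di_a_in_b = if (na > 0) ni / na else 0,
    di_b_in_a = if (nb > 0) ni / nb else 0,
    dice = 2 * ni / (na + nb),
    jaccard = ni / nu,
    hausdorff = hd,
    vol_a = na * vcc, vol_b = nb * vcc, vol_intersection = ni * vcc
  ), class = "overlap_record")
}

#' Shape measures of one contour
#'
#' Volume (voxel count times voxel volume, cm^3), cranio-caudal length
#' (occupied-slice extent: (max occupied slice - min occupied slice + 1)
#' times slice thickness, cm), and maximum transverse diameter (max over
#' axial slices of the largest in-plane distance between member-voxel
#' centers plus one in-plane voxel, full-width convention; cm).
#'
#' @param mask a nonempty `binary_mask`.
#' @return list of class `shape_record`: `volume` (cm^3), `length` (cm),
#'   `max_transverse_diameter` (cm).
#' @export
shape_measures <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (n_voxels(mask) == 0) stop("shape measures of an empty mask are undefined")
  sp <- mask$spacing
  occ <- which(apply(mask$data, 3, any))
  len_mm <- (max(occ) - min(occ) + 1) * sp[3]
  vox_in <- mean(sp[1:2])
  dmax <- 0
  for (k in occ) {
    pts <- which(mask$data[, , k, drop = TRUE], arr.ind = TRUE)
    if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
    xy <- cbind((pts[, 1] - 0.5) * sp[1], (pts[, 2] - 0.5) * sp[2])
    if (nrow(xy) > 3) xy <- xy[grDevices::chull(xy), , drop = FALSE]
    if (nrow(xy) == 1) next
    d2 <- stats::dist(xy)
    dmax <- max(dmax, max(d2))
  }
  structure(list(volume = n_voxels(mask) * voxel_cc(mask),
                 length = len_mm / 10,
                 max_transverse_diameter = (dmax + vox_in) / 10),
            class = "shape_record")
}

# logical array of member voxels having a non-member 6-neighbor (grid edge
# counts as outside); the nearest member voxel of a set to any external
# point is such a surface voxel
surface_voxels <- function(arr) {
  d <- dim(arr)
  inner <- array(TRUE, d)
  shift_and <- function(acc, src) acc & src
  pad_shift <- function(axis, by) {
    out <- array(FALSE, d)
    if (d[axis] < 2) return(out)
    if (axis == 1) {
      if (by == 1) out[2:d[1], , ] <- arr[1:(d[1] - 1), , ]
      else out[1:(d[1] - 1), , ] <- arr[2:d[1], , ]
    } else if (axis == 2) {
      if (by == 1) out[, 2:d[2], ] <- arr[, 1:(d[2] - 1), ]
      else out[, 1:(d[2] - 1), ] <- arr[, 2:d[2], ]
    } else {
      if (by == 1) out[, , 2:d[3]] <- arr[, , 1:(d[3] - 1)]
      else out[, , 1:(d[3] - 1)] <- arr[, , 2:d[3]]
    }
    out
  }
  for (axis in 1:3) for (by in c(1, -1))
    inner <- shift_and(inner, pad_shift(axis, by))
  arr & !inner
}

# bounding box (index ranges) of the union of two mask arrays
union_bbox <- function(a, b) {
  u <- a | b
  lapply(1:3, function(ax) {
    pres <- apply(u, ax, any)
    range(which(pres))
  })
}

crop_arr <- function(arr, bb) arr[bb[[1]][1]:bb[[1]][2],
                                  bb[[2]][1]:bb[[2]][2],
                                  bb[[3]][1]:bb[[3]][2], drop = FALSE]

# min distance from each row of pts (n x 3) to the point set ref (m x 3)
min_dist_to_set <- function(pts, ref, chunk = 4000L) {
  if (nrow(pts) == 0) return(numeric(0))
  ref2 <- rowSums(ref^2)
  out <- numeric(nrow(pts))
  idx <- split(seq_len(nrow(pts)), ceiling(seq_len(nrow(pts)) / chunk))
  for (ii in idx) {
    p <- pts[ii, , drop = FALSE]
    cross <- p %*% t(ref)
    d2 <- outer(rowSums(p^2), ref2, `+`) - 2 * cross
    out[ii] <- sqrt(pmax(do.call(pmin, as.data.frame(d2)), 0))
  }
  out
}

#' Symmetric Hausdorff distance between two contours
#'
#' Max over the two directed max-min Euclidean distances between the sets of
#' member-voxel centers, in mm. Member voxels already inside the other mask
#' contribute zero; external voxels are matched against the other mask's
#' surface voxels (equivalent to matching against all of them).
#'
#' @param a,b nonempty `binary_mask`s on one grid.
#' @return mm (numeric scalar).
#' @export
hausdorff_distance <- function(a, b) {
  stop_if_geometry_mismatch(a, b)
  if (n_voxels(a) == 0 || n_voxels(b) == 0)
    stop("Hausdorff distance requires two nonempty masks")
  bb <- union_bbox(a$data, b$data)
  aa <- crop_arr(a$data, bb); ba <- crop_arr(b$data, bb)
  sp <- a$spacing
  centers <- function(arr, sel) {
    idx <- which(sel, arr.ind = TRUE)
    sweep(idx - 0.5, 2, sp, `*`)  # offset cancels in distances
  }
  directed <- function(x, y) {
    outside <- x & !y
    if (!any(outside)) return(0)
    pts <- centers(x, outside)
    ref <- centers(y, surface_voxels(y))
    max(min_dist_to_set(pts, ref))
  }
  max(directed(aa, ba), directed(ba, aa))
}

# canonical pair and variant labels used in all reports
gtv_pairs <- function() list(
  reg_ref = list(a = "gtv_pet_reg", b = "gtv_pet_ref",
                 label = "GTV_PET-reg and GTV_PET-ref"),
  reg_3d = list(a = "gtv_pet_reg", b = "gtv_3d",
                label = "GTV_PET-reg and GTV_3D"),
  ref_3d = list(a = "gtv_pet_ref", b = "gtv_3d",
                label = "GTV_PET-ref and GTV_3D"))

gtv_variant_labels <- function() c(gtv_3d = "GTV_3D", gtv_pet_ref = "GTV_PET-ref",
                                   gtv_pet_reg = "GTV_PET-reg")

#' Pairwise comparison of a three-contour GTV set
#'
#' Applies [displacement()] and [overlap()] to the three pairs
#' (GTV_PET-reg vs GTV_PET-ref, GTV_PET-reg vs GTV_3D, GTV_PET-ref vs
#' GTV_3D) and [shape_measures()] to each variant, yielding one patient's
#' metric record including all six ordered degree-of-inclusion entries. A
#' pair involving an empty mask is flagged (NA metrics) while the remaining
#' pairs are computed.
#'
#' @param gtvs a `gtv_set` or any list with elements `gtv_3d`, `gtv_pet_ref`,
#'   `gtv_pet_reg` (each a `binary_mask`).
#' @return object of class `metric_record`; see
#'   [as.data.frame.metric_record()] for the flat form.
#' @export
compare_gtv_set <- function(gtvs) {
  need <- c("gtv_3d", "gtv_pet_ref", "gtv_pet_reg")
  stopifnot(all(need %in% names(gtvs)))
  masks <- gtvs[need]
  rec <- list(pairs = list(), shapes = list(), flagged = character(0))
  for (pn in names(gtv_pairs())) {
    p <- gtv_pairs()[[pn]]
    a <- masks[[p$a]]; b <- masks[[p$b]]
    if (n_voxels(a) == 0 || n_voxels(b) == 0) {
      rec$flagged <- c(rec$flagged, pn)
      rec$pairs[[pn]] <- list(displacement = NULL, overlap = NULL,
                              label = p$label)
    } else {
      rec$pairs[[pn]] <- list(displacement = displacement(a, b),
                              overlap = overlap(a, b), label = p$label)
    }
  }
  for (v in need)
    rec$shapes[[v]] <- if (n_voxels(masks[[v]]) > 0)
      shape_measures(masks[[v]]) else NULL
  class(rec) <- "metric_record"
  rec
}

#' Flatten a metric record to a one-row data frame
#'
#' Column naming: `v_<pair>`, `dx_<pair>`, `dy_<pair>`, `dz_<pair>`,
#' `ci_<pair>`, `dice_<pair>`, `hd_<pair>`, the six ordered
#' `di_<a>_in_<b>` entries, and per-variant `vol_`, `len_`, `diam_` with
#' suffixes `3d`, `ref`, `reg`.
#'
#' @param x a `metric_record`.
#' @param ... unused.
#' @export
as.data.frame.metric_record <- function(x, ...) {
  short <- c(gtv_3d = "3d", gtv_pet_ref = "ref", gtv_pet_reg = "reg")
  out <- list()
  for (pn in names(gtv_pairs())) {
    p <- gtv_pairs()[[pn]]
    sa <- short[[p$a]]; sb <- short[[p$b]]
    tag <- paste0(sa, "_", sb)
    pr <- x$pairs[[pn]]
    dsp <- pr$displacement; ov <- pr$overlap
    out[[paste0("v_", tag)]] <- if (is.null(dsp)) NA_real_ else dsp$vector_v
    out[[paste0("dx_", tag)]] <- if (is.null(dsp)) NA_real_ else dsp$dx_lr
    out[[paste0("dy_", tag)]] <- if (is.null(dsp)) NA_real_ else dsp$dy_ap
    out[[paste0("dz_", tag)]] <- if (is.null(dsp)) NA_real_ else dsp$dz_cc
    out[[paste0("ci_", tag)]] <- if (is.null(ov)) NA_real_ else ov$ci
    out[[paste0("dice_", tag)]] <- if (is.null(ov)) NA_real_ else ov$dice
    out[[paste0("hd_", tag)]] <- if (is.null(ov)) NA_real_ else ov$hausdorff
    out[[paste0("di_", sa, "_in_", sb)]] <-
      if (is.null(ov)) NA_real_ else ov$di_a_in_b
    out[[paste0("di_", sb, "_in_", sa)]] <-
      if (is.null(ov)) NA_real_ else ov$di_b_in_a
  }
  for (v in names(short)) {
    sh <- x$shapes[[v]]
    out[[paste0("vol_", short[[v]])]] <- if (is.null(sh)) NA_real_ else sh$volume
    out[[paste0("len_", short[[v]])]] <- if (is.null(sh)) NA_real_ else sh$length
    out[[paste0("diam_", short[[v]])]] <-
      if (is.null(sh)) NA_real_ else sh$max_transverse_diameter
  }
  as.data.frame(out)
}
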