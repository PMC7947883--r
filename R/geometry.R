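#' Voxel volumes and binary masks
#'
#' `voxel_volume()` wraps a 3D numeric array with physical voxel spacing;
#' `binary_mask()` does the same for a logical array. Array dimensions are
#' ordered (LR, AP, CC): dimension 1 runs left-right (x), dimension 2
#' anterior-posterior (y), dimension 3 cranial-caudal (z). This is the single
#' place where axis roles are bound; all physical coordinates are reported in
#' mm as (LR, AP, CC) triples. The center of voxel (i, j, k) sits at
#' ((i - 0.5) * spacing_lr, (j - 0.5) * spacing_ap, (k - 0.5) * spacing_cc).
#'
#' @param data 3D numeric (volume) or logical/0-1 (mask) array.
#' @param spacing numeric length-3, mm per voxel along (LR, AP, CC).
#' @param unit unit label for a volume, e.g. "HU" or "SUV".
#' @return An object of class `voxel_volume` or `binary_mask`.
#' @export
voxel_volume <- function(data, spacing, unit = "HU") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm per voxel, LR/AP/CC)")
  structure(list(data = data, spacing = spacing, unit = unit),
            class = "voxel_volume")
}

#' @rdname voxel_volume
#' @export
binary_mask <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.logical(data)) {
    vals <- unique(as.vector(data))
    bad <- sum(!(vals %in% c(0, 1)))
    if (bad > 0)
      stop("mask data must be binary; found ", bad, " distinct non-0/1 values")
    data <- array(data != 0, dim(data))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm per voxel, LR/AP/CC)")
  structure(list(data = data, spacing = spacing), class = "binary_mask")
}

#' Grid geometry of a volume or mask
#'
#' @param x a `voxel_volume` or `binary_mask`.
#' @return list with `dim` (voxels per axis) and `spacing` (mm per axis).
#' @export
geometry <- function(x) list(dim = dim(x$data), spacing = x$spacing)

#' Test that two objects share one grid geometry
#' @param a,b `voxel_volume` or `binary_mask` objects.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-10))
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a, b))
    stop("masks/volumes do not share one grid geometry; resample first ",
         "(see resample_mask)")
}

#' Physical coordinates (mm) of member voxel centers
#'
#' @param mask a `binary_mask`.
#' @return n x 3 matrix of (LR, AP, CC) mm coordinates.
#' @export
voxel_centers <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  sweep(idx - 0.5, 2, mask$spacing, `*`)
}

n_voxels <- function(mask) sum(mask$data)

#' Voxel volume in cm^3
#' @param x `voxel_volume` or `binary_mask`.
#' @export
voxel_cc <- function(x) prod(x$spacing) / 1000

#' Nearest-neighbor resampling of a mask onto a reference geometry
#'
#' Maps a binary mask onto another grid by sampling the source mask at the
#' reference voxel centers (nearest neighbor, preserving binarity). Used when
#' two contours to be compared were not stored on one grid.
#'
#' @param mask a `binary_mask`.
#' @param ref a `voxel_volume` or `binary_mask` carrying the target geometry.
#' @return a `binary_mask` on the reference grid.
#' @export
resample_mask <- function(mask, ref) {
  g <- geometry(ref)
  # reference voxel-center coordinate -> source voxel index
  ax <- function(k) {
    cen <- (seq_len(g$dim[k]) - 0.5) * g$spacing[k]
    i <- round(cen / mask$spacing[k] + 0.5)
    i[i < 1 | i > dim(mask$data)[k]] <- NA_integer_
    i
  }
  ii <- ax(1); jj <- ax(2); kk <- ax(3)
  out <- array(FALSE, g$dim)
  ok_i <- !is.na(ii); ok_j <- !is.na(jj); ok_k <- !is.na(kk)
  out[ok_i, ok_j, ok_k] <- mask$data[ii[ok_i], jj[ok_j], kk[ok_k]]
  binary_mask(out, g$spacing)
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s, dim %s, spacing %s mm, range [%.3g, %.3g]\n",
              x$unit, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> dim %s, spacing %s mm, %d voxels (%.2f cm^3)\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              sum(x$data), sum(x$data) * voxel_cc(x)))
  invisible(x)
}
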