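# Brute-force oracles, deliberately written as plain enumerations over voxel
# centers so they stay independent of the package's vectorized/cropped code
# paths. All operate on binary_mask objects.

rand_mask <- function(dm = c(12, 12, 8), spacing = c(1, 1, 2), p = 0.2,
                      margin = 0) {
  arr <- array(stats::runif(prod(dm)) < p, dm)
  if (margin > 0) {
    keep <- array(FALSE, dm)
    keep[(margin + 1):(dm[1] - margin), (margin + 1):(dm[2] - margin),
         (margin + 1):(dm[3] - margin)] <- TRUE
    arr <- arr & keep
  }
  binary_mask(arr, spacing)
}

# random interior ball mask (stays clear of grid edges so it can be shifted)
rand_blob <- function(dm = c(14, 14, 10), spacing = c(1, 1, 2)) {
  ctr <- (dm * spacing) * stats::runif(3, 0.4, 0.6)
  rad <- stats::runif(1, 0.08, 0.16) * min(dm * spacing)
  arr <- array(FALSE, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    cen <- (c(i, j, k) - 0.5) * spacing
    arr[i, j, k] <- sum((cen - ctr)^2) <= rad^2
  }
  binary_mask(arr, spacing)
}

oracle_counts <- function(a, b) {
  na <- 0L; nb <- 0L; ni <- 0L
  dm <- dim(a$data)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    va <- a$data[i, j, k]; vb <- b$data[i, j, k]
    na <- na + va; nb <- nb + vb; ni <- ni + (va && vb)
  }
  list(na = na, nb = nb, ni = ni, nu = na + nb - ni)
}

oracle_com <- function(mask) {
  dm <- dim(mask$data); sp <- mask$spacing
  acc <- c(0, 0, 0); n <- 0
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3]))
    if (mask$data[i, j, k]) {
      acc <- acc + (c(i, j, k) - 0.5) * sp
      n <- n + 1
    }
  acc / n
}

oracle_hausdorff <- function(a, b) {
  pa <- voxel_centers(a); pb <- voxel_centers(b)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

oracle_shape <- function(mask) {
  sp <- mask$spacing
  idx <- which(mask$data, arr.ind = TRUE)
  ks <- sort(unique(idx[, 3]))
  len <- (max(ks) - min(ks) + 1) * sp[3]
  dmax <- 0
  for (k in ks) {
    pts <- idx[idx[, 3] == k, , drop = FALSE]
    if (nrow(pts) < 2) next
    for (u in seq_len(nrow(pts) - 1)) for (v in (u + 1):nrow(pts)) {
      d <- sqrt(((pts[u, 1] - pts[v, 1]) * sp[1])^2 +
                ((pts[u, 2] - pts[v, 2]) * sp[2])^2)
      dmax <- max(dmax, d)
    }
  }
  list(volume = nrow(idx) * prod(sp) / 1000,
       length = len / 10,
       max_transverse_diameter = (dmax + mean(sp[1:2])) / 10)
}

# count voxel centers inside the (possibly annular) cylinder by direct test
oracle_cylinder_count <- function(grid_shape, spacing, center, radius, len,
                                  inner_radius = 0) {
  n <- 0L
  for (i in seq_len(grid_shape[1])) for (j in seq_len(grid_shape[2]))
    for (k in seq_len(grid_shape[3])) {
      cen <- (c(i, j, k) - 0.5) * spacing
      r2 <- (cen[1] - center[1])^2 + (cen[2] - center[2])^2
      if (r2 <= radius^2 && r2 > inner_radius^2 &&
          abs(cen[3] - center[3]) <= len / 2) n <- n + 1L
    }
  n
}

# compact phantom spec for fast unit tests (tumor still obeys all invariants)
small_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(48, 48, 36), spacing = c(1.5, 1.5, 3),
         tumor_length = 36, tumor_radius = 9,
         noise_sd_hu = 0, noise_sd_suv = 0),
    list(...))
  do.call(phantom_spec, args)
}

# straight esophageal axis through a patient's tumor center
patient_axis <- function(patient) {
  spec <- patient$meta$spec
  ext <- spec$grid_shape * spec$spacing
  cbind(patient$meta$tumor_center[1], patient$meta$tumor_center[2],
        c(0.5 * spec$spacing[3], ext[3] - 0.5 * spec$spacing[3]))
}

# translate a mask by whole voxels (array roll, no resampling)
shift_mask <- function(mask, by) {
  dm <- dim(mask$data)
  out <- array(FALSE, dm)
  src <- lapply(1:3, function(ax) {
    s <- seq_len(dm[ax]) - by[ax]
    s[s >= 1 & s <= dm[ax]]
  })
  dst <- lapply(1:3, function(ax) {
    s <- seq_len(dm[ax])
    s[s - by[ax] >= 1 & s - by[ax] <= dm[ax]]
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    mask$data[src[[1]], src[[2]], src[[3]]]
  binary_mask(out, mask$spacing)
}
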