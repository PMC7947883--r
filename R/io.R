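#' Read and write volumes and masks as NIfTI
#'
#' Volumes and masks are stored in (optionally gzipped) NIfTI with voxel
#' spacing (mm) in the header; spacing survives the round trip to float
#' precision. Masks must be strictly binary on disk: any other value is an
#' error reporting the offending value count.
#'
#' @param x a `voxel_volume` or `binary_mask`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param unit unit label attached to a read volume.
#' @return `read_volume`/`read_mask` return the package containers;
#'   writers return the path invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "voxel_volume"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, unit = "HU") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (length(sp) < 3 || any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header of ", path, " carries no usable voxel spacing")
  voxel_volume(array(as.vector(img), dim(img)[1:3]), sp, unit = unit)
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(x$data), dim(x$data)))
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  v <- read_volume(path, unit = "binary")
  bad <- sum(!(v$data %in% c(0, 1)))
  if (bad > 0)
    stop("mask file ", path, " is not binary: ", bad,
         " voxel(s) outside {0, 1}")
  binary_mask(v$data != 0, v$spacing)
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip losslessly through YAML (all fields are plain
#' vectors and lists).
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()] list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# 31-bit rolling hash of a config's YAML serialization, logged with outputs
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
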