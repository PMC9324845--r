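#' Read a NIfTI volume
#'
#' Loads a 3-D (or 4-D multi-echo) NIfTI volume as a plain array plus its
#' voxel size. Axis order is x, y, z in storage order. The B0 direction
#' is never inferred from the NIfTI orientation matrix: pass it
#' explicitly to \code{\link{qsm_grid}}.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return 3-D or 4-D numeric array with attribute \code{"voxel_size"}
#'   (mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size") <- as.numeric(vox[seq_len(min(3L, length(vox)))])
  out
}

#' Write a volume as NIfTI
#'
#' @param volume 3-D or 4-D numeric array.
#' @param path output path (.nii or .nii.gz).
#' @param voxel_size voxel size in mm (default: the array's
#'   \code{"voxel_size"} attribute, else 1 mm isotropic).
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size = NULL) {
  if (is.null(voxel_size))
    voxel_size <- attr(volume, "voxel_size")
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  attributes(volume) <- list(dim = dim(volume))
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Split a 4-D multi-echo volume pair into an echo series
#'
#' @param magnitude 4-D array (x, y, z, echo).
#' @param phase 4-D array (x, y, z, echo).
#' @param te echo times in seconds.
#' @return an \code{\link{echo_series}}.
#' @export
split_echoes <- function(magnitude, phase, te) {
  stopifnot(length(dim(magnitude)) == 4L, identical(dim(magnitude), dim(phase)))
  n <- dim(magnitude)[4]
  if (n != length(te))
    stop("number of echoes does not match length(te)", call. = FALSE)
  echo_series(lapply(seq_len(n), function(i) magnitude[, , , i]),
              lapply(seq_len(n), function(i) phase[, , , i]),
              te)
}

#' Symmetric zero padding to a target shape
#'
#' Pads a volume with zeros, split as evenly as possible on both sides of
#' each axis, e.g. to 256^3 before FFT-based reconstruction to suppress
#' wrap-around aliasing. \code{crop_to_shape} inverts it exactly.
#'
#' @param volume 3-D array.
#' @param target integer vector of length 3, each >= the current shape.
#' @return padded 3-D array with attribute \code{"orig_shape"}.
#' @export
pad_to_shape <- function(volume, target) {
  shape <- dim(volume)
  target <- as.integer(target)
  if (any(target < shape))
    stop("target shape must be >= the current shape on every axis",
         call. = FALSE)
  lo <- (target - shape) %/% 2L
  out <- array(0, target)
  out[lo[1] + seq_len(shape[1]), lo[2] + seq_len(shape[2]),
      lo[3] + seq_len(shape[3])] <- volume
  attr(out, "orig_shape") <- shape
  out
}

#' Crop a padded volume back to a shape
#'
#' @param volume 3-D array (typically from \code{\link{pad_to_shape}}).
#' @param target integer vector of length 3 (default: the volume's
#'   \code{"orig_shape"} attribute).
#' @return cropped 3-D array.
#' @export
crop_to_shape <- function(volume, target = attr(volume, "orig_shape")) {
  if (is.null(target)) stop("no target shape given", call. = FALSE)
  shape <- dim(volume)
  target <- as.integer(target)
  if (any(target > shape))
    stop("target shape must be <= the current shape on every axis",
         call. = FALSE)
  lo <- (shape - target) %/% 2L
  out <- volume[lo[1] + seq_len(target[1]), lo[2] + seq_len(target[2]),
                lo[3] + seq_len(target[3]), drop = FALSE]
  attr(out, "orig_shape") <- NULL
  out
}

#' Read echo times from a JSON list
#'
#' @param path path to a JSON file holding a numeric list of echo times
#'   in seconds.
#' @return numeric vector of echo times.
#' @export
read_echo_times <- function(path) {
  te <- jsonlite::fromJSON(path)
  as.numeric(unlist(te))
}

#' Write a reproducibility manifest
#'
#' Records everything needed to re-run a reconstruction bit-identically:
#' the configuration, seeds, input file checksums, and package version.
#'
#' @param path output JSON path.
#' @param config a list or \code{\link{hdqsm_config}} snapshot.
#' @param seeds named list/vector of seeds used.
#' @param inputs named character vector of input file paths (checksummed
#'   with md5).
#' @param outputs named character vector of output paths.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seeds = list(), inputs = character(),
                           outputs = character()) {
  checksums <- if (length(inputs))
    vapply(inputs, function(p) unname(tools::md5sum(p)), character(1))
  else character()
  manifest <- list(
    package = "hdqsm",
    version = as.character(utils::packageVersion("hdqsm")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(config),
    seeds = seeds,
    inputs = as.list(inputs),
    input_md5 = as.list(checksums),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
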