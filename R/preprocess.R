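#' Multi-echo series container
#'
#' Bundles per-echo magnitude and phase volumes with their echo times.
#' Phases are assumed already unwrapped and background-corrected; this
#' package performs neither step.
#'
#' @param magnitudes list of nonnegative 3-D arrays, one per echo.
#' @param phases list of 3-D arrays (radians), one per echo.
#' @param te echo times in seconds, strictly increasing.
#' @return An object of class \code{"echo_series"}.
#' @export
echo_series <- function(magnitudes, phases, te) {
  te <- as.numeric(te)
  if (length(magnitudes) != length(phases) || length(te) != length(phases))
    stop("magnitudes, phases and te must have equal length", call. = FALSE)
  if (length(te) < 1L || any(te <= 0) ||
      (length(te) > 1L && is.unsorted(te, strictly = TRUE)))
    stop("'te' must be positive and strictly increasing", call. = FALSE)
  dims <- lapply(c(magnitudes, phases), dim)
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all echo volumes must share one shape", call. = FALSE)
  if (any(vapply(magnitudes, function(m) any(m < 0), logical(1))))
    stop("magnitudes must be nonnegative", call. = FALSE)
  structure(list(magnitudes = magnitudes, phases = phases, te = te),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  cat("Echo series: ", length(x$te), " echoes, ",
      paste(dim(x$magnitudes[[1]]), collapse = " x "), " voxels, TE = ",
      paste(format(x$te * 1e3), collapse = ", "), " ms\n", sep = "")
  invisible(x)
}

#' Magnitude-weighted local field fit
#'
#' Voxel-wise weighted least-squares slope of phase versus echo time,
#' through the origin, with weights Mag_i^2:
#' field = sum(Mag_i^2 TE_i phi_i) / sum(Mag_i^2 TE_i^2), in rad/s.
#' A single echo reduces to phi_1 / TE_1. The fit has no intercept: input
#' phases are assumed offset-corrected, so the line passes through zero.
#'
#' @param echoes an \code{\link{echo_series}}.
#' @return 3-D array of field values in rad/s, with attribute
#'   \code{"valid"}: a logical array, FALSE where the total weight was zero
#'   (field set to 0 there).
#' @export
fit_local_field <- function(echoes) {
  stopifnot(inherits(echoes, "echo_series"))
  num <- den <- array(0, dim(echoes$phases[[1]]))
  for (i in seq_along(echoes$te)) {
    w2 <- echoes$magnitudes[[i]]^2
    num <- num + w2 * echoes$te[i] * echoes$phases[[i]]
    den <- den + w2 * echoes$te[i]^2
  }
  valid <- den > 0
  field <- ifelse(valid, num / ifelse(valid, den, 1), 0)
  dim(field) <- dim(num)
  attr(field, "valid") <- valid
  field
}

#' Magnitude-based data-consistency weight
#'
#' The echo-combination weight
#' w = sum(Mag_i^2 TE_i) / sum(Mag_i TE_i), voxel-wise, which matches the
#' SNR of the magnitude-weighted field estimate. Where the denominator is
#' zero w is 0. The result is multiplied by the mask (if given) and
#' rescaled so its maximum inside the mask is 1, making regularization
#' weights comparable across data sets.
#'
#' @param echoes an \code{\link{echo_series}}.
#' @param mask optional binary 3-D array restricting (and normalizing) the
#'   weight.
#' @return nonnegative 3-D weight array, maximum 1 inside the mask.
#' @export
magnitude_weight <- function(echoes, mask = NULL) {
  stopifnot(inherits(echoes, "echo_series"))
  num <- den <- array(0, dim(echoes$magnitudes[[1]]))
  for (i in seq_along(echoes$te)) {
    m <- echoes$magnitudes[[i]]
    num <- num + m^2 * echoes$te[i]
    den <- den + m * echoes$te[i]
  }
  ok <- den > 0
  w <- ifelse(ok, num / ifelse(ok, den, 1), 0)
  dim(w) <- dim(num)
  if (!is.null(mask)) w <- w * (mask != 0)
  top <- max(w)
  if (top > 0) w <- w / top
  w
}

#' Discrepancy-modulated data-consistency weight
#'
#' Attenuates a base weight by the stage-one phase discrepancy: with
#' r = |phi - D * chi1| (the residual of the stage-one solution under the
#' forward model), W = w * (1 - r / max(r)), the max taken over mask
#' voxels. Voxels whose stage-one residual is large — noisy voxels and
#' phase inconsistencies that seed streaking artifacts — get their L2
#' data-consistency penalty reduced, down to zero at the worst voxel.
#' If max(r) = 0 (stage one reproduces the data exactly) W = w.
#'
#' @param w base weight (nonnegative 3-D array).
#' @param phi measured local field/phase (same unit as the kernel output).
#' @param chi1 stage-one susceptibility estimate (ppm).
#' @param kernel a \code{\link{dipole_kernel}}.
#' @param mask binary 3-D array; the normalizing max is taken inside it.
#' @return 3-D weight array with 0 <= W <= w everywhere.
#' @export
discrepancy_weight <- function(w, phi, chi1, kernel, mask) {
  stopifnot(inherits(kernel, "dipole_kernel"))
  grid <- kernel$grid
  check_volume(w, grid, "w")
  check_volume(phi, grid, "phi")
  check_volume(chi1, grid, "chi1")
  check_volume(mask, grid, "mask")
  if (any(w < 0)) stop("'w' must be nonnegative", call. = FALSE)
  inmask <- mask != 0
  if (!any(inmask)) stop("mask is empty", call. = FALSE)
  r <- abs(phi - forward_field(chi1, kernel))
  rmax <- max(r[inmask])
  if (rmax == 0) return(w)
  W <- w * pmax(1 - r / rmax, 0)
  dim(W) <- dim(w)
  W
}
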