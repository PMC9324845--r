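#' Grid geometry for volumetric QSM data
#'
#' Describes the regular voxel grid on which all volumes (susceptibility,
#' field, weights) live: the array dimensions, the physical voxel size and
#' the direction of the main magnetic field B0.
#'
#' Axis order is x, y, z in array storage order. The B0 direction is taken
#' from this explicit parameter and never inferred from NIfTI orientation
#' matrices; by default it points along the third (z) axis.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 2).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#' @param b0_direction unit 3-vector giving the B0 direction.
#' @return An object of class \code{"qsm_grid"}.
#' @examples
#' g <- qsm_grid(c(64, 64, 64), c(1, 1, 1))
#' @export
qsm_grid <- function(shape, voxel_size = c(1, 1, 1), b0_direction = c(0, 0, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L))
    stop("'shape' must be three integers, each >= 2", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive numbers (mm)", call. = FALSE)
  b0_direction <- as.numeric(b0_direction)
  if (length(b0_direction) != 3L || abs(sqrt(sum(b0_direction^2)) - 1) > 1e-9)
    stop("'b0_direction' must be a unit 3-vector", call. = FALSE)
  structure(list(shape = shape, voxel_size = voxel_size,
                 b0_direction = b0_direction),
            class = "qsm_grid")
}

#' @export
print.qsm_grid <- function(x, ...) {
  cat("QSM grid: ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(format(x$voxel_size), collapse = " x "), " mm\n",
      "B0 direction: (", paste(format(x$b0_direction), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Acquisition parameters for phase-unit conversion
#'
#' Gyromagnetic ratio, main field strength and echo times, used to convert
#' between susceptibility-induced field offsets (ppm) and measured phase
#' (radians) at each echo.
#'
#' @param b0 main field strength in tesla.
#' @param te echo times in seconds, strictly increasing.
#' @param gamma gyromagnetic ratio in rad s^-1 T^-1 (default: proton,
#'   2.67522e8).
#' @return An object of class \code{"qsm_acq"}.
#' @examples
#' acq <- qsm_acq(b0 = 3, te = c(4, 12, 20, 28) * 1e-3)
#' @export
qsm_acq <- function(b0, te, gamma = 267.522e6) {
  te <- as.numeric(te)
  if (!is.numeric(b0) || length(b0) != 1L || b0 <= 0)
    stop("'b0' must be a single positive number (tesla)", call. = FALSE)
  if (length(te) < 1L || any(te <= 0) || is.unsorted(te, strictly = TRUE))
    stop("'te' must be nonempty, positive and strictly increasing (seconds)",
         call. = FALSE)
  if (gamma <= 0) stop("'gamma' must be positive", call. = FALSE)
  structure(list(b0 = b0, te = te, gamma = gamma), class = "qsm_acq")
}

#' Radians-per-ppm conversion factor
#'
#' Phase accrued at echo time \code{te} per ppm of susceptibility-induced
#' field offset: gamma * B0 * te * 1e-6.
#'
#' @param acq a \code{\link{qsm_acq}} object.
#' @param te echo time in seconds (default: first echo).
#' @return scalar, radians per ppm.
#' @export
ppm_to_rad <- function(acq, te = acq$te[1]) {
  stopifnot(inherits(acq, "qsm_acq"))
  acq$gamma * acq$b0 * te * 1e-6
}

# FFT frequency coordinates (cycles / mm) for one axis, in FFT bin order.
fft_freq <- function(n, d) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

same_shape <- function(x, shape) {
  identical(as.integer(dim(x)), as.integer(shape))
}

check_volume <- function(x, grid, name = deparse(substitute(x))) {
  if (is.null(dim(x)) || length(dim(x)) != 3L || !same_shape(x, grid$shape))
    stop(sprintf("'%s' must be a 3-D array of shape %s", name,
                 paste(grid$shape, collapse = "x")), call. = FALSE)
  invisible(TRUE)
}
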