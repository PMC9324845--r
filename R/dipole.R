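#' Fourier-domain dipole kernel
#'
#' Builds the unit magnetic dipole response on the discrete FFT frequency
#' grid, D(k) = 1/3 - kz^2 / |k|^2, where kz is the component of the
#' spatial frequency k along the B0 direction. The kernel vanishes on the
#' "magic cone" kz^2/|k|^2 = 1/3, which is what makes dipole inversion
#' ill-posed. The zero-frequency bin is set to 0 (the mean field offset is
#' unobservable), so spatially constant susceptibility produces no field.
#'
#' With \code{unit = "ppm"} the kernel maps susceptibility in ppm to field
#' offset in ppm (scale 1). With \code{unit = "radians"} the output of
#' \code{\link{forward_field}} is phase in radians at echo time \code{te}:
#' the scale is gamma * B0 * te * 1e-6.
#'
#' @param grid a \code{\link{qsm_grid}}.
#' @param acq a \code{\link{qsm_acq}}; required when \code{unit = "radians"}.
#' @param unit \code{"ppm"} (default) or \code{"radians"}.
#' @param te echo time used for the radians scale (default: first echo).
#' @return An object of class \code{"dipole_kernel"} with elements
#'   \code{values} (3-D array, dimensionless, in FFT bin order),
#'   \code{grid}, \code{scale} and \code{unit}.
#' @examples
#' g <- qsm_grid(c(16, 16, 16))
#' d <- dipole_kernel(g)
#' range(d$values)  # within [-2/3, 1/3]
#' @export
dipole_kernel <- function(grid, acq = NULL, unit = c("ppm", "radians"),
                          te = NULL) {
  stopifnot(inherits(grid, "qsm_grid"))
  unit <- match.arg(unit)
  if (unit == "radians") {
    if (is.null(acq))
      stop("acquisition parameters are required for unit = \"radians\"",
           call. = FALSE)
    if (is.null(te)) te <- acq$te[1]
    scale <- ppm_to_rad(acq, te)
  } else {
    scale <- 1
  }
  n <- grid$shape
  kx <- fft_freq(n[1], grid$voxel_size[1])
  ky <- fft_freq(n[2], grid$voxel_size[2])
  kz <- fft_freq(n[3], grid$voxel_size[3])
  b <- grid$b0_direction
  # k . b0_hat on the full grid, built by outer sums to avoid expand.grid
  kpar <- outer(outer(kx * b[1], ky * b[2], `+`), kz * b[3], `+`)
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  values <- 1 / 3 - kpar^2 / k2
  values[1, 1, 1] <- 0  # zero-frequency bin: mean offset unobservable
  structure(list(values = values, grid = grid, scale = scale, unit = unit),
            class = "dipole_kernel")
}

#' @export
print.dipole_kernel <- function(x, ...) {
  cat("Dipole kernel on ", paste(x$grid$shape, collapse = " x "),
      " grid; unit = ", x$unit, ", scale = ", format(x$scale), "\n", sep = "")
  invisible(x)
}

# internal: effective k-space multiplier (dimensionless values * scale)
kernel_mult <- function(kernel) kernel$values * kernel$scale

#' Susceptibility-to-field forward model
#'
#' Applies the dipole convolution F^H D F: the field (or phase, depending
#' on the kernel unit) induced by a susceptibility distribution. Periodic
#' boundary conditions are implied by the FFT; zero-pad beforehand (see
#' \code{\link{pad_to_shape}}) when wrap-around matters.
#'
#' @param chi 3-D susceptibility array (ppm).
#' @param kernel a \code{\link{dipole_kernel}} on the same grid.
#' @return 3-D field array (ppm, or radians for a radians-unit kernel).
#' @seealso \code{\link{adjoint_field}}
#' @export
forward_field <- function(chi, kernel) {
  stopifnot(inherits(kernel, "dipole_kernel"))
  check_volume(chi, kernel$grid, "chi")
  n <- length(chi)
  Re(fft(kernel_mult(kernel) * fft(chi), inverse = TRUE)) / n
}

#' Adjoint of the forward field operator
#'
#' Because the dipole multiplier is real and even in k, the adjoint equals
#' the forward operator; it is kept as a named operation so solver code
#' reads correctly and the adjoint identity can be tested.
#'
#' @param phi 3-D field array.
#' @param kernel a \code{\link{dipole_kernel}} on the same grid.
#' @return 3-D array, the adjoint image of \code{phi}.
#' @export
adjoint_field <- function(phi, kernel) {
  stopifnot(inherits(kernel, "dipole_kernel"))
  check_volume(phi, kernel$grid, "phi")
  n <- length(phi)
  Re(fft(Conj(kernel_mult(kernel)) * fft(phi), inverse = TRUE)) / n
}

#' Simulate a multi-echo gradient-echo signal
#'
#' Generates complex gradient-echo images for each echo time: magnitude
#' M0 * exp(-TE_i * R2*) and phase equal to the dipole-convolved field
#' scaled to radians at TE_i.
#'
#' @param chi 3-D susceptibility array (ppm).
#' @param grid a \code{\link{qsm_grid}}.
#' @param acq a \code{\link{qsm_acq}} providing B0 and the echo times.
#' @param m0 proton-density magnitude, scalar or 3-D array (default 1).
#' @param r2star effective transverse relaxation rate in s^-1, scalar or
#'   3-D array, >= 0 (default 0: no decay).
#' @return list of complex 3-D arrays, one per echo.
#' @export
simulate_multiecho_signal <- function(chi, grid, acq, m0 = 1, r2star = 0) {
  stopifnot(inherits(grid, "qsm_grid"), inherits(acq, "qsm_acq"))
  check_volume(chi, grid, "chi")
  if (any(r2star < 0)) stop("'r2star' must be >= 0", call. = FALSE)
  field_ppm <- forward_field(chi, dipole_kernel(grid))
  lapply(acq$te, function(te) {
    mag <- m0 * exp(-te * r2star)
    mag * exp(1i * field_ppm * ppm_to_rad(acq, te))
  })
}
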