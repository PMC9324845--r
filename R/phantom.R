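# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic susceptibility phantom
#'
#' Defines the study conditions of a simulated acquisition: the grid, the
#' noise level, the phase-jump corruption, and the piecewise-constant
#' susceptibility structures inside an ellipsoidal head mask.
#'
#' The default structure set spans paramagnetic and diamagnetic tissue at
#' literature-plausible magnitudes: paired deep gray-matter spheres at
#' +0.18 and +0.09 ppm, a caudate-like ellipsoid at +0.06 ppm, a white
#' matter ellipsoid at -0.03 ppm, and a vein-like cylinder at +0.30 ppm;
#' an optional calcification sphere at -0.50 ppm emulates a strongly
#' diamagnetic lesion. SNR is defined as the reciprocal of the complex
#' noise standard deviation per quadrature channel on a unit-magnitude
#' signal.
#'
#' @param shape grid size (default 64^3).
#' @param voxel_size voxel size in mm (default 1 mm isotropic).
#' @param seed integer seed driving every stochastic element.
#' @param snr signal-to-noise ratio, > 0 (default 100).
#' @param n_jumps number of phase-jump regions, 0 or 2 (default 0).
#' @param jump_amplitude phase-jump magnitude in radians (default 20*pi;
#'   applied as +amp in one region and -amp in the other).
#' @param jump_radius radius of the spherical jump regions in voxels.
#' @param include_calcification add the -0.5 ppm calcification sphere.
#' @param structures optional replacement structure list; each element is
#'   a list with \code{type} ("sphere", "ellipsoid" or "cylinder"),
#'   \code{center} (fractions of the grid extent), \code{radius} or
#'   \code{semi_axes} (fractions), \code{value} (ppm) and \code{label}.
#' @param background background susceptibility outside the head mask (ppm).
#' @return An object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), voxel_size = c(1, 1, 1),
                         seed = 1L, snr = 100, n_jumps = 0L,
                         jump_amplitude = 20 * pi, jump_radius = 2,
                         include_calcification = FALSE, structures = NULL,
                         background = 0) {
  if (snr <= 0) stop("'snr' must be positive", call. = FALSE)
  if (!n_jumps %in% c(0L, 2L))
    stop("'n_jumps' must be 0 or 2 (one positive and one negative jump)",
         call. = FALSE)
  if (is.null(structures)) {
    structures <- list(
      list(type = "sphere", center = c(0.38, 0.45, 0.50), radius = 0.07,
           value = 0.18, label = "deep_gm_left"),
      list(type = "sphere", center = c(0.62, 0.45, 0.50), radius = 0.07,
           value = 0.18, label = "deep_gm_right"),
      list(type = "ellipsoid", center = c(0.50, 0.62, 0.48),
           semi_axes = c(0.10, 0.06, 0.08), value = 0.09, label = "putamen"),
      list(type = "ellipsoid", center = c(0.50, 0.32, 0.52),
           semi_axes = c(0.08, 0.07, 0.06), value = 0.06, label = "caudate"),
      list(type = "ellipsoid", center = c(0.50, 0.50, 0.30),
           semi_axes = c(0.22, 0.20, 0.10), value = -0.03,
           label = "white_matter"),
      list(type = "cylinder", center = c(0.30, 0.65, 0.50), radius = 0.025,
           half_length = 0.18, value = 0.30, label = "vein"))
    if (include_calcification)
      structures <- c(structures,
                      list(list(type = "sphere", center = c(0.66, 0.62, 0.60),
                                radius = 0.05, value = -0.50,
                                label = "calcification")))
  }
  structure(list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
                 seed = as.integer(seed), snr = snr, n_jumps = as.integer(n_jumps),
                 jump_amplitude = jump_amplitude, jump_radius = jump_radius,
                 include_calcification = include_calcification,
                 structures = structures, background = background),
            class = "phantom_spec")
}

#' Save / load a phantom specification
#'
#' Serializes the full specification (grid, noise, jumps, structure list)
#' as JSON, so an experiment bundle can be regenerated bit-identically
#' from the file.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param path JSON file path.
#' @return \code{write_phantom_spec}: the path, invisibly;
#'   \code{read_phantom_spec}: the restored \code{phantom_spec}.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  # I(17) significant digits: doubles survive the round trip exactly
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  phantom_spec(shape = x$shape, voxel_size = x$voxel_size, seed = x$seed,
               snr = x$snr, n_jumps = x$n_jumps,
               jump_amplitude = x$jump_amplitude, jump_radius = x$jump_radius,
               include_calcification = isTRUE(x$include_calcification),
               structures = lapply(x$structures, function(s) {
                 s[c("center", "semi_axes")] <-
                   lapply(s[c("center", "semi_axes")], unlist)
                 s[!vapply(s, is.null, logical(1))]
               }),
               background = x$background)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Phantom spec: ", paste(x$shape, collapse = " x "), " voxels, SNR ",
      x$snr, ", ", x$n_jumps, " phase jumps, ", length(x$structures),
      " structures, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# normalized coordinate arrays in [0, 1) for each axis
coord_grids <- function(shape) {
  cx <- (seq_len(shape[1]) - 0.5) / shape[1]
  cy <- (seq_len(shape[2]) - 0.5) / shape[2]
  cz <- (seq_len(shape[3]) - 0.5) / shape[3]
  list(x = array(rep(cx, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(cy, each = shape[1]), times = shape[3]), shape),
       z = array(rep(cz, each = shape[1] * shape[2]), shape))
}

structure_mask <- function(s, co) {
  switch(s$type,
         sphere = ((co$x - s$center[1])^2 + (co$y - s$center[2])^2 +
                     (co$z - s$center[3])^2) <= s$radius^2,
         ellipsoid = ((co$x - s$center[1])^2 / s$semi_axes[1]^2 +
                        (co$y - s$center[2])^2 / s$semi_axes[2]^2 +
                        (co$z - s$center[3])^2 / s$semi_axes[3]^2) <= 1,
         cylinder = (((co$x - s$center[1])^2 + (co$y - s$center[2])^2)
                     <= s$radius^2) & (abs(co$z - s$center[3]) <= s$half_length),
         stop("unknown structure type: ", s$type, call. = FALSE))
}

#' Generate the ground-truth phantom
#'
#' Builds the piecewise-constant susceptibility volume, the ellipsoidal
#' head mask (semi-axes 0.42, 0.45, 0.38 of the grid extent) and an
#' integer label volume (0 = unlabeled tissue/background, then one label
#' per structure in specification order). Deterministic given the spec.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{chi} (ppm), \code{mask} (0/1), \code{labels}
#'   (integer array), \code{label_names}, \code{label_values} and
#'   \code{grid}.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  co <- coord_grids(shape)
  head <- ((co$x - 0.5)^2 / 0.42^2 + (co$y - 0.5)^2 / 0.45^2 +
             (co$z - 0.5)^2 / 0.38^2) <= 1
  chi <- array(spec$background, shape)
  chi[head] <- 0
  labels <- array(0L, shape)
  for (i in seq_along(spec$structures)) {
    s <- spec$structures[[i]]
    m <- structure_mask(s, co)
    if (any(m & !head))
      stop(sprintf("structure '%s' extends outside the head mask", s$label),
           call. = FALSE)
    chi[m] <- s$value
    labels[m] <- i
  }
  list(chi = chi, mask = head * 1, labels = labels,
       label_names = vapply(spec$structures, `[[`, character(1), "label"),
       label_values = vapply(spec$structures, `[[`, numeric(1), "value"),
       grid = qsm_grid(shape, spec$voxel_size))
}

#' Add complex Gaussian noise to a phase volume
#'
#' Models the phase of a unit-magnitude complex signal corrupted by
#' additive complex Gaussian noise: s = exp(i phase) + eta with
#' independent N(0, 1/snr^2) real and imaginary parts, returning Arg(s).
#' In the high-SNR limit the induced phase noise is approximately
#' Gaussian with standard deviation 1/snr.
#'
#' @param phase 3-D phase array (radians).
#' @param snr signal-to-noise ratio, > 0.
#' @param seed integer seed.
#' @return 3-D phase array (radians), wrapped to (-pi, pi].
#' @export
add_complex_noise <- function(phase, snr, seed) {
  if (snr <= 0) stop("'snr' must be positive", call. = FALSE)
  n <- length(phase)
  eta <- with_seed(seed, complex(real = rnorm(n, sd = 1 / snr),
                                 imaginary = rnorm(n, sd = 1 / snr)))
  out <- Arg(exp(1i * phase) + eta)
  dim(out) <- dim(phase)
  out
}

#' Inject a pair of opposite phase jumps
#'
#' Adds +amplitude in one small spherical region and -amplitude in a
#' second, disjoint one, both placed pseudo-randomly well inside the
#' mask. Emulates the strong localized phase inconsistencies (e.g.
#' unwrapping failures) that seed streaking artifacts in L2
#' reconstructions.
#'
#' @param phase 3-D phase array (radians).
#' @param mask binary head mask.
#' @param amplitude jump magnitude in radians (default 20*pi).
#' @param radius region radius in voxels (default 2).
#' @param seed integer seed.
#' @return list with \code{phase} (corrupted) and \code{jumps}: an array
#'   holding the added offset at each voxel (0 outside the regions).
#' @export
inject_phase_jumps <- function(phase, mask, amplitude = 20 * pi, radius = 2,
                               seed = 1L) {
  shape <- dim(phase)
  stopifnot(identical(dim(mask), shape))
  # candidate centers: voxels whose whole sphere stays inside the mask
  # (morphological erosion of the mask by the sphere, via shifts)
  r <- ceiling(radius)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= radius^2, ]
  inside <- mask != 0
  eroded <- inside
  for (o in seq_len(nrow(offs))) {
    sh <- inside
    for (a in 1:3) {
      by <- offs[o, a]
      if (by != 0) sh <- axshift(sh, a, by)
    }
    eroded <- eroded & sh
  }
  # keep the sphere away from the volume faces as well
  pad <- r + 1
  idx <- which(eroded, arr.ind = TRUE)
  ok <- idx[, 1] > pad & idx[, 1] <= shape[1] - pad &
    idx[, 2] > pad & idx[, 2] <= shape[2] - pad &
    idx[, 3] > pad & idx[, 3] <= shape[3] - pad
  cand <- idx[ok, , drop = FALSE]
  if (nrow(cand) < 2)
    stop("mask too small to place two disjoint jump regions", call. = FALSE)
  centers <- with_seed(seed, {
    c1 <- cand[sample.int(nrow(cand), 1L), ]
    sep <- sqrt(rowSums(sweep(cand, 2, c1)^2))
    far <- cand[sep > 2 * radius + 1, , drop = FALSE]
    if (nrow(far) == 0)
      stop("cannot place two disjoint jump regions", call. = FALSE)
    list(c1, far[sample.int(nrow(far), 1L), ])
  })
  jumps <- array(0, shape)
  ax <- lapply(1:3, function(a) seq_len(shape[a]))
  for (k in 1:2) {
    ctr <- centers[[k]]
    d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, `+`),
                (ax[[3]] - ctr[3])^2, `+`)
    jumps[d2 <= radius^2] <- if (k == 1) amplitude else -amplitude
  }
  list(phase = phase + jumps, jumps = jumps)
}

#' Simulate a full forward experiment
#'
#' Chains the phantom pipeline: ground-truth generation, dipole forward
#' simulation of the local field, complex Gaussian noise added to the
#' phase at the reference echo time, and optional phase-jump corruption.
#' A multi-echo branch additionally simulates per-echo noisy phases and
#' magnitudes and fits them back to a local field map with
#' \code{\link{fit_local_field}}, exercising the preprocessing chain.
#' The returned bundle carries every intermediate product needed for
#' solver validation.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param acq a \code{\link{qsm_acq}} (default: 3 T, TE = 4, 12, 20, 28 ms).
#' @param r2star effective transverse relaxation rate for the echo
#'   magnitudes, in s^-1 (default 20).
#' Reconstruction inputs are provided in phase units (radians at the
#' reference echo time \code{te_ref}, the mean echo time): with the
#' fixed data-consistency Lagrangian weight mu2 = 1, the L1 stage's
#' outlier rejection threshold w/mu2 is calibrated for phase-scale
#' residuals — strong inconsistencies (tens of radians) exceed it while
#' thermal phase noise (~1/SNR radians) does not.
#'
#' @return list with \code{chi} (ground truth, ppm), \code{mask},
#'   \code{labels}, \code{grid}, \code{kernel} (ppm unit),
#'   \code{kernel_rad} (radians at \code{te_ref}), \code{te_ref},
#'   \code{field_clean} (noise-free local field, ppm),
#'   \code{field_noisy} (noise at the stated SNR, ppm),
#'   \code{field_corrupted} (noise plus phase jumps when requested, else
#'   identical to \code{field_noisy}), \code{phase_clean},
#'   \code{phase_noisy}, \code{phase_corrupted} (the same as radians at
#'   \code{te_ref}), \code{jumps} (radians), \code{echoes} (an
#'   \code{\link{echo_series}} with independent per-echo noise),
#'   \code{field_fit} (ppm, fitted from the echoes), \code{weight}
#'   (magnitude weight, max 1 in mask), \code{acq}, \code{spec}.
#' @export
simulate_cosmos_experiment <- function(spec,
                                       acq = qsm_acq(3, c(4, 12, 20, 28) * 1e-3),
                                       r2star = 20) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(acq, "qsm_acq"))
  ph <- make_phantom(spec)
  kernel <- dipole_kernel(ph$grid)
  field_ppm <- forward_field(ph$chi, kernel)
  te_ref <- mean(acq$te)
  s_ref <- ppm_to_rad(acq, te_ref)
  kernel_rad <- dipole_kernel(ph$grid, acq, unit = "radians", te = te_ref)

  # single-phase branch: noise and jumps applied to the phase at te_ref
  phase_clean <- field_ppm * s_ref
  phase_noisy <- if (is.finite(spec$snr))
    add_complex_noise(phase_clean, spec$snr, spec$seed) else phase_clean
  jumps <- array(0, spec$shape)
  phase_corrupted <- phase_noisy
  if (spec$n_jumps == 2L) {
    jmp <- inject_phase_jumps(phase_noisy, ph$mask,
                              amplitude = spec$jump_amplitude,
                              radius = spec$jump_radius, seed = spec$seed)
    phase_corrupted <- jmp$phase
    jumps <- jmp$jumps
  }

  # multi-echo branch: independent per-echo noise, magnitude decay, WLS fit
  mags <- phases <- vector("list", length(acq$te))
  for (i in seq_along(acq$te)) {
    phase_i <- field_ppm * ppm_to_rad(acq, acq$te[i])
    phases[[i]] <- if (is.finite(spec$snr))
      add_complex_noise(phase_i, spec$snr, spec$seed + i) else phase_i
    mags[[i]] <- array(exp(-acq$te[i] * r2star), dim(phase_i))
  }
  echoes <- echo_series(mags, phases, acq$te)
  rad_per_s_to_ppm <- 1 / (acq$gamma * acq$b0 * 1e-6)
  field_fit <- fit_local_field(echoes) * rad_per_s_to_ppm
  attr(field_fit, "valid") <- NULL

  weight <- magnitude_weight(echoes, mask = ph$mask)
  list(chi = ph$chi, mask = ph$mask, labels = ph$labels,
       label_names = ph$label_names, label_values = ph$label_values,
       grid = ph$grid, kernel = kernel, kernel_rad = kernel_rad,
       te_ref = te_ref, field_clean = field_ppm,
       field_noisy = phase_noisy / s_ref,
       field_corrupted = phase_corrupted / s_ref,
       phase_clean = phase_clean, phase_noisy = phase_noisy,
       phase_corrupted = phase_corrupted,
       jumps = jumps, echoes = echoes, field_fit = field_fit,
       weight = weight, acq = acq, spec = spec)
}
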