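#' @useDynLib hdqsm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd
NULL

# circularly shift a 3-D array by `by` along `axis`
axshift <- function(x, axis, by) {
  n <- dim(x)[axis]
  idx <- ((seq_len(n) - 1L + by) %% n) + 1L
  switch(axis,
         x[idx, , , drop = FALSE],
         x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

#' Forward finite-difference gradient with periodic wrap
#'
#' Forward differences along each axis, g_a[i] = x[i + e_a] - x[i] with
#' periodic boundary, so each component is the circular convolution with
#' Fourier multiplier exp(2 pi i k_a / N_a) - 1 and the ADMM chi-update
#' stays exactly FFT-diagonal.
#'
#' @param x real 3-D array.
#' @return list of three 3-D arrays (differences along x, y, z).
#' @export
grad_forward <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  lapply(1:3, function(a) axshift(x, a, 1L) - x)
}

#' Adjoint of the periodic forward gradient
#'
#' The negative backward divergence: for each axis,
#' (G_a' v)[i] = v[i - e_a] - v[i], summed over axes.
#'
#' @param g list of three 3-D arrays as produced by \code{\link{grad_forward}}.
#' @return real 3-D array.
#' @export
grad_adjoint <- function(g) {
  stopifnot(is.list(g), length(g) == 3L)
  Reduce(`+`, lapply(1:3, function(a) axshift(g[[a]], a, -1L) - g[[a]]))
}

#' Soft-thresholding (proximal operator of the weighted L1 norm)
#'
#' sign(x) * max(|x| - t, 0), element-wise; the threshold may vary per
#' element.
#'
#' @param x numeric array or vector.
#' @param threshold nonnegative scalar or array conformable with \code{x}.
#' @return same shape as \code{x}.
#' @export
soft_threshold <- function(x, threshold) {
  if (any(threshold < 0)) stop("'threshold' must be nonnegative", call. = FALSE)
  out <- sign(x) * pmax(abs(x) - threshold, 0)
  dim(out) <- dim(x)
  out
}

#' ADMM stage parameters
#'
#' Parameters of one solver stage: the TV regularization weight lambda,
#' the two Lagrangian (augmented-penalty) weights — mu1 couples the TV
#' split variable to the gradient of chi, mu2 couples the data split
#' variable to the dipole-convolved chi — the fixed iteration count, and
#' which data-fidelity norm the stage minimizes.
#'
#' @param lambda TV regularization weight, > 0.
#' @param mu1 gradient-consistency weight, > 0.
#' @param mu2 data-consistency weight, > 0 (default 1).
#' @param n_iter number of ADMM iterations, >= 0 (no early stopping).
#' @param norm \code{"l1"} or \code{"l2"} data fidelity.
#' @param isotropic if TRUE, use isotropic TV shrinkage (joint vector
#'   magnitude across axes); default FALSE (anisotropic, component-wise).
#' @return An object of class \code{"solver_params"}.
#' @export
solver_params <- function(lambda, mu1, mu2 = 1, n_iter, norm = c("l1", "l2"),
                          isotropic = FALSE) {
  norm <- match.arg(norm)
  if (lambda <= 0 || mu1 <= 0 || mu2 <= 0)
    stop("lambda, mu1 and mu2 must be positive", call. = FALSE)
  n_iter <- as.integer(n_iter)
  if (n_iter < 0) stop("'n_iter' must be >= 0", call. = FALSE)
  structure(list(lambda = lambda, mu1 = mu1, mu2 = mu2, n_iter = n_iter,
                 norm = norm, isotropic = isotropic),
            class = "solver_params")
}

#' Zero ADMM state
#'
#' All-zero solver iterate: susceptibility estimate, TV split variables
#' (one per axis) with their scaled multipliers, and the data split
#' variable with its multiplier.
#'
#' @param shape integer vector of length 3.
#' @return An object of class \code{"admm_state"}.
#' @export
admm_state <- function(shape) {
  z <- function() array(0, shape)
  structure(list(chi = z(),
                 z_grad = list(z(), z(), z()),
                 s_grad = list(z(), z(), z()),
                 z_data = z(), s_data = z(), iteration = 0L),
            class = "admm_state")
}

# sum over axes of |exp(2 pi i k_a/N_a) - 1|^2 on the FFT grid
grad_mult_sq <- function(shape) {
  f <- function(n) 2 - 2 * cos(2 * pi * (seq_len(n) - 1L) / n)
  outer(outer(f(shape[1]), f(shape[2]), `+`), f(shape[3]), `+`)
}

#' L1 data-consistency split update
#'
#' Proximal step of the weighted L1 data term around the current
#' consistency point: z = phi + soft(D chi + s - phi, w / mu2). Voxels
#' whose residual is below w/mu2 match the data exactly; larger residuals
#' are shrunk toward it — the outlier-rejection mechanism of the L1 stage.
#'
#' @param state an \code{\link{admm_state}}.
#' @param phi measured field/phase array.
#' @param w weight array (nonnegative).
#' @param params a \code{\link{solver_params}} with \code{norm = "l1"}.
#' @param kernel a \code{\link{dipole_kernel}}.
#' @return updated \code{z_data} array.
#' @export
l1_data_update <- function(state, phi, w, params, kernel) {
  if (params$mu2 <= 0) stop("mu2 must be positive", call. = FALSE)
  dchi <- forward_field(state$chi, kernel)
  phi + soft_threshold(dchi + state$s_data - phi, w / params$mu2)
}

#' L2 data-consistency split update
#'
#' Closed-form minimizer of the weighted squared-L2 data term plus the
#' augmented coupling: z = (W^2 phi + mu2 (D chi + s)) / (W^2 + mu2).
#'
#' @inheritParams l1_data_update
#' @param W weight array (nonnegative).
#' @return updated \code{z_data} array.
#' @export
l2_data_update <- function(state, phi, W, params, kernel) {
  if (params$mu2 <= 0) stop("mu2 must be positive", call. = FALSE)
  dchi <- forward_field(state$chi, kernel)
  (W^2 * phi + params$mu2 * (dchi + state$s_data)) / (W^2 + params$mu2)
}

#' Fourier-diagonal chi update
#'
#' Solves the quadratic chi subproblem
#' min_chi mu2/2 ||D chi - (z_d - s_d)||^2 +
#'         mu1/2 sum_a ||G_a chi - (z_ga - s_ga)||^2
#' exactly in one FFT round trip, since D and the periodic gradients G_a
#' are all diagonal in the Fourier basis. The zero-frequency bin — which
#' neither D nor the gradients constrain — is forced to 0 (mean-free
#' susceptibility).
#'
#' @param state an \code{\link{admm_state}}.
#' @param kernel a \code{\link{dipole_kernel}}.
#' @param params a \code{\link{solver_params}}.
#' @return updated \code{chi} array.
#' @export
chi_update <- function(state, kernel, params) {
  dk <- kernel_mult(kernel)
  shape <- dim(dk)
  n <- length(dk)
  den <- params$mu2 * dk^2 + params$mu1 * grad_mult_sq(shape)
  den[1, 1, 1] <- 1  # guarded: numerator bin forced to zero below
  gdiff <- lapply(1:3, function(a) state$z_grad[[a]] - state$s_grad[[a]])
  num <- params$mu2 * dk * fft(state$z_data - state$s_data) +
    params$mu1 * fft(grad_adjoint(gdiff))
  chat <- num / den
  chat[1, 1, 1] <- 0
  Re(fft(chat, inverse = TRUE)) / n
}

#' Scaled dual (Lagrange multiplier) ascent
#'
#' s_grad_a += G_a chi - z_grad_a; s_data += D chi - z_data.
#'
#' @param state an \code{\link{admm_state}}.
#' @param kernel a \code{\link{dipole_kernel}}.
#' @return the state with updated multipliers.
#' @export
multiplier_update <- function(state, kernel) {
  g <- grad_forward(state$chi)
  for (a in 1:3)
    state$s_grad[[a]] <- state$s_grad[[a]] + g[[a]] - state$z_grad[[a]]
  state$s_data <- state$s_data + forward_field(state$chi, kernel) - state$z_data
  state
}

#' Objective value of a stage functional
#'
#' The exact value being minimized: for \code{norm = "l1"},
#' ||w (D chi - phi)||_1 + lambda TV(chi); for \code{norm = "l2"},
#' 1/2 ||W (D chi - phi)||_2^2 + lambda TV(chi). TV is anisotropic
#' (sum of absolute forward differences) unless \code{isotropic}.
#'
#' @param chi susceptibility array (ppm).
#' @param phi measured field/phase array.
#' @param weight weight array.
#' @param kernel a \code{\link{dipole_kernel}}.
#' @param lambda TV weight.
#' @param norm \code{"l1"} or \code{"l2"}.
#' @param isotropic isotropic TV if TRUE.
#' @return scalar objective value.
#' @export
qsm_objective <- function(chi, phi, weight, kernel, lambda,
                          norm = c("l1", "l2"), isotropic = FALSE) {
  norm <- match.arg(norm)
  res <- forward_field(chi, kernel) - phi
  data_term <- if (norm == "l1") sum(abs(weight * res))
  else 0.5 * sum((weight * res)^2)
  g <- grad_forward(chi)
  tv <- if (isotropic) sum(sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2))
  else sum(abs(g[[1]])) + sum(abs(g[[2]])) + sum(abs(g[[3]]))
  data_term + lambda * tv
}

#' Run one ADMM stage
#'
#' Runs exactly \code{params$n_iter} iterations of the splitting scheme
#' for the selected data-fidelity norm. Each iteration performs, in this
#' fixed order: TV split soft-threshold (threshold lambda/mu1), data split
#' update (L1 proximal or L2 closed form), Fourier-diagonal chi update,
#' scaled multiplier ascent. There is no early stopping; the iteration
#' order is part of the contract (changing it changes the iterates).
#'
#' Two engines produce identical results (to floating-point noise): the
#' default compiled engine (FFTW-backed C++, used for production-size
#' volumes) and a pure-R reference engine used for oracle validation.
#'
#' @param phi measured field/phase, 3-D array.
#' @param weight data-consistency weight, nonnegative 3-D array.
#' @param kernel a \code{\link{dipole_kernel}}.
#' @param params a \code{\link{solver_params}}.
#' @param init an \code{\link{admm_state}} to start from (default: zeros).
#' @param engine \code{"cpp"} (default) or \code{"R"}.
#' @param truth optional ground-truth susceptibility; when given, the
#'   returned state carries an attribute \code{"nrmse"} with the masked
#'   NRMSE after every iteration.
#' @param mask binary array for the NRMSE trace (default: all voxels).
#' @return the final \code{\link{admm_state}}.
#' @export
qsm_stage <- function(phi, weight, kernel, params, init = NULL,
                      engine = c("cpp", "R"), truth = NULL, mask = NULL) {
  stopifnot(inherits(kernel, "dipole_kernel"), inherits(params, "solver_params"))
  engine <- match.arg(engine)
  grid <- kernel$grid
  check_volume(phi, grid, "phi")
  check_volume(weight, grid, "weight")
  if (is.null(init)) init <- admm_state(grid$shape)
  stopifnot(inherits(init, "admm_state"))
  if (!same_shape(init$chi, grid$shape))
    stop("init state shape does not match the kernel grid", call. = FALSE)
  if (!is.null(truth)) check_volume(truth, grid, "truth")
  if (is.null(mask)) mask <- array(1, grid$shape) else check_volume(mask, grid, "mask")

  if (params$n_iter == 0L) {
    if (!is.null(truth)) attr(init, "nrmse") <- numeric(0)
    return(init)
  }

  if (engine == "cpp") {
    res <- admm_run_cpp(as.numeric(phi), as.numeric(weight),
                        as.numeric(kernel_mult(kernel)), grid$shape,
                        params$lambda, params$mu1, params$mu2, params$n_iter,
                        params$norm == "l1", isTRUE(params$isotropic),
                        as.numeric(init$chi),
                        lapply(init$z_grad, as.numeric),
                        lapply(init$s_grad, as.numeric),
                        as.numeric(init$z_data), as.numeric(init$s_data),
                        if (is.null(truth)) numeric(0) else as.numeric(truth),
                        as.numeric(mask != 0))
    shape <- grid$shape
    wrap <- function(v) { dim(v) <- shape; v }
    state <- structure(list(chi = wrap(res$chi),
                            z_grad = lapply(res$z_grad, wrap),
                            s_grad = lapply(res$s_grad, wrap),
                            z_data = wrap(res$z_data),
                            s_data = wrap(res$s_data),
                            iteration = init$iteration + params$n_iter),
                       class = "admm_state")
    if (!is.null(truth)) attr(state, "nrmse") <- res$nrmse
    return(state)
  }

  # pure-R reference engine: same updates, same order
  state <- init
  thresh <- params$lambda / params$mu1
  trace <- if (is.null(truth)) NULL else numeric(params$n_iter)
  inmask <- mask != 0
  tnorm <- if (!is.null(truth)) sqrt(sum((truth[inmask])^2)) else NA_real_
  for (it in seq_len(params$n_iter)) {
    g <- grad_forward(state$chi)
    if (isTRUE(params$isotropic)) {
      v <- lapply(1:3, function(a) g[[a]] + state$s_grad[[a]])
      mag <- sqrt(v[[1]]^2 + v[[2]]^2 + v[[3]]^2)
      shrink <- ifelse(mag > 0, pmax(1 - thresh / mag, 0), 0)
      state$z_grad <- lapply(v, function(x) shrink * x)
    } else {
      for (a in 1:3)
        state$z_grad[[a]] <- soft_threshold(g[[a]] + state$s_grad[[a]], thresh)
    }
    state$z_data <- if (params$norm == "l1")
      l1_data_update(state, phi, weight, params, kernel)
    else
      l2_data_update(state, phi, weight, params, kernel)
    state$chi <- chi_update(state, kernel, params)
    state <- multiplier_update(state, kernel)
    state$iteration <- state$iteration + 1L
    if (!is.null(trace))
      trace[it] <- 100 * sqrt(sum(((state$chi - truth)[inmask])^2)) / tnorm
  }
  if (!is.null(trace)) attr(state, "nrmse") <- trace
  state
}
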