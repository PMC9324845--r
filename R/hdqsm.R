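#' Two-stage solver configuration
#'
#' Holds the per-stage parameters of the hybrid reconstruction. With
#' \code{use_heuristic = TRUE} (the default) the six parameters collapse
#' to one free regularization weight: lambda_L1 = lambda_L2 = lambda,
#' mu1_L1 = mu1_L2 = mu_ratio * lambda, mu2_L1 = mu2_L2 = 1. Ratios
#' mu1/lambda between 10 and 100 leave the optimal reconstruction nearly
#' unchanged; values outside that range trigger a warning but are
#' accepted.
#'
#' @param lambda stage-2 TV regularization weight (the one free
#'   parameter), > 0.
#' @param mu_ratio mu1 / lambda (default 10).
#' @param i1 stage-1 (L1) iteration count.
#' @param i2 stage-2 (L2) iteration count.
#' @param use_heuristic derive all six parameters from \code{lambda} and
#'   \code{mu_ratio}; set FALSE to pass the six explicitly.
#' @param lambda_l1,mu1_l1,mu2_l1,lambda_l2,mu1_l2,mu2_l2 explicit
#'   per-stage parameters, used when \code{use_heuristic = FALSE}.
#' @param isotropic isotropic TV shrinkage (default FALSE).
#' @return An object of class \code{"hdqsm_config"}.
#' @examples
#' cfg <- hdqsm_config(lambda = 6.3096e-6, mu_ratio = 10, i1 = 20, i2 = 280)
#' @export
hdqsm_config <- function(lambda = NULL, mu_ratio = 10, i1 = 20, i2 = 280,
                         use_heuristic = TRUE,
                         lambda_l1 = NULL, mu1_l1 = NULL, mu2_l1 = 1,
                         lambda_l2 = NULL, mu1_l2 = NULL, mu2_l2 = 1,
                         isotropic = FALSE) {
  i1 <- as.integer(i1); i2 <- as.integer(i2)
  if (i1 < 0 || i2 < 0) stop("i1 and i2 must be >= 0", call. = FALSE)
  if (use_heuristic) {
    if (is.null(lambda) || lambda <= 0)
      stop("'lambda' must be a positive number", call. = FALSE)
    if (mu_ratio < 10 || mu_ratio > 100)
      warning("mu_ratio outside [10, 100]; reconstructions may need retuning")
    lambda_l1 <- lambda_l2 <- lambda
    mu1_l1 <- mu1_l2 <- mu_ratio * lambda
    mu2_l1 <- mu2_l2 <- 1
  } else {
    if (is.null(lambda_l1) || is.null(mu1_l1) ||
        is.null(lambda_l2) || is.null(mu1_l2))
      stop("explicit per-stage parameters required when use_heuristic = FALSE",
           call. = FALSE)
  }
  structure(list(lambda_l1 = lambda_l1, mu1_l1 = mu1_l1, mu2_l1 = mu2_l1,
                 lambda_l2 = lambda_l2, mu1_l2 = mu1_l2, mu2_l2 = mu2_l2,
                 i1 = i1, i2 = i2, use_heuristic = use_heuristic,
                 isotropic = isotropic),
            class = "hdqsm_config")
}

#' One-free-parameter heuristic
#'
#' Builds a full two-stage configuration from the regularization weight
#' alone, splitting a total iteration budget between the stages. Stage-1
#' counts between 10 and 100 are recommended; the optimized error is
#' insensitive to the split.
#'
#' @param lambda regularization weight, > 0.
#' @param mu_ratio mu1 / lambda in [10, 100] (default 10).
#' @param i_total total iteration count.
#' @param i1 stage-1 iterations (i2 = i_total - i1).
#' @return An \code{\link{hdqsm_config}}.
#' @examples
#' heuristic_params(6.3096e-6, 10, 300, 20)  # i2 = 280, mu1 = 6.3096e-5
#' @export
heuristic_params <- function(lambda, mu_ratio = 10, i_total, i1 = 20) {
  i_total <- as.integer(i_total); i1 <- as.integer(i1)
  if (i1 > i_total)
    stop("i1 cannot exceed the total iteration count", call. = FALSE)
  hdqsm_config(lambda = lambda, mu_ratio = mu_ratio, i1 = i1,
               i2 = i_total - i1, use_heuristic = TRUE)
}

#' @export
print.hdqsm_config <- function(x, ...) {
  cat("HD-QSM configuration",
      if (x$use_heuristic) " (one-parameter heuristic)" else "", "\n",
      sprintf("  stage 1 (L1): lambda = %g, mu1 = %g, mu2 = %g, %d iterations\n",
              x$lambda_l1, x$mu1_l1, x$mu2_l1, x$i1),
      sprintf("  stage 2 (L2): lambda = %g, mu1 = %g, mu2 = %g, %d iterations\n",
              x$lambda_l2, x$mu1_l2, x$mu2_l2, x$i2), sep = "")
  invisible(x)
}

#' Hybrid data-fidelity dipole inversion
#'
#' Reconstructs a susceptibility map from a local field map in two stages.
#' Stage one minimizes the weighted L1-norm data-consistency functional
#' with TV regularization from a zero start, producing a streaking-robust
#' but noisy estimate chi1. Its voxel-wise forward-model residual then
#' attenuates the data weight (see \code{\link{discrepancy_weight}}), and
#' stage two minimizes the weighted squared-L2 functional initialized at
#' the stage-one state (susceptibility and split variables carried over,
#' Lagrange multipliers reset — stale duals are not meaningful across the
#' change of functional), yielding the final map chi2. With
#' \code{i1 = 0} the method degenerates to the single-stage L2 solver
#' (chi1 = 0, W = w); with \code{i2 = 0} to the single-stage L1 solver
#' (chi2 = chi1).
#'
#' @param phi local field map, 3-D array (same unit as the kernel output;
#'   ppm for the default kernel).
#' @param weight data-consistency weight w: a binary ROI mask or a
#'   magnitude-based weight (\code{\link{magnitude_weight}}).
#' @param kernel a \code{\link{dipole_kernel}}.
#' @param config an \code{\link{hdqsm_config}}.
#' @param mask binary ROI mask (default: \code{weight != 0}); used for the
#'   discrepancy-weight normalization and metric traces.
#' @param truth optional ground-truth susceptibility; enables the
#'   per-iteration NRMSE trace.
#' @param engine \code{"cpp"} (default) or \code{"R"}.
#' @return An object of class \code{"hdqsm"} with elements \code{chi1},
#'   \code{chi2}, \code{W}, \code{trace} (per-iteration NRMSE, length
#'   i1 + i2, when \code{truth} is given), \code{config}, \code{kernel},
#'   \code{phi}, \code{weight}, \code{mask}.
#' @examples
#' sim <- simulate_cosmos_experiment(phantom_spec(shape = c(24, 24, 24),
#'                                                snr = 100, seed = 7))
#' cfg <- heuristic_params(1e-3, 10, i_total = 30, i1 = 10)
#' fit <- hdqsm(sim$field_noisy, sim$mask, sim$kernel, cfg,
#'              mask = sim$mask, truth = sim$chi)
#' fit
#' @export
hdqsm <- function(phi, weight, kernel, config, mask = NULL, truth = NULL,
                  engine = c("cpp", "R")) {
  stopifnot(inherits(kernel, "dipole_kernel"), inherits(config, "hdqsm_config"))
  engine <- match.arg(engine)
  grid <- kernel$grid
  check_volume(phi, grid, "phi")
  check_volume(weight, grid, "weight")
  if (is.null(mask)) mask <- (weight != 0) * 1
  check_volume(mask, grid, "mask")
  if (!any(mask != 0)) stop("mask is empty", call. = FALSE)

  shape <- grid$shape
  trace1 <- numeric(0)
  if (config$i1 > 0L) {
    p1 <- solver_params(config$lambda_l1, config$mu1_l1, config$mu2_l1,
                        config$i1, "l1", config$isotropic)
    st1 <- qsm_stage(phi, weight, kernel, p1, init = NULL, engine = engine,
                     truth = truth, mask = mask)
    chi1 <- st1$chi
    if (!is.null(truth)) trace1 <- attr(st1, "nrmse")
    W <- discrepancy_weight(weight, phi, chi1, kernel, mask)
    # warm start: carry chi and TV splits, reset multipliers and data split
    init2 <- admm_state(shape)
    init2$chi <- st1$chi
    init2$z_grad <- st1$z_grad
    init2$z_data <- st1$z_data
  } else {
    chi1 <- array(0, shape)
    W <- weight
    init2 <- NULL
  }

  trace2 <- numeric(0)
  if (config$i2 > 0L) {
    p2 <- solver_params(config$lambda_l2, config$mu1_l2, config$mu2_l2,
                        config$i2, "l2", config$isotropic)
    st2 <- qsm_stage(phi, W, kernel, p2, init = init2, engine = engine,
                     truth = truth, mask = mask)
    chi2 <- st2$chi
    if (!is.null(truth)) trace2 <- attr(st2, "nrmse")
  } else {
    chi2 <- chi1
  }

  structure(list(chi1 = chi1, chi2 = chi2, W = W,
                 trace = if (is.null(truth)) NULL else c(trace1, trace2),
                 config = config, kernel = kernel, phi = phi,
                 weight = weight, mask = mask, engine = engine),
            class = "hdqsm")
}

#' Single-stage baseline solvers
#'
#' The pure L1-norm and pure L2-norm TV-regularized inversions that the
#' hybrid method is built from, run from a zero start with weight w.
#'
#' @inheritParams hdqsm
#' @param lambda TV regularization weight.
#' @param mu_ratio mu1 / lambda (default 10).
#' @param n_iter iteration count.
#' @param norm \code{"l1"} or \code{"l2"}.
#' @return 3-D susceptibility array; attribute \code{"nrmse"} carries the
#'   per-iteration trace when \code{truth} is given.
#' @export
qsm_single_stage <- function(phi, weight, kernel, lambda, n_iter,
                             norm = c("l1", "l2"), mu_ratio = 10,
                             mask = NULL, truth = NULL,
                             engine = c("cpp", "R")) {
  norm <- match.arg(norm)
  engine <- match.arg(engine)
  params <- solver_params(lambda, mu_ratio * lambda, 1, n_iter, norm)
  st <- qsm_stage(phi, weight, kernel, params, init = NULL, engine = engine,
                  truth = truth, mask = mask)
  out <- st$chi
  attr(out, "nrmse") <- attr(st, "nrmse")
  out
}

#' Regularization-weight sensitivity sweep
#'
#' Evaluates reconstruction NRMSE on a geometric grid of regularization
#' weights lambda_i = center * 10^(i / (n per decade)) spanning
#' [center / 10^half_decades, center * 10^half_decades], the default
#' matching one decade each way. Requires ground truth (simulation
#' studies only).
#'
#' @param phi local field map.
#' @param weight data-consistency weight.
#' @param kernel a \code{\link{dipole_kernel}}.
#' @param mask binary ROI mask.
#' @param truth ground-truth susceptibility map.
#' @param center sweep center lambda*, > 0.
#' @param method \code{"hdqsm"}, \code{"l1"} or \code{"l2"}.
#' @param n_points number of grid points (default 13), including both
#'   endpoints center/10^h and center*10^h exactly.
#' @param half_decades half-width of the grid in decades (default 1).
#' @param i1,i_total iteration split for the hybrid method (single-stage
#'   methods run i_total iterations).
#' @param mu_ratio mu1 / lambda (default 10).
#' @param engine \code{"cpp"} or \code{"R"}.
#' @return data.frame with columns \code{lambda}, \code{nrmse} and, for
#'   the hybrid method, \code{stage1_nrmse}; attribute \code{"opt"} holds
#'   the argmin row.
#' @export
lambda_sweep <- function(phi, weight, kernel, mask, truth, center,
                         method = c("hdqsm", "l1", "l2"), n_points = 13,
                         half_decades = 1, i1 = 20, i_total = 100,
                         mu_ratio = 10, engine = c("cpp", "R")) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  if (center <= 0) stop("'center' must be positive", call. = FALSE)
  lambdas <- center * 10^seq(-half_decades, half_decades, length.out = n_points)
  res <- lapply(lambdas, function(lam) {
    if (method == "hdqsm") {
      cfg <- heuristic_params(lam, mu_ratio, i_total, i1)
      fit <- hdqsm(phi, weight, kernel, cfg, mask = mask, truth = truth,
                   engine = engine)
      c(nrmse = nrmse(fit$chi2, truth, mask),
        stage1_nrmse = nrmse(fit$chi1, truth, mask))
    } else {
      chi <- qsm_single_stage(phi, weight, kernel, lam, i_total, method,
                              mu_ratio, mask = mask, engine = engine)
      c(nrmse = nrmse(chi, truth, mask), stage1_nrmse = NA_real_)
    }
  })
  out <- data.frame(lambda = lambdas,
                    nrmse = vapply(res, `[[`, numeric(1), "nrmse"),
                    stage1_nrmse = vapply(res, `[[`, numeric(1), "stage1_nrmse"))
  if (method != "hdqsm") out$stage1_nrmse <- NULL
  attr(out, "opt") <- out[which.min(out$nrmse), , drop = FALSE]
  out
}

# ---- S3 methods for the fitted object ----

#' @export
print.hdqsm <- function(x, ...) {
  cat("Hybrid data-fidelity QSM reconstruction\n")
  cat("  grid: ", paste(x$kernel$grid$shape, collapse = " x "),
      " voxels; mask: ", sum(x$mask != 0), " voxels\n", sep = "")
  cat(sprintf("  stage 1 (L1): %d iterations; stage 2 (L2): %d iterations\n",
              x$config$i1, x$config$i2))
  cat(sprintf("  lambda = %g, mu1/lambda = %g\n", x$config$lambda_l2,
              x$config$mu1_l2 / x$config$lambda_l2))
  if (!is.null(x$trace))
    cat(sprintf("  final NRMSE: %.2f%%\n", x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
summary.hdqsm <- function(object, ...) {
  inmask <- object$mask != 0
  out <- list(config = object$config,
              n_voxels = sum(inmask),
              chi_range = range(object$chi2[inmask]),
              chi_sd = sd(object$chi2[inmask]),
              residual_rms = sqrt(mean(residuals(object)[inmask]^2)),
              trace = object$trace)
  class(out) <- "summary.hdqsm"
  out
}

#' @export
print.summary.hdqsm <- function(x, ...) {
  print(x$config)
  cat(sprintf("ROI: %d voxels; chi in [%.3f, %.3f] ppm (sd %.4f)\n",
              x$n_voxels, x$chi_range[1], x$chi_range[2], x$chi_sd))
  cat(sprintf("RMS field residual in ROI: %.3g\n", x$residual_rms))
  if (!is.null(x$trace))
    cat(sprintf("NRMSE: start %.2f%%, final %.2f%%\n",
                x$trace[1], x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
coef.hdqsm <- function(object, stage = 2L, ...) {
  if (stage == 1L) object$chi1 else object$chi2
}

#' @export
fitted.hdqsm <- function(object, ...) {
  forward_field(object$chi2, object$kernel)
}

#' @export
residuals.hdqsm <- function(object, ...) {
  object$phi - fitted(object)
}

#' Plot the NRMSE convergence trace
#'
#' Per-iteration NRMSE of a fit run with ground truth, with the stage
#' transition marked.
#'
#' @param x an \code{"hdqsm"} fit with a trace.
#' @param ... passed to \code{plot}.
#' @export
plot.hdqsm <- function(x, ...) {
  if (is.null(x$trace))
    stop("fit has no trace; rerun with ground truth", call. = FALSE)
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 xlab = "iteration", ylab = "NRMSE (%)", ...)
  if (x$config$i1 > 0 && x$config$i2 > 0)
    graphics::abline(v = x$config$i1 + 0.5, lty = 2, col = "grey40")
  invisible(x)
}
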