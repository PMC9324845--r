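#' Normalized root-mean-square error
#'
#' 100 * ||(estimate - truth) * mask||_2 / ||truth * mask||_2, in percent.
#'
#' @param estimate 3-D array.
#' @param truth 3-D array, same shape.
#' @param mask optional binary array restricting the norm (default: all).
#' @return scalar NRMSE in percent.
#' @export
nrmse <- function(estimate, truth, mask = NULL) {
  stopifnot(identical(dim(estimate), dim(truth)))
  if (is.null(mask)) mask <- array(1, dim(truth))
  m <- mask != 0
  tn <- sqrt(sum(truth[m]^2))
  if (tn == 0) stop("truth is identically zero inside the mask; NRMSE undefined",
                    call. = FALSE)
  100 * sqrt(sum((estimate[m] - truth[m])^2)) / tn
}

#' NRMSE restricted to a set of region masks
#'
#' One NRMSE per caller-supplied mask (e.g. tissue, deep gray matter,
#' vessels). This is plain masked NRMSE; no detrending is applied.
#'
#' @param estimate,truth 3-D arrays.
#' @param masks named list of binary arrays.
#' @return data.frame with columns \code{region}, \code{n_voxels},
#'   \code{nrmse}.
#' @export
masked_nrmse_suite <- function(estimate, truth, masks) {
  stopifnot(is.list(masks), length(masks) > 0)
  nm <- names(masks)
  if (is.null(nm)) nm <- paste0("region", seq_along(masks))
  data.frame(region = nm,
             n_voxels = vapply(masks, function(m) sum(m != 0), numeric(1)),
             nrmse = vapply(masks, function(m) nrmse(estimate, truth, m),
                            numeric(1)),
             row.names = NULL)
}

# Laplacian-of-Gaussian kernel, zero-sum, in a cube of odd side `size`
log_kernel <- function(size = 15, sigma = 1.5) {
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-outer(outer(r^2, r^2, `+`), r^2, `+`) / (2 * sigma^2))
  h <- g * (outer(outer(r^2, r^2, `+`), r^2, `+`) - 3 * sigma^2) / sigma^4
  h - mean(h)  # zero-sum: constant offsets map to zero
}

# circular convolution of a volume with a small centered kernel, via FFT
conv_circular <- function(x, kern) {
  shape <- dim(x)
  kd <- dim(kern)
  if (any(kd > shape))
    stop("volume smaller than the filter kernel", call. = FALSE)
  big <- array(0, shape)
  big[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kern
  # center the kernel on the origin bin
  for (a in 1:3) big <- axshift(big, a, (kd[a] - 1) / 2)
  Re(fft(fft(big) * fft(x), inverse = TRUE)) / length(x)
}

#' High-frequency error norm
#'
#' NRMSE between Laplacian-of-Gaussian-filtered estimate and truth
#' (default kernel 15^3 voxels, sigma 1.5 voxels), masked after
#' filtering. Emphasizes errors in fine structure; invariant to constant
#' offsets because the filter is zero-sum.
#'
#' @inheritParams nrmse
#' @param size filter cube side in voxels (odd, default 15).
#' @param sigma Gaussian width in voxels (default 1.5).
#' @return scalar HFEN in percent.
#' @export
hfen <- function(estimate, truth, mask = NULL, size = 15, sigma = 1.5) {
  stopifnot(identical(dim(estimate), dim(truth)))
  kern <- log_kernel(size, sigma)
  nrmse(conv_circular(estimate, kern), conv_circular(truth, kern), mask)
}

# Gaussian smoothing kernel used by xsim, normalized to unit sum
gauss_kernel <- function(sigma = 1.5) {
  size <- 2 * ceiling(3 * sigma) + 1
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-outer(outer(r^2, r^2, `+`), r^2, `+`) / (2 * sigma^2))
  g / sum(g)
}

#' Susceptibility-tuned structural similarity
#'
#' Mean SSIM index over the mask, computed with constants adapted to
#' signed ppm-valued maps: dynamic range L = 1 ppm, K1 = 0.01,
#' K2 = 0.001, Gaussian window of width sigma = 1.5 voxels. Values lie in
#' [-1, 1]; 1 means the volumes agree within every window.
#'
#' @inheritParams nrmse
#' @param L dynamic range in ppm (default 1).
#' @param K1,K2 stability constants (defaults 0.01 and 0.001).
#' @param sigma Gaussian window width in voxels (default 1.5).
#' @return scalar similarity index.
#' @export
xsim <- function(estimate, truth, mask = NULL, L = 1, K1 = 0.01, K2 = 0.001,
                 sigma = 1.5) {
  stopifnot(identical(dim(estimate), dim(truth)))
  if (is.null(mask)) mask <- array(1, dim(truth))
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  g <- gauss_kernel(sigma)
  mu_x <- conv_circular(estimate, g)
  mu_y <- conv_circular(truth, g)
  var_x <- conv_circular(estimate^2, g) - mu_x^2
  var_y <- conv_circular(truth^2, g) - mu_y^2
  cov_xy <- conv_circular(estimate * truth, g) - mu_x * mu_y
  ssim <- ((2 * mu_x * mu_y + C1) * (2 * cov_xy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2))
  mean(ssim[mask != 0])
}

#' Per-region statistics
#'
#' Mean, standard deviation and voxel count of a volume within each
#' nonzero label, plus the local RMSE against a ground truth when one is
#' given. Units follow the input volume (ppm for susceptibility maps).
#'
#' @param volume 3-D array.
#' @param labels integer label array (0 = unlabeled).
#' @param truth optional ground-truth array for the local RMSE column.
#' @param label_names optional names, one per distinct nonzero label.
#' @return data.frame with one row per label: \code{label}, \code{region},
#'   \code{n_voxels}, \code{mean}, \code{sd}, and \code{rmse} when truth
#'   is supplied.
#' @export
region_stats <- function(volume, labels, truth = NULL, label_names = NULL) {
  stopifnot(identical(dim(volume), dim(labels)))
  ids <- sort(unique(labels[labels != 0]))
  out <- data.frame(
    label = ids,
    region = if (is.null(label_names)) as.character(ids) else label_names[ids],
    n_voxels = vapply(ids, function(l) sum(labels == l), numeric(1)),
    mean = vapply(ids, function(l) mean(volume[labels == l]), numeric(1)),
    sd = vapply(ids, function(l) stats::sd(volume[labels == l]), numeric(1)),
    row.names = NULL)
  out$sd[out$n_voxels == 1] <- 0
  if (!is.null(truth))
    out$rmse <- vapply(ids, function(l)
      sqrt(mean((volume[labels == l] - truth[labels == l])^2)), numeric(1))
  out
}
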