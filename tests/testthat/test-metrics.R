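test_that("nrmse satisfies its algebraic identities", {
  truth <- rand_vol(c(8, 8, 8), 1, sd = 0.2)
  mask <- array(1, dim(truth))
  expect_equal(nrmse(truth, truth, mask), 0)
  expect_equal(nrmse(array(0, dim(truth)), truth, mask), 100)
  expect_equal(nrmse(1.1 * truth, truth, mask), 10, tolerance = 1e-10)
  # reporting-scale consistency under joint rescaling
  est <- truth + rand_vol(dim(truth), 2, sd = 0.05)
  expect_equal(nrmse(-3.7 * est, -3.7 * truth, mask), nrmse(est, truth, mask),
               tolerance = 1e-10)
  expect_error(nrmse(est, array(0, dim(truth)), mask), "undefined")
})

test_that("masked nrmse suite reduces to per-mask nrmse", {
  truth <- rand_vol(c(6, 6, 6), 3, sd = 0.2)
  est <- truth + rand_vol(dim(truth), 4, sd = 0.1)
  full <- array(1, dim(truth))
  tab <- masked_nrmse_suite(est, truth, list(a = full, b = full))
  expect_equal(tab$nrmse, rep(nrmse(est, truth, full), 2))
  # disjoint masks each reproduce the restricted metric; toy hand check
  m1 <- array(0, dim(truth)); m1[1:3, , ] <- 1
  m2 <- 1 - m1
  tab2 <- masked_nrmse_suite(est, truth, list(left = m1, right = m2))
  expect_equal(tab2$nrmse[1], nrmse(est, truth, m1))
  expect_equal(tab2$nrmse[2], nrmse(est, truth, m2))
  # 3-voxel hand-computed case
  t3 <- array(0, c(3, 2, 2)); t3[1:3, 1, 1] <- c(1, 2, 2)
  e3 <- t3; e3[1:3, 1, 1] <- c(1.1, 1.9, 2)
  m3 <- array(0, c(3, 2, 2)); m3[1:3, 1, 1] <- 1
  expect_equal(masked_nrmse_suite(e3, t3, list(toy = m3))$nrmse,
               100 * sqrt(0.01 + 0.01) / sqrt(9))
})

test_that("hfen is zero at equality and blind to constant offsets", {
  sim <- small_sim(snr = Inf, shape = c(24, 24, 24))
  expect_equal(hfen(sim$chi, sim$chi, sim$mask), 0)
  est <- sim$chi + rand_vol(dim(sim$chi), 5, sd = 0.02)
  h0 <- hfen(est, sim$chi, sim$mask)
  expect_gt(h0, 0)
  expect_equal(hfen(est + 0.25, sim$chi, sim$mask), h0, tolerance = 1e-8)
})

test_that("hfen filtering matches a direct shift-and-accumulate convolution", {
  kern <- hdqsm:::log_kernel(7, 1.5)
  # impulse responses: FFT path vs explicit shift-and-accumulate oracle
  x <- array(0, c(16, 16, 16))
  x[8, 8, 8] <- 1
  x[3, 12, 6] <- -0.5
  expect_equal(hdqsm:::conv_circular(x, kern), conv_direct(x, kern),
               tolerance = 1e-10)
  # full hfen value against the oracle pipeline on a toy truth/estimate
  truth <- rand_vol(c(16, 16, 16), 44, sd = 0.1)
  est <- truth + x * 0.2
  mask <- array(1, dim(x))
  oracle <- nrmse(conv_direct(est, kern), conv_direct(truth, kern), mask)
  expect_equal(hfen(est, truth, mask, size = 7, sigma = 1.5), oracle,
               tolerance = 1e-8)
})

test_that("xsim is 1 at equality and negative under anticorrelation", {
  sim <- small_sim(snr = Inf, shape = c(24, 24, 24))
  expect_equal(xsim(sim$chi, sim$chi, sim$mask), 1)
  # locally zero-mean volume (Nyquist checkerboard) against its negation:
  # luminance term ~ 1, structure term ~ -1
  v <- 0.3 * array((-1)^(slice.index(array(0, c(16, 16, 16)), 1)),
                   c(16, 16, 16))
  expect_lt(xsim(-v, v), 0)
})

test_that("xsim agrees with the windowed SSIM formula at a single voxel", {
  set.seed(31)
  x <- rand_vol(c(12, 12, 12), 31, sd = 0.2)
  y <- x + rand_vol(c(12, 12, 12), 32, sd = 0.05)
  mask <- array(0, dim(x)); mask[6, 6, 6] <- 1
  got <- xsim(x, y, mask)
  # direct evaluation of the SSIM formula with the same Gaussian window
  g <- hdqsm:::gauss_kernel(1.5)
  half <- (dim(g) - 1) / 2
  sub <- function(v) v[6 + (-half[1]:half[1]), 6 + (-half[2]:half[2]),
                       6 + (-half[3]:half[3])]
  wx <- sub(x); wy <- sub(y)
  mx <- sum(g * wx); my <- sum(g * wy)
  vx <- sum(g * wx^2) - mx^2; vy <- sum(g * wy^2) - my^2
  cxy <- sum(g * wx * wy) - mx * my
  C1 <- (0.01 * 1)^2; C2 <- (0.001 * 1)^2
  want <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("region statistics partition the label support", {
  sim <- small_sim(snr = Inf, shape = c(24, 24, 24))
  st <- region_stats(sim$chi, sim$labels, truth = sim$chi,
                     label_names = sim$label_names)
  expect_equal(sum(st$n_voxels), sum(sim$labels != 0))
  expect_equal(st$mean, sim$label_values[st$label])
  expect_equal(st$rmse, rep(0, nrow(st)))
  # 5-voxel toy, hand-checked
  vol <- array(0, c(5, 2, 2))
  vol[1:5, 1, 1] <- c(1, 2, 3, 4, 10)
  lab <- array(0L, c(5, 2, 2))
  lab[1:5, 1, 1] <- c(1L, 1L, 1L, 1L, 1L)
  tr <- array(0, c(5, 2, 2))
  tr[1:5, 1, 1] <- c(1, 2, 3, 4, 5)
  st2 <- region_stats(vol, lab, truth = tr)
  expect_equal(st2$n_voxels, 5)
  expect_equal(st2$mean, 4)
  expect_equal(st2$sd, sd(c(1, 2, 3, 4, 10)))
  expect_equal(st2$rmse, sqrt(mean(c(0, 0, 0, 0, 25))))
})
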