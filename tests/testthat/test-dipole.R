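test_that("dipole kernel takes the analytic values on axis, plane and cone", {
  g <- qsm_grid(c(16, 16, 16), c(1, 1, 1))
  k <- dipole_kernel(g)
  v <- k$values
  # bins on the B0 (z) axis: kz != 0, kx = ky = 0 -> 1/3 - 1 = -2/3
  expect_equal(v[1, 1, 5], -2 / 3)
  expect_equal(v[1, 1, 9], -2 / 3)
  # bins in the plane orthogonal to B0: kz = 0 -> 1/3
  expect_equal(v[4, 7, 1], 1 / 3)
  expect_equal(v[9, 1, 1], 1 / 3)
  # zero-frequency bin is forced to zero
  expect_identical(v[1, 1, 1], 0)
  # magic cone: kz^2/|k|^2 = 1/3. With isotropic voxels pick k = (1,1,1)*c:
  # kz^2/k^2 = 1/3 exactly
  expect_equal(v[2, 2, 2], 0)
  # global bounds for several geometries and B0 directions
  for (b0 in list(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1) / sqrt(3))) {
    ka <- dipole_kernel(qsm_grid(c(8, 12, 10), c(0.8, 1, 2), b0))
    expect_true(all(ka$values >= -2 / 3 - 1e-12))
    expect_true(all(ka$values <= 1 / 3 + 1e-12))
  }
})

test_that("kernel values are even under frequency negation", {
  k <- dipole_kernel(qsm_grid(c(8, 6, 10), c(1, 1.5, 0.7), c(0, 1, 0)))
  v <- k$values
  shape <- dim(v)
  neg <- function(i, n) ((n - (i - 1)) %% n) + 1
  for (probe in list(c(2, 3, 4), c(5, 2, 9), c(8, 6, 10))) {
    expect_equal(v[probe[1], probe[2], probe[3]],
                 v[neg(probe[1], shape[1]), neg(probe[2], shape[2]),
                   neg(probe[3], shape[3])])
  }
})

test_that("kernel constructor validates its inputs", {
  expect_error(qsm_grid(c(8, 8, 8), b0_direction = c(0, 0, 2)), "unit")
  expect_error(dipole_kernel(qsm_grid(c(8, 8, 8)), unit = "radians"),
               "acquisition")
  acq <- qsm_acq(3, c(10, 20) * 1e-3)
  kr <- dipole_kernel(qsm_grid(c(8, 8, 8)), acq, unit = "radians")
  expect_equal(kr$scale, 267.522e6 * 3 * 0.010 * 1e-6)
})

test_that("forward field annihilates constants and is linear", {
  g <- qsm_grid(c(8, 8, 8))
  k <- dipole_kernel(g)
  const <- array(0.37, g$shape)
  expect_lt(max(abs(forward_field(const, k))), 1e-12)
  x1 <- rand_vol(g$shape, 1)
  x2 <- rand_vol(g$shape, 2)
  lhs <- forward_field(2.5 * x1 - 1.3 * x2, k)
  rhs <- 2.5 * forward_field(x1, k) - 1.3 * forward_field(x2, k)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # mean-free output: the zero-frequency bin of D is zero
  expect_lt(abs(mean(forward_field(x1, k))), 1e-10)
})

test_that("forward and adjoint match the dense DFT oracle on 8^3", {
  g <- qsm_grid(c(8, 8, 8), c(1.2, 0.9, 1))
  k <- dipole_kernel(g)
  A <- dense_forward_matrix(k)
  # unit impulse at the grid center
  imp <- array(0, g$shape)
  imp[5, 5, 5] <- 1
  expect_equal(forward_field(imp, k),
               array(Re(A %*% as.vector(imp)), g$shape), tolerance = 1e-10)
  x <- rand_vol(g$shape, 3)
  expect_equal(forward_field(x, k), array(Re(A %*% as.vector(x)), g$shape),
               tolerance = 1e-10)
  # adjoint of an impulse against the conjugate-transposed dense operator
  expect_equal(adjoint_field(imp, k),
               array(Re(Conj(t(A)) %*% as.vector(imp)), g$shape),
               tolerance = 1e-10)
  # applying the operator twice equals convolution with D^2
  twice <- forward_field(forward_field(x, k), k)
  expect_equal(twice, array(Re(A %*% (A %*% as.vector(x))), g$shape),
               tolerance = 1e-9)
})

test_that("adjoint identity <Ax, y> = <x, A'y> holds to 1e-10", {
  g <- qsm_grid(c(8, 8, 8), c(1, 1, 2), c(1, 2, 2) / 3)
  k <- dipole_kernel(g)
  for (s in 1:3) {
    x <- rand_vol(g$shape, s)
    y <- rand_vol(g$shape, s + 10)
    lhs <- sum(forward_field(x, k) * y)
    rhs <- sum(x * adjoint_field(y, k))
    expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-300), 1e-10)
  }
  expect_identical(adjoint_field(array(0, g$shape), k), array(0, g$shape))
})

test_that("multi-echo signal has exponential decay and linear phase", {
  g <- qsm_grid(c(8, 8, 8))
  acq <- qsm_acq(3, c(5, 10, 20) * 1e-3)
  chi <- rand_vol(g$shape, 4, sd = 0.05)
  sig0 <- simulate_multiecho_signal(chi, g, acq, m0 = 2, r2star = 0)
  # R2* = 0: all echoes share the magnitude
  for (s in sig0) expect_equal(Mod(s), array(2, g$shape))
  sig <- simulate_multiecho_signal(chi, g, acq, m0 = 1, r2star = 30)
  # |signal| never increases with TE
  for (i in 2:3) expect_true(all(Mod(sig[[i]]) <= Mod(sig[[i - 1]]) + 1e-12))
  # phase evolves linearly in TE; restrict to voxels that never wrap
  f <- forward_field(chi, dipole_kernel(g))
  nowrap <- abs(f * ppm_to_rad(acq, acq$te[3])) < 3 & abs(f) > 1e-6
  ph1 <- Arg(sig[[1]])
  ph3 <- Arg(sig[[3]])
  expect_equal(ph3[nowrap] / ph1[nowrap],
               rep(acq$te[3] / acq$te[1], sum(nowrap)), tolerance = 1e-6)
  expect_error(simulate_multiecho_signal(chi, g, acq, r2star = -1), "r2star")
})
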