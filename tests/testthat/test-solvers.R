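test_that("periodic gradient matches explicit index arithmetic", {
  x <- rand_vol(c(6, 6, 6), 21)
  g <- grad_forward(x)
  # independent oracle: explicit loops with wrapped indices
  expected <- list(array(0, dim(x)), array(0, dim(x)), array(0, dim(x)))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expected[[1]][i, j, k] <- x[i %% 6 + 1, j, k] - x[i, j, k]
    expected[[2]][i, j, k] <- x[i, j %% 6 + 1, k] - x[i, j, k]
    expected[[3]][i, j, k] <- x[i, j, k %% 6 + 1] - x[i, j, k]
  }
  for (a in 1:3) expect_equal(g[[a]], expected[[a]], tolerance = 1e-12)
  # periodic telescoping: every component sums to zero
  for (a in 1:3) expect_lt(abs(sum(g[[a]])), 1e-10)
  # constants are annihilated
  gc <- grad_forward(array(3.2, c(6, 6, 6)))
  for (a in 1:3) expect_identical(max(abs(gc[[a]])), 0)
})

test_that("gradient adjoint is the negative backward divergence", {
  v <- lapply(1:3, function(a) rand_vol(c(6, 6, 6), 30 + a))
  adj <- grad_adjoint(v)
  # oracle: v[i - e_a] - v[i] accumulated over axes, explicit loops
  expected <- array(0, c(6, 6, 6))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expected[i, j, k] <-
      (v[[1]][(i - 2) %% 6 + 1, j, k] - v[[1]][i, j, k]) +
      (v[[2]][i, (j - 2) %% 6 + 1, k] - v[[2]][i, j, k]) +
      (v[[3]][i, j, (k - 2) %% 6 + 1] - v[[3]][i, j, k])
  }
  expect_equal(adj, expected, tolerance = 1e-12)
  # adjoint identity
  x <- rand_vol(c(6, 6, 6), 40)
  g <- grad_forward(x)
  lhs <- sum(mapply(function(a, b) sum(a * b), g, v))
  rhs <- sum(x * adj)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  zero <- list(array(0, c(6, 6, 6)), array(0, c(6, 6, 6)), array(0, c(6, 6, 6)))
  expect_identical(grad_adjoint(zero), array(0, c(6, 6, 6)))
})

test_that("soft threshold solves the scalar proximal problem", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_error(soft_threshold(1, -0.1), "nonnegative")
  # grid-search oracle: argmin_z  mu/2 (z - x)^2 + t |z|
  for (case in list(c(x = 1.7, t = 0.6, mu = 1), c(x = -0.9, t = 0.3, mu = 1),
                    c(x = 0.2, t = 0.5, mu = 1))) {
    zs <- seq(-3, 3, length.out = 1e5)
    obj <- case["mu"] / 2 * (zs - case["x"])^2 + case["t"] * abs(zs)
    expect_lt(abs(soft_threshold(case["x"], case["t"] / case["mu"]) -
                    zs[which.min(obj)]), 1e-4)
  }
})

test_that("L1 and L2 data updates match scalar grid-search oracles", {
  shape <- c(2, 2, 2)
  k <- dipole_kernel(qsm_grid(shape))
  st <- admm_state(shape)
  st$chi <- rand_vol(shape, 50, sd = 0.3)
  st$s_data <- rand_vol(shape, 51, sd = 0.2)
  phi <- rand_vol(shape, 52, sd = 0.5)
  w <- abs(rand_vol(shape, 53))
  dchi <- forward_field(st$chi, k)

  p1 <- solver_params(1e-3, 1e-2, mu2 = 0.8, n_iter = 1, norm = "l1")
  z1 <- l1_data_update(st, phi, w, p1, k)
  # per voxel: argmin_z  w |z - phi| + mu2/2 (z - (Dchi + s))^2
  for (i in seq_len(8)) {
    v <- dchi[i] + st$s_data[i]
    zs <- seq(min(phi[i], v) - 1, max(phi[i], v) + 1, length.out = 2e5)
    obj <- w[i] * abs(zs - phi[i]) + p1$mu2 / 2 * (zs - v)^2
    expect_lt(abs(z1[i] - zs[which.min(obj)]), 1e-4)
  }

  p2 <- solver_params(1e-3, 1e-2, mu2 = 0.8, n_iter = 1, norm = "l2")
  z2 <- l2_data_update(st, phi, w, p2, k)
  # per voxel: argmin_z  1/2 W^2 (z - phi)^2 + mu2/2 (z - (Dchi + s))^2
  for (i in seq_len(8)) {
    v <- dchi[i] + st$s_data[i]
    opt <- stats::optimize(function(z)
      0.5 * w[i]^2 * (z - phi[i])^2 + p2$mu2 / 2 * (z - v)^2,
      lower = min(phi[i], v) - 1, upper = max(phi[i], v) + 1, tol = 1e-10)
    expect_lt(abs(z2[i] - opt$minimum), 1e-6)
  }

  # limit behavior
  expect_equal(l1_data_update(st, phi, array(0, shape), p1, k),
               dchi + st$s_data, tolerance = 1e-12)
  big <- array(1e8, shape)
  expect_equal(l2_data_update(st, phi, big, p2, k), phi, tolerance = 1e-6)
})

test_that("chi update equals a dense normal-equations solve on 4^3", {
  shape <- c(4, 4, 4)
  k <- dipole_kernel(qsm_grid(shape, c(1, 1.3, 0.8)))
  p <- solver_params(lambda = 2e-3, mu1 = 3e-2, mu2 = 0.7, n_iter = 1,
                     norm = "l2")
  st <- admm_state(shape)
  st$z_data <- rand_vol(shape, 60)
  st$s_data <- rand_vol(shape, 61)
  for (a in 1:3) {
    st$z_grad[[a]] <- rand_vol(shape, 62 + a)
    st$s_grad[[a]] <- rand_vol(shape, 65 + a)
  }
  chi <- chi_update(st, k, p)
  # dense oracle: (mu2 A'A + mu1 sum G'G) chi = rhs, mean-zero solution via
  # deflating the constant null direction
  n <- prod(shape)
  A <- Re(dense_forward_matrix(k))
  G <- lapply(1:3, function(a) dense_grad_matrix(shape, a))
  M <- p$mu2 * t(A) %*% A +
    p$mu1 * Reduce(`+`, lapply(G, function(g) t(g) %*% g))
  rhs <- p$mu2 * t(A) %*% as.vector(st$z_data - st$s_data) +
    p$mu1 * Reduce(`+`, lapply(1:3, function(a)
      t(G[[a]]) %*% as.vector(st$z_grad[[a]] - st$s_grad[[a]])))
  sol <- solve(M + matrix(1 / n, n, n), rhs)
  expect_lt(max(abs(as.vector(chi) - sol)) / max(abs(sol)), 1e-8)
  # all-zero splits give chi = 0; result is real by construction
  expect_identical(chi_update(admm_state(shape), k, p), array(0, shape))
})

test_that("multiplier update is stationary at a fixed point and traceable", {
  shape <- c(2, 2, 2)
  k <- dipole_kernel(qsm_grid(shape))
  st <- admm_state(shape)
  st$chi <- rand_vol(shape, 70, sd = 0.2)
  st$z_grad <- grad_forward(st$chi)
  st$z_data <- forward_field(st$chi, k)
  st$s_grad <- lapply(1:3, function(a) rand_vol(shape, 70 + a))
  st$s_data <- rand_vol(shape, 74)
  upd <- multiplier_update(st, k)
  for (a in 1:3) expect_equal(upd$s_grad[[a]], st$s_grad[[a]], tolerance = 1e-12)
  expect_equal(upd$s_data, st$s_data, tolerance = 1e-12)
  # one iteration from a zero state reproduces the composed exported updates
  phi <- rand_vol(shape, 75, sd = 0.4)
  w <- abs(rand_vol(shape, 76))
  p <- solver_params(1e-2, 1e-1, 1, n_iter = 1, norm = "l1")
  ref <- admm_state(shape)
  g0 <- grad_forward(ref$chi)
  for (a in 1:3)
    ref$z_grad[[a]] <- soft_threshold(g0[[a]] + ref$s_grad[[a]],
                                      p$lambda / p$mu1)
  ref$z_data <- l1_data_update(ref, phi, w, p, k)
  ref$chi <- chi_update(ref, k, p)
  ref <- multiplier_update(ref, k)
  one <- qsm_stage(phi, w, k, p, engine = "R")
  expect_equal(one$chi, ref$chi, tolerance = 1e-12)
  expect_equal(one$s_data, ref$s_data, tolerance = 1e-12)
  expect_equal(one$z_grad, ref$z_grad, tolerance = 1e-12)
})

test_that("the two engines produce identical iterates", {
  shape <- c(10, 8, 12)
  k <- dipole_kernel(qsm_grid(shape, c(1, 1.1, 0.9)))
  phi <- rand_vol(shape, 80, sd = 0.3)
  w <- abs(rand_vol(shape, 81))
  for (norm in c("l1", "l2")) for (iso in c(FALSE, TRUE)) {
    p <- solver_params(2e-3, 2e-2, 1, n_iter = 20, norm = norm,
                       isotropic = iso)
    a <- qsm_stage(phi, w, k, p, engine = "R")
    b <- qsm_stage(phi, w, k, p, engine = "cpp")
    expect_equal(a$chi, b$chi, tolerance = 1e-11)
    expect_equal(a$s_data, b$s_data, tolerance = 1e-11)
    expect_equal(a$z_grad[[2]], b$z_grad[[2]], tolerance = 1e-11)
  }
})

test_that("run_stage honors iteration contracts and limits", {
  shape <- c(8, 8, 8)
  k <- dipole_kernel(qsm_grid(shape))
  phi <- rand_vol(shape, 90, sd = 0.2)
  w <- array(1, shape)
  # n_iter = 0 returns the initial state untouched
  init <- admm_state(shape)
  init$chi <- rand_vol(shape, 91)
  p0 <- solver_params(1e-3, 1e-2, 1, n_iter = 0, norm = "l2")
  expect_identical(qsm_stage(phi, w, k, p0, init = init)$chi, init$chi)
  # zero weight and positive lambda drive the solution TV-flat
  pflat <- solver_params(1e-2, 1e-1, 1, n_iter = 200, norm = "l1")
  flat <- qsm_stage(phi, array(0, shape), k, pflat, engine = "cpp")
  expect_lt(diff(range(flat$chi)), 1e-6)
  # huge lambda/mu1 flattens the L1 solution toward a constant
  pbig <- solver_params(1e3, 10, 1, n_iter = 300, norm = "l1")
  flat2 <- qsm_stage(phi, w, k, pbig, engine = "cpp")
  expect_lt(diff(range(flat2$chi)), 1e-3 * max(abs(phi)))
  # multipliers stay finite over 300 iterations on a noiseless phantom
  sim <- small_sim(snr = Inf, shape = c(16, 16, 16))
  pl <- solver_params(1e-2, 1e-1, 1, n_iter = 300, norm = "l2")
  stl <- qsm_stage(sim$phase_clean, sim$mask, sim$kernel_rad, pl)
  expect_true(all(is.finite(stl$s_data)))
  expect_true(all(vapply(stl$s_grad, function(s) all(is.finite(s)), logical(1))))
})

test_that("the L2 objective decreases from the initial iterate", {
  sim <- small_sim(snr = 100, shape = c(16, 16, 16))
  lam <- 1e-2
  p <- solver_params(lam, 10 * lam, 1, n_iter = 60, norm = "l2")
  st <- qsm_stage(sim$phase_noisy, sim$mask, sim$kernel_rad, p)
  obj0 <- qsm_objective(array(0, dim(sim$chi)), sim$phase_noisy, sim$mask,
                        sim$kernel_rad, lam, "l2")
  obj1 <- qsm_objective(st$chi, sim$phase_noisy, sim$mask, sim$kernel_rad,
                        lam, "l2")
  expect_lt(obj1, obj0)
  # NRMSE decreases across iterations on noiseless data with small lambda
  simc <- small_sim(snr = Inf, shape = c(16, 16, 16))
  pc <- solver_params(1e-3, 1e-2, 1, n_iter = 80, norm = "l2")
  stc <- qsm_stage(simc$phase_clean, simc$mask, simc$kernel_rad, pc,
                   truth = simc$chi, mask = simc$mask)
  tr <- attr(stc, "nrmse")
  expect_lt(tr[length(tr)], tr[1])
})
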