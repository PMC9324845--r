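# Shared fixtures and independent oracles used across the test files.

rand_vol <- function(shape, seed, sd = 1) {
  set.seed(seed)
  array(rnorm(prod(shape), sd = sd), shape)
}

# Dense DFT matrix for one axis (unitary up to 1/N on inversion, matching
# stats::fft conventions).
dft_matrix <- function(n) {
  j <- 0:(n - 1)
  exp(-2i * pi * outer(j, j) / n)
}

# Dense matrix of the forward dipole operator F^H diag(D) F acting on
# column-major vectorized volumes: kron(Fz, Fy, Fx) matches the layout
# index x + nx*(y + ny*z).
dense_forward_matrix <- function(kernel) {
  shape <- kernel$grid$shape
  F3 <- kronecker(dft_matrix(shape[3]),
                  kronecker(dft_matrix(shape[2]), dft_matrix(shape[1])))
  d <- as.vector(kernel$values * kernel$scale)
  # fft is x -> F3 x; the inverse is X -> Conj(F3) X / N
  Conj(F3) %*% (d * F3) / prod(shape)
}

# Dense matrix of the periodic forward difference along one axis.
dense_grad_matrix <- function(shape, axis) {
  n <- prod(shape)
  shift <- matrix(0, n, n)
  idx <- arrayInd(seq_len(n), shape)
  nxt <- idx
  nxt[, axis] <- (idx[, axis] %% shape[axis]) + 1L
  lin <- (nxt[, 3] - 1L) * shape[1] * shape[2] + (nxt[, 2] - 1L) * shape[1] + nxt[, 1]
  shift[cbind(seq_len(n), lin)] <- 1
  shift - diag(n)
}

# Circular convolution by explicit shift-and-accumulate (no FFT).
conv_direct <- function(x, kern) {
  shape <- dim(x)
  kd <- dim(kern)
  half <- (kd - 1) / 2
  out <- array(0, shape)
  ax <- lapply(1:3, function(a) seq_len(shape[a]))
  for (i in seq_len(kd[1])) for (j in seq_len(kd[2])) for (k in seq_len(kd[3])) {
    cf <- kern[i, j, k]
    if (cf == 0) next
    off <- c(i, j, k) - half - 1
    ix <- ((ax[[1]] - 1 - off[1]) %% shape[1]) + 1
    iy <- ((ax[[2]] - 1 - off[2]) %% shape[2]) + 1
    iz <- ((ax[[3]] - 1 - off[3]) %% shape[3]) + 1
    out <- out + cf * x[ix, iy, iz]
  }
  out
}

# Small simulated experiment reused by several files (cheap: 24^3).
small_sim <- function(snr = 100, n_jumps = 0L, seed = 5, shape = c(24, 24, 24)) {
  simulate_cosmos_experiment(phantom_spec(shape = shape, snr = snr,
                                          n_jumps = n_jumps, seed = seed))
}
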