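# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written along different code paths than the implementation
# they check.

# Small, fast phantom used where the full default grid is unnecessary.
small_phantom_spec <- function(...) {
  defaults <- list(dim = c(24, 24, 8), voxel_size = c(1, 1, 2), slice = 4L,
                   n_dirs = 32L, n_b0 = 2L)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# Forward-simulate diffusion signals for a single tensor, independently of
# the phantom generator (direct quadratic form, per volume).
simulate_signals <- function(D, table, s0 = 1000) {
  g <- cbind(table$gx, table$gy, table$gz)
  vapply(seq_len(nrow(table)), function(i) {
    s0 * exp(-table$b[i] * as.numeric(t(g[i, ]) %*% D %*% g[i, ]))
  }, numeric(1))
}

# Tensor with prescribed eigenvalues and first eigenvector azimuth
# (degrees, in the x-y plane) and elevation (degrees, towards +z).
make_tensor <- function(evals = c(2.1, 1.6, 1.4) * 1e-3, azimuth = 30, elevation = 0) {
  a <- azimuth * pi / 180
  e <- elevation * pi / 180
  e1 <- c(cos(e) * cos(a), cos(e) * sin(a), sin(e))
  e2 <- c(-sin(a), cos(a), 0)
  e3 <- c(-sin(e) * cos(a), -sin(e) * sin(a), cos(e))
  evals[1] * tcrossprod(e1) + evals[2] * tcrossprod(e2) + evals[3] * tcrossprod(e3)
}

# A one-tensor stack: every voxel carries the same signal vector.
uniform_stack <- function(D, table, dim = c(8, 8, 4), voxel_size = c(1, 1, 1),
                          s0 = 1000) {
  sig <- simulate_signals(D, table, s0)
  data <- array(rep(sig, each = prod(dim)), dim = c(dim, nrow(table)))
  dwi_stack(data, diag(c(voxel_size, 1)))
}

test_gradient_table <- function(n_dirs = 32, bval = 450, n_b0 = 2) {
  spec <- phantom_spec(n_dirs = n_dirs, bval = bval, n_b0 = n_b0)
  phantom_gradient_table(spec)
}

# Independent FA formula: regularized variance form
# FA = sqrt(3 Var(lambda) / (2/3) / sum(lambda_i^2) ... written from the
# population-variance identity rather than the deviation-norm identity.
fa_oracle <- function(lam) {
  lam <- pmax(lam, 0)
  lbar <- mean(lam)
  if (sum(lam^2) == 0) return(0)
  sqrt(3 / 2) * sqrt(sum((lam - lbar)^2) / sum(lam^2))
}

# Brute-force two-way ANOVA ICC oracle built on stats::aov (a separate
# decomposition path from the implementation's closed-form mean squares).
icc_oracle_aov <- function(m, variant = "single") {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(
    y = as.numeric(m),
    subject = factor(rep(seq_len(n), k)),
    meas = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + meas, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (variant == "single") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
}

# 3D rotation about a unit axis (Rodrigues), used for equivariance checks.
rotation_about <- function(axis, angle_rad) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * K %*% K
}

# Largest angle between consecutive step directions over a streamline set.
max_interstep_angle <- function(set) {
  worst <- 0
  for (s in set$streamlines) {
    if (nrow(s) < 3) next
    d <- diff(s)
    d <- d / sqrt(rowSums(d^2))
    ca <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
    worst <- max(worst, max(acos(pmin(1, pmax(-1, ca))) * 180 / pi))
  }
  worst
}
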