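# Shared fixtures and independent oracles, built in code at test time.

# Brute-force robust-Capon oracle: minimize a' R^{-1} a over the sphere
# ||a - a_bar||^2 = eps (the constraint is active because the unconstrained
# minimizer is a = 0), by multi-start numeric optimization over the sphere
# direction. Independent of the eigendecomposition/Lagrange path.
rcb_oracle_kernel <- function(R, a_bar, eps, n_starts = 25, seed = 99) {
  Rinv <- solve(R)
  f <- function(v) {
    a <- a_bar + sqrt(eps) * v / sqrt(sum(v^2))
    drop(a %*% Rinv %*% a)
  }
  set.seed(seed)
  best <- Inf
  for (i in seq_len(n_starts)) {
    v0 <- rnorm(length(a_bar))
    opt <- optim(v0, f, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, opt$value)
  }
  best
}

# Random symmetric positive-definite matrix.
random_spd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(0.1, n)
}

# Wrap a plain matrix as a correlation_matrix object.
as_corr <- function(M, T_H = 1) {
  structure(list(matrix = M, T_H = T_H), class = "correlation_matrix")
}

# Separable Gaussian pressure field on a small 3-D grid (metres).
gaussian_field <- function(sigmas = c(0.5e-3, 0.4e-3, 2e-3),
                           center = c(0, 0, 60e-3),
                           half = c(2e-3, 2e-3, 8e-3),
                           steps = c(5e-5, 5e-5, 2e-4)) {
  gx <- seq(center[1] - half[1], center[1] + half[1], by = steps[1])
  gy <- seq(center[2] - half[2], center[2] + half[2], by = steps[2])
  gz <- seq(center[3] - half[3], center[3] + half[3], by = steps[3])
  mag <- outer(outer(exp(-(gx - center[1])^2 / (2 * sigmas[1]^2)),
                     exp(-(gy - center[2])^2 / (2 * sigmas[2]^2))),
               exp(-(gz - center[3])^2 / (2 * sigmas[3]^2)))
  structure(list(grid = list(x = gx, y = gy, z = gz),
                 magnitude = array(mag, c(length(gx), length(gy), length(gz))),
                 frequency = 1.5e6),
            class = "pressure_field")
}

# Small binary mask from explicit pixel index sets (1-based), unit spacing.
mask_from_indices <- function(dims, idx, spacing = 1, origin = c(0, 0)) {
  px <- matrix(FALSE, dims[1], dims[2])
  if (!is.null(idx)) px[idx] <- TRUE
  binary_mask(px, spacing = spacing, origin = origin)
}

# Synthetic power_map from a matrix.
as_power_map <- function(power, azimuth, range_mm) {
  structure(list(grid = list(azimuth = azimuth, range = range_mm),
                 power = power, frames_averaged = 1L, beamformer = "rcb",
                 db_convention = "power"),
            class = "power_map")
}

test_medium <- function() medium(sound_speed = 1500, density = 1000)
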