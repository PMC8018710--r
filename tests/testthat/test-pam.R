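# Passive mapping: steering, correlation, robust Capon power (against a
# brute-force constrained-optimization oracle and closed forms), map
# formation, frame averaging, centroid and 1 dB region extraction.

test_that("steering delays follow the 3-4-5 geometry and symmetric points", {
  med <- test_medium()
  geom <- array_geometry(n_elements = 2, pitch = 3e-3)
  cd <- channel_data(matrix(rnorm(2 * 64), 2, 64), sampling_rate = 31.25e6)
  # point on the first element's axis at 4 mm range: distances 4 and 5 mm
  ss <- steer_signals(cd, c(-1.5, 4), med, geom)
  expect_equal(ss$delays[1], 0)
  expect_equal(ss$delays[2], 1e-3 / 1500, tolerance = 1e-12)
  expect_equal(ss$d_mean, mean(c(4, 5)) * 1e-3, tolerance = 1e-9)
  # equidistant point -> zero relative delays, steered equals input
  ss0 <- steer_signals(cd, c(0, 50), med, geom)
  expect_equal(ss0$delays, c(0, 0))
  expect_identical(ss0$steered, cd$samples)
})

test_that("steering preserves per-channel energy of band-limited noise", {
  med <- test_medium()
  geom <- array_geometry(n_elements = 4, pitch = 2e-3)
  set.seed(42)
  # band-limited noise away from the record edges so the shifted support
  # stays inside the window
  n <- 512
  raw <- matrix(rnorm(4 * n), 4, n)
  taper <- exp(-((seq_len(n) - n / 2)^2) / (2 * 60^2))
  cd <- channel_data(sweep(raw, 2, taper, `*`) , sampling_rate = 31.25e6)
  sm <- stats::filter(t(cd$samples), rep(1 / 8, 8), circular = TRUE)
  cd <- channel_data(t(sm), sampling_rate = 31.25e6)
  ss <- steer_signals(cd, c(1, 30), med, geom)
  e_in <- rowSums(cd$samples^2)
  e_out <- rowSums(ss$steered^2)
  expect_lt(max(abs(e_out / e_in - 1)), 0.01)
})

test_that("steering beyond the record raises a truncation error", {
  med <- test_medium()
  geom <- array_geometry(n_elements = 8, pitch = 10e-3)
  cd <- channel_data(matrix(0, 8, 4), sampling_rate = 31.25e6)
  expect_error(steer_signals(cd, c(0, 2), med, geom),
               class = "histopam_truncation")
})

test_that("correlation matrix matches hand computations", {
  st <- list(steered = rbind(c(1, 0), c(0, 2)), sampling_rate = 1)
  R <- correlation_matrix(st)
  expect_equal(R$matrix, rbind(c(1, 0), c(0, 4)))
  expect_equal(R$T_H, 2)
  # identical unit-energy signal on all channels -> rank-1, equal entries
  s <- sin(2 * pi * (0:63) / 8)
  stc <- list(steered = rbind(s, s, s), sampling_rate = 10)
  Rc <- correlation_matrix(stc)$matrix
  expect_equal(max(abs(Rc - Rc[1, 1])), 0)
  expect_equal(qr(Rc)$rank, 1)
  # all-zero record -> zero matrix
  expect_equal(correlation_matrix(list(steered = matrix(0, 3, 5),
                                       sampling_rate = 1))$matrix,
               matrix(0, 3, 3))
})

test_that("robust Capon power matches the brute-force constrained oracle", {
  med <- test_medium()
  for (seed in 1:4) {
    n <- if (seed %% 2) 4 else 6
    M <- random_spd(n, seed)
    a_bar <- rep(1, n)
    eps <- 0.5
    p <- rcb_power(as_corr(M), a_bar, rcb_params(epsilon = eps, loading = 0),
                   d_mean = 1, med = med)
    oracle <- rcb_oracle_kernel(M, a_bar, eps)
    expect_lt(abs(attr(p, "kernel") / oracle - 1), 1e-3)
  }
})

test_that("robust Capon limits: white noise and the standard Capon estimate", {
  med <- test_medium()
  n <- 8; sig2 <- 2.5
  pref <- 4 * pi / (1 * med$density * med$sound_speed)  # d_mean 1, T_H 1
  p <- rcb_power(as_corr(diag(sig2, n)), rep(1, n),
                 rcb_params(epsilon = 1e-8, loading = 0), d_mean = 1,
                 med = med)
  expect_equal(as.numeric(p), pref * sig2 / n, tolerance = 1e-3)
  # epsilon -> 0 recovers 1 / (a' R^{-1} a) for a general SPD matrix
  M <- random_spd(5, 7)
  a <- rep(1, 5)
  p2 <- rcb_power(as_corr(M), a, rcb_params(epsilon = 1e-9, loading = 0),
                  d_mean = 1, med = med)
  capon <- 1 / drop(a %*% solve(M) %*% a)
  expect_equal(attr(p2, "kernel"), 1 / capon, tolerance = 1e-4)
})

test_that("rank-1 coherent source: aligned steering recovers the energy", {
  med <- test_medium()
  n <- 6; E <- 3.7
  R <- as_corr(matrix(E, n, n))  # identical signal of energy E per channel
  p_al <- rcb_power(R, rep(1, n), rcb_params(epsilon = 0.05), d_mean = 1,
                    med = med)
  pref <- 4 * pi / (1 * med$density * med$sound_speed)
  expect_equal(as.numeric(p_al), pref * E, tolerance = 0.05)
  a_mis <- sqrt(n) * (c(1, -1, 1, -1, 1, -1) / sqrt(n))
  p_mis <- rcb_power(R, a_mis, rcb_params(epsilon = 0.05), d_mean = 1,
                     med = med)
  expect_lt(as.numeric(p_mis), 0.01 * as.numeric(p_al))
  # zero-energy matrix -> defined zero power
  p0 <- rcb_power(as_corr(matrix(0, n, n)), rep(1, n), rcb_params(),
                  d_mean = 1, med = med)
  expect_equal(as.numeric(p0), 0)
})

test_that("map values equal the composed steer/correlate/power operations", {
  med <- test_medium()
  geom <- array_geometry(n_elements = 8, pitch = 1.5e-3)
  em <- emitter_set(c(0.5, 30), onset_times = -18e-6)
  cd <- simulate_emissions(em, geom, med, duration = 8e-6, snr_db = 15,
                           seed = 11)
  grid <- list(azimuth = c(-1, 0.5, 2), range = c(28, 30, 33))
  params <- rcb_params(epsilon = 0.8)
  m <- pam_map(cd, grid, geom, med, params)
  for (i in seq_along(grid$azimuth)) {
    for (j in seq_along(grid$range)) {
      ss <- steer_signals(cd, c(grid$azimuth[i], grid$range[j]), med, geom)
      R <- correlation_matrix(ss)
      p <- rcb_power(R, rep(1, 8), params, d_mean = ss$d_mean, med = med)
      expect_equal(m$power[i, j], as.numeric(p), tolerance = 1e-6)
    }
  }
  # delay-and-sum path agrees with the composed operations as well
  md <- pam_map(cd, grid, geom, med, params, beamformer = "das")
  ss <- steer_signals(cd, c(grid$azimuth[2], grid$range[2]), med, geom)
  beam <- colMeans(ss$steered)
  pref <- 4 * pi * ss$d_mean^2 /
    (ncol(cd$samples) / cd$sampling_rate * med$density * med$sound_speed)
  expect_equal(md$power[2, 2], pref * sum(beam^2) / cd$sampling_rate,
               tolerance = 1e-6)
})

test_that("zero-signal frames map to zero and amplitude scales as power^2", {
  med <- test_medium()
  geom <- array_geometry(n_elements = 8, pitch = 1.5e-3)
  grid <- list(azimuth = seq(-2, 2, by = 1), range = c(29, 31))
  m0 <- pam_map(channel_data(matrix(0, 8, 256)), grid, geom, med)
  expect_true(all(m0$power == 0))
  em <- emitter_set(c(0, 30), onset_times = -18e-6)
  cd <- simulate_emissions(em, geom, med, duration = 8e-6, snr_db = Inf)
  cd2 <- channel_data(3 * cd$samples, cd$sampling_rate)
  m1 <- pam_map(cd, grid, geom, med)
  m2 <- pam_map(cd2, grid, geom, med)
  expect_equal(m2$power, 9 * m1$power, tolerance = 1e-9)
})

test_that("maps are invariant to a common time shift of all channels", {
  med <- test_medium()
  geom <- array_geometry(n_elements = 8, pitch = 1.5e-3)
  grid <- list(azimuth = seq(-2, 2, by = 0.5), range = c(28, 30, 32))
  cd_a <- simulate_emissions(emitter_set(c(0.5, 30), onset_times = -17e-6),
                             geom, med, duration = 10e-6, snr_db = Inf)
  cd_b <- simulate_emissions(emitter_set(c(0.5, 30), onset_times = -16e-6),
                             geom, med, duration = 10e-6, snr_db = Inf)
  m_a <- pam_map(cd_a, grid, geom, med)
  m_b <- pam_map(cd_b, grid, geom, med)
  expect_equal(m_a$power, m_b$power, tolerance = 0.01)
})

test_that("two equal emitters produce maxima at the correct azimuths", {
  med <- test_medium()
  geom <- array_geometry(n_elements = 32, pitch = 1.2e-3)
  em <- emitter_set(rbind(c(-2.5, 60), c(2.5, 60)), onset_times = -36e-6)
  cd <- simulate_emissions(em, geom, med, duration = 16e-6, snr_db = 20,
                           seed = 21)
  grid <- list(azimuth = seq(-5, 5, by = 0.5), range = c(59, 60, 61))
  m <- pam_map(cd, grid, geom, med, rcb_params(epsilon = 3.2))
  prof <- apply(m$power, 1, max)
  locmax <- which(diff(sign(diff(prof))) == -2) + 1
  peaks <- sort(grid$azimuth[locmax[order(prof[locmax],
                                          decreasing = TRUE)][1:2]])
  expect_equal(peaks, c(-2.5, 2.5), tolerance = 0.51)
  # cross-beamformer consistency on the azimuth of a strong source
  md <- pam_map(cd, grid, geom, med, rcb_params(epsilon = 3.2),
                beamformer = "das")
  expect_lt(abs(emission_centroid(md)[["azimuth"]] -
                  emission_centroid(m)[["azimuth"]]), 0.5)
})

test_that("frame averaging is the pixel-wise mean with grid checks", {
  a <- as_power_map(matrix(1:6, 2, 3), c(0, 1), c(10, 11, 12))
  b <- as_power_map(matrix(7:12, 2, 3), c(0, 1), c(10, 11, 12))
  expect_equal(frame_average(list(a))$power, a$power)
  avg <- frame_average(list(a, b))
  expect_equal(avg$power, (a$power + b$power) / 2)
  expect_equal(avg$frames_averaged, 2L)
  many <- frame_average(rep(list(a), 50))
  expect_equal(many$power, a$power)
  expect_equal(many$frames_averaged, 50L)
  c_bad <- as_power_map(matrix(0, 2, 3), c(0, 2), c(10, 11, 12))
  expect_error(frame_average(list(a, c_bad)),
               class = "histopam_grid_mismatch")
})

test_that("emission centroid follows the power-weighted mean", {
  p <- matrix(0, 3, 3)
  p[2, 3] <- 5
  m <- as_power_map(p, c(0, 2, 4), c(50, 51, 52))
  expect_equal(unname(emission_centroid(m)), c(2, 52))
  # two pixels at x = 0 and 4 with powers 1 and 3 -> weighted mean x = 3
  p2 <- matrix(0, 3, 1)
  p2[1, 1] <- 1; p2[3, 1] <- 3
  m2 <- as_power_map(p2, c(0, 2, 4), 50)
  expect_equal(unname(emission_centroid(m2))[1], 3)
  expect_error(emission_centroid(as_power_map(matrix(0, 2, 2), c(0, 1),
                                              c(1, 2))),
               class = "histopam_undefined_centroid")
})

test_that("the 1 dB region matches the closed-form Gaussian contour", {
  ax <- seq(-5, 5, by = 0.05)
  rg <- seq(55, 65, by = 0.05)
  sigma <- 1.2
  pw <- outer(exp(-ax^2 / (2 * sigma^2)), exp(-(rg - 60)^2 / (2 * sigma^2)))
  m <- as_power_map(pw, ax, rg)
  reg <- one_dB_region(m)
  r_expected <- sigma * sqrt(2 * log(10^0.1))
  area_expected <- pi * r_expected^2
  area <- sum(reg$pixels) * 0.05^2
  expect_lt(abs(area / area_expected - 1), 0.05)
  # uniform map -> entire grid; single hot pixel -> single-pixel mask
  expect_true(all(one_dB_region(as_power_map(matrix(1, 3, 3), 1:3,
                                             1:3))$pixels))
  hot <- matrix(1e-3, 3, 3); hot[2, 2] <- 1
  expect_equal(sum(one_dB_region(as_power_map(hot, 1:3, 1:3))$pixels), 1)
  # the amplitude convention sets a higher power threshold (10^(-1/20) >
  # 10^(-1/10)), shrinking the region
  reg_amp <- one_dB_region(m, convention = "amplitude")
  expect_lt(sum(reg_amp$pixels), sum(reg$pixels))
})
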