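# Passive acoustic mapping of cavitation emissions.
#
# Receive-only RF channel data are beamformed to a spatial map of relative
# acoustic power with the robust Capon beamformer: per pixel, channels are
# steered (delayed) to the pixel, the time-domain correlation matrix
# integral s_n(t) s_m(t) dt is eigendecomposed, and the data-adaptive
# steering vector that shrinks the nominal (all-ones, post-steering) vector
# against the eigenspectrum within an uncertainty ball of radius sqrt(eps)
# is solved via the Lagrange multiplier. The per-pixel power carries the
# spherical-spreading prefactor 4*pi*dbar^2 / (T_H * rho * c). A
# delay-and-sum power map is available as the conventional baseline.

#' Linear receive-array geometry
#'
#' Defaults describe an L11-5v-like 128-element linear array.
#'
#' @param n_elements Number of elements.
#' @param pitch Element spacing, m.
#' @param center_frequency Hz.
#' @return Object of class `array_geometry` with `element_positions`
#'   (n x 3, m; elements along the azimuth axis, centered at the origin).
#' @export
array_geometry <- function(n_elements = 128, pitch = 0.3e-3,
                           center_frequency = 7.8e6) {
  stopifnot(n_elements >= 2, pitch > 0, center_frequency > 0)
  x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  structure(list(element_positions = cbind(x = x, y = 0, z = 0),
                 pitch = pitch, n_elements = as.integer(n_elements),
                 center_frequency = center_frequency),
            class = "array_geometry")
}

#' RF channel-data record
#'
#' @param samples Matrix, `n_elements x n_samples`.
#' @param sampling_rate Hz; must satisfy Nyquist for the array band.
#' @param t0 Acquisition clock origin, s.
#' @param frame_id Frame index within the acquisition.
#' @return Object of class `channel_data`.
#' @export
channel_data <- function(samples, sampling_rate = 31.25e6, t0 = 0,
                         frame_id = 1L) {
  samples <- as.matrix(samples)
  if (!all(is.finite(samples)))
    stop_histopam("channel data contain non-finite samples",
                  "histopam_bad_samples")
  stopifnot(sampling_rate > 0)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 t0 = t0, frame_id = as.integer(frame_id)),
            class = "channel_data")
}

# Hann-windowed sinc fractional-delay interpolation of one channel;
# identical kernel to the C++ fast path. tau in samples (advance).
steer_one <- function(s, tau, taps = 32L) {
  n <- length(s)
  p <- seq_len(n) - 1 + tau
  half <- taps / 2
  out <- numeric(n)
  k0 <- floor(p) - taps %/% 2 + 1
  for (off in 0:(taps - 1)) {
    k <- k0 + off
    ok <- k >= 0 & k < n
    if (!any(ok)) next
    u <- (p[ok] - k[ok]) / half
    x <- p[ok] - k[ok]
    snc <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
    out[ok] <- out[ok] + s[k[ok] + 1] * snc * 0.5 * (1 + cos(pi * u))
  }
  out
}

#' Steer channel data to a focus point
#'
#' Delays each channel by `(d_n - min(d)) / c` (band-limited windowed-sinc
#' interpolation) so that a wavefront emitted at the focus point aligns
#' across channels.
#'
#' @param data A [channel_data()].
#' @param point Focus position, mm, length 2 `(azimuth, range)` or length 3
#'   `(x, y, z)`.
#' @param med A [medium()].
#' @param geom An [array_geometry()].
#' @param taps Interpolation kernel length (samples).
#' @return Object of class `steered_set`: `steered` (matrix like `samples`),
#'   `point` (mm), `distances` (m per element), `d_mean` (m), `delays` (s),
#'   `sampling_rate`.
#' @export
steer_signals <- function(data, point, med, geom, taps = 32L) {
  stopifnot(inherits(data, "channel_data"), inherits(geom, "array_geometry"))
  if (length(point) == 2L) point <- c(point[1], 0, point[2])
  pm <- point / 1e3
  dpos <- sweep(geom$element_positions, 2, pm)
  dist <- sqrt(rowSums(dpos^2))
  delays <- (dist - min(dist)) / med$sound_speed
  n_samp <- ncol(data$samples)
  if (max(delays) * data$sampling_rate > n_samp)
    stop_histopam("steering delay exceeds the record length",
                  "histopam_truncation")
  steered <- data$samples
  tau <- delays * data$sampling_rate
  for (n in seq_len(nrow(steered)))
    if (tau[n] != 0)
      steered[n, ] <- steer_one(data$samples[n, ], tau[n], taps = taps)
  structure(list(steered = steered, point = point, distances = dist,
                 d_mean = mean(dist), delays = delays,
                 sampling_rate = data$sampling_rate),
            class = "steered_set")
}

#' Time-domain correlation matrix of steered channels
#'
#' Entry (n, m) is `sum_t s_n(t) s_m(t) * dt` over the record duration.
#'
#' @param steered A [steer_signals()] result (or any object with a
#'   `steered` matrix and `sampling_rate`).
#' @return Object of class `correlation_matrix` with `matrix` (symmetric,
#'   `n_elements` square) and `T_H` (record duration, s).
#' @export
correlation_matrix <- function(steered) {
  S <- steered$steered
  stopifnot(is.matrix(S), nrow(S) >= 2, ncol(S) >= 2)
  if (!all(is.finite(S)))
    stop_histopam("non-finite samples in steered set", "histopam_bad_samples")
  dt <- 1 / steered$sampling_rate
  R <- tcrossprod(S) * dt
  structure(list(matrix = (R + t(R)) / 2, T_H = ncol(S) * dt),
            class = "correlation_matrix")
}

#' Robust Capon beamformer parameters
#'
#' @param epsilon Steering-vector uncertainty bound (`||a_hat - a_bar||^2
#'   <= epsilon`); `NULL` selects the default `0.1 * n_elements` at use.
#' @param loading Diagonal regularization added before eigendecomposition,
#'   as a fraction of `trace(R)/N`.
#' @param range_exponent Exponent of the mean pixel-element distance in the
#'   spherical-spreading prefactor (1 or 2; default 2, energy-conserving).
#' @param db_convention Decibel convention used by [one_dB_region()]:
#'   `"power"` (10 log10 of map values) or `"amplitude"` (20 log10).
#' @return Object of class `rcb_params`.
#' @export
rcb_params <- function(epsilon = NULL, loading = 1e-6, range_exponent = 2,
                       db_convention = c("power", "amplitude")) {
  stopifnot(is.null(epsilon) || (epsilon > 0), loading >= 0,
            range_exponent %in% c(1, 2))
  structure(list(epsilon = epsilon, loading = loading,
                 range_exponent = range_exponent,
                 db_convention = match.arg(db_convention)),
            class = "rcb_params")
}

#' Robust Capon acoustic power for one correlation matrix
#'
#' Eigendecomposes `R = U V U'`, solves for the Lagrange multiplier
#' `lambda > 0` such that the data-adaptive steering vector
#' `a_hat = a_bar - (I + lambda R)^{-1} a_bar` satisfies
#' `||a_hat - a_bar||^2 = epsilon` (the constraint function
#' `g(lambda) = sum z_i^2 / (1 + lambda v_i)^2`, `z = U' a_bar`, is
#' monotone decreasing), and returns
#' `4 pi dbar^q / (T_H rho c) / (a_hat' R^{-1} a_hat)` with
#' `a_hat' R^{-1} a_hat = sum lambda^2 v_i z_i^2 / (1 + lambda v_i)^2`.
#'
#' @param R A [correlation_matrix()].
#' @param a_bar Nominal steering vector with `||a_bar||^2 = n_elements`
#'   (after time steering the nominal vector is all-ones).
#' @param params An [rcb_params()].
#' @param d_mean Mean pixel-element distance, m.
#' @param med A [medium()].
#' @return Relative acoustic power (>= 0), with attributes `lambda`,
#'   `kernel` (`a_hat' R^{-1} a_hat`) and `a_hat`.
#' @export
rcb_power <- function(R, a_bar = NULL, params = rcb_params(), d_mean, med) {
  stopifnot(inherits(R, "correlation_matrix"))
  M <- R$matrix
  N <- nrow(M)
  if (is.null(a_bar)) a_bar <- rep(1, N)
  if (abs(sum(a_bar^2) - N) > 1e-6 * N)
    stop_histopam("nominal steering vector must satisfy ||a_bar||^2 = N",
                  "histopam_bad_steering")
  eps <- if (is.null(params$epsilon)) 0.1 * N else params$epsilon
  if (eps >= N)
    stop_histopam("epsilon must be smaller than n_elements",
                  "histopam_bad_params")
  tr <- sum(diag(M))
  pref <- 4 * pi * d_mean^params$range_exponent /
    (R$T_H * med$density * med$sound_speed)
  if (tr <= 0) {
    out <- 0
    attributes(out) <- list(lambda = NA_real_, kernel = Inf,
                            a_hat = rep(0, N))
    return(out)
  }
  Md <- M + diag(params$loading * tr / N, N)
  e <- eigen(Md, symmetric = TRUE)
  gam <- pmax(e$values, 0)
  z <- drop(crossprod(e$vectors, a_bar))
  z2 <- z^2
  g <- function(l) sum(z2 / (1 + l * gam)^2)
  hi <- max(1, 1 / (eps * max(gam)))
  it <- 0
  while (g(hi) > eps && it < 200) { hi <- hi * 10; it <- it + 1 }
  if (it >= 200)
    stop_histopam(paste0("Lagrange multiplier root not bracketed; spectrum: ",
                         paste(signif(gam, 4), collapse = ", ")),
                  "histopam_numeric_failure", spectrum = gam)
  lambda <- uniroot(function(l) g(l) - eps, c(0, hi),
                    tol = .Machine$double.eps^0.75)$root
  kern <- sum(lambda^2 * gam * z2 / (1 + lambda * gam)^2)
  a_hat <- a_bar - drop(e$vectors %*% (z / (1 + lambda * gam)))
  out <- if (kern > 0) pref / kern else 0
  attributes(out) <- list(lambda = lambda, kernel = kern, a_hat = a_hat)
  out
}

#' Passive acoustic power map
#'
#' Per-pixel steer / correlate / power over a 2-D azimuth-range grid. The
#' `"rcb"` beamformer is the robust Capon estimator; `"das"` computes the
#' conventional delay-sum-square power as a baseline, with the same
#' geometric prefactor.
#'
#' @param data A [channel_data()].
#' @param grid List with `azimuth` and `range` axis vectors in mm; see
#'   [default_pam_grid()].
#' @param geom An [array_geometry()].
#' @param med A [medium()].
#' @param params An [rcb_params()].
#' @param beamformer `"rcb"` or `"das"`.
#' @param taps Fractional-delay kernel length.
#' @return Object of class `power_map`: `grid` (mm), `power`
#'   (`length(azimuth) x length(range)`, relative acoustic power),
#'   `frames_averaged`, `beamformer`.
#' @export
pam_map <- function(data, grid = default_pam_grid(), geom = array_geometry(),
                    med = medium(), params = rcb_params(),
                    beamformer = c("rcb", "das"), taps = 32L) {
  stopifnot(inherits(data, "channel_data"))
  beamformer <- match.arg(beamformer)
  eps <- if (is.null(params$epsilon)) 0.1 * geom$n_elements else params$epsilon
  power <- pam_map_cpp(data$samples, data$sampling_rate,
                       geom$element_positions,
                       grid$azimuth / 1e3, grid$range / 1e3,
                       med$sound_speed, med$density, eps, params$loading,
                       as.integer(params$range_exponent),
                       beamformer == "das", as.integer(taps))
  structure(list(grid = lapply(grid[c("azimuth", "range")], as.numeric),
                 power = power, frames_averaged = 1L,
                 beamformer = beamformer, db_convention = params$db_convention),
            class = "power_map")
}

#' Default passive-map grid
#'
#' 0.2 mm azimuth by 0.5 mm range spacing over +/- 12 mm x 40-80 mm.
#'
#' @param azimuth_lim,range_lim Extents, mm.
#' @param azimuth_step,range_step Spacing, mm.
#' @return List with `azimuth` and `range` axis vectors (mm).
#' @export
default_pam_grid <- function(azimuth_lim = c(-12, 12), range_lim = c(40, 80),
                             azimuth_step = 0.2, range_step = 0.5) {
  list(azimuth = seq(azimuth_lim[1], azimuth_lim[2], by = azimuth_step),
       range = seq(range_lim[1], range_lim[2], by = range_step))
}

#' @export
print.power_map <- function(x, ...) {
  cat(sprintf("<power_map> %d x %d px (%s), %d frame(s), peak %.3g\n",
              nrow(x$power), ncol(x$power), x$beamformer,
              x$frames_averaged, max(x$power)))
  invisible(x)
}

#' Pixel-wise average of passive maps
#'
#' @param maps List of [pam_map()] results on identical grids.
#' @return A `power_map` with the arithmetic mean power and
#'   `frames_averaged` equal to the number of maps.
#' @export
frame_average <- function(maps) {
  stopifnot(length(maps) >= 1)
  g0 <- maps[[1]]$grid
  for (m in maps[-1])
    if (!isTRUE(all.equal(m$grid, g0)))
      stop_histopam("passive maps have mismatched grids",
                    "histopam_grid_mismatch")
  avg <- Reduce(`+`, lapply(maps, `[[`, "power")) / length(maps)
  out <- maps[[1]]
  out$power <- avg
  out$frames_averaged <- length(maps)
  out
}

#' Power-weighted emission centroid
#'
#' @param map A `power_map`.
#' @return Position `(azimuth, range)` in mm.
#' @export
emission_centroid <- function(map) {
  w <- map$power
  tot <- sum(w)
  if (tot <= 0)
    stop_histopam("emission centroid undefined for an all-zero map",
                  "histopam_undefined_centroid")
  c(azimuth = sum(rowSums(w) * map$grid$azimuth) / tot,
    range = sum(colSums(w) * map$grid$range) / tot)
}

#' Region within 1 dB of the peak emission level
#'
#' @param map A `power_map`.
#' @param db Width of the band below the peak, dB.
#' @param convention `"power"` (threshold `peak * 10^(-db/10)`, default,
#'   since the mapped quantity is acoustic power) or `"amplitude"`
#'   (`peak * 10^(-db/20)`).
#' @return A [binary_mask()] on the map grid (mm).
#' @export
one_dB_region <- function(map, db = 1,
                          convention = map$db_convention %||% "power") {
  pk <- max(map$power)
  if (pk <= 0)
    stop_histopam("peak power must be positive", "histopam_undefined_centroid")
  fac <- if (convention == "amplitude") 10^(-db / 20) else 10^(-db / 10)
  binary_mask(map$power >= pk * fac,
              spacing = c(diff(map$grid$azimuth[1:2]),
                          diff(map$grid$range[1:2])),
              origin = c(map$grid$azimuth[1], map$grid$range[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
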