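# Synthetic-data generators with known ground truth: broadband point
# emitters received on a linear array (RF channel data), vessel/clot
# phantom cross-section images, and liquefaction masks consistent with a
# predicted focal footprint. Every generator is deterministic given a seed.

#' Broadband point-emitter set
#'
#' Emitters stand in for cavitation bubble clouds: each radiates a
#' Gaussian-windowed sinusoid (default 3 MHz centre, 100% fractional
#' bandwidth, reflecting broadband emissions received in the imaging-array
#' band).
#'
#' @param positions n x 2 (azimuth, range) or n x 3 matrix, mm; emitters
#'   must lie in front of the array (positive range).
#' @param amplitudes Relative source amplitudes (> 0).
#' @param center_frequency,fractional_bandwidth Pulse descriptor.
#' @param onset_times Emission onsets, s.
#' @return Object of class `emitter_set`.
#' @export
emitter_set <- function(positions, amplitudes = 1,
                        center_frequency = 3e6, fractional_bandwidth = 1,
                        onset_times = 0) {
  pos <- if (is.null(dim(positions))) matrix(positions, nrow = 1)
         else as.matrix(positions)
  if (ncol(pos) == 2L) pos <- cbind(pos[, 1], rep(0, nrow(pos)), pos[, 2])
  stopifnot(ncol(pos) == 3L, all(pos[, 3] > 0), all(amplitudes > 0))
  structure(list(positions = pos,
                 amplitudes = rep_len(amplitudes, nrow(pos)),
                 center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 onset_times = rep_len(onset_times, nrow(pos))),
            class = "emitter_set")
}

# Gaussian-windowed sinusoid evaluated at continuous times (s). The
# Gaussian envelope makes the waveform analytically band-limited, so
# sampling at exact arrival times is exact band-limited interpolation.
emitter_pulse <- function(t, f0, frac_bw) {
  sigma_t <- 2 * sqrt(2 * log(2)) / (2 * pi * frac_bw * f0)
  exp(-t^2 / (2 * sigma_t^2)) * sin(2 * pi * f0 * t)
}

#' Simulate RF channel data from point emitters
#'
#' Each channel receives `amplitude / R_n * pulse(t - R_n / c - onset)`
#' summed over emitters (spherical spreading, no attenuation), plus white
#' Gaussian noise scaled to the stated SNR. SNR is defined as the ratio of
#' mean signal power over the record to the noise variance; with an empty
#' emitter set the reference power is 1.
#'
#' @param emitters An [emitter_set()].
#' @param geom An [array_geometry()].
#' @param med A [medium()].
#' @param fs Sampling rate, Hz (>= twice the pulse centre frequency).
#' @param duration Record length, s; must cover the farthest arrival (a
#'   truncation warning is issued otherwise).
#' @param snr_db Signal-to-noise ratio in dB; `Inf` disables noise.
#' @param seed Integer seed; generation is reproducible.
#' @return A [channel_data()].
#' @export
simulate_emissions <- function(emitters, geom = array_geometry(),
                               med = medium(), fs = 31.25e6,
                               duration = 60e-6, snr_db = Inf, seed = 1L) {
  stopifnot(inherits(emitters, "emitter_set"),
            fs >= 2 * emitters$center_frequency, duration > 0)
  n_samp <- round(duration * fs)
  t <- (seq_len(n_samp) - 1) / fs
  pos <- geom$element_positions
  sig <- matrix(0, geom$n_elements, n_samp)
  for (e in seq_len(nrow(emitters$positions))) {
    src <- emitters$positions[e, ] / 1e3
    Rn <- sqrt(rowSums(sweep(pos, 2, src)^2))
    arrival <- Rn / med$sound_speed + emitters$onset_times[e]
    if (max(arrival) > duration)
      warning("emitter arrival beyond the record: waveform truncated")
    for (n in seq_len(geom$n_elements))
      sig[n, ] <- sig[n, ] + emitters$amplitudes[e] / Rn[n] *
        emitter_pulse(t - arrival[n], emitters$center_frequency,
                      emitters$fractional_bandwidth)
  }
  if (is.finite(snr_db)) {
    p_sig <- mean(sig^2)
    if (p_sig <= 0) p_sig <- 1
    noise_sd <- sqrt(p_sig / 10^(snr_db / 10))
    set.seed(seed)
    sig <- sig + matrix(rnorm(length(sig), sd = noise_sd),
                        nrow(sig), ncol(sig))
  }
  channel_data(sig, sampling_rate = fs)
}

#' Ground-truth description of the vessel/clot phantom
#'
#' Defaults match the in vitro model: latex tubing of 6.35 mm inner
#' diameter and 0.79 mm wall, holding a clot of about 2 mm radius.
#'
#' @param lumen_center In-plane (azimuth, range) centre of the vessel
#'   cross-section, mm.
#' @param lumen_inner_diameter,wall_thickness,clot_radius mm.
#' @param clot_center In-plane clot centre (mm) or `NULL` for a clot-free
#'   vessel; must lie inside the lumen.
#' @return Object of class `phantom_truth`.
#' @export
phantom_truth <- function(lumen_center = c(0, 60),
                          lumen_inner_diameter = 6.35, wall_thickness = 0.79,
                          clot_center = lumen_center, clot_radius = 2) {
  if (!is.null(clot_center)) {
    reach <- sqrt(sum((clot_center - lumen_center)^2)) + clot_radius
    if (reach > lumen_inner_diameter / 2 + 1e-9)
      stop_histopam("clot does not fit inside the lumen",
                    "histopam_invalid_geometry")
  }
  structure(list(lumen_center = lumen_center,
                 lumen_inner_diameter = lumen_inner_diameter,
                 wall_thickness = wall_thickness,
                 clot_center = clot_center, clot_radius = clot_radius),
            class = "phantom_truth")
}

#' Synthetic B-mode-like image of the vessel cross-section
#'
#' Intensity-map-level emulation (not RF-level): bright annulus for the
#' latex wall, dark lumen interior, mid-intensity disk for the clot, over a
#' mid-low background, with optional multiplicative log-normal speckle.
#' A noise-free, clot-free image has exactly three intensity levels.
#'
#' @param truth A [phantom_truth()].
#' @param spacing Pixel spacing, mm (<= 0.2).
#' @param margin Image margin beyond the vessel wall, mm.
#' @param noise_sd Log-scale speckle standard deviation (0 disables).
#' @param noise_seed Integer seed.
#' @return List: `image` (a [grayscale_image()]) and `truth` (the input,
#'   with `lumen_mask` and `clot_mask` ground-truth [binary_mask()]s
#'   attached).
#' @export
make_vessel_image <- function(truth, spacing = 0.1, margin = 3,
                              noise_sd = 0.15, noise_seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"), spacing <= 0.2, spacing > 0)
  r_in <- truth$lumen_inner_diameter / 2
  r_out <- r_in + truth$wall_thickness
  half <- r_out + margin
  n <- 2 * floor(half / spacing) + 1
  origin <- truth$lumen_center - (n - 1) / 2 * spacing
  xs <- origin[1] + (seq_len(n) - 1) * spacing
  ys <- origin[2] + (seq_len(n) - 1) * spacing
  r2 <- outer((xs - truth$lumen_center[1])^2, (ys - truth$lumen_center[2])^2,
              `+`)
  px <- matrix(0.30, n, n)                        # background
  px[r2 <= r_out^2] <- 0.95                       # latex wall
  lumen <- r2 <= r_in^2
  px[lumen] <- 0.05                               # anechoic lumen interior
  clot <- matrix(FALSE, n, n)
  if (!is.null(truth$clot_center)) {
    c2 <- outer((xs - truth$clot_center[1])^2, (ys - truth$clot_center[2])^2,
                `+`)
    clot <- c2 <= truth$clot_radius^2
    px[clot] <- 0.55                              # echogenic clot
  }
  if (noise_sd > 0) {
    set.seed(noise_seed)
    px <- px * exp(rnorm(length(px), sd = noise_sd) - noise_sd^2 / 2)
    px <- pmin(pmax(px, 0), 1)
    px <- matrix(px, n, n)
  }
  truth$lumen_mask <- binary_mask(lumen & !clot, spacing, origin)
  truth$lumen_full_mask <- binary_mask(lumen, spacing, origin)
  truth$clot_mask <- binary_mask(clot, spacing, origin)
  list(image = grayscale_image(px, spacing, origin), truth = truth)
}

#' Synthetic liquefaction outcome for a treatment plan
#'
#' Builds the "actual" ablation mask as the union of the per-stop predicted
#' footprint ellipses (major axis along range), each perturbed by seeded
#' Gaussian centre jitter, then eroded at the boundary to mimic
#' under-treatment of thin targets by a slightly misaligned focal plane.
#' At least three fiducials are placed outside the mask.
#'
#' @param plan An [interpolate_path()] result or an m x 2 matrix of
#'   in-plane stops (mm).
#' @param footprint A `footprint_ellipse` (see [predicted_footprint()]) or
#'   list with `major_axis` / `minor_axis` in mm.
#' @param jitter_mm Per-stop centre jitter SD, mm.
#' @param seed Integer seed.
#' @param erosion_px Boundary erosion in pixels (0 disables).
#' @param spacing Mask pixel spacing, mm.
#' @param margin Mask margin beyond the stops, mm.
#' @return List of class `liquefaction_truth`: `mask` (a [binary_mask()]),
#'   `predicted_mask` (unjittered, uneroded union), `fiducials`
#'   (data.frame label, x_mm, y_mm), `stops`.
#' @export
make_liquefaction_truth <- function(plan, footprint, jitter_mm = 0.3,
                                    seed = 1L, erosion_px = 1L,
                                    spacing = 0.1, margin = 3) {
  stops <- if (inherits(plan, "insonation_plan")) plan$stops[, c(1, 3)]
           else as.matrix(plan)
  stops <- matrix(stops, ncol = 2)
  stopifnot(nrow(stops) >= 1, footprint$major_axis > 0,
            footprint$minor_axis > 0)
  semi_major <- footprint$major_axis / 2   # along range (second axis)
  semi_minor <- footprint$minor_axis / 2   # along azimuth
  lo <- apply(stops, 2, min) - semi_major - margin
  hi <- apply(stops, 2, max) + semi_major + margin
  dims <- ceiling((hi - lo) / spacing) + 1
  set.seed(seed)
  jitter <- matrix(rnorm(length(stops), sd = jitter_mm), ncol = 2)
  actual_centers <- stops + jitter
  predicted <- rasterize_ellipses(dims, c(spacing, spacing), lo, stops,
                                  semi_minor, semi_major)
  actual <- rasterize_ellipses(dims, c(spacing, spacing), lo, actual_centers,
                               semi_minor, semi_major)
  if (erosion_px > 0)
    actual <- EBImage::erode(actual,
                             EBImage::makeBrush(2 * erosion_px + 1,
                                                "diamond")) > 0
  mask <- binary_mask(actual, spacing, lo)
  pred_mask <- binary_mask(predicted, spacing, lo)
  fid <- rbind(c(lo[1] + 1, lo[2] + 1),
               c(lo[1] + (dims[1] - 2) * spacing, lo[2] + 1),
               c(lo[1] + 1, lo[2] + (dims[2] - 2) * spacing),
               c(lo[1] + (dims[1] - 2) * spacing,
                 lo[2] + (dims[2] - 2) * spacing))
  fiducials <- data.frame(label = paste0("F", seq_len(nrow(fid))),
                          x_mm = fid[, 1], y_mm = fid[, 2])
  structure(list(mask = mask, predicted_mask = pred_mask,
                 fiducials = fiducials, stops = stops,
                 jitter_mm = jitter_mm, erosion_px = erosion_px),
            class = "liquefaction_truth")
}
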