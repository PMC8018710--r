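# Linear focal-field model for the elliptic focused histotripsy source.
#
# The source is a spherically focused shell whose boundary projects to an
# ellipse (9 x 7 cm axes at 6 cm focal length by default), with a central
# rectangular cutout holding the coaxial imaging array. The low-amplitude
# field is computed by Rayleigh-Sommerfeld summation of spherical wavelets
# over a discretized aperture; focal-zone metrics (-6 dB widths, predicted
# cavitation footprint) are derived from the resulting pressure magnitude.

#' Elliptic focused-source geometry
#'
#' Geometry of a spherically focused shell with elliptic outline and a
#' central rectangular window for the coaxial imaging array. The window's
#' long side lies along the major aperture axis, which is also the imaging
#' azimuth direction (the linear array's lateral axis).
#'
#' @param major_axis Full extent of the aperture along x (azimuth), m.
#' @param minor_axis Full extent along y (elevation), m.
#' @param focal_length Radius of curvature / geometric focus range, m.
#' @param frequency Drive frequency, Hz.
#' @param window_width Central cutout extent along the major axis, m.
#' @param window_height Central cutout extent along the minor axis, m.
#' @return An object of class `source_geometry`.
#' @export
source_geometry <- function(major_axis = 0.09, minor_axis = 0.07,
                            focal_length = 0.06, frequency = 1.5e6,
                            window_width = 0.040, window_height = 0.014) {
  stopifnot(major_axis > 0, minor_axis > 0, focal_length > 0, frequency > 0,
            window_width >= 0, window_height >= 0)
  a <- major_axis / 2; b <- minor_axis / 2
  if (focal_length <= a)
    stop_histopam("focal length must exceed the aperture semi-major axis",
                  "histopam_invalid_geometry")
  if (window_width > 0 || window_height > 0) {
    corner <- (window_width / 2 / a)^2 + (window_height / 2 / b)^2
    if (corner >= 1)
      stop_histopam("imaging window does not fit inside the elliptic aperture",
                    "histopam_invalid_geometry")
  }
  structure(list(major_axis = major_axis, minor_axis = minor_axis,
                 focal_length = focal_length, frequency = frequency,
                 window_width = window_width, window_height = window_height),
            class = "source_geometry")
}

#' Discretize the focused aperture into point sources
#'
#' Samples the spherical cap on a regular (x, y) grid with pitch at most
#' `wavelength / points_per_wavelength`, keeps points inside the elliptic
#' outline and outside the central window, and projects them onto the
#' focused shell. Element areas are true cap areas (planar cell area times
#' the local slope factor), so that the on-axis sum converges to the
#' closed-form focused-radiator solution.
#'
#' @param geom A [source_geometry()].
#' @param points_per_wavelength Sampling density (>= 2); default 4.
#' @param med A [medium()] supplying the sound speed for the wavelength.
#' @return An object of class `aperture_sampling` with fields `points`
#'   (n x 3, m), `areas` (m^2), `normals` (unit, pointing at the focus),
#'   `pitch`, and the originating `geom`.
#' @export
discretize_aperture <- function(geom, points_per_wavelength = 4, med = medium()) {
  stopifnot(inherits(geom, "source_geometry"), points_per_wavelength >= 2)
  lambda <- med$sound_speed / geom$frequency
  pitch <- lambda / points_per_wavelength
  a <- geom$major_axis / 2; b <- geom$minor_axis / 2
  F <- geom$focal_length
  nx <- ceiling(a / pitch); ny <- ceiling(b / pitch)
  # grid symmetric about both axes so mirrored field points see identical sums
  x <- pitch * (seq(-nx, nx) )
  y <- pitch * (seq(-ny, ny) )
  g <- expand.grid(x = x, y = y)
  inside <- (g$x / a)^2 + (g$y / b)^2 <= 1
  in_window <- abs(g$x) < geom$window_width / 2 &
    abs(g$y) < geom$window_height / 2
  keep <- inside & !in_window
  if (!any(keep))
    stop_histopam("window removes the entire aperture",
                  "histopam_invalid_geometry")
  px <- g$x[keep]; py <- g$y[keep]
  rho2 <- px^2 + py^2
  zc <- sqrt(F^2 - rho2)           # height of the cap point above the focus plane
  pz <- F - zc                     # apex of the shell at z = 0, focus at z = F
  slope <- F / zc                  # cap-area / planar-area ratio
  areas <- pitch^2 * slope
  normals <- cbind(-px, -py, zc) / F   # unit vectors toward the focus (0,0,F)
  structure(list(points = cbind(x = px, y = py, z = pz),
                 areas = areas, normals = normals,
                 pitch = pitch, geom = geom, med = med),
            class = "aperture_sampling")
}

#' @export
print.aperture_sampling <- function(x, ...) {
  cat(sprintf("<aperture_sampling> %d points, pitch %.3g mm, area %.3g cm^2\n",
              nrow(x$points), x$pitch * 1e3, sum(x$areas) * 1e4))
  invisible(x)
}

#' Linear focal pressure field by Rayleigh-Sommerfeld summation
#'
#' Field magnitude at each grid node is the modulus of the sum of spherical
#' wavelets `exp(i k R) / R` weighted by element area over all aperture
#' points (continuous-wave, linear propagation). Units are relative; use
#' [predicted_footprint()] to attach a drive-level scaling.
#'
#' @param sampling An [discretize_aperture()] result.
#' @param med A [medium()].
#' @param grid List with numeric axis vectors `x`, `y`, `z` in metres
#'   (any axis may be a single value for planar or line evaluations).
#' @return An object of class `pressure_field`: `grid` (axes, m),
#'   `magnitude` (array, dim `c(nx, ny, nz)`), `frequency`.
#' @export
compute_focal_field <- function(sampling, med = sampling$med, grid) {
  stopifnot(inherits(sampling, "aperture_sampling"),
            is.list(grid), all(c("x", "y", "z") %in% names(grid)))
  k <- 2 * pi * sampling$geom$frequency / med$sound_speed
  g <- expand.grid(x = grid$x, y = grid$y, z = grid$z)
  val <- rs_sum_cpp(sampling$points, sampling$areas, as.matrix(g), k)
  mag <- array(Mod(val), dim = c(length(grid$x), length(grid$y), length(grid$z)))
  structure(list(grid = lapply(grid[c("x", "y", "z")], as.numeric),
                 magnitude = mag, frequency = sampling$geom$frequency),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("<pressure_field> %s grid, peak %.3g at (%.1f, %.1f, %.1f) mm\n",
              paste(dim(x$magnitude), collapse = " x "), max(x$magnitude),
              field_peak_position(x)[1] * 1e3, field_peak_position(x)[2] * 1e3,
              field_peak_position(x)[3] * 1e3))
  invisible(x)
}

# (x, y, z) in metres of the field maximum.
field_peak_position <- function(field) {
  i <- arrayInd(which.max(field$magnitude), dim(field$magnitude))
  c(field$grid$x[i[1]], field$grid$y[i[2]], field$grid$z[i[3]])
}

# Full width of the connected >= level*peak lobe along one axis of a profile,
# with linear interpolation of the crossings. `coords` in metres, returns mm.
# Errors if the lobe is clipped by the grid boundary.
profile_width <- function(coords, values, level) {
  p <- which.max(values)
  thr <- values[p] * level
  n <- length(values)
  lo <- p
  while (lo > 1 && values[lo - 1] >= thr) lo <- lo - 1
  hi <- p
  while (hi < n && values[hi + 1] >= thr) hi <- hi + 1
  if (lo == 1 || hi == n)
    stop_histopam("half-peak contour clipped by the grid boundary",
                  "histopam_widths_unresolved")
  # linear sub-grid interpolation of the two crossings
  f_lo <- (values[lo] - thr) / (values[lo] - values[lo - 1])
  x_lo <- coords[lo] - f_lo * (coords[lo] - coords[lo - 1])
  f_hi <- (values[hi] - thr) / (values[hi] - values[hi + 1])
  x_hi <- coords[hi] + f_hi * (coords[hi + 1] - coords[hi])
  (x_hi - x_lo) * 1e3
}

#' -6 dB focal widths of a pressure field
#'
#' For each grid axis with more than one node, measures the full width of the
#' connected region around the peak where the magnitude is at least half the
#' peak (-6 dB in pressure), along the principal axis through the peak, with
#' linear sub-grid interpolation of the half-peak crossings.
#'
#' @param field A [compute_focal_field()] result.
#' @param level Fraction of peak defining the width (default 0.5, i.e. -6 dB
#'   pressure).
#' @return Object of class `focal_widths` with `w_azimuth`, `w_elevation`,
#'   `w_range` in mm (`NA` for singleton axes).
#' @export
minus6dB_widths <- function(field, level = 0.5) {
  stopifnot(inherits(field, "pressure_field"))
  dims <- dim(field$magnitude)
  p <- arrayInd(which.max(field$magnitude), dims)
  axes <- c("x", "y", "z")
  w <- c(w_azimuth = NA_real_, w_elevation = NA_real_, w_range = NA_real_)
  for (d in 1:3) {
    if (dims[d] < 2) next
    idx <- as.list(p)
    idx[[d]] <- seq_len(dims[d])
    prof <- do.call(`[`, c(list(field$magnitude), idx))
    w[d] <- profile_width(field$grid[[axes[d]]], as.numeric(prof), level)
  }
  structure(as.list(w), class = "focal_widths")
}

#' @export
print.focal_widths <- function(x, ...) {
  cat(sprintf("<focal_widths> azimuth %.2f, elevation %.2f, range %.2f mm\n",
              x$w_azimuth, x$w_elevation, x$w_range))
  invisible(x)
}

#' Characterize the focal zone of a source
#'
#' Convenience driver: locates the axial peak, evaluates line profiles
#' through it along all three axes, and returns the -6 dB widths together
#' with the peak range. Profile extents and steps are chosen from the
#' expected focal-lobe scale.
#'
#' @param sampling An [discretize_aperture()] result.
#' @param med A [medium()].
#' @param lateral_halfspan,lateral_step,axial_span,axial_step Profile extents
#'   and sampling, m.
#' @return List with `widths` ([minus6dB_widths()]), `peak_range_m`,
#'   `profiles` (the three 1-D `pressure_field`s).
#' @export
characterize_focus <- function(sampling, med = sampling$med,
                               lateral_halfspan = 3e-3, lateral_step = 2.5e-5,
                               axial_span = c(0.75, 1.3), axial_step = 1e-4) {
  F <- sampling$geom$focal_length
  zax <- seq(axial_span[1] * F, axial_span[2] * F, by = axial_step)
  fz <- compute_focal_field(sampling, med, list(x = 0, y = 0, z = zax))
  z_peak <- zax[which.max(fz$magnitude)]
  lat <- seq(-lateral_halfspan, lateral_halfspan, by = lateral_step)
  fx <- compute_focal_field(sampling, med, list(x = lat, y = 0, z = z_peak))
  fy <- compute_focal_field(sampling, med, list(x = 0, y = lat, z = z_peak))
  widths <- list(
    w_azimuth = minus6dB_widths(fx)$w_azimuth,
    w_elevation = minus6dB_widths(fy)$w_elevation,
    w_range = minus6dB_widths(fz)$w_range)
  class(widths) <- "focal_widths"
  list(widths = widths, peak_range_m = z_peak,
       profiles = list(azimuth = fx, elevation = fy, range = fz))
}

#' Predicted cavitation footprint in the imaging plane
#'
#' Scales the linear field so its maximum equals the calibrated focal peak
#' pressure, thresholds the azimuth-range plane at the cavitation-cloud
#' pressure threshold, and reports both the supra-threshold pixel mask and
#' an ellipse whose axes are the extents of the supra-threshold region
#' through the peak (major axis along range).
#'
#' @param field A planar `pressure_field` (singleton y axis) covering the
#'   focus, with axes in metres.
#' @param drive_peak Calibrated peak pressure at the field maximum, Pa.
#' @param threshold Cavitation threshold pressure, Pa.
#' @return List of class `footprint` with `ellipse` (class
#'   `footprint_ellipse`: `center` mm, `major_axis` and `minor_axis` mm) and
#'   `mask` (a [binary_mask()] in mm, azimuth x range). A threshold above
#'   the drive peak yields an explicitly empty footprint.
#' @export
predicted_footprint <- function(field, drive_peak = 35e6, threshold = 27.4e6) {
  stopifnot(inherits(field, "pressure_field"),
            dim(field$magnitude)[2] == 1L, drive_peak > 0, threshold >= 0)
  mag <- field$magnitude[, 1, ]
  scale <- drive_peak / max(mag)
  xs <- field$grid$x * 1e3; zs <- field$grid$z * 1e3
  spacing <- c(if (length(xs) > 1) diff(xs[1:2]) else 1,
               if (length(zs) > 1) diff(zs[1:2]) else 1)
  mk <- function(px) binary_mask(px, spacing = spacing, origin = c(xs[1], zs[1]))
  if (threshold > drive_peak) {
    ell <- structure(list(center = c(NA_real_, NA_real_),
                          major_axis = 0, minor_axis = 0, empty = TRUE),
                     class = "footprint_ellipse")
    return(structure(list(ellipse = ell,
                          mask = mk(matrix(FALSE, length(xs), length(zs)))),
                     class = "footprint"))
  }
  scaled <- mag * scale
  mask <- scaled >= threshold
  p <- arrayInd(which.max(scaled), dim(scaled))
  extent <- function(coords, values) {
    if (length(values) < 3) return(0)
    if (threshold <= 0) return(abs(coords[length(coords)] - coords[1]))
    if (threshold >= drive_peak) return(0)
    profile_width(coords / 1e3, values, threshold / drive_peak)
  }
  minor <- extent(xs, scaled[, p[2]])
  major <- extent(zs, scaled[p[1], ])
  ell <- structure(list(center = c(xs[p[1]], zs[p[2]]),
                        major_axis = max(major, minor),
                        minor_axis = min(major, minor),
                        axis_range = major, axis_azimuth = minor,
                        empty = FALSE),
                   class = "footprint_ellipse")
  structure(list(ellipse = ell, mask = mk(mask)), class = "footprint")
}

#' @export
print.footprint_ellipse <- function(x, ...) {
  cat(sprintf("<footprint_ellipse> %.2f x %.2f mm\n",
              x$major_axis, x$minor_axis))
  invisible(x)
}

#' Closed-form on-axis pressure of an unobstructed focused bowl
#'
#' Exact on-axis Rayleigh-Sommerfeld integral for a spherically focused
#' circular radiator (O'Neil's focused-radiator solution), used as the
#' analytic oracle for the numerical summation. Returns the same relative
#' magnitude scale as [compute_focal_field()].
#'
#' @param z Axial positions, m (apex of the bowl at z = 0).
#' @param aperture_radius Bowl outline radius, m.
#' @param focal_length Radius of curvature, m.
#' @param frequency Hz.
#' @param med A [medium()].
#' @return Numeric vector of on-axis pressure magnitudes (relative units).
#' @export
oneil_on_axis <- function(z, aperture_radius, focal_length, frequency,
                          med = medium()) {
  k <- 2 * pi * frequency / med$sound_speed
  F <- focal_length
  h <- F - sqrt(F^2 - aperture_radius^2)  # cap depth
  vapply(z, function(zz) {
    if (abs(zz - F) < 1e-12) return(2 * pi * h)
    R1 <- sqrt(zz^2 + 2 * h * (F - zz))
    Mod(2 * pi * F / (F - zz) * (exp(1i * k * R1) - exp(1i * k * zz)) / (1i * k))
  }, numeric(1))
}
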