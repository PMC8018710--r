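# Treatment-path planning: arc-length interpolation of user waypoints at a
# fixed stop increment along a vessel, and hexagonal packing of insonation
# points over a drawn region. All positions are world millimetres.

#' Interpolate an insonation path through waypoints
#'
#' Piecewise-linear chain through the waypoints re-parameterized by arc
#' length, with stops at `s = 0, step, 2*step, ...`; the final waypoint is
#' always included as a stop even when the remaining spacing is shorter
#' than `step`, so the treated extent equals the planned extent. Duplicate
#' consecutive waypoints collapse with a warning.
#'
#' @param waypoints Ordered n x 3 matrix (x, y, z in mm) or n x 2 (z = 0).
#' @param step Arc-length stop increment, mm.
#' @param pulses_per_stop,pulse_rate_hz,frame_decimation Insonation
#'   bookkeeping carried as plan metadata (defaults: 500 pulses per stop at
#'   40 Hz, one passive frame recorded every 10th pulse).
#' @return Object of class `insonation_plan`: `stops` (m x 3 mm), `step`,
#'   `arc_length`, `pulses_per_stop`, `frames_per_stop`, `pulse_rate_hz`.
#' @export
interpolate_path <- function(waypoints, step = 0.5, pulses_per_stop = 500L,
                             pulse_rate_hz = 40, frame_decimation = 10L) {
  wp <- as.matrix(waypoints)
  if (ncol(wp) == 2L) wp <- cbind(wp, 0)
  stopifnot(ncol(wp) == 3L, nrow(wp) >= 1L, all(is.finite(wp)), step > 0)
  if (nrow(wp) > 1L) {
    seg <- sqrt(rowSums((wp[-1, , drop = FALSE] -
                           wp[-nrow(wp), , drop = FALSE])^2))
    if (any(seg < 1e-9)) {
      warning("collapsing duplicate consecutive waypoints")
      wp <- wp[c(TRUE, seg >= 1e-9), , drop = FALSE]
    }
  }
  if (nrow(wp) == 1L) {
    stops <- wp
    L <- 0
  } else {
    seg <- sqrt(rowSums((wp[-1, , drop = FALSE] -
                           wp[-nrow(wp), , drop = FALSE])^2))
    s_wp <- c(0, cumsum(seg))
    L <- s_wp[length(s_wp)]
    s_stops <- seq(0, L, by = step)
    if (L - s_stops[length(s_stops)] > 1e-6) s_stops <- c(s_stops, L)
    stops <- sapply(seq_len(3), function(d)
      approx(s_wp, wp[, d], xout = s_stops, method = "linear")$y)
    stops <- matrix(stops, ncol = 3)
  }
  colnames(stops) <- c("x", "y", "z")
  structure(list(stops = stops, step = step, arc_length = L,
                 pulses_per_stop = as.integer(pulses_per_stop),
                 pulse_rate_hz = pulse_rate_hz,
                 frame_decimation = as.integer(frame_decimation),
                 frames_per_stop = as.integer(pulses_per_stop %/%
                                                frame_decimation)),
            class = "insonation_plan")
}

#' @export
print.insonation_plan <- function(x, ...) {
  cat(sprintf(
    "<insonation_plan> %d stops, step %.2f mm, arc length %.2f mm, %d pulses/stop (%d frames)\n",
    nrow(x$stops), x$step, x$arc_length, x$pulses_per_stop, x$frames_per_stop))
  invisible(x)
}

#' Hexagonally packed insonation points over a region of interest
#'
#' Generates a triangular lattice (row offset `pitch * sqrt(3)/2`, alternate
#' rows shifted by `pitch / 2`) anchored at the ROI centroid with rows
#' parallel to the azimuth axis, clipped to the ROI. An ROI smaller than one
#' lattice cell yields a single point at the ROI centroid.
#'
#' @param roi Either a simple polygon (n x 2 matrix of in-plane mm
#'   coordinates, vertices in order) or a [binary_mask()].
#' @param pitch Lattice constant (nearest-neighbour separation), mm.
#' @return m x 2 matrix of in-plane positions (mm).
#' @export
hex_pack <- function(roi, pitch = 0.5) {
  stopifnot(pitch > 0)
  if (inherits(roi, "binary_mask")) {
    if (!any(roi$pixels))
      stop_histopam("empty region of interest", "histopam_empty_mask")
    ctr <- component_centroid(roi)
    bbox <- apply(mask_coords(roi), 2, range)
    inside <- function(p) {
      ix <- round((p[, 1] - roi$origin[1]) / roi$spacing[1]) + 1
      iy <- round((p[, 2] - roi$origin[2]) / roi$spacing[2]) + 1
      ok <- ix >= 1 & ix <= nrow(roi$pixels) & iy >= 1 & iy <= ncol(roi$pixels)
      ok[ok] <- roi$pixels[cbind(ix[ok], iy[ok])]
      ok
    }
  } else {
    poly <- as.matrix(roi)
    stopifnot(ncol(poly) == 2L, nrow(poly) >= 1L)
    if (nrow(poly) < 3L) {
      ctr <- colMeans(poly)
      return(matrix(ctr, 1, 2, dimnames = list(NULL, c("x", "y"))))
    }
    ctr <- polygon_centroid(poly)
    bbox <- apply(poly, 2, range)
    inside <- function(p) point_in_polygon(p, poly)
  }
  row_h <- pitch * sqrt(3) / 2
  jr <- seq(floor((bbox[1, 2] - ctr[2]) / row_h),
            ceiling((bbox[2, 2] - ctr[2]) / row_h))
  pts <- do.call(rbind, lapply(jr, function(j) {
    off <- (abs(j) %% 2) * pitch / 2
    xi <- seq(floor((bbox[1, 1] - ctr[1] - off) / pitch),
              ceiling((bbox[2, 1] - ctr[1] - off) / pitch))
    cbind(ctr[1] + off + xi * pitch, ctr[2] + j * row_h)
  }))
  keep <- inside(pts)
  if (!any(keep))
    return(matrix(ctr, 1, 2, dimnames = list(NULL, c("x", "y"))))
  out <- pts[keep, , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

# Shoelace centroid of a simple polygon (falls back to the vertex mean for
# degenerate, zero-area polygons).
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xn) * cross) / (6 * a), sum((y + yn) * cross) / (6 * a))
}

# Even-odd ray-casting point-in-polygon test (boundary points count as in).
point_in_polygon <- function(pts, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  vapply(seq_len(nrow(pts)), function(i) {
    px <- pts[i, 1]; py <- pts[i, 2]
    crosses <- ((y > py) != (yn > py)) &
      (px < (xn - x) * (py - y) / (yn - y) + x)
    on_edge <- any(abs((xn - x) * (py - y) - (yn - y) * (px - x)) < 1e-9 &
                     px >= pmin(x, xn) - 1e-9 & px <= pmax(x, xn) + 1e-9 &
                     py >= pmin(y, yn) - 1e-9 & py <= pmax(y, yn) + 1e-9)
    on_edge || (sum(crosses) %% 2 == 1)
  }, logical(1))
}

#' Per-stop tracking error along a planned path
#'
#' Euclidean distance between each planned focus stop and the measured
#' target (lumen) centroid at that stop, with mean +/- SD summary.
#'
#' @param plan An [interpolate_path()] result.
#' @param lumen_centroids Matrix of per-stop measured positions (mm), same
#'   number of rows as stops and 2 or 3 columns.
#' @return List of class `tracking_series`: `errors` (mm per stop), `mean`,
#'   `sd`.
#' @export
tracking_error_series <- function(plan, lumen_centroids) {
  stopifnot(inherits(plan, "insonation_plan"))
  ctr <- as.matrix(lumen_centroids)
  if (nrow(ctr) != nrow(plan$stops))
    stop_histopam("centroid list length does not match the plan",
                  "histopam_length_mismatch")
  # 2-column centroids are in-plane (azimuth, range) measurements
  stops <- if (ncol(ctr) == 2L) plan$stops[, c(1, 3), drop = FALSE]
           else plan$stops
  err <- sqrt(rowSums((stops - ctr)^2))
  structure(list(errors = err, mean = mean(err), sd = sd(err)),
            class = "tracking_series")
}
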