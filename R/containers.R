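# Core value containers shared across the pipeline.
#
# Coordinate conventions
# ----------------------
# 3-D world frame (planning, field simulation): x = azimuth, y = elevation,
# z = range, in metres for acoustics and millimetres for planning I/O (each
# function documents its unit).
# 2-D image frame (B-mode images, masks, power maps): the imaging plane is
# (azimuth, range). Pixel arrays are indexed `pixels[ix, iy]` with the first
# index along the first (azimuth) axis; world position of pixel (ix, iy) is
# `origin + (c(ix, iy) - 1) * spacing`, all in mm.

#' Acoustic propagation medium
#'
#' Default values are water at 37 degrees C, the bath temperature used for
#' in vitro histotripsy work.
#'
#' @param sound_speed Speed of sound in m/s.
#' @param density Mass density in kg/m^3.
#' @return An object of class `medium`.
#' @export
medium <- function(sound_speed = 1524, density = 993) {
  stopifnot(is.numeric(sound_speed), sound_speed > 0,
            is.numeric(density), density > 0)
  structure(list(sound_speed = sound_speed, density = density),
            class = "medium")
}

#' Grayscale image with physical pixel geometry
#'
#' @param pixels Numeric matrix of intensities, indexed `[ix, iy]`.
#' @param spacing Pixel spacing in mm per pixel, length-2 (azimuth, range)
#'   or a scalar for isotropic pixels.
#' @param origin World coordinates (mm) of pixel (1, 1).
#' @return An object of class `grayscale_image`.
#' @export
grayscale_image <- function(pixels, spacing, origin = c(0, 0)) {
  pixels <- as.matrix(pixels)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  stopifnot(is.numeric(pixels), all(is.finite(pixels)),
            length(spacing) == 2L, all(spacing > 0),
            length(origin) == 2L, all(is.finite(origin)))
  structure(list(pixels = pixels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "grayscale_image")
}

#' Binary pixel mask with physical pixel geometry
#'
#' @param pixels Logical matrix, indexed `[ix, iy]`.
#' @param spacing,origin As for [grayscale_image()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, spacing, origin = c(0, 0)) {
  pixels <- as.matrix(pixels)
  if (is.numeric(pixels)) pixels <- pixels > 0.5
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  stopifnot(is.logical(pixels), !anyNA(pixels),
            length(spacing) == 2L, all(spacing > 0),
            length(origin) == 2L, all(is.finite(origin)))
  structure(list(pixels = pixels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, spacing %.3g x %.3g mm, %d set\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              sum(x$pixels)))
  invisible(x)
}

#' @export
print.grayscale_image <- function(x, ...) {
  cat(sprintf("<grayscale_image> %d x %d px, spacing %.3g x %.3g mm\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2]))
  invisible(x)
}

# World coordinates (mm, n x 2) of the TRUE pixels of a mask.
mask_coords <- function(mask) {
  idx <- which(mask$pixels, arr.ind = TRUE)
  cbind(mask$origin[1] + (idx[, 1] - 1) * mask$spacing[1],
        mask$origin[2] + (idx[, 2] - 1) * mask$spacing[2])
}

# TRUE if two image-like objects share pixel geometry.
same_geometry <- function(a, b, tol = 1e-9) {
  all(dim(a$pixels) == dim(b$pixels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_histopam <- function(msg, class, ...) {
  stop(structure(class = c(class, "histopam_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# Rasterize world-frame discs/ellipses onto a pixel grid. `centers` is n x 2
# (mm), semi-axes in mm; returns a logical matrix on the geometry of `ref`
# (a list with spacing/origin and pixel dims).
rasterize_ellipses <- function(dim_px, spacing, origin, centers, semi_x, semi_y) {
  centers <- matrix(centers, ncol = 2)
  semi_x <- rep_len(semi_x, nrow(centers))
  semi_y <- rep_len(semi_y, nrow(centers))
  xs <- origin[1] + (seq_len(dim_px[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dim_px[2]) - 1) * spacing[2]
  out <- matrix(FALSE, dim_px[1], dim_px[2])
  for (i in seq_len(nrow(centers))) {
    dx2 <- ((xs - centers[i, 1]) / semi_x[i])^2
    dy2 <- ((ys - centers[i, 2]) / semi_y[i])^2
    out <- out | (outer(dx2, dy2, `+`) <= 1)
  }
  out
}
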