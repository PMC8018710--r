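# Segmentation and accuracy metrics: Otsu masks, centroids, Dice overlap,
# Hausdorff distance, fiducial-based rigid co-registration, and targeting
# error. Thresholding and morphology go through EBImage; pixel-set distances
# are computed exactly on pixel-center world coordinates in mm (handles
# anisotropic pixel spacing).

#' Otsu segmentation of a grayscale image
#'
#' Normalizes intensities to `[0, 1]` (making the threshold invariant to any
#' increasing affine intensity rescaling), picks the threshold maximizing
#' between-class variance over a 256-bin histogram, keeps the bright or dark
#' class, and (optionally) fills holes, removes specks and retains the
#' largest connected component.
#'
#' @param image A [grayscale_image()].
#' @param polarity Keep the `"bright"` or `"dark"` class.
#' @param cleanup Apply morphological cleanup (default `TRUE`).
#' @param min_size Minimum component size in pixels retained before the
#'   largest-component selection.
#' @return A [binary_mask()] on the image geometry, with the threshold (on
#'   the normalized scale) in attribute `threshold`.
#' @export
otsu_mask <- function(image, polarity = c("bright", "dark"), cleanup = TRUE,
                      min_size = 5L) {
  stopifnot(inherits(image, "grayscale_image"))
  polarity <- match.arg(polarity)
  px <- image$pixels
  rng <- range(px)
  if (diff(rng) <= 0)
    stop_histopam("constant image: Otsu histogram is degenerate",
                  "histopam_degenerate_histogram")
  norm <- (px - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
  keep <- if (polarity == "bright") norm > thr else norm <= thr
  if (cleanup) keep <- clean_mask(keep, min_size = min_size)
  out <- binary_mask(keep, spacing = image$spacing, origin = image$origin)
  attr(out, "threshold") <- as.numeric(thr)
  out
}

# Fill holes, drop components below min_size, keep the largest component.
clean_mask <- function(px, min_size = 5L) {
  px <- EBImage::fillHull(px) > 0
  lab <- EBImage::bwlabel(px)
  if (max(lab) == 0) return(px)
  sizes <- tabulate(lab[lab > 0])
  ok <- which(sizes >= min_size)
  if (length(ok) == 0) ok <- which.max(sizes)
  largest <- ok[which.max(sizes[ok])]
  matrix(lab == largest, nrow(px), ncol(px))
}

#' Centroid of a mask component
#'
#' Unweighted mean of member-pixel world coordinates.
#'
#' @param mask A non-empty [binary_mask()].
#' @return Position `(x, y)` in mm.
#' @export
component_centroid <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$pixels))
    stop_histopam("centroid of an empty mask", "histopam_empty_mask")
  colMeans(mask_coords(mask))
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)` over pixel sets on identical
#' geometry.
#'
#' @param A,B [binary_mask()] objects sharing geometry.
#' @return Coefficient in `[0, 1]`.
#' @export
dice <- function(A, B) {
  stopifnot(inherits(A, "binary_mask"), inherits(B, "binary_mask"))
  if (!same_geometry(A, B))
    stop_histopam("masks have mismatched geometry", "histopam_grid_mismatch")
  na <- sum(A$pixels); nb <- sum(B$pixels)
  if (na + nb == 0)
    stop_histopam("Dice undefined for two empty masks", "histopam_empty_mask")
  2 * sum(A$pixels & B$pixels) / (na + nb)
}

#' Hausdorff distance between two masks
#'
#' Directed form: `h(A, B) = max over a in A of min over b in B of d(a, b)`
#' with Euclidean distance on member-pixel world coordinates (mm).
#' Symmetric mode returns the maximum of the two directed distances.
#'
#' @param A,B Non-empty [binary_mask()] objects (geometries may differ; the
#'   distance is computed in world mm).
#' @param mode `"directed"` (default, A to B) or `"symmetric"`.
#' @return Distance in mm.
#' @export
hausdorff <- function(A, B, mode = c("directed", "symmetric")) {
  mode <- match.arg(mode)
  stopifnot(inherits(A, "binary_mask"), inherits(B, "binary_mask"))
  if (!any(A$pixels) || !any(B$pixels))
    stop_histopam("Hausdorff distance needs two non-empty masks",
                  "histopam_empty_mask")
  pa <- mask_coords(A); pb <- mask_coords(B)
  h <- directed_hausdorff(pa, pb)
  if (mode == "symmetric") h <- max(h, directed_hausdorff(pb, pa))
  h
}

# Exact max-min Euclidean distance between point sets (chunked to bound
# memory at ~ 2e6 pairwise entries per block).
directed_hausdorff <- function(pa, pb) {
  nb <- nrow(pb)
  chunk <- max(1L, floor(2e6 / nb))
  worst <- 0
  for (start in seq(1L, nrow(pa), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(pa))
    d2 <- outer(pa[idx, 1], pb[, 1], `-`)^2 + outer(pa[idx, 2], pb[, 2], `-`)^2
    worst <- max(worst, sqrt(max(apply(d2, 1, min))))
  }
  worst
}

#' Least-squares rigid transform from matched fiducials
#'
#' Closed-form (SVD) solution for the rotation + translation (optionally
#' with isotropic scale) minimizing the mean squared distance between
#' transformed moving points and fixed points.
#'
#' @param moving_points,fixed_points Matched n x 2 matrices (mm), n >= 2.
#' @param scale Estimate an isotropic scale factor (default `FALSE`).
#' @return Object of class `rigid_transform_2d`: `rotation` (radians),
#'   `translation` (mm), `scale`, `rms` (residual root-mean-square, mm).
#' @export
register_fiducials <- function(moving_points, fixed_points, scale = FALSE) {
  m <- as.matrix(moving_points); f <- as.matrix(fixed_points)
  if (nrow(m) < 2 || nrow(m) != nrow(f))
    stop_histopam("need >= 2 matched fiducial pairs",
                  "histopam_bad_fiducials")
  cm <- colMeans(m); cf <- colMeans(f)
  mc <- sweep(m, 2, cm); fc <- sweep(f, 2, cf)
  if (max(abs(mc)) < 1e-12 || max(abs(fc)) < 1e-12)
    stop_histopam("degenerate fiducial configuration",
                  "histopam_bad_fiducials")
  H <- crossprod(mc, fc)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (scale) sum(diag(D) * sv$d) / sum(mc^2) else 1
  t_vec <- cf - s * drop(R %*% cm)
  pred <- s * m %*% t(R) + matrix(t_vec, nrow(m), 2, byrow = TRUE)
  rms <- sqrt(mean(rowSums((pred - f)^2)))
  structure(list(rotation = atan2(R[2, 1], R[1, 1]),
                 translation = t_vec, scale = s, rms = rms),
            class = "rigid_transform_2d")
}

#' @export
print.rigid_transform_2d <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform_2d> rot %.3f deg, t (%.3f, %.3f) mm, scale %.4f, rms %.3g mm\n",
    x$rotation * 180 / pi, x$translation[1], x$translation[2], x$scale, x$rms))
  invisible(x)
}

rotation_matrix <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

#' Apply / invert a 2-D rigid transform
#'
#' @param points n x 2 matrix or length-2 vector, mm.
#' @param tf A `rigid_transform_2d`.
#' @return Transformed points (same shape).
#' @export
apply_transform <- function(points, tf) {
  p <- matrix(points, ncol = 2)
  out <- tf$scale * p %*% t(rotation_matrix(tf$rotation)) +
    matrix(tf$translation, nrow(p), 2, byrow = TRUE)
  if (is.null(dim(points))) drop(out) else out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  Rinv <- t(rotation_matrix(tf$rotation))
  structure(list(rotation = -tf$rotation,
                 translation = -drop(Rinv %*% tf$translation) / tf$scale,
                 scale = 1 / tf$scale, rms = tf$rms),
            class = "rigid_transform_2d")
}

#' Resample a mask through a rigid transform
#'
#' Maps each pixel of the reference geometry back through the inverse
#' transform and takes the nearest source pixel (nearest-neighbour, so the
#' result stays binary).
#'
#' @param mask Source [binary_mask()].
#' @param tf Transform taking source world coordinates to reference world
#'   coordinates.
#' @param reference A mask or image supplying the output geometry (default:
#'   the source geometry).
#' @return A [binary_mask()] on the reference geometry.
#' @export
transform_mask <- function(mask, tf, reference = mask) {
  dims <- dim(reference$pixels)
  xs <- reference$origin[1] + (seq_len(dims[1]) - 1) * reference$spacing[1]
  ys <- reference$origin[2] + (seq_len(dims[2]) - 1) * reference$spacing[2]
  pts <- cbind(rep(xs, times = dims[2]), rep(ys, each = dims[1]))
  src <- apply_transform(pts, invert_transform(tf))
  ix <- round((src[, 1] - mask$origin[1]) / mask$spacing[1]) + 1
  iy <- round((src[, 2] - mask$origin[2]) / mask$spacing[2]) + 1
  ok <- ix >= 1 & ix <= nrow(mask$pixels) & iy >= 1 & iy <= ncol(mask$pixels)
  vals <- logical(nrow(pts))
  vals[ok] <- mask$pixels[cbind(ix[ok], iy[ok])]
  binary_mask(matrix(vals, dims[1], dims[2]),
              spacing = reference$spacing, origin = reference$origin)
}

#' Targeting error of a focus against a segmented region
#'
#' Euclidean distance between the focus position and the region centroid.
#'
#' @param focus Position (mm), length 2.
#' @param region Non-empty [binary_mask()].
#' @param location_index Optional stop index for bookkeeping.
#' @return Object of class `targeting_record`: `location_index`, `focus`,
#'   `region_centroid`, `error` (mm).
#' @export
targeting_error <- function(focus, region, location_index = NA_integer_) {
  ctr <- component_centroid(region)
  structure(list(location_index = location_index, focus = as.numeric(focus),
                 region_centroid = ctr,
                 error = sqrt(sum((as.numeric(focus) - ctr)^2))),
            class = "targeting_record")
}

#' Otsu segmentation restricted to a region
#'
#' Computes the Otsu threshold from the intensity histogram of the pixels
#' inside `region` only (Otsu depends on the histogram alone), then keeps
#' the bright or dark class within the region. Used e.g. to delineate the
#' echogenic clot inside the anechoic lumen, where a global threshold is
#' dominated by the wall and background classes.
#'
#' @param image A [grayscale_image()].
#' @param region A [binary_mask()] on the same geometry.
#' @param polarity Keep the `"bright"` or `"dark"` class.
#' @param cleanup,min_size As for [otsu_mask()].
#' @return A [binary_mask()].
#' @export
segment_within <- function(image, region, polarity = c("bright", "dark"),
                           cleanup = TRUE, min_size = 5L) {
  stopifnot(inherits(image, "grayscale_image"), inherits(region, "binary_mask"))
  polarity <- match.arg(polarity)
  if (!same_geometry(image, region))
    stop_histopam("image and region have mismatched geometry",
                  "histopam_grid_mismatch")
  v <- image$pixels[region$pixels]
  rng <- range(v)
  if (diff(rng) <= 0)
    stop_histopam("constant intensities inside the region",
                  "histopam_degenerate_histogram")
  # Otsu uses only the histogram, so the subset can be reshaped arbitrarily
  thr <- EBImage::otsu(EBImage::Image(matrix(c((v - rng[1]) / diff(rng)),
                                             ncol = 1)),
                       range = c(0, 1), levels = 256)
  norm <- (image$pixels - rng[1]) / diff(rng)
  keep <- if (polarity == "bright") norm > thr else norm <= thr
  keep <- keep & region$pixels
  if (cleanup) keep <- clean_mask(keep, min_size = min_size)
  binary_mask(keep, spacing = image$spacing, origin = image$origin)
}
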