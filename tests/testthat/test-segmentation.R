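# Segmentation and accuracy metrics: Otsu thresholding, centroids, Dice,
# Hausdorff (with an independent cross-check), fiducial registration and
# targeting error.

test_that("Otsu separates two-valued and bimodal images", {
  px <- matrix(0, 20, 20)
  px[6:15, 6:15] <- 255
  img <- grayscale_image(px, spacing = 0.5)
  m <- otsu_mask(img, "bright")
  expect_identical(m$pixels, px == 255)
  # bimodal with well-separated modes: threshold between them, >= 99% match
  set.seed(3)
  truth <- matrix(FALSE, 64, 64)
  truth[20:45, 12:50] <- TRUE
  vals <- ifelse(truth, rnorm(64 * 64, 200, 5), rnorm(64 * 64, 50, 5))
  img2 <- grayscale_image(matrix(vals, 64, 64), spacing = 0.1)
  m2 <- otsu_mask(img2, "bright")
  thr_raw <- attr(m2, "threshold") * diff(range(vals)) + min(vals)
  expect_gt(thr_raw, 65)
  expect_lt(thr_raw, 185)
  expect_gte(mean(m2$pixels == truth), 0.99)
  expect_error(otsu_mask(grayscale_image(matrix(7, 5, 5), 1)),
               class = "histopam_degenerate_histogram")
})

test_that("Otsu threshold is invariant to increasing affine rescaling", {
  set.seed(9)
  vals <- c(rnorm(500, 0.3, 0.05), rnorm(500, 0.7, 0.05))
  img_a <- grayscale_image(matrix(vals, 25, 40), spacing = 1)
  img_b <- grayscale_image(matrix(3.5 * vals + 11, 25, 40), spacing = 1)
  expect_identical(otsu_mask(img_a, "bright")$pixels,
                   otsu_mask(img_b, "bright")$pixels)
})

test_that("component centroid averages member-pixel world coordinates", {
  m1 <- mask_from_indices(c(10, 10), rbind(c(4, 8)), spacing = 1,
                          origin = c(0, 0))
  expect_equal(unname(component_centroid(m1)), c(3, 7))
  # L-tromino at 1 mm spacing: pixels (0,0), (1,0), (0,1) -> (1/3, 1/3)
  m2 <- mask_from_indices(c(5, 5), rbind(c(1, 1), c(2, 1), c(1, 2)))
  expect_equal(unname(component_centroid(m2)), c(1 / 3, 1 / 3))
  # filled disk centred at c recovers c within half a pixel
  disk <- binary_mask(
    outer((seq_len(41) - 21)^2, (seq_len(41) - 21)^2, `+`) <= 100,
    spacing = 0.5, origin = c(-5, -5))
  ctr <- component_centroid(disk)
  expect_lt(max(abs(ctr - c(5, 5))), 0.25)
  expect_error(component_centroid(mask_from_indices(c(3, 3), NULL)),
               class = "histopam_empty_mask")
})

test_that("Dice matches hand computations and satisfies its axioms", {
  A <- mask_from_indices(c(20, 20), which(matrix(seq_len(400) <= 100, 20),
                                          arr.ind = TRUE))
  B <- mask_from_indices(c(20, 20), which(matrix(seq_len(400) %in% 76:125,
                                                 20), arr.ind = TRUE))
  expect_equal(dice(A, B), 2 * 25 / 150)   # |A|=100, |B|=50, overlap 25
  expect_equal(dice(A, A), 1)
  expect_equal(dice(B, A), dice(A, B))     # symmetry
  disjoint <- mask_from_indices(c(20, 20),
                                which(matrix(seq_len(400) > 300, 20),
                                      arr.ind = TRUE))
  expect_equal(dice(A, disjoint), 0)
  expect_error(dice(mask_from_indices(c(20, 20), NULL),
                    mask_from_indices(c(20, 20), NULL)),
               class = "histopam_empty_mask")
  expect_error(dice(A, mask_from_indices(c(10, 10), rbind(c(1, 1)))),
               class = "histopam_grid_mismatch")
})

test_that("directed Hausdorff matches exhaustive examples and subsets", {
  # 1-D sets on a 1 mm grid: A = {0, 1}, B = {2, 3} -> h(A, B) = 2
  A <- mask_from_indices(c(6, 1), rbind(c(1, 1), c(2, 1)))
  B <- mask_from_indices(c(6, 1), rbind(c(3, 1), c(4, 1)))
  expect_equal(hausdorff(A, B), 2)
  expect_equal(hausdorff(B, A), 2)
  expect_equal(hausdorff(A, A), 0)
  # subset property: h(A, B) = 0 iff A within B
  AB <- mask_from_indices(c(6, 1), rbind(c(1, 1), c(2, 1), c(3, 1), c(4, 1)))
  expect_equal(hausdorff(A, AB), 0)
  expect_gt(hausdorff(AB, A), 0)
  expect_error(hausdorff(A, mask_from_indices(c(6, 1), NULL)),
               class = "histopam_empty_mask")
})

test_that("Hausdorff agrees with the independent pracma implementation", {
  skip_if_not_installed("pracma")
  set.seed(12)
  for (i in 1:5) {
    A <- mask_from_indices(c(15, 15),
                           cbind(sample(15, 25, TRUE), sample(15, 25, TRUE)),
                           spacing = 0.3)
    B <- mask_from_indices(c(15, 15),
                           cbind(sample(15, 25, TRUE), sample(15, 25, TRUE)),
                           spacing = 0.3)
    expect_equal(hausdorff(A, B, mode = "symmetric"),
                 pracma::hausdorff_dist(mask_coords(A), mask_coords(B)),
                 tolerance = 1e-12)
  }
})

test_that("fiducial registration recovers a known rigid transform", {
  pts <- rbind(c(0, 0), c(10, 2), c(4, 8), c(-3, 5))
  tf_true <- structure(list(rotation = 30 * pi / 180,
                            translation = c(2, -1), scale = 1, rms = 0),
                       class = "rigid_transform_2d")
  moved <- apply_transform(pts, tf_true)
  est <- register_fiducials(moved, pts)
  # estimated transform maps photo coordinates back to the planning frame
  back <- apply_transform(moved, est)
  expect_lt(max(abs(back - pts)), 1e-6)
  expect_equal(est$rotation, -tf_true$rotation, tolerance = 1e-6)
  expect_lt(est$rms, 1e-9)
  # identity case
  est0 <- register_fiducials(pts, pts)
  expect_equal(est0$rotation, 0, tolerance = 1e-12)
  expect_equal(unname(est0$translation), c(0, 0), tolerance = 1e-12)
  expect_error(register_fiducials(pts[1, , drop = FALSE],
                                  pts[1, , drop = FALSE]),
               class = "histopam_bad_fiducials")
})

test_that("registration residual stays within 1 mm under 0.5 mm jitter", {
  base <- rbind(c(0, 0), c(12, 0), c(6, 9))
  set.seed(31)
  for (i in 1:20) {
    jit <- matrix(rnorm(6, sd = 0.5), 3, 2)
    est <- register_fiducials(base + jit, base)
    expect_lte(est$rms, 1)
  }
})

test_that("similarity mode recovers an isotropic scale", {
  pts <- rbind(c(0, 0), c(8, 1), c(3, 6), c(-2, 4))
  tf <- structure(list(rotation = -0.4, translation = c(1, 2), scale = 1.3,
                       rms = 0), class = "rigid_transform_2d")
  moved <- apply_transform(pts, tf)
  est <- register_fiducials(moved, pts, scale = TRUE)
  expect_equal(est$scale, 1 / 1.3, tolerance = 1e-9)
  expect_lt(est$rms, 1e-9)
})

test_that("targeting error is the focus-centroid distance", {
  disk <- binary_mask(outer((seq_len(21) - 11)^2, (seq_len(21) - 11)^2,
                            `+`) <= 25, spacing = 1, origin = c(-10, -10))
  rec <- targeting_error(c(0, 0), disk)
  expect_equal(rec$error, 0, tolerance = 1e-9)
  rec2 <- targeting_error(c(3, 4), disk)
  expect_equal(rec2$error, 5, tolerance = 1e-9)
  rec3 <- targeting_error(c(0.35, 0), disk)
  expect_equal(rec3$error, 0.35, tolerance = 1e-9)
})

test_that("region-restricted Otsu isolates a mid-intensity structure", {
  # three-class image: dark interior, mid clot, bright wall
  truth <- phantom_truth(clot_center = c(0.5, 60.3))
  out <- make_vessel_image(truth, noise_sd = 0)
  clot_seg <- segment_within(out$image, out$truth$lumen_full_mask, "bright")
  ctr <- component_centroid(clot_seg)
  expect_lt(sqrt(sum((ctr - c(0.5, 60.3))^2)), 0.15)
})
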