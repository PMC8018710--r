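# On-disk containers: PNG images/masks with JSON sidecars carrying pixel
# geometry, CSV channel data and fiducials, JSON metric reports, YAML
# configuration blocks. All plain-text or PNG; geometry is always mm.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a binary mask as PNG with a JSON geometry sidecar
#'
#' @param mask A [binary_mask()].
#' @param path Output PNG path; the sidecar goes to the same stem `.json`.
#' @return `path`, invisibly (writer); a [binary_mask()] (reader).
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  # PNG rasters are row-major top-down; store transposed so that the PNG
  # x axis is the mask's first (azimuth) axis
  png::writePNG(t(mask$pixels * 1), path)
  jsonlite::write_json(list(spacing_mm = mask$spacing,
                            origin_mm = mask$origin, kind = "binary_mask"),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  binary_mask(t(px) > 0.5, spacing = meta$spacing_mm, origin = meta$origin_mm)
}

#' Write / read a grayscale image as PNG with a JSON geometry sidecar
#'
#' Intensities are clipped to `[0, 1]` on write.
#'
#' @param image A [grayscale_image()].
#' @param path Output PNG path.
#' @return `path`, invisibly (writer); a [grayscale_image()] (reader).
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "grayscale_image"))
  png::writePNG(t(pmin(pmax(image$pixels, 0), 1)), path)
  jsonlite::write_json(list(spacing_mm = image$spacing,
                            origin_mm = image$origin,
                            kind = "grayscale_image"),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  grayscale_image(t(px), spacing = meta$spacing_mm, origin = meta$origin_mm)
}

#' Write / read RF channel data as CSV
#'
#' Toy-scale plain-text container: one row per element, one column per time
#' sample, with the sampling rate and clock origin in a JSON sidecar.
#'
#' @param data A [channel_data()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a [channel_data()] (reader).
#' @export
write_channel_csv <- function(data, path) {
  stopifnot(inherits(data, "channel_data"))
  write.table(data$samples, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(list(sampling_rate_hz = data$sampling_rate,
                            t0_s = data$t0, frame_id = data$frame_id),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channel_csv
#' @export
read_channel_csv <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  samples <- as.matrix(read.csv(path, header = FALSE))
  dimnames(samples) <- NULL
  channel_data(samples, sampling_rate = meta$sampling_rate_hz,
               t0 = meta$t0_s, frame_id = meta$frame_id)
}

#' Write / read fiducial coordinates as CSV (label, x_mm, y_mm)
#'
#' @param fiducials Data frame with columns `label`, `x_mm`, `y_mm`.
#' @param path CSV path.
#' @return `path`, invisibly (writer); a data frame (reader).
#' @export
write_fiducials_csv <- function(fiducials, path) {
  stopifnot(all(c("label", "x_mm", "y_mm") %in% names(fiducials)))
  write.csv(fiducials[c("label", "x_mm", "y_mm")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiducials_csv
#' @export
read_fiducials_csv <- function(path) read.csv(path)

#' Write a power map or pressure field with a JSON sidecar
#'
#' The array goes to CSV (first axis in rows), the grid to a JSON sidecar.
#'
#' @param map A `power_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "power_map"))
  write.table(map$power, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(list(azimuth_mm = map$grid$azimuth,
                            range_mm = map$grid$range,
                            frames_averaged = map$frames_averaged,
                            beamformer = map$beamformer),
                       sidecar_path(path), digits = NA)
  invisible(path)
}

#' Read a YAML configuration block
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

# Stable short hash of a configuration list (provenance field in reports).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(config, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}
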