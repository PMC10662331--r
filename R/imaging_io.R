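#' Two-channel image containers
#'
#' `channel_image()` wraps a single 2-D intensity plane (rows = y, columns =
#' x) together with its pixel size; `image_stack()` wraps a 4-D voxel array
#' ordered `(z, channel, y, x)`. Both are plain lists with a class attribute;
#' all downstream measurements run on `channel_image` objects obtained by
#' maximum projection.
#'
#' @param pixels Numeric matrix of non-negative finite intensities.
#' @param pixel_size_um Pixel edge length in micrometres (isotropic in x/y).
#' @param channel_name Label for the channel (e.g. `"dapi"`, `"paint"`).
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size_um, channel_name = "unknown") {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    abort("`pixels` must be a non-empty matrix.", class = "chromterr_error")
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    abort("Channel intensities must be finite and >= 0.",
          class = "chromterr_error")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.",
          class = "chromterr_error")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel_name = channel_name),
    class = "channel_image"
  )
}

#' @rdname channel_image
#' @param voxels 4-D numeric array ordered `(z, channel, y, x)`.
#' @param channel_names Character vector naming each channel slot; must
#'   include `"dapi"` and `"paint"`.
#' @export
image_stack <- function(voxels, channel_names, pixel_size_um) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L) {
    abort("`voxels` must be a 4-D array (z, channel, y, x).",
          class = "chromterr_error")
  }
  if (dim(voxels)[1] < 1L) {
    abort("Stack needs at least one z slice.", class = "chromterr_error")
  }
  if (length(channel_names) != dim(voxels)[2]) {
    abort("`channel_names` length must match the channel dimension.",
          class = "chromterr_error")
  }
  if (!all(c("dapi", "paint") %in% channel_names)) {
    abort("Channels must include both \"dapi\" and \"paint\".",
          class = "chromterr_error")
  }
  if (pixel_size_um <= 0) {
    abort("`pixel_size_um` must be > 0.", class = "chromterr_error")
  }
  structure(
    list(voxels = voxels, channel_names = channel_names,
         pixel_size_um = pixel_size_um),
    class = "image_stack"
  )
}

#' Read a multi-page TIFF as a two-channel z-stack
#'
#' Pages are assumed channel-interleaved: page `(z - 1) * n_channels + c + 1`
#' holds z-slice `z` of 0-based channel index `c` (the layout written by
#' [generate_cohort()]). Intensities are rescaled from the TIFF's `[0, 1]`
#' storage convention back to 16-bit counts.
#'
#' @param path TIFF file path.
#' @param channel_map Named list/vector of 0-based channel indices, e.g.
#'   `list(dapi = 0, paint = 1)`.
#' @param pixel_size_um Pixel size in micrometres (TIFF exports rarely carry
#'   reliable resolution tags, so it is an explicit input).
#' @param n_channels Number of interleaved channels in the file.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map = list(dapi = 0, paint = 1),
                       pixel_size_um, n_channels = 2L) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "chromterr_io_error")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]      # collapse grayscale-as-RGB
    if (length(dim(p)) != 2L) {
      abort("TIFF pages must be 2-D planes.", class = "chromterr_io_error")
    }
    round(p * 65535)
  })
  n_pages <- length(pages)
  if (n_pages %% n_channels != 0L) {
    abort("Page count is not a multiple of `n_channels`.",
          class = "chromterr_io_error")
  }
  idx <- vapply(channel_map, as.integer, integer(1))
  if (any(idx < 0L) || any(idx >= n_channels)) {
    abort("channel index out of range for this file.",
          class = "chromterr_io_error")
  }
  nz <- n_pages %/% n_channels
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  vox <- array(0, dim = c(nz, length(idx), h, w))
  for (z in seq_len(nz)) {
    for (ci in seq_along(idx)) {
      vox[z, ci, , ] <- pages[[(z - 1L) * n_channels + idx[ci] + 1L]]
    }
  }
  image_stack(vox, channel_names = names(channel_map),
              pixel_size_um = pixel_size_um)
}

#' Maximum-intensity projection of one channel
#'
#' Collapses the z axis by taking, at every (y, x) position, the maximum
#' intensity across slices of the named channel. All downstream analysis
#' runs on these 2-D projections.
#'
#' @param stack An [image_stack()].
#' @param channel Channel label present in `stack$channel_names`.
#' @return A [channel_image()].
#' @export
max_project <- function(stack, channel) {
  ci <- match(channel, stack$channel_names)
  if (is.na(ci)) {
    abort(paste0("unknown channel: ", channel), class = "chromterr_error")
  }
  planes <- stack$voxels[, ci, , , drop = FALSE]
  proj <- apply(planes, c(3, 4), max)
  channel_image(proj, stack$pixel_size_um, channel_name = channel)
}

#' Write a measurement table to CSV
#'
#' Writes one row per record at full floating-point precision after checking
#' that all required columns are present, so downstream re-reads reproduce
#' every numeric field bit-identically.
#'
#' @param records A data frame of per-nucleus or per-territory measurements.
#' @param path Output CSV path.
#' @param required_cols Character vector of columns that must be present.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path,
                               required_cols = c("scene", "nucleus")) {
  missing_cols <- setdiff(required_cols, names(records))
  if (length(missing_cols) > 0L) {
    abort(paste0("records are missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "chromterr_schema_error")
  }
  readr::write_csv(as_tibble(records), path)
  invisible(path)
}
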