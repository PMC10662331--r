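#' Nuclear shape descriptors from a binary mask
#'
#' Fits the intensity-equivalent ellipse of the binary mask from its second
#' central moments: the full axis lengths are `4 * sqrt(eigenvalue)` of the
#' moment (covariance) matrix, the convention used by standard cell-image
#' morphometry tools. The centroid is the unweighted mask centroid;
#' eccentricity is `sqrt(1 - (minor/major)^2)`; orientation is the angle of
#' the major axis in the mathematical convention (counter-clockwise from +x,
#' with y up), folded to `[0, 180)`.
#'
#' @param mask Logical (or 0/1) matrix, rows = y (down), columns = x.
#' @param pixel_size_um Pixel size in micrometres.
#' @return One-row tibble: `centroid_x`, `centroid_y` (px), `area_px`,
#'   `area_um2`, `major_um`, `minor_um`, `eccentricity`, `orientation_deg`.
#' @export
nucleus_morphometry <- function(mask, pixel_size_um) {
  px <- which(mask != 0, arr.ind = TRUE)
  if (nrow(px) == 0L) {
    abort("empty mask.", class = "chromterr_error")
  }
  y <- px[, 1]; x <- px[, 2]
  cx <- mean(x); cy <- mean(y)
  # mathematical y axis points up: flip the image row coordinate
  u <- x - cx; v <- -(y - cy)
  cxx <- mean(u * u); cyy <- mean(v * v); cxy <- mean(u * v)
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  major_px <- 4 * sqrt(lam[1])
  minor_px <- 4 * sqrt(lam[2])
  vec <- e$vectors[, 1]
  orientation <- (atan2(vec[2], vec[1]) * 180 / pi) %% 180
  ecc <- if (major_px > 0) sqrt(max(0, 1 - (minor_px / major_px)^2)) else 0
  tibble(
    centroid_x = cx, centroid_y = cy,
    area_px = nrow(px),
    area_um2 = nrow(px) * pixel_size_um^2,
    major_um = major_px * pixel_size_um,
    minor_um = minor_px * pixel_size_um,
    eccentricity = ecc,
    orientation_deg = orientation
  )
}

#' Territory count and fragmentation class of a nucleus
#'
#' The fragmentation score of a nucleus is the number of detected paint
#' signals (territories) of one chromosome assigned to it; nuclei are
#' dichotomised into those with two or fewer detectable signals and those
#' with more than two (fragmentation and/or aneuploidy).
#'
#' @param assignments Tibble from [assign_to_nuclei()].
#' @param nucleus Nucleus label (must exist in the segmentation that
#'   produced `assignments`; pass `known_nuclei` to validate).
#' @param known_nuclei Optional vector of valid nucleus labels.
#' @return One-row tibble: `nucleus`, `fragmentation_score`,
#'   `fragmentation_class` (`"<=2"` or `">2"`).
#' @export
fragmentation_score <- function(assignments, nucleus, known_nuclei = NULL) {
  if (!is.null(known_nuclei) && !nucleus %in% known_nuclei) {
    abort(paste0("unknown nucleus label: ", nucleus),
          class = "chromterr_error")
  }
  score <- sum(!is.na(assignments$parent_nucleus) &
                 assignments$parent_nucleus == nucleus)
  tibble(nucleus = as.integer(nucleus),
         fragmentation_score = as.integer(score),
         fragmentation_class = if (score <= 2L) "<=2" else ">2")
}
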