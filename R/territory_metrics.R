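#' Fraction of the nucleus occupied by a chromosome's territories
#'
#' Union area of the territory masks divided by the nucleus area;
#' overlapping territory pixels are counted once, since the measure is the
#' area of the nucleus occupied.
#'
#' @param territory_masks List of logical matrices (may be empty).
#' @param nucleus_mask Logical matrix.
#' @return Fraction in `[0, 1]`.
#' @export
area_occupancy <- function(territory_masks, nucleus_mask) {
  n_nuc <- sum(nucleus_mask != 0)
  if (n_nuc == 0L) abort("empty nucleus mask.", class = "chromterr_error")
  if (length(territory_masks) == 0L) return(0)
  union_mask <- Reduce(`|`, lapply(territory_masks, function(m) m != 0))
  sum(union_mask & (nucleus_mask != 0)) / n_nuc
}

#' Territory-to-nucleus DAPI density ratio
#'
#' `r_fragment` = median DAPI intensity over the territory pixels divided by
#' the median over all nucleus pixels — a per-object DNA-density measure
#' that cancels non-biological intensity variation (illumination,
#' acquisition time), and is invariant to rescaling the DAPI channel.
#'
#' @param dapi A [channel_image()] or intensity matrix.
#' @param territory_mask,nucleus_mask Logical matrices.
#' @return One-row tibble: `r_fragment`.
#' @export
density_ratio <- function(dapi, territory_mask, nucleus_mask) {
  img <- if (inherits(dapi, "channel_image")) dapi$pixels else dapi
  tm <- territory_mask != 0
  nm <- nucleus_mask != 0
  if (!any(tm) || !any(nm)) {
    abort("territory and nucleus masks must be non-empty.",
          class = "chromterr_error")
  }
  nuc_med <- median(img[nm])
  if (nuc_med <= 0) {
    abort("undefined ratio: zero nuclear median DAPI.",
          class = "chromterr_degenerate_error")
  }
  tibble(r_fragment = median(img[tm]) / nuc_med)
}

#' Axial angle and class of a territory
#'
#' The angle theta between the undirected nuclear major-axis line and the
#' vector from the nuclear centroid to the territory centroid, folded to
#' `[0, 180)`. Territories with theta <= 45 or theta >= 135 degrees are
#' major-parallel (within 45 degrees of the major-axis line); those with
#' 45 < theta < 135 are minor-parallel. Both boundaries classify
#' major-parallel.
#'
#' @param territory_centroid,nucleus_centroid Numeric `(x, y)` in pixel
#'   coordinates (y down).
#' @param orientation_deg Major-axis orientation from
#'   [nucleus_morphometry()] (mathematical convention, degrees).
#' @return One-row tibble: `theta_deg`, `axial_class`, `undefined_angle`.
#' @export
axial_angle <- function(territory_centroid, nucleus_centroid,
                        orientation_deg) {
  dx <- territory_centroid[1] - nucleus_centroid[1]
  dy <- territory_centroid[2] - nucleus_centroid[2]
  if (dx == 0 && dy == 0) {
    return(tibble(theta_deg = NA_real_, axial_class = NA_character_,
                  undefined_angle = TRUE))
  }
  vec_angle <- (atan2(-dy, dx) * 180 / pi) %% 180   # y flipped: math convention
  theta <- (vec_angle - orientation_deg) %% 180
  tibble(theta_deg = theta,
         axial_class = classify_axial(theta),
         undefined_angle = FALSE)
}

#' @rdname axial_angle
#' @param theta_deg Angle(s) in `[0, 180)`.
#' @return `classify_axial()`: character vector, `"major_parallel"` or
#'   `"minor_parallel"`.
#' @export
classify_axial <- function(theta_deg) {
  ifelse(theta_deg <= 45 | theta_deg >= 135,
         "major_parallel", "minor_parallel")
}

#' Per-cell axial classification
#'
#' Normal scheme (diploid cells, exactly two homologs): `"both_minor"` iff
#' both territories are minor-parallel, else `"one_plus_major"`. Tumor
#' scheme (fragmented / aneuploid signals): `">=50%_major"` iff at least
#' half of the measured territories are major-parallel, else
#' `"<50%_major"`.
#'
#' @param axial_classes Character vector of per-territory classes
#'   (`"major_parallel"` / `"minor_parallel"`).
#' @param scheme `"normal"` or `"tumor"`.
#' @return One-row tibble: `scheme`, `cell_axial_class`, `n_major`, `n`.
#' @export
classify_cell <- function(axial_classes, scheme = c("normal", "tumor")) {
  scheme <- match.arg(scheme)
  axial_classes <- axial_classes[!is.na(axial_classes)]
  n <- length(axial_classes)
  if (n < 1L) abort("need >= 1 axial measurement.", class = "chromterr_error")
  n_major <- sum(axial_classes == "major_parallel")
  if (scheme == "normal") {
    if (n != 2L) {
      abort("normal scheme expects exactly 2 measurements.",
            class = "chromterr_scheme_error")
    }
    cls <- if (n_major == 0L) "both_minor" else "one_plus_major"
  } else {
    cls <- if (n_major / n >= 0.5) ">=50%_major" else "<50%_major"
  }
  tibble(scheme = scheme, cell_axial_class = cls,
         n_major = as.integer(n_major), n = as.integer(n))
}

#' Distance between two homologous territory centroids
#'
#' @param c1,c2 Centroids `(x, y)` in pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @return Euclidean distance in micrometres.
#' @export
inter_territory_distance <- function(c1, c2, pixel_size_um) {
  sqrt(sum((c1 - c2)^2)) * pixel_size_um
}

#' Angle subtended at the nuclear centroid by two territories
#'
#' @param c1,c2 Territory centroids `(x, y)`.
#' @param nucleus_centroid Nuclear centroid `(x, y)`.
#' @return One-row tibble: `angle_deg` in `[0, 180]`, `undefined_angle`.
#' @export
inter_territory_angle <- function(c1, c2, nucleus_centroid) {
  v1 <- c1 - nucleus_centroid
  v2 <- c2 - nucleus_centroid
  if (all(v1 == 0) || all(v2 == 0)) {
    return(tibble(angle_deg = NA_real_, undefined_angle = TRUE))
  }
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  tibble(angle_deg = acos(pmin(pmax(cosang, -1), 1)) * 180 / pi,
         undefined_angle = FALSE)
}
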