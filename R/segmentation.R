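#' Connected-component size and border filters
#'
#' Applies the retention predicates used for nuclei and territories:
#' a component is retained iff `min_area <= area <= max_area` (inclusive
#' bounds, "between 100 and 10,000 pixel") and, when `exclude_border` is
#' set, no pixel lies on the image frame edge.
#'
#' @param labels Integer label matrix (0 = background), e.g. from
#'   `EBImage::bwlabel`.
#' @param min_area,max_area Inclusive pixel-count bounds.
#' @param exclude_border Drop components touching the frame edge?
#' @return Tibble with one row per component: `label`, `area_px`,
#'   `touches_border`, `retained`, `reason` (`NA` when retained).
#' @export
filter_components <- function(labels, min_area = 0L, max_area = Inf,
                              exclude_border = FALSE) {
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (length(ids) == 0L) {
    return(tibble(label = integer(), area_px = integer(),
                  touches_border = logical(), retained = logical(),
                  reason = character()))
  }
  areas <- tabulate(labels, nbins = max(ids))[ids]
  edge <- c(labels[1, ], labels[nrow(labels), ],
            labels[, 1], labels[, ncol(labels)])
  border_ids <- setdiff(unique(as.integer(edge)), 0L)
  touches <- ids %in% border_ids
  reason <- rep(NA_character_, length(ids))
  reason[areas > max_area] <- "too_large"
  reason[areas < min_area] <- "too_small"
  if (exclude_border) reason[touches & is.na(reason)] <- "touches_border"
  tibble(label = ids, area_px = as.integer(areas),
         touches_border = touches, retained = is.na(reason),
         reason = reason)
}

#' Segment nuclei from a DAPI projection
#'
#' Pipeline: (1) non-local-means smoothing to normalise staining;
#' (2) Kapur maximum-entropy threshold; (3) morphological closing with a
#' radius-2 disc (a 2-pixel dilation followed by a 2-pixel erosion, undoing
#' boundary nibbling from the normalisation); (4) connected-component
#' labelling; (5) exclusion of components larger than `max_area` pixels or
#' touching the image boundary (and, by default, debris below `min_area`).
#'
#' @param dapi A [channel_image()] of the DAPI channel.
#' @param params List of overrides: `nlm_patch_radius` (1),
#'   `nlm_search_radius` (3), `nlm_h` (auto), `close_radius` (2),
#'   `min_area` (500; set 0 to disable), `max_area` (10000),
#'   `n_bins` (256).
#' @return Object of class `ct_segmentation`: list with `labels` (retained
#'   components relabelled 1..K), `info` (tibble from
#'   [filter_components()] over all components), `threshold`.
#' @export
segment_nuclei <- function(dapi, params = list()) {
  p <- utils::modifyList(
    list(nlm_patch_radius = 1L, nlm_search_radius = 3L, nlm_h = NULL,
         close_radius = 2L, min_area = 500L, max_area = 10000L,
         n_bins = 256L),
    params)
  smooth <- nlm_denoise(dapi$pixels, p$nlm_patch_radius,
                        p$nlm_search_radius, p$nlm_h)
  thr <- kapur_threshold_image(smooth, n_bins = p$n_bins)
  mask <- smooth > thr
  if (p$close_radius > 0) {
    brush <- EBImage::makeBrush(2L * p$close_radius + 1L, shape = "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0.5
  }
  labels <- ebi_label(mask)
  info <- filter_components(labels, min_area = p$min_area,
                            max_area = p$max_area, exclude_border = TRUE)
  structure(
    list(labels = relabel_retained(labels, info), info = info,
         threshold = thr),
    class = "ct_segmentation")
}

#' Segment chromosome-paint territories
#'
#' Pipeline: (1) median filter over a 2-pixel radius to even out paint
#' staining; (2) Kapur threshold computed from the histogram of pixels
#' inside the nuclear-mask union (confining the threshold to nuclear
#' signal); (3) connected components; (4) retention of components with
#' area between 100 and 10,000 pixels inclusive.
#'
#' @param paint A [channel_image()] of the paint channel.
#' @param nuclei Optional `ct_segmentation` of nuclei; when given, the
#'   threshold histogram is restricted to the nuclear-mask union.
#' @param params Overrides: `median_radius` (2), `min_area` (100),
#'   `max_area` (10000), `n_bins` (256).
#' @return A `ct_segmentation` (territory labels are not border-filtered).
#' @export
segment_territories <- function(paint, nuclei = NULL, params = list()) {
  p <- utils::modifyList(
    list(median_radius = 2L, min_area = 100L, max_area = 10000L,
         n_bins = 256L),
    params)
  img <- paint$pixels
  if (p$median_radius > 0) {
    top <- max(img, 1)
    f <- EBImage::medianFilter(t(img) / top, p$median_radius)
    img <- t(as.matrix(f)) * top
  }
  restrict <- NULL
  if (!is.null(nuclei)) {
    restrict <- nuclei$labels > 0
    if (!any(restrict)) restrict <- NULL
  }
  thr <- kapur_threshold_image(img, restrict = restrict, n_bins = p$n_bins)
  labels <- ebi_label(img > thr)
  info <- filter_components(labels, min_area = p$min_area,
                            max_area = p$max_area, exclude_border = FALSE)
  structure(
    list(labels = relabel_retained(labels, info), info = info,
         threshold = thr),
    class = "ct_segmentation")
}

#' Assign territories to parent nuclei
#'
#' A territory belongs to the nucleus containing its centroid pixel; if the
#' centroid falls in background, it is assigned to the nucleus holding the
#' largest share of its pixels provided that share is at least 50%,
#' otherwise it is left unassigned and flagged (unassigned territories are
#' excluded downstream).
#'
#' @param territories,nuclei `ct_segmentation` objects on congruent frames.
#' @return Tibble: `territory`, `parent_nucleus` (`NA` if unassigned),
#'   `assign_method` (`"centroid"`, `"majority"`, `NA`), `flagged`.
#' @export
assign_to_nuclei <- function(territories, nuclei) {
  tl <- territories$labels
  nl <- nuclei$labels
  ids <- setdiff(sort(unique(as.integer(tl))), 0L)
  if (length(ids) == 0L) {
    return(tibble(territory = integer(), parent_nucleus = integer(),
                  assign_method = character(), flagged = logical()))
  }
  rows <- lapply(ids, function(id) {
    px <- which(tl == id, arr.ind = TRUE)
    cy <- round(mean(px[, 1])); cx <- round(mean(px[, 2]))
    parent <- nl[cy, cx]
    if (parent > 0L) {
      return(tibble(territory = id, parent_nucleus = as.integer(parent),
                    assign_method = "centroid", flagged = FALSE))
    }
    under <- nl[px]
    under <- under[under > 0L]
    if (length(under) > 0L) {
      tab <- table(under)
      share <- max(tab) / nrow(px)
      if (share >= 0.5) {
        return(tibble(territory = id,
                      parent_nucleus = as.integer(names(tab)[which.max(tab)]),
                      assign_method = "majority", flagged = FALSE))
      }
    }
    tibble(territory = id, parent_nucleus = NA_integer_,
           assign_method = NA_character_, flagged = TRUE)
  })
  bind_rows(rows)
}

# --- internal helpers -------------------------------------------------------

# EBImage works column-major with x as the first dimension; our matrices are
# (y, x). bwlabel is orientation-agnostic, so transpose in and out.
ebi_label <- function(mask) {
  t(as.matrix(EBImage::bwlabel(t(mask * 1))))
}

relabel_retained <- function(labels, info) {
  keep <- info$label[info$retained]
  map <- integer(max(c(0L, info$label)) + 1L)
  map[keep + 1L] <- seq_along(keep)
  out <- matrix(map[labels + 1L], nrow(labels), ncol(labels))
  storage.mode(out) <- "integer"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the mask of one labelled object
#' @param seg A `ct_segmentation` or integer label matrix.
#' @param id Label id.
#' @return Logical matrix.
#' @export
mask_of <- function(seg, id) {
  labels <- if (inherits(seg, "ct_segmentation")) seg$labels else seg
  labels == id
}
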