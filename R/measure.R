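#' Measure one two-channel scene
#'
#' Runs the full measurement chain on a DAPI/paint projection pair:
#' nuclear and territory segmentation, territory-to-nucleus assignment,
#' nuclear morphometry, six-ring radial partition with paint-signal
#' fractions and DAPI ring means, and per-territory metrics (axial angle
#' and class, density ratio, area), rolled up into per-nucleus summaries
#' (occupancy, fragmentation, inter-territory distance/angle, per-cell
#' axial class).
#'
#' @param dapi,paint [channel_image()]s of the two channels.
#' @param params List of segmentation overrides (see [segment_nuclei()],
#'   [segment_territories()]); the key `scheme` (`"normal"` or `"tumor"`,
#'   default `"tumor"`) selects the per-cell classification rule, with
#'   `"normal"` applied only to nuclei carrying exactly two territories.
#' @param n_rings Number of concentric rings.
#' @return List of tibbles: `nuclei` (one row per retained nucleus, with
#'   ring fraction columns `ring1..ringN`, DAPI means `dapi_ring1..N` and
#'   normalised `dapi_norm_ring1..N`), `territories` (one row per assigned
#'   territory), `exclusions` (objects dropped, with reason codes), and the
#'   two `ct_segmentation` objects.
#' @export
measure_scene <- function(dapi, paint, params = list(), n_rings = 6L) {
  scheme <- params$scheme %||% "tumor"
  params$scheme <- NULL
  nuc_seg <- segment_nuclei(dapi, params)
  ter_seg <- segment_territories(paint, nuclei = nuc_seg, params)
  assign_tab <- assign_to_nuclei(ter_seg, nuc_seg)

  exclusions <- bind_rows(
    mutate(filter(nuc_seg$info, !.data$retained), object = "nucleus"),
    mutate(filter(ter_seg$info, !.data$retained), object = "territory"),
    tibble(label = assign_tab$territory[assign_tab$flagged],
           area_px = NA_integer_, touches_border = NA,
           retained = FALSE, reason = "unassigned",
           object = "territory"))

  nuc_ids <- setdiff(sort(unique(as.integer(nuc_seg$labels))), 0L)
  px_um <- dapi$pixel_size_um

  territories <- list()
  nuclei <- list()
  for (nid in nuc_ids) {
    nmask <- nuc_seg$labels == nid
    # work on the nucleus bounding box (pad 2) -- identical results, since
    # retained nuclei never touch the frame, but far cheaper per nucleus
    bb <- which(nmask, arr.ind = TRUE)
    r1 <- max(1L, min(bb[, 1]) - 2L); r2 <- min(nrow(nmask), max(bb[, 1]) + 2L)
    c1 <- max(1L, min(bb[, 2]) - 2L); c2 <- min(ncol(nmask), max(bb[, 2]) + 2L)
    nmask_c <- nmask[r1:r2, c1:c2]
    dapi_c <- dapi$pixels[r1:r2, c1:c2]
    paint_c <- paint$pixels[r1:r2, c1:c2]

    shape <- nucleus_morphometry(nmask_c, px_um)
    shape$centroid_x <- shape$centroid_x + c1 - 1L
    shape$centroid_y <- shape$centroid_y + r1 - 1L
    ringmap <- ring_partition(nmask_c, n_rings = n_rings)
    t_ids <- assign_tab$territory[!is.na(assign_tab$parent_nucleus) &
                                    assign_tab$parent_nucleus == nid]
    t_masks <- lapply(t_ids,
                      function(tid) ter_seg$labels[r1:r2, c1:c2] == tid)
    frag <- fragmentation_score(assign_tab, nid)

    t_rows <- list()
    for (j in seq_along(t_ids)) {
      tm <- t_masks[[j]]
      tpx <- which(ter_seg$labels == t_ids[j], arr.ind = TRUE)
      cen <- c(mean(tpx[, 2]), mean(tpx[, 1]))
      ax <- axial_angle(cen, c(shape$centroid_x, shape$centroid_y),
                        shape$orientation_deg)
      dr <- density_ratio(dapi_c, tm & nmask_c, nmask_c)
      t_rows[[j]] <- tibble(
        nucleus = nid, territory = t_ids[j],
        area_px = nrow(tpx),
        centroid_x = cen[1], centroid_y = cen[2],
        theta_deg = ax$theta_deg, axial_class = ax$axial_class,
        undefined_angle = ax$undefined_angle,
        r_fragment = dr$r_fragment)
    }
    t_tab <- if (length(t_rows) > 0L) bind_rows(t_rows) else
      empty_territory_table()

    restrict <- if (length(t_masks) > 0L) Reduce(`|`, t_masks) else NULL
    prof <- signal_ring_fractions(paint_c, ringmap, restrict = restrict)
    dapi_prof <- dapi_ring_intensity(dapi_c, ringmap)

    occ <- area_occupancy(t_masks, nmask_c)
    inter_d <- NA_real_; inter_a <- NA_real_
    if (length(t_ids) == 2L) {
      c1 <- c(t_tab$centroid_x[1], t_tab$centroid_y[1])
      c2 <- c(t_tab$centroid_x[2], t_tab$centroid_y[2])
      inter_d <- inter_territory_distance(c1, c2, px_um)
      inter_a <- inter_territory_angle(
        c1, c2, c(shape$centroid_x, shape$centroid_y))$angle_deg
    }
    cls <- NA_character_
    ok_classes <- t_tab$axial_class[!is.na(t_tab$axial_class)]
    if (length(ok_classes) > 0L) {
      if (scheme == "normal") {
        if (length(ok_classes) == 2L) {
          cls <- classify_cell(ok_classes, "normal")$cell_axial_class
        }
      } else {
        cls <- classify_cell(ok_classes, "tumor")$cell_axial_class
      }
    }

    ring_w <- stats::setNames(as.list(prof$fraction),
                              paste0("ring", prof$ring))
    dapi_w <- stats::setNames(as.list(dapi_prof$mean_intensity),
                              paste0("dapi_ring", dapi_prof$ring))
    dapi_n <- stats::setNames(as.list(dapi_prof$norm_intensity),
                              paste0("dapi_norm_ring", dapi_prof$ring))
    nuclei[[length(nuclei) + 1L]] <- dplyr::bind_cols(
      tibble(nucleus = nid), shape, frag[, -1],
      tibble(occupancy_fraction = occ,
             inter_distance_um = inter_d, inter_angle_deg = inter_a,
             cell_axial_class = cls,
             profile_undefined = attr(prof, "undefined")),
      as_tibble(ring_w), as_tibble(dapi_w), as_tibble(dapi_n))
    territories[[length(territories) + 1L]] <- t_tab
  }
  territories_tab <- bind_rows(territories)
  if (nrow(territories_tab) == 0L) territories_tab <- empty_territory_table()
  list(nuclei = bind_rows(nuclei), territories = territories_tab,
       exclusions = exclusions, nucleus_segmentation = nuc_seg,
       territory_segmentation = ter_seg)
}

empty_territory_table <- function() {
  tibble(nucleus = integer(), territory = integer(), area_px = integer(),
         centroid_x = numeric(), centroid_y = numeric(),
         theta_deg = numeric(), axial_class = character(),
         undefined_angle = logical(), r_fragment = numeric())
}
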