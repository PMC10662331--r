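#' Kapur maximum-entropy threshold
#'
#' Selects the threshold level that maximises the sum of Shannon entropies of
#' the two intensity classes it induces (the Kapur-Sahoo-Wong criterion):
#' for a candidate level t splitting the histogram into classes
#' \eqn{A = \{levels \le t\}} and \eqn{B = \{levels > t\}} with masses
#' \eqn{P_A, P_B}, the criterion is
#' \deqn{H(t) = -\sum_{i \in A} \frac{p_i}{P_A}\log\frac{p_i}{P_A}
#'              -\sum_{i \in B} \frac{p_i}{P_B}\log\frac{p_i}{P_B}.}
#' Ties are broken toward the lower level.
#'
#' @param counts Non-negative histogram counts, one per intensity level.
#' @param levels Intensity values of the bins (default `0:(length-1)`).
#' @return The threshold level t; pixels with intensity `<= t` form the low
#'   class.
#' @export
kapur_threshold <- function(counts, levels = seq_along(counts) - 1) {
  if (length(counts) != length(levels)) {
    abort("`counts` and `levels` must have equal length.",
          class = "chromterr_error")
  }
  if (sum(counts > 0) < 2L) {
    abort("degenerate histogram: fewer than 2 nonzero bins.",
          class = "chromterr_degenerate_error")
  }
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  cp <- cumsum(p)
  cs <- cumsum(plogp)
  s_tot <- cs[length(cs)]
  # candidate split after bin i: both classes must have mass
  i <- seq_len(length(p) - 1L)
  pa <- cp[i]
  pb <- 1 - pa
  ok <- pa > 0 & pb > 0
  h <- rep(-Inf, length(i))
  h[ok] <- (log(pa[ok]) - cs[i][ok] / pa[ok]) +
    (log(pb[ok]) - (s_tot - cs[i][ok]) / pb[ok])
  levels[which.max(h)]
}

#' Histogram of an intensity image for thresholding
#'
#' Integer-valued images (the native case for microscopy counts) are binned
#' at unit width over their range; real-valued images fall back to `n_bins`
#' equal-width bins.
#'
#' @param pixels Numeric matrix or vector of intensities.
#' @param n_bins Bin count for non-integer data.
#' @return List with `counts` and `levels` (upper bin edges / integer
#'   values), suitable for [kapur_threshold()].
#' @export
intensity_histogram <- function(pixels, n_bins = 256L) {
  v <- as.numeric(pixels)
  v <- v[is.finite(v)]
  if (length(v) == 0L) {
    abort("no finite intensities.", class = "chromterr_error")
  }
  rng <- range(v)
  is_int <- all(v == round(v)) && diff(rng) <= 65535
  if (is_int) {
    levels <- seq(rng[1], rng[2])
    counts <- tabulate(v - rng[1] + 1, nbins = length(levels))
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    counts <- as.vector(table(cut(v, breaks, include.lowest = TRUE)))
    levels <- breaks[-1]
  }
  list(counts = counts, levels = levels)
}

#' Threshold an image with the Kapur criterion
#'
#' @inheritParams intensity_histogram
#' @param restrict Optional logical mask; when given, the histogram is built
#'   only from pixels inside the mask (used to confine the territory
#'   threshold to nuclear signal).
#' @return Threshold on the intensity scale; foreground is `pixels > t`.
#' @export
kapur_threshold_image <- function(pixels, restrict = NULL, n_bins = 256L) {
  v <- if (is.null(restrict)) pixels else pixels[restrict]
  h <- intensity_histogram(v, n_bins = n_bins)
  kapur_threshold(h$counts, h$levels)
}
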