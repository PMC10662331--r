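#' Random-positioning null models for axial orientation
#'
#' Probability that a territory positioned at random in the nucleus is
#' classified major-parallel (within 45 degrees of the major-axis line).
#' Three nulls are provided and reported side by side:
#' * `naive`: p_major = 0.5 (uniform angle, any shape);
#' * `ellipse_corrected`: a point uniform in an ellipse with semi-axes
#'   a >= b — correcting for the greater angular mass near the longer
#'   axis — giving in closed form, via the parametric-angle substitution
#'   for elliptical sector area, \deqn{p = \frac{2}{\pi}\arctan(a/b);}
#' * `empirical_mask`: Monte-Carlo over the actual nuclear mask pixels.
#'
#' @param a,b Semi-major and semi-minor axis (any common unit), `a >= b > 0`.
#' @return One-row tibble: `model`, `p_major`, `axis_ratio`, `se`
#'   (`NA` unless Monte-Carlo), `n_mc`.
#' @export
expected_major_fraction_ellipse <- function(a, b) {
  if (!is.finite(a) || !is.finite(b) || b <= 0 || a < b) {
    abort("need a >= b > 0.", class = "chromterr_error")
  }
  tibble(model = "ellipse_corrected",
         p_major = (2 / pi) * atan(a / b),
         axis_ratio = a / b, se = NA_real_, n_mc = NA_integer_)
}

#' @rdname expected_major_fraction_ellipse
#' @param mask Logical nuclear mask.
#' @param shape One-row tibble from [nucleus_morphometry()] (supplies the
#'   centroid and major-axis orientation).
#' @param n_mc Number of Monte-Carlo points (>= 100).
#' @param seed Integer seed for reproducibility.
#' @export
expected_major_fraction_mask <- function(mask, shape, n_mc = 1e5,
                                         seed = NULL) {
  if (n_mc < 100) abort("n_mc must be >= 100.", class = "chromterr_error")
  px <- which(mask != 0, arr.ind = TRUE)
  if (nrow(px) == 0L) abort("empty mask.", class = "chromterr_error")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  i <- sample.int(nrow(px), n_mc, replace = TRUE)
  # jitter within the pixel so the point process is continuous-uniform
  x <- px[i, 2] + runif(n_mc) - 0.5
  y <- px[i, 1] + runif(n_mc) - 0.5
  vec_angle <- (atan2(-(y - shape$centroid_y),
                      x - shape$centroid_x) * 180 / pi) %% 180
  theta <- (vec_angle - shape$orientation_deg) %% 180
  p <- mean(classify_axial(theta) == "major_parallel")
  tibble(model = "empirical_mask", p_major = p,
         axis_ratio = shape$major_um / shape$minor_um,
         se = sqrt(p * (1 - p) / n_mc), n_mc = as.integer(n_mc))
}

#' @rdname expected_major_fraction_ellipse
#' @return `naive_axial_null()`: the naive null (p_major = 0.5).
#' @export
naive_axial_null <- function() {
  tibble(model = "naive", p_major = 0.5, axis_ratio = NA_real_,
         se = NA_real_, n_mc = NA_integer_)
}

#' Expected per-cell class probability under a null
#'
#' Assumes homologs are positioned independently. Normal scheme:
#' P(both_minor) = (1 - p_major)^2. Tumor scheme: P(at least half of n
#' territories major) = P(Binomial(n, p_major) >= ceiling(n/2)).
#'
#' @param p_major Per-territory major-parallel probability in (0, 1)
#'   (degenerate 0/1 allowed for limit checks).
#' @param scheme `"normal"` or `"tumor"`.
#' @param n Number of territories per cell (normal requires 2).
#' @return Probability of the reference class (`both_minor` for normal,
#'   `>=50%_major` for tumor).
#' @export
expected_cell_class_probability <- function(p_major,
                                            scheme = c("normal", "tumor"),
                                            n = 2L) {
  scheme <- match.arg(scheme)
  if (p_major < 0 || p_major > 1) {
    abort("p_major must be in [0, 1].", class = "chromterr_error")
  }
  if (scheme == "normal") {
    if (n != 2L) {
      abort("normal scheme requires n = 2.", class = "chromterr_scheme_error")
    }
    return((1 - p_major)^2)
  }
  if (n < 1L) abort("n must be >= 1.", class = "chromterr_error")
  k <- ceiling(n / 2)
  sum(dbinom(k:n, n, p_major))
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
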