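#' Axis-symmetric axial-angle distribution
#'
#' Territory axial angles are drawn from a wrapped, axis-symmetric family:
#' a von Mises variate phi ~ vM(0, kappa) on the doubled angle, halved and
#' folded, so theta = (phi/2) mod 180 lies in `[0, 180)` and is symmetric
#' about the major-axis line. Concentration `kappa = 0` yields theta exactly
#' uniform on `[0, 180)`; `kappa -> Inf` collapses all mass onto the major
#' axis (theta in {0, 180}).
#'
#' @param n Number of draws.
#' @param kappa Concentration parameter (>= 0).
#' @return `sample_axial_angle()`: numeric vector of angles in degrees.
#' @export
sample_axial_angle <- function(n, kappa) {
  phi <- rvonmises(n, kappa)
  (phi / 2 * 180 / pi) %% 180
}

# Best-Fisher (1979) von Mises sampler, mean 0
rvonmises <- function(n, kappa) {
  if (kappa < 1e-12) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1))
    }
  }
  out
}

#' @rdname sample_axial_angle
#' @param p_major Target probability that a sampled angle is classified
#'   major-parallel (0.5 < p_major < 1; 0.5 maps to kappa 0).
#' @return `axial_concentration_for()`: the concentration kappa whose
#'   major-parallel probability equals `p_major`.
#' @export
axial_concentration_for <- function(p_major) {
  if (p_major < 0.5 || p_major >= 1) {
    abort("p_major must be in [0.5, 1).", class = "chromterr_error")
  }
  if (p_major == 0.5) return(0)
  uniroot(function(k) axial_major_probability(k) - p_major,
          lower = 1e-6, upper = 500, tol = 1e-10)$root
}

#' @rdname sample_axial_angle
#' @return `axial_major_probability()`: P(major-parallel) for a given
#'   concentration, \eqn{P(|\phi| \le \pi/2)} under vM(0, kappa) on the
#'   doubled angle.
#' @export
axial_major_probability <- function(kappa) {
  if (kappa < 1e-12) return(0.5)
  num <- stats::integrate(function(t) exp(kappa * cos(t)), -pi / 2, pi / 2,
                          rel.tol = 1e-12)$value
  den <- stats::integrate(function(t) exp(kappa * cos(t)), -pi, pi,
                          rel.tol = 1e-12)$value
  num / den
}
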