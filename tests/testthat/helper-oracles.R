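# Independent oracles and fixture builders (kept free of package internals).

# exhaustive-search Kapur criterion: double loop, no shared code with the
# package's vectorised implementation
brute_kapur <- function(counts, levels = seq_along(counts) - 1) {
  p <- counts / sum(counts)
  best <- -Inf; best_i <- NA
  for (i in 1:(length(p) - 1)) {
    pa <- sum(p[1:i]); pb <- 1 - pa
    if (pa <= 0 || pb <= 0) next
    qa <- p[1:i] / pa; qa <- qa[qa > 0]
    qb <- p[(i + 1):length(p)] / pb; qb <- qb[qb > 0]
    h <- -sum(qa * log(qa)) - sum(qb * log(qb))
    if (h > best) { best <- h; best_i <- i }
  }
  levels[best_i]
}

# two-sided minimum-likelihood binomial p-value by direct log-choose
# enumeration
enum_binom_p <- function(k, n, p0) {
  j <- 0:n
  logp <- lchoose(n, j) + j * log(p0) + (n - j) * log(1 - p0)
  pj <- exp(logp)
  min(1, sum(pj[pj <= pj[k + 1] * (1 + 1e-7)]))
}

# two-sided Fisher p-value by enumerating all tables with the observed
# margins via log-choose
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  xs <- lo:hi
  logp <- lchoose(c1, xs) + lchoose(n - c1, r1 - xs) - lchoose(n, r1)
  pj <- exp(logp)
  pobs <- exp(lchoose(c1, tab[1, 1]) + lchoose(n - c1, r1 - tab[1, 1]) -
                lchoose(n, r1))
  min(1, sum(pj[pj <= pobs * (1 + 1e-7)]))
}

# uniform points in an ellipse by rejection; classification by polar angle
mc_ellipse_major_fraction <- function(a, b, n = 1e6, seed = 1) {
  set.seed(seed)
  x <- numeric(0); y <- numeric(0)
  while (length(x) < n) {
    m <- ceiling((n - length(x)) / (pi / 4) * 1.05)
    cx <- runif(m, -a, a); cy <- runif(m, -b, b)
    keep <- (cx / a)^2 + (cy / b)^2 <= 1
    x <- c(x, cx[keep]); y <- c(y, cy[keep])
  }
  x <- x[1:n]; y <- y[1:n]
  theta <- (atan2(y, x) * 180 / pi) %% 180
  mean(theta <= 45 | theta >= 135)
}

# pixel-centre rasterised ellipse mask, independent of generate_nucleus
make_ellipse_mask <- function(h, w, cx, cy, a, b, phi_deg = 0) {
  phi <- phi_deg * pi / 180
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep(seq_len(h), times = w), h, w)
  u <- (x - cx) * cos(phi) - (y - cy) * sin(phi)
  v <- -(x - cx) * sin(phi) - (y - cy) * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

# one-nucleus scene with study-like intensities, used across tests
demo_scene <- function(seed = 7, noise = 12, dapi_contrast = 1.16,
                       kappa = 0, exponent = 1, n_territories = 2L,
                       area_fraction = 0.08, shape = c(150, 170),
                       a = 55, b = 34, orientation = 30,
                       bg_gradient = 0.15) {
  ns <- nucleus_spec(center = c(shape[2] / 2, shape[1] / 2),
                     semi_major_px = a, semi_minor_px = b,
                     orientation_deg = orientation,
                     dapi_gradient_exponent = exponent)
  ps <- placement_spec(n_territories = n_territories,
                       angular_concentration = kappa,
                       territory_area_fraction = area_fraction,
                       dapi_contrast = dapi_contrast)
  generate_scene(list(ns), list(ps), shape, noise_sigma = noise,
                 bg_gradient = bg_gradient, seed = seed)
}
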