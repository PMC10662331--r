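#' Exact binomial test of observed vs expected counts
#'
#' Two-sided exact binomial p-value by the minimum-likelihood method (the
#' convention of mainstream biostatistics software): the p-value is the sum
#' of P(X = j) over all outcomes j whose probability under the null does
#' not exceed that of the observed count k (with a 1e-7 relative tolerance
#' for floating-point ties), capped at 1.
#'
#' @param k Observed successes (0..n).
#' @param n Trials.
#' @param p0 Null success probability in (0, 1).
#' @return A `ct_test` object (see [tidy.ct_test()]).
#' @export
binomial_obs_vs_expected <- function(k, n, p0) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    abort("need integer 0 <= k <= n, n >= 1.", class = "chromterr_error")
  }
  if (p0 <= 0 || p0 >= 1) {
    abort("p0 must be in (0, 1).", class = "chromterr_error")
  }
  d <- dbinom(0:n, n, p0)
  p <- min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
  ct_test(statistic = k / n, p_value = p, test_name = "exact_binomial",
          n = n, estimate = k / n, null_value = p0)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing, over the hypergeometric distribution with
#' the observed margins, the probabilities of all tables no more likely
#' than the observed one (minimum-likelihood definition, 1e-7 relative
#' tie tolerance). A table with a zero margin carries no information and
#' returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return A `ct_test` object.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("need a 2x2 table of non-negative integers.",
          class = "chromterr_error")
  }
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); total <- sum(tab)
  if (total == 0 || r1 == 0 || r1 == total || c1 == 0 || c1 == total) {
    return(ct_test(statistic = NA_real_, p_value = 1,
                   test_name = "fisher_exact", n = total,
                   estimate = NA_real_, null_value = 1))
  }
  lo <- max(0, r1 + c1 - total); hi <- min(r1, c1)
  xs <- lo:hi
  d <- dhyper(xs, c1, total - c1, r1)
  d_obs <- dhyper(tab[1, 1], c1, total - c1, r1)
  p <- min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  ct_test(statistic = or, p_value = p, test_name = "fisher_exact",
          n = total, estimate = or, null_value = 1)
}

#' Welch's two-sample t-test
#'
#' Two-tailed t-test with Welch's correction (no equal-variance
#' assumption; Satterthwaite degrees of freedom), as used for all pairwise
#' comparisons of nuclear and territory measurements.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2.
#' @return A `ct_test` object with `df` recorded.
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs n >= 2.", class = "chromterr_error")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(ct_test(statistic = 0, p_value = 1, test_name = "welch_t",
                     n = length(group_a) + length(group_b),
                     estimate = 0, null_value = 0,
                     df = length(group_a) + length(group_b) - 2))
    }
    abort("zero variance in both groups.", class = "chromterr_error")
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  ct_test(statistic = unname(tt$statistic), p_value = tt$p.value,
          test_name = "welch_t", n = length(group_a) + length(group_b),
          estimate = unname(diff(rev(tt$estimate))), null_value = 0,
          df = unname(tt$parameter))
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; used to compare the
#' spread of nuclear characteristics across cell types on a common scale.
#'
#' @param values Numeric vector, n >= 2, nonzero mean.
#' @return The CV (dimensionless).
#' @export
coefficient_of_variation <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) abort("need n >= 2.", class = "chromterr_error")
  m <- mean(values)
  if (m == 0) abort("undefined CV: zero mean.", class = "chromterr_error")
  sd(values) / m
}

# --- test-result container --------------------------------------------------

ct_test <- function(statistic, p_value, test_name, n, estimate = NA_real_,
                    null_value = NA_real_, df = NA_real_) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(statistic = statistic, p_value = p_value, test_name = test_name,
         n = n, estimate = estimate, null_value = null_value, df = df),
    class = "ct_test")
}

#' @export
print.ct_test <- function(x, ...) {
  cat(sprintf("<%s>  statistic = %.4g, p = %.4g, n = %d\n",
              x$test_name, x$statistic, x$p_value, as.integer(x$n)))
  invisible(x)
}

#' Tidy a chromterr test result
#'
#' @param x A `ct_test` object.
#' @param ... Unused.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `estimate`,
#'   `null_value`, `df`, `n`.
#' @export
tidy.ct_test <- function(x, ...) {
  tibble(test = x$test_name, statistic = x$statistic, p_value = x$p_value,
         estimate = x$estimate, null_value = x$null_value, df = x$df,
         n = as.integer(x$n))
}

#' @rdname tidy.ct_test
#' @export
glance.ct_test <- function(x, ...) tidy(x)
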