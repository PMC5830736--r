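## Thin, contract-checked wrappers over the standard tests used to compare
## song and movement metrics, plus the arcsine-square-root transform.
## Proportions (SR, J') are variance-stabilized before the paired t; all
## movement comparisons are non-parametric. Sample sizes in this kind of
## study are ~9-11 dyads, so exact small-sample p-values are used wherever
## the data permit.

new_test_result <- function(test_name, statistic, p_two, p_one, n) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_two = p_two, p_one = p_one, n = n),
            class = "song_test_result")
}

#' @export
print.song_test_result <- function(x, ...) {
  cat(sprintf("%s (n = %s): statistic = %.4g, p (two-tailed) = %.4g, p (one-tailed) = %s\n",
              x$test_name, paste(x$n, collapse = "/"), x$statistic, x$p_two,
              if (is.na(x$p_one)) "NA" else sprintf("%.4g", x$p_one)))
  invisible(x)
}

#' Arcsine-square-root transform for proportions
#'
#' `asin(sqrt(p))`, in radians on \[0, pi/2\]; the standard
#' variance-stabilizing transform applied to switching rates and evenness
#' scores before parametric testing. Monotone increasing on \[0, 1\].
#'
#' @param p Proportion(s) in \[0, 1\].
#' @return Transformed value(s) in radians.
#' @export
arcsine_sqrt <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_validation("arcsine_sqrt requires proportions in [0, 1]")
  asin(sqrt(p))
}

#' Paired t-test
#'
#' Standard paired t on the differences `x - y`, pairs matched by singer.
#' Both the two-tailed p and a one-tailed p in a stated direction are
#' reported, because switching rate and evenness are conventional signals
#' whose direction of change cannot always be assumed a priori.
#'
#' @param x,y Paired numeric vectors of equal length (at least 3 pairs).
#' @param direction Direction of the one-tailed alternative for `x - y`.
#' @return A `song_test_result`.
#' @export
paired_t <- function(x, y, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop_validation("paired samples differ in length")
  if (length(x) < 3) stop_validation("paired t requires at least 3 pairs")
  d <- x - y
  if (sd(d) == 0)
    stop_degenerate("zero variance of paired differences")
  ht2 <- t.test(x, y, paired = TRUE)
  ht1 <- t.test(x, y, paired = TRUE, alternative = direction)
  new_test_result("paired t-test", ht2$statistic, ht2$p.value, ht1$p.value,
                  length(x))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares an observed sample against a (resampled) null sample via the
#' maximum ECDF difference D, with the asymptotic p-value (the null samples
#' here are large resampled distributions, where exact small-sample p-values
#' do not apply).
#'
#' @param observed,null_sample Numeric vectors (each at least 2 values).
#' @return A `song_test_result` (`p_one` is `NA`: one-sided KS alternatives
#'   concern stochastic ordering, not a mean shift, and are not used here).
#' @export
ks_two_sample <- function(observed, null_sample) {
  if (length(observed) < 2 || length(null_sample) < 2)
    stop_validation("K-S test requires at least 2 values per sample")
  ht <- suppressWarnings(ks.test(observed, null_sample, exact = FALSE))
  new_test_result("two-sample K-S test", ht$statistic, ht$p.value, NA_real_,
                  c(length(observed), length(null_sample)))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The reported statistic is
#' U for the first sample. The p-value is exact when the combined sample is
#' small (<= 20) and tie-free, otherwise the normal approximation with tie
#' and continuity correction is used.
#'
#' @param a,b Numeric vectors (combined length at least 4).
#' @param direction Direction of the one-tailed alternative for `a` versus
#'   `b` (`"less"`: `a` shifted below `b`).
#' @return A `song_test_result`.
#' @export
mann_whitney_u <- function(a, b, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (length(a) < 1 || length(b) < 1 || length(a) + length(b) < 4)
    stop_validation("Mann-Whitney requires n >= 1 per group, combined >= 4")
  if (length(unique(c(a, b))) == 1)
    stop_degenerate("all values tied in Mann-Whitney input")
  exact <- (length(a) + length(b) <= 20) && !anyDuplicated(c(a, b))
  ht2 <- suppressWarnings(wilcox.test(a, b, exact = exact))
  ht1 <- suppressWarnings(wilcox.test(a, b, exact = exact, alternative = direction))
  new_test_result("Mann-Whitney U test", ht2$statistic, ht2$p.value,
                  ht1$p.value, c(length(a), length(b)))
}

#' Wilcoxon signed-rank test
#'
#' Paired rank test on the differences `x - y`; zero differences are
#' dropped (at least 5 non-zero pairs are required). Exact p-values are
#' used when the retained sample is tie-free and small.
#'
#' @param x,y Paired numeric vectors.
#' @param direction Direction of the one-tailed alternative for `x - y`.
#' @return A `song_test_result`.
#' @export
wilcoxon_signed_rank <- function(x, y, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop_validation("paired samples differ in length")
  d <- x - y
  nz <- d[d != 0]
  if (length(nz) == 0)
    stop_degenerate("all paired differences are zero")
  if (length(nz) < 5)
    stop_validation("signed-rank test requires at least 5 non-zero differences")
  exact <- length(nz) <= 25 && !anyDuplicated(abs(nz))
  ht2 <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact))
  ht1 <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact,
                                      alternative = direction))
  new_test_result("Wilcoxon signed-rank test", ht2$statistic, ht2$p.value,
                  ht1$p.value, length(nz))
}
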