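# Agreement statistics between predicted and reference exposure:
# percent mean error, percent RMSE, Passing-Bablok regression and
# Bland-Altman limits of agreement.

check_pred_ref <- function(pred, ref) {
  if (length(pred) != length(ref)) {
    stop("`pred` and `ref` lengths differ", call. = FALSE)
  }
  if (any(ref <= 0)) {
    stop("reference values must be positive for percentage metrics",
         call. = FALSE)
  }
}

#' Percent mean error (bias)
#'
#' `mean((pred - ref) / ref) * 100`.
#'
#' @param pred Predicted values.
#' @param ref Reference values (all positive).
#' @return Bias in percent.
#' @export
percent_me <- function(pred, ref) {
  check_pred_ref(pred, ref)
  mean((pred - ref) / ref) * 100
}

#' Percent root mean squared error (precision)
#'
#' `sqrt(mean(((pred - ref) / ref)^2)) * 100`.
#'
#' @inheritParams percent_me
#' @return Precision in percent.
#' @export
percent_rmse <- function(pred, ref) {
  check_pred_ref(pred, ref)
  sqrt(mean(((pred - ref) / ref)^2)) * 100
}

#' Passing-Bablok regression
#'
#' The original rank-based procedure: all pairwise slopes
#' `(y_j - y_i) / (x_j - x_i)` are formed, slopes of exactly -1 and pairs
#' with equal x are discarded, and the slope is the shifted median with
#' offset K = number of slopes below -1. The intercept is the median of
#' `y - slope * x`. Confidence intervals are not computed.
#'
#' @param x Reference measurements.
#' @param y Comparison measurements.
#' @return A list with `slope`, `intercept` and `n_slopes`.
#' @export
passing_bablok <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("at least 3 points are required", call. = FALSE)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  defined <- dx != 0 | dy != 0
  slopes <- ifelse(dx == 0, Inf * sign(dy), dy / dx)[defined]
  slopes <- slopes[slopes != -1]
  slopes <- slopes[is.finite(slopes)]
  if (!length(slopes)) {
    stop("no defined pairwise slopes (all x equal?)", call. = FALSE)
  }
  s <- sort(slopes)
  nn <- length(s)
  k <- sum(s < -1)
  if (nn %% 2 == 1) {
    b <- s[(nn + 1) %/% 2 + k]
  } else {
    b <- 0.5 * (s[nn %/% 2 + k] + s[nn %/% 2 + 1 + k])
  }
  list(slope = b, intercept = stats::median(y - b * x), n_slopes = nn)
}

#' Bland-Altman analysis
#'
#' Raw differences `d = y - x`; bias is their mean and the limits of
#' agreement are `bias +/- 1.96 * sd(d)` (sample standard deviation).
#'
#' @param x Reference measurements.
#' @param y Comparison measurements.
#' @return A list with `bias`, `loa` (lower, upper), `sd`, `outliers`
#'   (logical flags outside the limits) and `outlier_count`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2) stop("at least 2 points are required", call. = FALSE)
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- c(bias - 1.96 * s, bias + 1.96 * s)
  flags <- d < loa[1] | d > loa[2]
  list(bias = bias, loa = loa, sd = s, outliers = flags,
       outlier_count = sum(flags))
}

#' Bundle of agreement statistics
#'
#' Convenience wrapper computing [percent_me()], [percent_rmse()],
#' [passing_bablok()] and [bland_altman()] for one predicted-vs-reference
#' comparison.
#'
#' @inheritParams percent_me
#' @return A list of class `agreement_stats`.
#' @export
agreement_stats <- function(pred, ref) {
  pb <- passing_bablok(ref, pred)
  ba <- bland_altman(ref, pred)
  structure(list(pct_me = percent_me(pred, ref),
                 pct_rmse = percent_rmse(pred, ref),
                 pb_slope = pb$slope, pb_intercept = pb$intercept,
                 ba_bias = ba$bias, ba_loa = ba$loa,
                 outlier_count = ba$outlier_count, n = length(pred)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Agreement over n = %d pairs\n", x$n))
  cat(sprintf("  %%ME %.2f, %%RMSE %.2f\n", x$pct_me, x$pct_rmse))
  cat(sprintf("  Passing-Bablok slope %.3f, intercept %.3f\n",
              x$pb_slope, x$pb_intercept))
  cat(sprintf("  Bland-Altman bias %.3f, limits [%.3f, %.3f], %d outside\n",
              x$ba_bias, x$ba_loa[1], x$ba_loa[2], x$outlier_count))
  invisible(x)
}
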