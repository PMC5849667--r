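#' Pairwise slopes for Passing-Bablok regression
#'
#' Enumerates the slopes \eqn{S_{ij} = (y_j - y_i)/(x_j - x_i)} over all point
#' pairs \eqn{i < j}. Pairs with identical x are degenerate and discarded;
#' slopes exactly equal to -1 are discarded by construction of the estimator
#' (they cannot be assigned a direction under the method's invariance
#' argument). The offset K counts retained slopes below -1 and shifts the
#' median so that the estimator is invariant to swapping the roles of the two
#' measurement methods.
#'
#' @param x,y Numeric vectors of paired measurements, same length, n >= 3.
#' @return A list with `slopes` (sorted ascending), `offset_k` (number of
#'   retained slopes < -1), `n` (points), `n_slopes` (slopes retained) and
#'   `n_discarded` (degenerate or exactly -1 pairs dropped).
#' @examples
#' pairwise_slopes(c(1, 2, 3), c(1, 2, 3))
#' @export
pairwise_slopes <- function(x, y) {
  check_pair_vectors(x, y, min_n = 3)
  n <- length(x)
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  i <- idx[, 1]
  j <- idx[, 2]
  dx <- x[j] - x[i]
  dy <- y[j] - y[i]
  keep <- dx != 0
  s <- dy[keep] / dx[keep]
  s <- s[s != -1]
  if (length(s) == 0L) {
    abort("All point pairs are degenerate; cannot fit Passing-Bablok.")
  }
  list(
    slopes = sort(s),
    offset_k = sum(s < -1),
    n = n,
    n_slopes = length(s),
    n_discarded = n * (n - 1) / 2 - length(s)
  )
}

# shifted median of sorted slopes; even counts average the two central
# order statistics
shifted_median <- function(sorted_slopes, offset_k) {
  nn <- length(sorted_slopes)
  if (nn %% 2L == 1L) {
    idx <- (nn + 1L) / 2L + offset_k
    if (idx < 1L || idx > nn) {
      abort("Median slope index out of range; data look negatively correlated.")
    }
    sorted_slopes[idx]
  } else {
    idx <- nn / 2L + offset_k
    if (idx < 1L || idx + 1L > nn) {
      abort("Median slope index out of range; data look negatively correlated.")
    }
    mean(sorted_slopes[c(idx, idx + 1L)])
  }
}

#' Fit a Passing-Bablok regression
#'
#' Robust, rank-based errors-in-both-variables regression for method
#' comparison. The slope is the shifted median of all pairwise slopes and the
#' intercept the median of `y - slope * x`. Confidence intervals use the
#' rank-based order-statistic construction: with N retained slopes and
#' \eqn{C = z_{1-\alpha/2}\sqrt{n(n-1)(2n+5)/18}}, the slope bounds are the
#' order statistics at ranks \eqn{M_1 + K} and \eqn{M_2 + K} where
#' \eqn{M_1 = \mathrm{round}((N - C)/2)}, \eqn{M_2 = N - M_1 + 1}; intercept
#' bounds are re-derived from the slope bounds as median residuals. Ranks that
#' fall outside 1..N (possible at very small n) are clamped to the extreme
#' slopes.
#'
#' @param data A data frame holding the paired measurements.
#' @param x,y Columns of comparator (x) and reference (y) concentrations;
#'   tidy evaluation, defaults `x` and `y`.
#' @param conf_level Confidence level for the slope/intercept intervals.
#' @param ci Interval method: `"analytic"` (rank-based), `"bootstrap"`
#'   (percentile over pair resampling) or `"none"`.
#' @param ci_min_n Minimum n for the analytic interval; below it the fit is
#'   returned with `NA` intervals and a warning (the order-statistic ranks
#'   degenerate at tiny n). Lower it deliberately to force small-n intervals.
#' @param boot_reps,boot_seed Resamples and seed for `ci = "bootstrap"`.
#' @return An object of class `pb_fit`: slope, intercept, their intervals,
#'   counts, offset K, Pearson r, and the data used. Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`, `predict()`.
#' @examples
#' d <- tibble::tibble(x = c(1, 2, 3, 4, 10), y = c(1.1, 1.9, 3.2, 4.0, 9.8))
#' fit <- pb_fit(d, ci = "none")
#' tidy(fit)
#' @export
pb_fit <- function(data, x = x, y = y, conf_level = 0.95,
                   ci = c("analytic", "bootstrap", "none"),
                   ci_min_n = 10, boot_reps = 2000, boot_seed = 1L) {
  ci <- arg_match(ci)
  xv <- pull_num(data, {{ x }})
  yv <- pull_num(data, {{ y }})
  check_pair_vectors(xv, yv, min_n = 3, positive_x = TRUE)
  if (!(conf_level > 0 && conf_level < 1)) {
    abort("`conf_level` must be in (0, 1).")
  }
  ps <- pairwise_slopes(xv, yv)
  if (suppressWarnings(cor(xv, yv, method = "kendall")) < 0) {
    warn(paste(
      "x and y appear negatively correlated;",
      "Passing-Bablok assumes positively related methods."
    ))
  }
  slope <- shifted_median(ps$slopes, ps$offset_k)
  intercept <- median(yv - slope * xv)

  slope_ci <- c(NA_real_, NA_real_)
  intercept_ci <- c(NA_real_, NA_real_)
  ci_method <- "none"
  if (ci == "analytic") {
    if (ps$n < ci_min_n) {
      warn(sprintf(
        "n = %d below `ci_min_n` = %d; analytic confidence interval withheld.",
        ps$n, as.integer(ci_min_n)
      ))
    } else {
      b <- pb_analytic_ci(ps, conf_level)
      slope_ci <- b
      intercept_ci <- c(median(yv - b[2] * xv), median(yv - b[1] * xv))
      ci_method <- "analytic"
    }
  } else if (ci == "bootstrap") {
    bs <- withr::with_seed(boot_seed, {
      vapply(seq_len(boot_reps), function(k) {
        take <- sample.int(ps$n, ps$n, replace = TRUE)
        p <- tryCatch(pairwise_slopes(xv[take], yv[take]),
                      error = function(e) NULL)
        if (is.null(p)) return(c(NA_real_, NA_real_))
        bb <- tryCatch(shifted_median(p$slopes, p$offset_k),
                       error = function(e) NA_real_)
        c(bb, median(yv[take] - bb * xv[take]))
      }, numeric(2))
    })
    probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
    slope_ci <- unname(quantile(bs[1, ], probs, na.rm = TRUE))
    intercept_ci <- unname(quantile(bs[2, ], probs, na.rm = TRUE))
    ci_method <- "bootstrap"
  }

  r <- cor(xv, yv)
  structure(
    list(
      slope = slope, intercept = intercept,
      slope_ci = slope_ci, intercept_ci = intercept_ci,
      conf_level = conf_level, ci_method = ci_method,
      n = ps$n, n_slopes = ps$n_slopes, offset_k = ps$offset_k,
      n_discarded = ps$n_discarded,
      r = r, r_squared = r^2,
      data = tibble(x = xv, y = yv)
    ),
    class = "pb_fit"
  )
}

# rank-based slope bounds from the sorted pairwise slopes
pb_analytic_ci <- function(ps, conf_level) {
  n <- ps$n
  nn <- ps$n_slopes
  z <- qnorm(1 - (1 - conf_level) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((nn - C) / 2)
  m2 <- nn - m1 + 1
  lo <- min(max(m1 + ps$offset_k, 1L), nn)
  hi <- min(max(m2 + ps$offset_k, 1L), nn)
  c(ps$slopes[lo], ps$slopes[hi])
}

#' Classify constant and proportional bias from a Passing-Bablok fit
#'
#' Constant bias is called when the intercept interval excludes 0;
#' proportional bias when the slope interval excludes 1.
#'
#' @param fit A [pb_fit()] object with confidence intervals.
#' @return A tibble with one row per bias type: `bias`, `estimate`,
#'   `conf.low`, `conf.high`, `detected`.
#' @export
classify_bias <- function(fit) {
  stopifnot(inherits(fit, "pb_fit"))
  if (anyNA(c(fit$slope_ci, fit$intercept_ci))) {
    abort("Bias classification needs confidence intervals; refit with `ci`.")
  }
  tibble(
    bias = c("constant", "proportional"),
    estimate = c(fit$intercept, fit$slope),
    conf.low = c(fit$intercept_ci[1], fit$slope_ci[1]),
    conf.high = c(fit$intercept_ci[2], fit$slope_ci[2]),
    null_value = c(0, 1),
    detected = c(
      fit$intercept_ci[1] > 0 || fit$intercept_ci[2] < 0,
      fit$slope_ci[1] > 1 || fit$slope_ci[2] < 1
    )
  )
}

#' Pearson correlation between two measurement methods
#'
#' @inheritParams pb_fit
#' @return A one-row tibble with `r`, `r_squared` and `n`.
#' @export
pearson_correlation <- function(data, x = x, y = y) {
  xv <- pull_num(data, {{ x }})
  yv <- pull_num(data, {{ y }})
  check_pair_vectors(xv, yv, min_n = 3)
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("Correlation undefined: a method has zero variance.")
  }
  r <- cor(xv, yv)
  tibble(r = r, r_squared = r^2, n = length(xv))
}

#' @export
print.pb_fit <- function(x, digits = 3, ...) {
  cat("Passing-Bablok regression (n = ", x$n, ")\n", sep = "")
  fmt_ci <- function(est, ci) {
    if (anyNA(ci)) return(sprintf("%.*f (CI not computed)", digits, est))
    sprintf("%.*f (%g%% CI %.*f to %.*f)", digits, est,
            100 * x$conf_level, digits, ci[1], digits, ci[2])
  }
  cat("  slope:     ", fmt_ci(x$slope, x$slope_ci), "\n", sep = "")
  cat("  intercept: ", fmt_ci(x$intercept, x$intercept_ci), "\n", sep = "")
  cat(sprintf("  r = %.*f, r^2 = %.*f\n", digits, x$r, digits, x$r_squared))
  invisible(x)
}

#' @export
predict.pb_fit <- function(object, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) {
    object$data$x
  } else if (is.data.frame(newdata)) {
    pull_num(newdata, "x")
  } else {
    as.numeric(newdata)
  }
  object$intercept + object$slope * xv
}

#' @method tidy pb_fit
#' @export
tidy.pb_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(x$intercept_ci[1], x$slope_ci[1]),
    conf.high = c(x$intercept_ci[2], x$slope_ci[2])
  )
}

#' @method glance pb_fit
#' @export
glance.pb_fit <- function(x, ...) {
  tibble(
    n = x$n, n_slopes = x$n_slopes, offset_k = x$offset_k,
    r = x$r, r.squared = x$r_squared,
    conf.level = x$conf_level, ci.method = x$ci_method
  )
}
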