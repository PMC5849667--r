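#' Ratio-scale Bland-Altman agreement
#'
#' Summarises between-method agreement through per-patient concentration
#' ratios r_i = y_i / x_i (reference over comparator, e.g. WB/DBS). The 95%
#' limits of agreement are `mean(r) +/- 1.96 * sd(r)` on the raw ratio scale.
#' Limits of clinical relevance default to (0.75, 1.25) — a 25% band around
#' unity, the step size in which everolimus doses are adjusted — and may
#' instead be centred on the observed mean ratio.
#'
#' @param data A data frame of paired concentrations.
#' @param x,y Comparator and reference columns (tidy evaluation; defaults
#'   `x`, `y`). Ratios are `y / x`.
#' @param clinical_limits Length-2 numeric band on the ratio scale.
#' @param center `"unity"` keeps `clinical_limits` as given; `"mean_ratio"`
#'   rescales them by the observed mean ratio.
#' @param loa_z Multiplier for the limits of agreement (1.96 for the classic
#'   95% limits).
#' @return A `ba_agreement` object: `mean_ratio`, `sd_ratio`, `loa`,
#'   `clinical_limits`, counts outside each band, `n`, `ratio_direction`,
#'   and the per-patient ratios. Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' d <- tibble::tibble(x = c(10, 12, 15, 20), y = c(9, 11.5, 13, 19))
#' ba_agreement(d)
#' @export
ba_agreement <- function(data, x = x, y = y, clinical_limits = c(0.75, 1.25),
                         center = c("unity", "mean_ratio"), loa_z = 1.96) {
  center <- arg_match(center)
  xv <- pull_num(data, {{ x }})
  yv <- pull_num(data, {{ y }})
  check_pair_vectors(xv, yv, min_n = 3, positive_x = TRUE, positive_y = TRUE)
  if (length(clinical_limits) != 2 || clinical_limits[1] >= clinical_limits[2]) {
    abort("`clinical_limits` must be an increasing length-2 vector.")
  }
  ratios <- yv / xv
  m <- mean(ratios)
  s <- sd(ratios)
  loa <- c(m - loa_z * s, m + loa_z * s)
  cl <- if (center == "mean_ratio") m * clinical_limits else clinical_limits
  labels <- if ("patient_id" %in% names(data)) {
    as.character(data$patient_id)
  } else {
    as.character(seq_along(ratios))
  }
  structure(
    list(
      mean_ratio = m, sd_ratio = s, loa = loa, loa_z = loa_z,
      clinical_limits = cl, n = length(ratios),
      n_outside_loa = sum(ratios < loa[1] | ratios > loa[2]),
      n_outside_clinical = sum(ratios < cl[1] | ratios > cl[2]),
      ratio_direction = "reference/comparator (y/x)",
      data = tibble(patient_id = labels, x = xv, y = yv, ratio = ratios,
                    mean_conc = (xv + yv) / 2)
    ),
    class = "ba_agreement"
  )
}

#' Fractions inside and outside the limits of clinical relevance
#'
#' @param result A [ba_agreement()] object.
#' @return A one-row tibble with `n`, `pct_inside`, `pct_outside` (percent,
#'   summing to 100).
#' @export
clinical_relevance_fraction <- function(result) {
  stopifnot(inherits(result, "ba_agreement"))
  out_pct <- 100 * result$n_outside_clinical / result$n
  tibble(n = result$n, pct_inside = 100 - out_pct, pct_outside = out_pct)
}

#' @export
print.ba_agreement <- function(x, digits = 2, ...) {
  cat("Bland-Altman ratio agreement (n = ", x$n, ", ratio = ",
      x$ratio_direction, ")\n", sep = "")
  cat(sprintf("  mean ratio %.2f (95%% LoA %.2f to %.2f)\n",
              x$mean_ratio, x$loa[1], x$loa[2]))
  cat(sprintf("  clinical limits %.2f to %.2f: %d/%d outside (%.1f%%)\n",
              x$clinical_limits[1], x$clinical_limits[2],
              x$n_outside_clinical, x$n, 100 * x$n_outside_clinical / x$n))
  invisible(x)
}

#' @method tidy ba_agreement
#' @export
tidy.ba_agreement <- function(x, ...) {
  tibble(
    statistic = c("mean_ratio", "sd_ratio", "loa_low", "loa_high",
                  "clinical_low", "clinical_high"),
    value = c(x$mean_ratio, x$sd_ratio, x$loa, x$clinical_limits)
  )
}

#' @method glance ba_agreement
#' @export
glance.ba_agreement <- function(x, ...) {
  tibble(
    n = x$n, mean_ratio = x$mean_ratio, sd_ratio = x$sd_ratio,
    loa_low = x$loa[1], loa_high = x$loa[2],
    n_outside_loa = x$n_outside_loa,
    n_outside_clinical = x$n_outside_clinical,
    pct_outside_clinical = 100 * x$n_outside_clinical / x$n
  )
}

validate_power_spec <- function(mu, sigma, delta, alpha, target_power = 0.8) {
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (delta <= abs(mu)) abort("`delta` must exceed |mu|.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (target_power <= 0 || target_power >= 1) {
    abort("`target_power` must be in (0, 1).")
  }
  invisible(TRUE)
}

#' Power of the Bland-Altman agreement design
#'
#' Design-stage power for demonstrating agreement: with relative differences
#' assumed normal with mean `mu` and SD `sigma` (both in percent), the
#' estimated 95% limits of agreement are `dbar +/- 1.96 s`, with approximate
#' sampling variance `sigma^2 (1/n + 1.96^2 / (2(n-1)))`. Agreement is
#' demonstrated when two one-sided assessments at level `alpha` show the
#' upper limit below `delta` and the lower limit above `-delta`. The returned
#' power is the normal-approximation probability that both succeed,
#'
#' \deqn{\Phi\!\big(\tfrac{\delta-\mu-1.96\sigma}{\tau}-z_{1-\alpha}\big) +
#'       \Phi\!\big(\tfrac{\delta+\mu-1.96\sigma}{\tau}-z_{1-\alpha}\big) - 1}
#'
#' with \eqn{\tau = \sigma\sqrt{1/n + 1.96^2/(2(n-1))}}. Monotone increasing
#' in `n` and `delta`, decreasing in `sigma` and `|mu|`.
#'
#' @param n Sample size(s), each at least 3 (vectorised).
#' @param mu Expected mean relative difference between methods, percent.
#' @param sigma SD of the relative difference, percent.
#' @param delta Maximum allowed difference, percent.
#' @param alpha One-sided significance level of each assessment.
#' @return Power in \[0, 1\], same length as `n`.
#' @examples
#' ba_power(20, mu = 9, sigma = 5, delta = 25)
#' @export
ba_power <- function(n, mu, sigma, delta, alpha = 0.05) {
  validate_power_spec(mu, sigma, delta, alpha)
  if (any(n < 3)) abort("`n` must be at least 3.")
  z <- qnorm(0.975)
  za <- qnorm(1 - alpha)
  tau <- sigma * sqrt(1 / n + z^2 / (2 * (n - 1)))
  p <- pnorm((delta - mu - z * sigma) / tau - za) +
    pnorm((delta + mu - z * sigma) / tau - za) - 1
  pmin(pmax(p, 0), 1)
}

#' Monte-Carlo check of the Bland-Altman power approximation
#'
#' Simulates cohorts of relative differences, computes the estimated limits
#' of agreement from each, and applies the same two one-sided demonstration
#' rule as [ba_power()] (planning-stage standard error). Used to verify the
#' normal approximation.
#'
#' @inheritParams ba_power
#' @param reps Number of simulated cohorts.
#' @param seed Seed for reproducibility.
#' @return Estimated power (a single number).
#' @export
ba_power_mc <- function(n, mu, sigma, delta, alpha = 0.05, reps = 1e5,
                        seed = 1L) {
  validate_power_spec(mu, sigma, delta, alpha)
  stopifnot(length(n) == 1, n >= 3)
  z <- qnorm(0.975)
  za <- qnorm(1 - alpha)
  tau <- sigma * sqrt(1 / n + z^2 / (2 * (n - 1)))
  withr::with_seed(seed, {
    d <- matrix(rnorm(n * reps, mu, sigma), nrow = reps)
    m <- rowMeans(d)
    s <- sqrt((rowSums(d^2) - n * m^2) / (n - 1))
    upper <- m + z * s
    lower <- m - z * s
    mean(upper < delta - za * tau & lower > -delta + za * tau)
  })
}

#' Minimal sample size for the Bland-Altman agreement design
#'
#' Smallest `n` whose [ba_power()] reaches `target_power`; by monotonicity
#' the previous `n` falls short (bracketing).
#'
#' @inheritParams ba_power
#' @param target_power Desired power in (0, 1).
#' @param n_max Search ceiling.
#' @return The minimal sample size (integer).
#' @examples
#' ba_sample_size(mu = 9, sigma = 5, delta = 25)
#' @export
ba_sample_size <- function(mu, sigma, delta, alpha = 0.05,
                           target_power = 0.80, n_max = 10000) {
  validate_power_spec(mu, sigma, delta, alpha, target_power)
  z <- qnorm(0.975)
  if (delta <= abs(mu) + z * sigma) {
    abort(paste(
      "Unreachable power: `delta` must exceed |mu| + 1.96 * sigma,",
      "otherwise the true limits of agreement lie outside the allowed band",
      "and no sample size can demonstrate agreement."
    ))
  }
  ns <- 3:n_max
  hit <- which(ba_power(ns, mu, sigma, delta, alpha) >= target_power)
  if (length(hit) == 0) {
    abort(sprintf("Target power not reached by n = %d.", n_max))
  }
  ns[hit[1]]
}
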