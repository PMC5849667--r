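#' Leave-one-out prediction of reference concentrations
#'
#' For each patient, fits a Passing-Bablok regression on all other patients
#' and predicts that patient's reference (WB) concentration from their
#' comparator (DBS) concentration: `pred_i = a_(-i) + b_(-i) * x_i`. The
#' patient's own observation never enters the fit used to predict it.
#'
#' @param data A data frame of paired concentrations; a `patient_id` column
#'   is carried through if present.
#' @param x,y Comparator and reference columns (tidy evaluation).
#' @return A tibble with `patient_id`, `observed`, `predicted`, `loo_slope`,
#'   `loo_intercept`; patients whose reduced fit fails get `NA` predictions
#'   and a warning, and are excluded from downstream metrics.
#' @export
loo_predict <- function(data, x = x, y = y) {
  xv <- pull_num(data, {{ x }})
  yv <- pull_num(data, {{ y }})
  check_pair_vectors(xv, yv, min_n = 4, positive_x = TRUE, positive_y = TRUE)
  labels <- if ("patient_id" %in% names(data)) {
    as.character(data$patient_id)
  } else {
    as.character(seq_along(xv))
  }
  n <- length(xv)
  fits <- purrr::map(seq_len(n), function(i) {
    tryCatch(
      pb_fit(tibble(x = xv[-i], y = yv[-i]), ci = "none"),
      error = function(e) NULL
    )
  })
  failed <- purrr::map_lgl(fits, is.null)
  if (any(failed)) {
    warn(sprintf("%d leave-one-out fit(s) failed; patients excluded: %s",
                 sum(failed), paste(labels[failed], collapse = ", ")))
  }
  tibble(
    patient_id = labels,
    observed = yv,
    predicted = purrr::map_dbl(seq_len(n), function(i) {
      if (failed[i]) NA_real_ else fits[[i]]$intercept + fits[[i]]$slope * xv[i]
    }),
    loo_slope = purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else .x$slope),
    loo_intercept = purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else .x$intercept)
  )
}

#' Sheiner-Beal predictive-performance statistics
#'
#' Median-based bias and imprecision of predicted versus observed
#' concentrations: median prediction error (MPE, ug/L), median percentage
#' prediction error (MPPE, %), root median squared prediction error
#' (root-median-square, ug/L) and median absolute percentage prediction
#' error (MAPE, %), plus the percentage of patients with an absolute
#' percentage prediction error below 20%. The conventional root-mean-square
#' error is also reported, clearly labelled, for reference.
#'
#' @param pred A data frame with `observed` and `predicted` columns (as from
#'   [loo_predict()]); rows with missing predictions are dropped.
#' @param within_pct Threshold (percent) for the within-error fraction.
#' @return A `prediction_metrics` object; see also [acceptance_verdict()],
#'   [tidy()], [glance()].
#' @export
prediction_metrics <- function(pred, within_pct = 20) {
  stopifnot(all(c("observed", "predicted") %in% names(pred)))
  keep <- !is.na(pred$predicted) & !is.na(pred$observed)
  obs <- pred$observed[keep]
  prd <- pred$predicted[keep]
  if (length(obs) < 1) abort("At least one prediction is required.")
  if (any(obs <= 0)) abort("Observed concentrations must be positive.")
  err <- prd - obs
  pct_err <- 100 * err / obs
  structure(
    list(
      mpe = median(err),
      mppe = median(pct_err),
      rmse_median = sqrt(median(err^2)),
      rmse_mean = sqrt(mean(err^2)),
      mape = median(abs(pct_err)),
      fraction_within = 100 * mean(abs(pct_err) < within_pct),
      within_pct = within_pct,
      n = length(obs),
      n_dropped = sum(!keep),
      errors = tibble(
        patient_id = if ("patient_id" %in% names(pred)) {
          as.character(pred$patient_id[keep])
        } else {
          as.character(seq_along(obs))
        },
        observed = obs, predicted = prd, error = err, pct_error = pct_err
      )
    ),
    class = "prediction_metrics"
  )
}

#' Acceptance verdict for cross-validated predictive performance
#'
#' Mirrors the regulatory cross-validation criteria used for bioanalytical
#' bridging: absolute MPPE and MAPE below 15%, and at least 67% of patients
#' with an absolute percentage prediction error under 20%.
#'
#' @param metrics A [prediction_metrics()] object.
#' @param mppe_limit,mape_limit Bias/imprecision limits, percent.
#' @param fraction_limit Minimum percentage of patients within the
#'   prediction-error band.
#' @return A list with `pass` (logical), `criteria` (a tibble with one row
#'   per criterion) and `reasons` (names of failed criteria).
#' @export
acceptance_verdict <- function(metrics, mppe_limit = 15, mape_limit = 15,
                               fraction_limit = 67) {
  stopifnot(inherits(metrics, "prediction_metrics"))
  criteria <- tibble(
    criterion = c("mppe", "mape", "fraction_within"),
    value = c(metrics$mppe, metrics$mape, metrics$fraction_within),
    limit = c(mppe_limit, mape_limit, fraction_limit),
    pass = c(
      abs(metrics$mppe) < mppe_limit,
      metrics$mape < mape_limit,
      metrics$fraction_within >= fraction_limit
    )
  )
  list(
    pass = all(criteria$pass),
    criteria = criteria,
    reasons = criteria$criterion[!criteria$pass]
  )
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat("Leave-one-out predictive performance (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  MPE  %8.3f ug/L   MPPE %7.2f %%\n", x$mpe, x$mppe))
  cat(sprintf("  RMSE %8.3f ug/L (root-median-square; root-mean-square %.3f)\n",
              x$rmse_median, x$rmse_mean))
  cat(sprintf("  MAPE %8.2f %%\n", x$mape))
  cat(sprintf("  %.1f%% of patients within %g%% prediction error\n",
              x$fraction_within, x$within_pct))
  invisible(x)
}

#' @method tidy prediction_metrics
#' @export
tidy.prediction_metrics <- function(x, ...) {
  tibble(
    statistic = c("mpe", "mppe", "rmse_median", "rmse_mean", "mape",
                  "fraction_within"),
    value = c(x$mpe, x$mppe, x$rmse_median, x$rmse_mean, x$mape,
              x$fraction_within),
    unit = c("ug/L", "%", "ug/L", "ug/L", "%", "%")
  )
}

#' @method glance prediction_metrics
#' @export
glance.prediction_metrics <- function(x, ...) {
  v <- acceptance_verdict(x)
  tibble(
    n = x$n, mpe = x$mpe, mppe = x$mppe, rmse_median = x$rmse_median,
    mape = x$mape, fraction_within = x$fraction_within, pass = v$pass
  )
}
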