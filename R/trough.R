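#' Extrapolate a measured concentration to the trough
#'
#' Log-linear elimination-phase extrapolation: a concentration measured `t`
#' hours after the last dose is carried forward to the end of the dosing
#' interval `tau`, \deqn{C_{trough} = C \exp(-\ln 2 / t_{1/2} \cdot (\tau - t)).}
#' With once-daily everolimus the default interval is 24 h and the default
#' population elimination half-life 30 h. Samples drawn before the absorption
#' phase has plausibly finished (`t` below `absorption_cutoff`) are still
#' extrapolated but should be treated as unreliable (see
#' [estimate_troughs()], which flags them).
#'
#' @param conc Measured concentration(s), ug/L.
#' @param time_after_dose Hours since last dose, in `(0, tau]` (vectorised).
#' @param tau Dosing interval, hours.
#' @param half_life Elimination half-life, hours.
#' @return Estimated trough concentration(s), ug/L.
#' @examples
#' extrapolate_trough(20, time_after_dose = 12, tau = 24, half_life = 30)
#' @export
extrapolate_trough <- function(conc, time_after_dose, tau = 24,
                               half_life = 30) {
  if (any(half_life <= 0)) abort("`half_life` must be positive.")
  if (any(conc <= 0, na.rm = TRUE)) abort("`conc` must be positive.")
  if (any(time_after_dose <= 0, na.rm = TRUE)) {
    abort("`time_after_dose` must be positive.")
  }
  if (any(time_after_dose > tau, na.rm = TRUE)) {
    abort("`time_after_dose` exceeds the dosing interval `tau`.")
  }
  conc * exp(-log(2) / half_life * (tau - time_after_dose))
}

#' Classify a trough concentration against a therapeutic window
#'
#' Default bounds are the exposure window associated with longer
#' progression-free survival and less toxicity for everolimus in oncology:
#' troughs of 11.9 to 26.3 ug/L. Bounds are inclusive.
#'
#' @param c_trough Trough concentration(s), ug/L (vectorised).
#' @param low,high Window bounds, ug/L, `low < high`.
#' @return A factor with levels `below`, `within`, `above`.
#' @export
classify_window <- function(c_trough, low = 11.9, high = 26.3) {
  if (low >= high) abort("`low` must be less than `high`.")
  factor(
    dplyr::case_when(
      c_trough < low ~ "below",
      c_trough > high ~ "above",
      TRUE ~ "within"
    ),
    levels = c("below", "within", "above")
  )
}

#' Cohort summary of therapeutic-window classes
#'
#' @param classes A vector of window classes ([classify_window()] output or
#'   character).
#' @return A one-row tibble: `n`, `pct_below`, `pct_within`, `pct_above`,
#'   `pct_outside` (= below + above). Percentages sum to 100 exactly.
#' @export
cohort_window_summary <- function(classes) {
  classes <- factor(as.character(classes),
                    levels = c("below", "within", "above"))
  if (length(classes) == 0 || anyNA(classes)) {
    abort("`classes` must be non-empty below/within/above values.")
  }
  counts <- table(classes)
  n <- length(classes)
  tibble(
    n = n,
    pct_below = 100 * counts[["below"]] / n,
    pct_within = 100 * counts[["within"]] / n,
    pct_above = 100 * counts[["above"]] / n,
    pct_outside = 100 * (counts[["below"]] + counts[["above"]]) / n
  )
}

#' Estimate troughs for a sample table
#'
#' Applies [extrapolate_trough()] to a measured concentration column (the
#' venous WB concentration by default) using each patient's documented time
#' after dose, classifies the result against the therapeutic window, and
#' flags samples drawn before `absorption_cutoff` hours as unreliable
#' (`early_sample`).
#'
#' @param samples A sample table with `time_after_dose_h`.
#' @param conc Column holding the measured concentration (tidy evaluation,
#'   default `wb`).
#' @param tau,half_life See [extrapolate_trough()].
#' @param absorption_cutoff Hours; earlier samples are flagged.
#' @param window Length-2 therapeutic window, ug/L.
#' @return The table with `c_trough` and `window_class` columns and updated
#'   `flags`.
#' @export
estimate_troughs <- function(samples, conc = wb, tau = 24, half_life = 30,
                             absorption_cutoff = 2, window = c(11.9, 26.3)) {
  cv <- pull_num(samples, {{ conc }})
  t <- samples$time_after_dose_h
  out <- samples
  out$c_trough <- extrapolate_trough(cv, t, tau = tau, half_life = half_life)
  out$window_class <- classify_window(out$c_trough, window[1], window[2])
  if (!"flags" %in% names(out)) out$flags <- ""
  out$flags <- add_flag(out$flags, "early_sample",
                        !is.na(t) & t < absorption_cutoff)
  keep_attr(out, samples)
}
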