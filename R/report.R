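#' Configuration for a validation run
#'
#' @param principal_pair Comparison used for predictive performance
#'   (`"DBS-WB"`, `"DBSwb-WB"` or `"DBS-DBSwb"`).
#' @param conf_level Confidence level for regression intervals.
#' @param clinical_limits,clinical_center Limits of clinical relevance on the
#'   ratio scale and how they are centred (see [ba_agreement()]).
#' @param tau_h,half_life_h,absorption_cutoff_h Trough extrapolation
#'   parameters, hours (see [estimate_troughs()]).
#' @param window_low,window_high Therapeutic window bounds, ug/L.
#' @param mppe_limit,mape_limit,fraction_limit Acceptance thresholds
#'   (see [acceptance_verdict()]).
#' @return A `validation_config` list.
#' @export
validation_config <- function(principal_pair = "DBS-WB", conf_level = 0.95,
                              clinical_limits = c(0.75, 1.25),
                              clinical_center = "unity",
                              tau_h = 24, half_life_h = 30,
                              absorption_cutoff_h = 2,
                              window_low = 11.9, window_high = 26.3,
                              mppe_limit = 15, mape_limit = 15,
                              fraction_limit = 67) {
  principal_pair <- arg_match(principal_pair,
                              c("DBS-WB", "DBSwb-WB", "DBS-DBSwb"))
  structure(
    list(
      principal_pair = principal_pair, conf_level = conf_level,
      clinical_limits = clinical_limits, clinical_center = clinical_center,
      tau_h = tau_h, half_life_h = half_life_h,
      absorption_cutoff_h = absorption_cutoff_h,
      window_low = window_low, window_high = window_high,
      mppe_limit = mppe_limit, mape_limit = mape_limit,
      fraction_limit = fraction_limit
    ),
    class = "validation_config"
  )
}

#' Run the full cross-validation analysis
#'
#' Orchestrates the pipeline on a paired-sample table: duplicate-spot
#' resolution and hematocrit QC, pairing, Passing-Bablok regression with
#' bias classification and Pearson correlation plus ratio-scale Bland-Altman
#' agreement for every available comparison, leave-one-out predictive
#' performance with the acceptance verdict for the principal comparison, and
#' the trough/therapeutic-window summary. Deterministic given the input and
#' configuration.
#'
#' @param x A sample table or a CSV path accepted by [read_samples()].
#' @param config A [validation_config()].
#' @return A `dbs_validation` object; see [write_report()], [tidy()],
#'   [glance()], `print()`.
#' @examples
#' report <- run_validation(generate_cohort(synthetic_config(seed = 7)))
#' glance(report)
#' @export
run_validation <- function(x, config = validation_config()) {
  samples <- if (is.character(x)) read_samples(x) else x
  if (!"flags" %in% names(samples)) samples$flags <- ""
  samples <- resolve_dbs(samples)
  samples <- flag_hematocrit(samples)
  pairs <- build_pairs(samples)

  principal <- config$principal_pair
  pr <- filter(pairs, .data$pair_name == principal)
  if (nrow(pr) < 4) {
    abort(sprintf(
      "Leave-one-out stage needs >= 4 complete pairs for '%s' (have %d).",
      principal, nrow(pr)
    ))
  }

  pair_results <- pairs |>
    split(factor(pairs$pair_name, levels = unique(pairs$pair_name))) |>
    purrr::map(function(p) {
      fit <- pb_fit(p, conf_level = config$conf_level)
      list(
        n = nrow(p),
        pb = fit,
        bias = classify_bias(fit),
        correlation = pearson_correlation(p),
        ba = ba_agreement(p, clinical_limits = config$clinical_limits,
                          center = config$clinical_center)
      )
    })

  loo <- loo_predict(pr)
  prediction <- prediction_metrics(loo)
  verdict <- acceptance_verdict(prediction, mppe_limit = config$mppe_limit,
                                mape_limit = config$mape_limit,
                                fraction_limit = config$fraction_limit)

  trough_summary <- NULL
  troughs <- NULL
  if (all(c("wb", "time_after_dose_h") %in% names(samples)) &&
        any(!is.na(samples$time_after_dose_h))) {
    ok <- !is.na(samples$wb) & !is.na(samples$time_after_dose_h)
    troughs <- estimate_troughs(
      samples[ok, , drop = FALSE], tau = config$tau_h,
      half_life = config$half_life_h,
      absorption_cutoff = config$absorption_cutoff_h,
      window = c(config$window_low, config$window_high)
    )
    trough_summary <- cohort_window_summary(troughs$window_class)
  }

  structure(
    list(
      pairs = pair_results,
      principal_pair = principal,
      loo = loo,
      prediction = prediction,
      verdict = verdict,
      trough = troughs[, intersect(c("patient_id", "wb", "time_after_dose_h",
                                     "c_trough", "window_class"),
                                   names(troughs))],
      trough_summary = trough_summary,
      qc = qc_log(samples),
      config = unclass(config),
      meta = list(package = "dbsagree",
                  version = as.character(utils::packageVersion("dbsagree")))
    ),
    class = "dbs_validation"
  )
}

#' @export
print.dbs_validation <- function(x, ...) {
  cat("== Dried blood spot cross-validation report ==\n")
  for (nm in names(x$pairs)) {
    p <- x$pairs[[nm]]
    cat(sprintf("\n-- %s (n = %d) --\n", nm, p$n))
    cat(sprintf(
      "  Bland-Altman: mean ratio %.2f (95%% LoA %.2f to %.2f); %d/%d outside clinical limits\n",
      p$ba$mean_ratio, p$ba$loa[1], p$ba$loa[2],
      p$ba$n_outside_clinical, p$ba$n
    ))
    slope_ci <- p$pb$slope_ci
    int_ci <- p$pb$intercept_ci
    cat(sprintf(
      "  Passing-Bablok: slope %.2f (%.2f to %.2f); intercept %.2f (%.2f to %.2f)\n",
      p$pb$slope, slope_ci[1], slope_ci[2],
      p$pb$intercept, int_ci[1], int_ci[2]
    ))
    cat(sprintf("  bias: constant %s, proportional %s; r = %.2f (r^2 = %.2f)\n",
                ifelse(p$bias$detected[1], "yes", "no"),
                ifelse(p$bias$detected[2], "yes", "no"),
                p$correlation$r, p$correlation$r_squared))
  }
  if (!is.null(x$prediction)) {
    cat(sprintf("\n-- Predictive performance (%s) --\n", x$principal_pair))
    cat(sprintf(
      "  MPE %.2f ug/L; MPPE %.1f%%; RMSE %.2f ug/L; MAPE %.1f%%; %.1f%% within %g%%\n",
      x$prediction$mpe, x$prediction$mppe, x$prediction$rmse_median,
      x$prediction$mape, x$prediction$fraction_within,
      x$prediction$within_pct
    ))
    cat(sprintf("  verdict: %s%s\n",
                ifelse(x$verdict$pass, "PASS", "FAIL"),
                if (x$verdict$pass) "" else
                  paste0(" (", paste(x$verdict$reasons, collapse = ", "), ")")))
  }
  if (!is.null(x$trough_summary)) {
    ts <- x$trough_summary
    cat(sprintf(
      "\n-- Trough window (%.1f to %.1f ug/L) --\n  below %.1f%% / within %.1f%% / above %.1f%% (outside %.1f%%)\n",
      x$config$window_low, x$config$window_high,
      ts$pct_below, ts$pct_within, ts$pct_above, ts$pct_outside
    ))
  }
  invisible(x)
}

#' @method tidy dbs_validation
#' @export
tidy.dbs_validation <- function(x, ...) {
  purrr::imap(x$pairs, function(p, nm) {
    tibble(
      pair_name = nm, n = p$n,
      slope = p$pb$slope, slope_low = p$pb$slope_ci[1],
      slope_high = p$pb$slope_ci[2],
      intercept = p$pb$intercept, intercept_low = p$pb$intercept_ci[1],
      intercept_high = p$pb$intercept_ci[2],
      constant_bias = p$bias$detected[1],
      proportional_bias = p$bias$detected[2],
      r = p$correlation$r, r_squared = p$correlation$r_squared,
      mean_ratio = p$ba$mean_ratio,
      loa_low = p$ba$loa[1], loa_high = p$ba$loa[2],
      pct_outside_clinical = 100 * p$ba$n_outside_clinical / p$ba$n
    )
  }) |> bind_rows()
}

#' @method glance dbs_validation
#' @export
glance.dbs_validation <- function(x, ...) {
  out <- tibble(principal_pair = x$principal_pair,
                n_pairs = length(x$pairs))
  if (!is.null(x$prediction)) {
    out <- dplyr::bind_cols(out, glance(x$prediction))
  }
  if (!is.null(x$trough_summary)) {
    out$pct_outside_window <- x$trough_summary$pct_outside
  }
  out
}

report_as_list <- function(report) {
  list(
    pairs = purrr::map(report$pairs, function(p) {
      list(
        n = p$n,
        passing_bablok = list(
          slope = p$pb$slope, slope_ci = p$pb$slope_ci,
          intercept = p$pb$intercept, intercept_ci = p$pb$intercept_ci,
          conf_level = p$pb$conf_level, n_slopes = p$pb$n_slopes,
          offset_k = p$pb$offset_k
        ),
        bias = p$bias,
        correlation = p$correlation,
        bland_altman = list(
          mean_ratio = p$ba$mean_ratio, sd_ratio = p$ba$sd_ratio,
          loa = p$ba$loa, clinical_limits = p$ba$clinical_limits,
          n_outside_loa = p$ba$n_outside_loa,
          n_outside_clinical = p$ba$n_outside_clinical,
          ratio_direction = p$ba$ratio_direction
        )
      )
    }),
    principal_pair = report$principal_pair,
    prediction = if (!is.null(report$prediction)) {
      m <- report$prediction
      list(mpe = m$mpe, mppe = m$mppe, rmse_median = m$rmse_median,
           rmse_mean = m$rmse_mean, mape = m$mape,
           fraction_within = m$fraction_within, within_pct = m$within_pct,
           n = m$n, errors = m$errors)
    },
    verdict = if (!is.null(report$verdict)) {
      list(pass = report$verdict$pass, criteria = report$verdict$criteria,
           reasons = as.list(report$verdict$reasons))
    },
    trough_summary = report$trough_summary,
    qc = report$qc,
    config = report$config,
    meta = report$meta
  )
}

#' Write a validation report to disk
#'
#' Emits a machine-readable JSON rendering at full precision, a
#' human-readable text rendering (two decimals for concentrations and
#' ratios, one for percentages), and optionally the three standard figures:
#' the Bland-Altman ratio plot, the Passing-Bablok scatter and the
#' per-patient prediction-error plot for the principal comparison.
#'
#' @param report A [run_validation()] result.
#' @param dir Output directory (created if needed).
#' @param formats Any of `"json"`, `"text"`.
#' @param plots Write PNG figures (skipped with a warning if no graphics
#'   device is available).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, formats = c("json", "text"),
                         plots = FALSE) {
  stopifnot(inherits(report, "dbs_validation"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  if ("json" %in% formats) {
    f <- file.path(dir, "report.json")
    jsonlite::write_json(report_as_list(report), f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files["json"] <- f
  }
  if ("text" %in% formats) {
    f <- file.path(dir, "report.txt")
    writeLines(utils::capture.output(print(report)), f)
    files["text"] <- f
  }
  if (plots) {
    pp <- report$principal_pair
    figs <- list(
      fig_bland_altman = autoplot(report$pairs[[pp]]$ba),
      fig_passing_bablok = autoplot(report$pairs[[pp]]$pb),
      fig_prediction_error = plot_prediction_errors(report$prediction)
    )
    for (nm in names(figs)) {
      f <- file.path(dir, paste0(nm, ".png"))
      ok <- tryCatch({
        ggplot2::ggsave(f, figs[[nm]], width = 6, height = 4.5, dpi = 150)
        TRUE
      }, error = function(e) {
        warn(paste0("Could not write ", f, ": ", conditionMessage(e)))
        FALSE
      })
      if (ok) files[nm] <- f
    }
  }
  invisible(files)
}
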