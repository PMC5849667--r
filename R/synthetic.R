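#' Configuration for synthetic paired-cohort generation
#'
#' Defaults emulate the validation-study conditions: 20 patients, capillary
#' DBS concentrations spanning 3.7 to 33.3 ug/L, a proportional bias of 0.89
#' between venous WB and DBS with near-zero intercept, multiplicative WB
#' noise whose CV (0.094) is back-calculated from the printed width of the
#' 95% limits of agreement, small within-duplicate and DBS_wb noise,
#' hematocrit uniform on 0.25 to 0.45 L/L, once-daily doses of 5 to 17.5 mg,
#' trough-time sampling 20 to 24 h after dose, and a small per-spot failure
#' rate.
#'
#' @param n_patients Cohort size.
#' @param slope,intercept Structural relation WB = intercept + slope * DBS
#'   (dimensionless; ug/L).
#' @param dbs_range Latent DBS concentration range, ug/L; levels are drawn
#'   log-uniformly so points spread across the whole range.
#' @param ratio_cv Fractional CV of the multiplicative lognormal WB noise.
#' @param duplicate_cv Within-duplicate fractional CV of the two capillary
#'   spots.
#' @param dbswb_cv Fractional CV of the venous-blood spot.
#' @param hematocrit_range Uniform hematocrit range, L/L.
#' @param invalid_spot_rate Per-spot probability of an unusable spot.
#' @param dose_choices Daily doses sampled uniformly, mg.
#' @param t_after_dose_range Uniform time-after-dose range, hours.
#' @param seed Master seed (kept below 2^31).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 20, slope = 0.89, intercept = 0.02,
                             dbs_range = c(3.7, 33.3), ratio_cv = 0.094,
                             duplicate_cv = 0.03, dbswb_cv = 0.05,
                             hematocrit_range = c(0.25, 0.45),
                             invalid_spot_rate = 0.025,
                             dose_choices = c(5, 7.5, 10, 17.5),
                             t_after_dose_range = c(20, 24), seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), slope = slope, intercept = intercept,
    dbs_range = dbs_range, ratio_cv = ratio_cv, duplicate_cv = duplicate_cv,
    dbswb_cv = dbswb_cv, hematocrit_range = hematocrit_range,
    invalid_spot_rate = invalid_spot_rate, dose_choices = dose_choices,
    t_after_dose_range = t_after_dose_range, seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  ordered2 <- function(r) length(r) == 2 && r[1] <= r[2]
  if (cfg$n_patients < 1) abort("`n_patients` must be at least 1.")
  if (cfg$slope <= 0) abort("`slope` must be positive.")
  if (any(c(cfg$ratio_cv, cfg$duplicate_cv, cfg$dbswb_cv) < 0)) {
    abort("CVs must be non-negative.")
  }
  if (!ordered2(cfg$dbs_range) || cfg$dbs_range[1] <= 0) {
    abort("`dbs_range` must be an ordered positive pair.")
  }
  if (!ordered2(cfg$hematocrit_range) || cfg$hematocrit_range[1] <= 0 ||
        cfg$hematocrit_range[2] >= 1) {
    abort("`hematocrit_range` must be an ordered pair inside (0, 1).")
  }
  if (cfg$invalid_spot_rate < 0 || cfg$invalid_spot_rate > 1) {
    abort("`invalid_spot_rate` must be a probability.")
  }
  if (any(cfg$dose_choices <= 0)) abort("`dose_choices` must be positive.")
  if (!ordered2(cfg$t_after_dose_range) || cfg$t_after_dose_range[1] <= 0) {
    abort("`t_after_dose_range` must be an ordered positive pair.")
  }
  invisible(TRUE)
}

# lognormal multiplicative noise with unit median; cv = 0 degenerates to 1
ln_noise <- function(n, cv) {
  exp(rnorm(n, 0, sqrt(log1p(cv^2))))
}

#' Generate a synthetic paired cohort
#'
#' Per patient, a latent capillary DBS level is drawn log-uniformly on
#' `dbs_range`; the two duplicate spots and the venous-blood spot are the
#' level times independent unit-median lognormal noises; the venous WB
#' concentration is `(intercept + slope * level)` times lognormal noise of
#' CV `ratio_cv`; spots fail independently at `invalid_spot_rate`. With all
#' CVs zero the cohort is an exact fixed point of the analysis pipeline.
#'
#' @param config A [synthetic_config()].
#' @return A sample table (same schema as [read_samples()]) with attribute
#'   `"truth"`: the latent levels and generating parameters.
#' @examples
#' cohort <- generate_cohort(synthetic_config(seed = 42))
#' cohort_truth(cohort)$slope
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  n <- config$n_patients
  samples <- withr::with_seed(config$seed, {
    level <- exp(runif(n, log(config$dbs_range[1]), log(config$dbs_range[2])))
    tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      dbs_spot_a = level * ln_noise(n, config$duplicate_cv),
      dbs_spot_a_valid = runif(n) >= config$invalid_spot_rate,
      dbs_spot_b = level * ln_noise(n, config$duplicate_cv),
      dbs_spot_b_valid = runif(n) >= config$invalid_spot_rate,
      dbs_wb = level * ln_noise(n, config$dbswb_cv),
      wb = (config$intercept + config$slope * level) *
        ln_noise(n, config$ratio_cv),
      hematocrit = runif(n, config$hematocrit_range[1],
                         config$hematocrit_range[2]),
      dose_mg = sample(config$dose_choices, n, replace = TRUE),
      time_after_dose_h = runif(n, config$t_after_dose_range[1],
                                config$t_after_dose_range[2]),
      flags = "",
      .latent = level
    )
  })
  truth <- list(
    latent = tibble(patient_id = samples$patient_id,
                    level = samples$.latent,
                    wb_true = config$intercept + config$slope * samples$.latent),
    config = unclass(config)
  )
  samples$.latent <- NULL
  structure(samples, truth = truth,
            rejected = tibble(row = integer(), patient_id = character(),
                              reason = character()))
}

#' Ground truth of a synthetic cohort
#'
#' @param cohort Output of [generate_cohort()].
#' @return A list with `latent` (per-patient latent levels and true WB) and
#'   `config` (the generating parameters, including the seed).
#' @export
cohort_truth <- function(cohort) {
  attr(cohort, "truth")
}

# deterministic sub-seed: replicate k depends only on (master seed, k)
derive_subseed <- function(master, k) {
  as.integer((as.numeric(master) + 1299721 * as.numeric(k)) %% 2147483629)
}

#' Generate independent replicate cohorts
#'
#' Derives a deterministic sub-seed per replicate from the master seed, so
#' replicate `k` regenerated alone equals replicate `k` from the full stream.
#'
#' @param config A [synthetic_config()]; its `seed` is the master seed.
#' @param n_reps Number of replicates.
#' @param indices Which replicates to generate (default all of `1:n_reps`).
#' @return A list of cohorts.
#' @export
generate_replicates <- function(config = synthetic_config(), n_reps,
                                indices = seq_len(n_reps)) {
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  purrr::map(indices, function(k) {
    cfg <- config
    cfg$seed <- derive_subseed(config$seed, k)
    generate_cohort(cfg)
  })
}

#' Write a synthetic cohort with its ground-truth sidecar
#'
#' @param cohort Output of [generate_cohort()].
#' @param path Output CSV path (sample schema of [read_samples()]).
#' @param truth_path Optional JSON path for the ground-truth record
#'   (parameters, seed, latent levels).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  write_samples(cohort, path)
  if (!is.null(truth_path)) {
    truth <- cohort_truth(cohort)
    jsonlite::write_json(
      list(config = truth$config, latent = truth$latent),
      truth_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
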