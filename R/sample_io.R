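#' Read a paired-sample table
#'
#' Reads one row per patient of paired dried blood spot (DBS) and venous
#' whole-blood (WB) everolimus concentrations: duplicate capillary spots with
#' spot-size validity flags, a spot prepared from venous blood (DBS_wb), the
#' venous WB concentration, hematocrit, daily dose and time after dose. Units
#' are fixed: concentrations in ug/L, hematocrit as a fraction (L/L), dose in
#' mg/day, time in hours. The file is comma-separated with a mandatory header;
#' missing values are empty fields.
#'
#' Rows violating basic physiology are rejected, not silently dropped: every
#' input row ends up either in the returned table or in the rejection report
#' attached as attribute `"rejected"` (also via [rejections()]).
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping the canonical column
#'   names (names) to the file's column names (values), for files using a
#'   different header. Canonical columns: `patient_id`, `dbs_spot_a`,
#'   `dbs_spot_a_valid`, `dbs_spot_b`, `dbs_spot_b_valid`, `dbs_wb`, `wb`,
#'   `hematocrit`, `dose_mg`, `time_after_dose_h`.
#' @return A tibble of validated samples with a `flags` character column
#'   (empty at this stage) and attribute `"rejected"`.
#' @export
read_samples <- function(path, schema = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols())
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0("Schema maps absent column(s): ",
                   paste(missing_src, collapse = ", ")))
    }
    names(raw)[match(unname(schema), names(raw))] <- names(schema)
  }
  missing_cols <- setdiff(sample_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[sample_columns()]
  num_cols <- c("dbs_spot_a", "dbs_spot_b", "dbs_wb", "wb", "hematocrit",
                "dose_mg", "time_after_dose_h")
  raw <- mutate(
    raw,
    patient_id = as.character(.data$patient_id),
    across(dplyr::all_of(num_cols), as.numeric),
    dbs_spot_a_valid = as.logical(.data$dbs_spot_a_valid),
    dbs_spot_b_valid = as.logical(.data$dbs_spot_b_valid)
  )
  validate_samples(raw)
}

sample_columns <- function() {
  c("patient_id", "dbs_spot_a", "dbs_spot_a_valid", "dbs_spot_b",
    "dbs_spot_b_valid", "dbs_wb", "wb", "hematocrit", "dose_mg",
    "time_after_dose_h")
}

# row-level validation: concentrations positive when present, hematocrit a
# fraction, dose positive, time non-negative
validate_samples <- function(raw) {
  bad_conc <- function(v) !is.na(v) & v <= 0
  reason <- dplyr::case_when(
    bad_conc(raw$dbs_spot_a) | bad_conc(raw$dbs_spot_b) |
      bad_conc(raw$dbs_wb) | bad_conc(raw$wb) ~
      "non-positive concentration",
    !is.na(raw$hematocrit) & (raw$hematocrit <= 0 | raw$hematocrit >= 1) ~
      "hematocrit outside (0, 1)",
    !is.na(raw$dose_mg) & raw$dose_mg <= 0 ~ "non-positive dose",
    !is.na(raw$time_after_dose_h) & raw$time_after_dose_h < 0 ~
      "negative time after dose",
    TRUE ~ NA_character_
  )
  rejected <- tibble(
    row = which(!is.na(reason)),
    patient_id = raw$patient_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  ok <- raw[is.na(reason), , drop = FALSE]
  ok$flags <- ""
  if (nrow(rejected) > 0) {
    warn(sprintf("%d row(s) rejected; see rejections().", nrow(rejected)))
  }
  structure(as_tibble(ok), rejected = rejected)
}

#' Row-level rejection report of a sample table
#'
#' @param samples A table returned by [read_samples()].
#' @return A tibble with `row`, `patient_id`, `reason` (possibly empty).
#' @export
rejections <- function(samples) {
  attr(samples, "rejected") %||%
    tibble(row = integer(), patient_id = character(), reason = character())
}

#' Resolve duplicate DBS spots into one concentration
#'
#' Each patient contributes two capillary spots, each scored for adequate spot
#' size. Both valid: the arithmetic mean is used. Exactly one valid: that
#' spot's value is used and the sample flagged `dbs_single_spot`. Neither
#' valid: the patient is excluded from DBS comparisons (`dbs_excluded`; the
#' DBS_wb and WB values remain usable). A missing spot concentration counts
#' as invalid.
#'
#' @param samples A sample table (see [read_samples()]).
#' @return The table with columns `dbs` (resolved concentration, `NA` when
#'   excluded) and updated `flags`.
#' @export
resolve_dbs <- function(samples) {
  a_ok <- !is.na(samples$dbs_spot_a) &
    !is.na(samples$dbs_spot_a_valid) & samples$dbs_spot_a_valid
  b_ok <- !is.na(samples$dbs_spot_b) &
    !is.na(samples$dbs_spot_b_valid) & samples$dbs_spot_b_valid
  dbs <- dplyr::case_when(
    a_ok & b_ok ~ (samples$dbs_spot_a + samples$dbs_spot_b) / 2,
    a_ok ~ samples$dbs_spot_a,
    b_ok ~ samples$dbs_spot_b,
    TRUE ~ NA_real_
  )
  out <- mutate(samples, dbs = dbs)
  out$flags <- add_flag(out$flags, "dbs_single_spot", xor(a_ok, b_ok))
  out$flags <- add_flag(out$flags, "dbs_excluded", !a_ok & !b_ok)
  keep_attr(out, samples)
}

#' Hematocrit quality-control flags
#'
#' Spot-based sampling under-recovers drug at low hematocrit because the
#' droplet spreads further on the paper. Hematocrit at or below 0.20 L/L gets
#' a hard warning (`hct_low`); hematocrit below 0.25 L/L combined with any
#' DBS concentration above 20 ug/L gets a caution flag (`hct_high_conc`).
#'
#' @param samples A sample table; [resolve_dbs()] need not have run.
#' @param hard_limit,caution_limit,caution_conc Thresholds in L/L, L/L, ug/L.
#' @return The table with updated `flags`.
#' @export
flag_hematocrit <- function(samples, hard_limit = 0.20, caution_limit = 0.25,
                            caution_conc = 20) {
  hct <- samples$hematocrit
  conc_cols <- cbind(samples$dbs_spot_a, samples$dbs_spot_b, samples$dbs_wb,
                     if ("dbs" %in% names(samples)) samples$dbs)
  any_high <- apply(conc_cols, 1, function(v) any(v > caution_conc, na.rm = TRUE))
  out <- samples
  out$flags <- add_flag(out$flags, "hct_low", !is.na(hct) & hct <= hard_limit)
  out$flags <- add_flag(
    out$flags, "hct_high_conc",
    !is.na(hct) & hct < caution_limit & hct > hard_limit & any_high
  )
  keep_attr(out, samples)
}

#' Build the three method-comparison pairings
#'
#' Assembles comparator/reference concentration pairs for the three
#' comparisons: capillary DBS vs venous WB (`DBS-WB`), venous-blood spot vs
#' venous WB (`DBSwb-WB`), and capillary spot vs venous-blood spot
#' (`DBS-DBSwb`). `x` is always the comparator and `y` the reference. Only
#' patients with both members present enter a pairing; a pairing with fewer
#' than 3 complete pairs is dropped with a warning.
#'
#' @param samples A sample table; [resolve_dbs()] is applied if the resolved
#'   `dbs` column is absent.
#' @return A long tibble with `pair_name`, `patient_id`, `x`, `y`.
#' @export
build_pairs <- function(samples) {
  if (!"dbs" %in% names(samples)) samples <- resolve_dbs(samples)
  defs <- list(
    "DBS-WB" = c(x = "dbs", y = "wb"),
    "DBSwb-WB" = c(x = "dbs_wb", y = "wb"),
    "DBS-DBSwb" = c(x = "dbs", y = "dbs_wb")
  )
  pairs <- purrr::imap(defs, function(cols, nm) {
    tibble(
      pair_name = nm,
      patient_id = samples$patient_id,
      x = samples[[cols[["x"]]]],
      y = samples[[cols[["y"]]]]
    ) |> filter(!is.na(.data$x), !is.na(.data$y))
  })
  short <- purrr::map_int(pairs, nrow) < 3
  if (all(short)) {
    abort("Fewer than 3 complete pairs in every comparison; cannot pair.")
  }
  if (any(short)) {
    warn(paste0("Dropped comparison(s) with fewer than 3 complete pairs: ",
                paste(names(pairs)[short], collapse = ", ")))
  }
  bind_rows(pairs[!short])
}

#' Quality-control log of a sample table
#'
#' One row per input patient stating what happened to it: `analyzed`,
#' `flagged` (analyzed with warnings), or `excluded` (no usable DBS
#' duplicate), plus any rejected input rows.
#'
#' @param samples A sample table after [resolve_dbs()]/[flag_hematocrit()].
#' @return A tibble with `patient_id`, `action`, `flags`.
#' @export
qc_log <- function(samples) {
  action <- dplyr::case_when(
    has_flag(samples$flags, "dbs_excluded") ~ "excluded",
    !is.na(samples$flags) & samples$flags != "" ~ "flagged",
    TRUE ~ "analyzed"
  )
  log <- tibble(patient_id = samples$patient_id, action = action,
                flags = samples$flags)
  rej <- rejections(samples)
  if (nrow(rej) > 0) {
    log <- bind_rows(log, tibble(patient_id = rej$patient_id,
                                 action = "rejected", flags = rej$reason))
  }
  log
}

#' Write a paired-sample table to CSV
#'
#' Inverse of [read_samples()]: writes the canonical columns so the file
#' round-trips field-identically.
#'
#' @param samples A sample table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  readr::write_csv(samples[sample_columns()], path, progress = FALSE)
  invisible(path)
}

keep_attr <- function(out, from) {
  attr(out, "rejected") <- attr(from, "rejected")
  out
}
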