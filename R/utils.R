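# shared input checks and small helpers

pull_num <- function(data, col) {
  v <- dplyr::pull(data, {{ col }})
  if (!is.numeric(v)) abort("Selected column must be numeric.")
  as.numeric(v)
}

check_pair_vectors <- function(x, y, min_n = 3, positive_x = FALSE,
                               positive_y = FALSE) {
  if (length(x) != length(y)) abort("x and y must have the same length.")
  if (length(x) < min_n) {
    abort(sprintf("At least %d paired values are required.", min_n))
  }
  if (anyNA(x) || anyNA(y)) abort("Paired values must not contain missing.")
  if (positive_x && any(x <= 0)) abort("x must be strictly positive.")
  if (positive_y && any(y <= 0)) abort("y must be strictly positive.")
  invisible(TRUE)
}

# flags are stored as a semicolon-separated character column
add_flag <- function(flags, new, where = TRUE) {
  flags[is.na(flags)] <- ""
  out <- flags
  hit <- where & !grepl(new, flags, fixed = TRUE)
  out[hit] <- ifelse(out[hit] == "", new, paste(out[hit], new, sep = ";"))
  out
}

has_flag <- function(flags, what) {
  !is.na(flags) & grepl(what, flags, fixed = TRUE)
}
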