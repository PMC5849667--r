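# Independent, deliberately plain (loop-based) oracles used to cross-check
# the vectorised implementations.

# Exhaustive-enumeration Passing-Bablok: slopes via double loop, shifted
# median by hand, rank-based CI by hand. Returns NULL components where the
# estimator is undefined.
oracle_pb <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0) next
      s <- dy / dx
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  if (length(slopes) == 0) return(NULL)
  slopes <- sort(slopes)
  nn <- length(slopes)
  K <- sum(slopes < -1)
  if (nn %% 2 == 1) {
    idx <- (nn + 1) / 2 + K
    if (idx < 1 || idx > nn) return(NULL)
    b <- slopes[idx]
  } else {
    idx <- nn / 2 + K
    if (idx < 1 || idx + 1 > nn) return(NULL)
    b <- (slopes[idx] + slopes[idx + 1]) / 2
  }
  a <- median(y - b * x)
  z <- qnorm(1 - (1 - conf_level) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((nn - C) / 2)
  m2 <- nn - m1 + 1
  lo_idx <- min(max(m1 + K, 1), nn)
  hi_idx <- min(max(m2 + K, 1), nn)
  b_lo <- slopes[lo_idx]
  b_hi <- slopes[hi_idx]
  list(
    slopes = slopes, offset_k = K, slope = b, intercept = a,
    slope_ci = c(b_lo, b_hi),
    intercept_ci = c(median(y - b_hi * x), median(y - b_lo * x))
  )
}

# random positively-related small instance; rounding induces ties/equal x
random_small_instance <- function(n = NULL) {
  if (is.null(n)) n <- sample(3:8, 1)
  x <- round(runif(n, 1, 30), sample(0:2, 1))
  b <- runif(1, 0.3, 3)
  a <- runif(1, -2, 2)
  y <- round(a + b * x + rnorm(n, 0, runif(1, 0.01, 3)), sample(0:2, 1))
  y <- pmax(y, 0.1)
  tibble::tibble(x = x, y = y)
}

quiet_pb <- function(...) suppressWarnings(pb_fit(...))

# noise-free study conditions: exact linear relation WB = a + b * DBS
noise_free_config <- function(seed = 11L, intercept = 0.02, n = 20) {
  synthetic_config(
    n_patients = n, intercept = intercept, ratio_cv = 0,
    duplicate_cv = 0, dbswb_cv = 0, invalid_spot_rate = 0, seed = seed
  )
}
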