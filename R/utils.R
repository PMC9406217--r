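# internal argument checks shared across modules

assert_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || !lo_ok || !hi_ok) {
    abort(sprintf("`%s` must be a single fraction in [0, 1], got %s",
                  name, paste(format(x), collapse = ", ")),
          class = "foxscreen_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "foxscreen_config_error")
  }
  invisible(as.integer(x))
}

assert_positive <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name),
          class = "foxscreen_config_error")
  }
  invisible(x)
}

# Welch/pooled t-test that tolerates zero-variance groups instead of erroring
safe_t_test <- function(x, y, alternative = "two.sided", var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    abort("at least 2 replicates per group are required for a t-test",
          class = "foxscreen_input_error")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    d <- mean(x) - mean(y)
    p <- switch(alternative,
                two.sided = if (d == 0) 1 else 0,
                greater   = if (d > 0) 0 else 1,
                less      = if (d < 0) 0 else 1)
    return(list(p.value = p, statistic = if (d == 0) 0 else sign(d) * Inf))
  }
  stats::t.test(x, y, alternative = alternative, var.equal = var_equal)
}

# whole-percent presentation of a count ratio (e.g. 115/186 -> 62)
count_percent <- function(k, n) {
  if (n <= 0) abort("denominator must be positive", class = "foxscreen_input_error")
  round(100 * k / n)
}
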