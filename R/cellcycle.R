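#' Fit the G1 center from a synchronized control
#'
#' In a fully synchronized control all cells are in G1, so the dominant mode
#' of the DNA-content histogram marks the G1 center. The fit locates the
#' dominant density mode and computes a local Gaussian fit (mean and SD) of
#' the events within `trim` of the mode. A control with two comparable
#' density modes is rejected as unsynchronized.
#'
#' @param events Numeric vector of per-event DNA-content intensities, or a
#'   data frame with an `intensity` column.
#' @param trim Half-width of the local fit window as a fraction of the mode
#'   location (default 0.25).
#' @param min_events Minimum number of events required (default 500).
#' @param bimodal_height Secondary density peaks at least this fraction of
#'   the main peak height and more than 20% of the mode away trigger the
#'   bimodality error (default 0.5).
#' @return A `g1_fit` object with `mu`, `sigma`, `mode`, `n`.
#' @export
#' @examples
#' fit <- fit_g1(rnorm(2000, 100, 3))
#' fit$mu
fit_g1 <- function(events, trim = 0.25, min_events = 500,
                   bimodal_height = 0.5) {
  if (is.data.frame(events)) events <- events$intensity
  events <- events[is.finite(events)]
  if (length(events) < min_events) {
    abort(sprintf("need at least %d control events, got %d",
                  min_events, length(events)),
          class = "foxscreen_input_error")
  }
  if (sd(events) == 0) {
    return(structure(list(mu = events[[1]], sigma = 0, mode = events[[1]],
                          n = length(events)), class = "g1_fit"))
  }
  d <- density(events)
  peak <- which(diff(sign(diff(d$y))) == -2) + 1L
  if (!length(peak)) peak <- which.max(d$y)
  main <- peak[which.max(d$y[peak])]
  mode <- d$x[main]
  rivals <- peak[d$y[peak] >= bimodal_height * d$y[main] &
                   abs(d$x[peak] - mode) > 0.2 * abs(mode)]
  if (length(rivals)) {
    abort("control histogram is bimodal: control does not look synchronized",
          class = "foxscreen_control_error")
  }
  win <- events[events >= mode * (1 - trim) & events <= mode * (1 + trim)]
  structure(list(mu = mean(win), sigma = sd(win), mode = mode,
                 n = length(events)),
            class = "g1_fit")
}

#' @export
print.g1_fit <- function(x, ...) {
  cat(sprintf("<g1_fit> mu=%.4g sigma=%.4g (n=%d events)\n",
              x$mu, x$sigma, x$n))
  invisible(x)
}

#' Phase gates anchored on a fitted G1 center
#'
#' The G1 gate is `mu +/- k * sigma`; the G2/M gate is centered at exactly
#' twice the G1 center (DNA content doubles) with doubled half-width,
#' `2*mu +/- 2*k*sigma`; S phase is the open interval between the gates.
#'
#' The default half-width of 2 control SDs balances the two leakage modes
#' analytically: wider gates swallow more true S-phase events, narrower
#' gates spill more G1/G2-M tail mass into the S interval.
#'
#' @param fit A [fit_g1()] object.
#' @param k Gate half-width in control SDs (default 2).
#' @return A `phase_gates` object.
#' @export
build_gates <- function(fit, k = 2) {
  stopifnot(inherits(fit, "g1_fit"))
  assert_positive(k, "k")
  g1 <- c(fit$mu - k * fit$sigma, fit$mu + k * fit$sigma)
  g2 <- c(2 * fit$mu - 2 * k * fit$sigma, 2 * fit$mu + 2 * k * fit$sigma)
  if (g1[2] >= g2[1]) {
    abort("G1 and G2/M gates overlap; reduce `k` or check the control fit",
          class = "foxscreen_input_error")
  }
  structure(list(g1_center = fit$mu, g2_center = 2 * fit$mu,
                 g1 = g1, g2 = g2, k = k, sigma = fit$sigma),
            class = "phase_gates")
}

#' @export
print.phase_gates <- function(x, ...) {
  cat(sprintf("<phase_gates> G1 [%.4g, %.4g]  S (%.4g, %.4g)  G2/M [%.4g, %.4g]\n",
              x$g1[1], x$g1[2], x$g1[2], x$g2[1], x$g2[1], x$g2[2]))
  invisible(x)
}

#' Gate DNA-content events into cell-cycle phases
#'
#' Events inside the closed G1 and G2/M gates are assigned to those phases;
#' events strictly between the gates are S phase; events below the G1 gate
#' (sub-G1 debris) or above the G2/M gate are excluded rather than assigned,
#' so they cannot bias the phase fractions.
#'
#' @param events Numeric vector of intensities, or a data frame with an
#'   `intensity` column.
#' @param gates A [build_gates()] object, or a [fit_g1()] object (gates are
#'   then built with half-width `k`).
#' @param k Gate half-width used when `gates` is a `g1_fit` (default 2).
#' @return A one-row `phase_distribution` tibble with `n_events` and
#'   fractions `g1`, `s`, `g2m`, `excluded` (summing to 1).
#' @export
#' @examples
#' ev <- generate_cytometry_events(synth_cytometry_config(seed = 1))
#' ctrl <- generate_cytometry_events(
#'   synth_cytometry_config(fractions = c(1, 0, 0), seed = 2))
#' gate_phases(ev, fit_g1(ctrl))
gate_phases <- function(events, gates, k = 2) {
  if (inherits(gates, "g1_fit")) gates <- build_gates(gates, k = k)
  stopifnot(inherits(gates, "phase_gates"))
  if (is.data.frame(events)) events <- events$intensity
  events <- events[is.finite(events)]
  n <- length(events)
  if (!n) abort("no events to gate", class = "foxscreen_input_error")
  n_g1 <- sum(events >= gates$g1[1] & events <= gates$g1[2])
  n_g2 <- sum(events >= gates$g2[1] & events <= gates$g2[2])
  n_s <- sum(events > gates$g1[2] & events < gates$g2[1])
  out <- tibble(
    n_events = n,
    g1 = n_g1 / n,
    s = n_s / n,
    g2m = n_g2 / n,
    excluded = 1 - (n_g1 + n_s + n_g2) / n
  )
  class(out) <- c("phase_distribution", class(out))
  attr(out, "gates") <- gates
  out
}

#' Compare G2/M fractions between treated and control replicates
#'
#' One-sided Welch t-test for an increase in the per-replicate G2/M
#' fraction, the criterion used to flag compounds that delay the G2/M
#' transition.
#'
#' @param treated,control Numeric vectors of per-replicate G2/M fractions
#'   (at least 2 each), or data frames with a `g2m` column (e.g. row-bound
#'   [gate_phases()] outputs).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use pooled-variance t instead of Welch (default FALSE).
#' @return One-row tibble with group means, difference, `p_value` and the
#'   `increased` flag.
#' @export
compare_g2m <- function(treated, control, alpha = 0.05, var_equal = FALSE) {
  if (is.data.frame(treated)) treated <- treated$g2m
  if (is.data.frame(control)) control <- control$g2m
  if (length(treated) < 2 || length(control) < 2) {
    abort("at least 2 replicates per arm are required",
          class = "foxscreen_input_error")
  }
  tt <- safe_t_test(treated, control, alternative = "greater",
                    var_equal = var_equal)
  tibble(
    mean_treated = mean(treated),
    mean_control = mean(control),
    difference = mean(treated) - mean(control),
    p_value = tt$p.value,
    increased = tt$p.value < alpha
  )
}

#' @rdname tidy.g1_fit
#' @method glance g1_fit
#' @export
glance.g1_fit <- function(x, ...) {
  tibble(mu = x$mu, sigma = x$sigma, mode = x$mode, n = x$n)
}

#' Tidy cell-cycle fit objects
#'
#' @param x A `g1_fit` or `phase_gates` object.
#' @param ... Unused.
#' @return A tibble: per-parameter rows for `tidy()`, a one-row summary for
#'   `glance()`.
#' @method tidy g1_fit
#' @export
tidy.g1_fit <- function(x, ...) {
  tibble(term = c("mu", "sigma"), estimate = c(x$mu, x$sigma))
}

#' @rdname tidy.g1_fit
#' @method tidy phase_gates
#' @export
tidy.phase_gates <- function(x, ...) {
  tibble(phase = c("g1", "s", "g2m"),
         lower = c(x$g1[1], x$g1[2], x$g2[1]),
         upper = c(x$g1[2], x$g2[1], x$g2[2]),
         closed = c(TRUE, FALSE, TRUE))
}
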