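#' Volcano plot of a classified differential-expression table
#'
#' @param de Tibble from [classify_de()].
#' @return A ggplot.
#' @export
plot_volcano <- function(de) {
  de |>
    filter(!is.na(.data$p_adj)) |>
    ggplot2::ggplot(ggplot2::aes(.data$log_fold_change,
                                 -log10(.data$p_adj),
                                 colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dose-response growth and viability curves
#'
#' @param summaries A [summarize_doses()] tibble.
#' @return A ggplot with percent growth and percent viability per dose,
#'   faceted by compound.
#' @export
plot_dose_response <- function(summaries) {
  long <- summaries |>
    as_tibble() |>
    tidyr::pivot_longer(c("percent_growth", "percent_viability"),
                        names_to = "metric", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(.data$dose, .data$percent,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$toxic)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$compound)) +
    ggplot2::labs(x = "dose", y = "%", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot dose_summary
#' @export
autoplot.dose_summary <- function(object, ...) plot_dose_response(object)

#' DNA-content histogram with phase gates
#'
#' @param events Numeric intensities or a data frame with `intensity`.
#' @param gates Optional [build_gates()] object drawn as shaded phase
#'   intervals.
#' @param bins Histogram bins (default 120).
#' @return A ggplot.
#' @export
plot_dna_content <- function(events, gates = NULL, bins = 120) {
  if (is.data.frame(events)) events <- events$intensity
  p <- ggplot2::ggplot(tibble(intensity = events),
                       ggplot2::aes(.data$intensity)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::labs(x = "DNA content (a.u.)", y = "events") +
    ggplot2::theme_minimal()
  if (!is.null(gates)) {
    bands <- tidy(gates)
    p <- p + ggplot2::geom_rect(
      data = bands, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                   ymin = -Inf, ymax = Inf, fill = .data$phase),
      alpha = 0.2)
  }
  p
}

#' @method autoplot phase_distribution
#' @export
autoplot.phase_distribution <- function(object, ...) {
  long <- object |>
    as_tibble() |>
    tidyr::pivot_longer(c("g1", "s", "g2m", "excluded"),
                        names_to = "phase", values_to = "fraction") |>
    mutate(phase = factor(.data$phase, c("g1", "s", "g2m", "excluded")))
  ggplot2::ggplot(long, ggplot2::aes(.data$phase, .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of events") +
    ggplot2::theme_minimal()
}

#' Information-content profile of a scoring matrix
#'
#' @param object A [build_pwm()] object.
#' @param ... Unused.
#' @return A ggplot of per-position information content; core positions
#'   highlighted.
#' @method autoplot foxd_pwm
#' @export
autoplot.foxd_pwm <- function(object, ...) {
  d <- tibble(position = seq_len(object$width), ic = object$ic,
              core = object$core,
              base = strsplit(object$consensus, "")[[1]])
  ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$ic,
                                  fill = .data$core)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$base), vjust = -0.4) +
    ggplot2::scale_x_continuous(breaks = d$position) +
    ggplot2::labs(y = "information content (bits)", fill = "core") +
    ggplot2::theme_minimal()
}

#' Tidy a scoring matrix
#'
#' `tidy()` returns one row per matrix cell (position, base, log-odds);
#' `glance()` a one-row summary (width, score range, consensus, core size).
#'
#' @param x A [build_pwm()] object.
#' @param ... Unused.
#' @method tidy foxd_pwm
#' @export
tidy.foxd_pwm <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$width), each = 4),
    base = rep(BASES, x$width),
    log_odds = as.numeric(x$logodds),
    consensus = rep(strsplit(x$consensus, "")[[1]], each = 4),
    core = rep(x$core, each = 4)
  )
}

#' @rdname tidy.foxd_pwm
#' @method glance foxd_pwm
#' @export
glance.foxd_pwm <- function(x, ...) {
  tibble(name = x$name, width = x$width, s_min = x$s_min, s_max = x$s_max,
         consensus = x$consensus, n_core = sum(x$core))
}
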