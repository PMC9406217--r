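#' Summarise a dose-response plate against vehicle wells
#'
#' For every compound/dose group: percent growth is 100 times the mean
#' treated total over the mean vehicle total (percent inhibition is its
#' complement); percent viability is 100 times the mean count of
#' dead-stain-negative cells over the mean total. Growth is compared with
#' vehicle by a two-sided t-test on per-well totals, and toxicity is called
#' when the per-well dead fraction is significantly *greater* than vehicle
#' (one-sided t-test at `alpha`) — a drop in cell number without excess
#' death indicates a proliferation effect, not cytotoxicity.
#'
#' @param plate Tibble with `compound`, `dose`, `replicate`, `total_cells`,
#'   `dead_cells`; vehicle wells have `dose == vehicle_dose`.
#' @param alpha Significance level (default 0.05).
#' @param vehicle_dose Dose value marking vehicle wells (default 0).
#' @param var_equal Pooled-variance t-tests instead of Welch (default
#'   FALSE).
#' @return A `dose_summary` tibble with one row per compound/dose:
#'   `percent_growth`, `percent_inhibition`, `percent_viability`,
#'   `growth_p`, `death_p`, `toxic`, `n`.
#' @export
#' @examples
#' plate <- generate_plate(doses = c(1, 10, 100), ec50 = 10, emax = 0.6,
#'                         seed = 1)
#' summarize_doses(plate)
summarize_doses <- function(plate, alpha = 0.05, vehicle_dose = 0,
                            var_equal = FALSE) {
  plate <- as_tibble(plate)
  req <- c("compound", "dose", "total_cells", "dead_cells")
  if (!all(req %in% names(plate))) {
    abort(paste("missing plate column(s):",
                paste(setdiff(req, names(plate)), collapse = ", ")),
          class = "foxscreen_input_error")
  }
  if (any(plate$dead_cells > plate$total_cells | plate$dead_cells < 0)) {
    abort("dead_cells must lie in [0, total_cells]",
          class = "foxscreen_input_error")
  }
  out <- plate |>
    group_by(.data$compound) |>
    dplyr::group_modify(function(df, key) {
      veh <- filter(df, .data$dose == vehicle_dose)
      if (nrow(veh) < 2) abort("need >= 2 vehicle replicates per compound",
                               class = "foxscreen_input_error")
      if (mean(veh$total_cells) == 0) abort("vehicle mean cell count is zero",
                                            class = "foxscreen_input_error")
      trt <- filter(df, .data$dose != vehicle_dose)
      veh_frac <- veh$dead_cells / pmax(veh$total_cells, 1)
      trt |>
        group_by(.data$dose) |>
        dplyr::group_modify(function(g, k) {
          if (nrow(g) < 2) abort("need >= 2 replicates per dose",
                                 class = "foxscreen_input_error")
          pg <- 100 * mean(g$total_cells) / mean(veh$total_cells)
          viab <- 100 * mean(g$total_cells - g$dead_cells) /
            mean(g$total_cells)
          gt <- safe_t_test(g$total_cells, veh$total_cells,
                            var_equal = var_equal)
          dt <- safe_t_test(g$dead_cells / pmax(g$total_cells, 1), veh_frac,
                            alternative = "greater", var_equal = var_equal)
          tibble(n = nrow(g), percent_growth = pg,
                 percent_inhibition = 100 - pg,
                 percent_viability = viab,
                 growth_p = gt$p.value, death_p = dt$p.value,
                 toxic = dt$p.value < alpha)
        }) |>
        ungroup()
    }) |>
    ungroup()
  class(out) <- c("dose_summary", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Optimal dose: greatest inhibition without toxicity
#'
#' Among doses that are not toxic and show a significant growth reduction
#' (`growth_p < alpha`), returns the dose with the greatest percent
#' inhibition (ties to the lowest dose). `NA` with a warning when no dose
#' qualifies.
#'
#' @param summaries A [summarize_doses()] tibble.
#' @param alpha Significance level (default the level stored on the
#'   summary, else 0.05).
#' @return Tibble with one row per compound: `optimal_dose`,
#'   `percent_inhibition` at that dose.
#' @export
optimal_dose <- function(summaries, alpha = attr(summaries, "alpha") %||% 0.05) {
  summaries |>
    as_tibble() |>
    group_by(.data$compound) |>
    dplyr::group_modify(function(df, key) {
      ok <- filter(df, !.data$toxic, .data$growth_p < alpha)
      if (!nrow(ok)) {
        warn(sprintf("no non-toxic significantly inhibitory dose for %s",
                     key$compound))
        return(tibble(optimal_dose = NA_real_,
                      percent_inhibition = NA_real_))
      }
      best <- ok[order(-ok$percent_inhibition, ok$dose), ][1, ]
      tibble(optimal_dose = best$dose,
             percent_inhibition = best$percent_inhibition)
    }) |>
    ungroup()
}

#' Compare two growth curves at their shared endpoint
#'
#' Two-sided t-test on final-day replicate counts, the endpoint comparison
#' used for conditioned-media and native-ECM growth assays.
#'
#' @param a,b Tibbles with `day` and `count` columns (replicate rows per
#'   day).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance t instead of Welch (default FALSE).
#' @return One-row tibble with the final day, group means, `p_value`,
#'   `significant`.
#' @export
compare_growth_curves <- function(a, b, alpha = 0.05, var_equal = FALSE) {
  for (x in list(a, b)) {
    if (!all(c("day", "count") %in% names(x))) {
      abort("growth curves need `day` and `count` columns",
            class = "foxscreen_input_error")
    }
    if (any(x$count < 0)) abort("counts must be non-negative",
                                class = "foxscreen_input_error")
  }
  if (max(a$day) != max(b$day)) {
    abort("curves do not share a final day", class = "foxscreen_input_error")
  }
  d <- max(a$day)
  xa <- a$count[a$day == d]
  xb <- b$count[b$day == d]
  if (length(xa) < 2 || length(xb) < 2) {
    abort("at least 2 endpoint replicates per curve are required",
          class = "foxscreen_input_error")
  }
  tt <- safe_t_test(xa, xb, var_equal = var_equal)
  tibble(day = d, mean_a = mean(xa), mean_b = mean(xb),
         p_value = tt$p.value, significant = tt$p.value < alpha)
}
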