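#' Generate a synthetic dose-response plate
#'
#' Per-well total and dead cell counts for one compound across doses plus
#' vehicle wells (dose 0). The expected total follows a Hill inhibition
#' curve, `vehicle_mean * (1 - emax * d^h / (d^h + ec50^h))`; totals are
#' Poisson around the expectation and dead counts binomial with a death
#' fraction that can itself follow a Hill curve (a toxic compound).
#'
#' @param vehicle_mean Expected cells per vehicle well.
#' @param doses Numeric vector of doses (> 0); vehicle wells at dose 0 are
#'   added automatically.
#' @param ec50,hill,emax Hill parameters of growth inhibition
#'   (`emax` in \[0, 1\]).
#' @param death_base Baseline dead fraction in every well.
#' @param death_emax,death_ec50,death_hill Hill parameters of the added
#'   drug-induced death fraction (default 0: non-toxic compound).
#' @param n_replicates Wells per dose (default 3).
#' @param compound Compound label.
#' @param seed Integer seed.
#' @return Tibble with `compound`, `dose`, `replicate`, `total_cells`,
#'   `dead_cells` and the noiseless `expected_total` truth column.
#' @export
#' @examples
#' generate_plate(doses = c(1, 10, 100), ec50 = 10, emax = 0.5, seed = 1)
generate_plate <- function(vehicle_mean = 2000, doses = c(1, 3, 10, 30, 100),
                           ec50 = 10, hill = 1, emax = 0.5,
                           death_base = 0.05, death_emax = 0,
                           death_ec50 = ec50, death_hill = hill,
                           n_replicates = 3, compound = "compound",
                           seed = 1L) {
  assert_positive(vehicle_mean, "vehicle_mean")
  assert_count(n_replicates, "n_replicates", min = 1)
  assert_fraction(emax, "emax")
  assert_fraction(death_base, "death_base")
  if (any(doses <= 0)) abort("doses must be positive (vehicle is added as dose 0)",
                             class = "foxscreen_config_error")
  hillf <- function(d, e, c50, h) ifelse(d <= 0, 0, e * d^h / (d^h + c50^h))
  all_doses <- c(0, sort(doses))
  with_seed(seed, {
    grid <- tidyr::expand_grid(dose = all_doses,
                               replicate = seq_len(n_replicates))
    expected <- vehicle_mean * (1 - hillf(grid$dose, emax, ec50, hill))
    death_frac <- pmin(death_base +
                         hillf(grid$dose, death_emax, death_ec50, death_hill),
                       0.999)
    total <- rpois(nrow(grid), expected)
    dead <- rbinom(nrow(grid), total, death_frac)
    tibble(compound = compound, dose = grid$dose,
           replicate = grid$replicate,
           total_cells = total, dead_cells = dead,
           expected_total = expected)
  })
}
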