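#' Configuration for synthetic DNA-content cytometry events
#'
#' Emulates a DNA-stain histogram: G1 events are Normal(`g1_mean`,
#' `cv * g1_mean`), G2/M events Normal(`2 * g1_mean`, `cv * 2 * g1_mean`)
#' (replicated genomes double the signal), and S-phase events uniform
#' between the two centers. Event counts follow the phase fractions
#' multinomially.
#'
#' @param n_events Number of events.
#' @param g1_mean G1 intensity center (arbitrary units, > 0).
#' @param cv Coefficient of variation of the G1 and G2/M components.
#' @param fractions Named or positional numeric of length 3 `(g1, s, g2m)`
#'   summing to 1.
#' @param seed Integer seed.
#' @return A `synth_cytometry_config` list.
#' @export
synth_cytometry_config <- function(n_events = 10000, g1_mean = 100,
                                   cv = 0.03,
                                   fractions = c(g1 = 0.6, s = 0.2,
                                                 g2m = 0.2),
                                   seed = 1L) {
  assert_count(n_events, "n_events")
  assert_positive(g1_mean, "g1_mean")
  assert_fraction(cv, "cv")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be 3 non-negative values summing to 1",
          class = "foxscreen_config_error")
  }
  fractions <- setNames(as.numeric(fractions), c("g1", "s", "g2m"))
  structure(list(n_events = as.integer(n_events), g1_mean = g1_mean,
                 cv = cv, fractions = fractions, seed = as.integer(seed)),
            class = "synth_cytometry_config")
}

#' Generate synthetic DNA-content events with phase truth labels
#'
#' @param cfg A [synth_cytometry_config()].
#' @return Tibble with `intensity` and `true_phase` (`g1`/`s`/`g2m`).
#' @export
#' @examples
#' ev <- generate_cytometry_events(synth_cytometry_config(n_events = 1000,
#'                                                        seed = 1))
#' table(ev$true_phase)
generate_cytometry_events <- function(cfg) {
  stopifnot(inherits(cfg, "synth_cytometry_config"))
  with_seed(cfg$seed, {
    counts <- as.integer(rmultinom(1, cfg$n_events, cfg$fractions))
    m <- cfg$g1_mean
    intensity <- c(
      rnorm(counts[1], m, cfg$cv * m),
      runif(counts[2], m, 2 * m),
      rnorm(counts[3], 2 * m, cfg$cv * 2 * m)
    )
    phase <- rep(c("g1", "s", "g2m"), counts)
    ord <- sample.int(length(intensity))
    tibble(intensity = intensity[ord], true_phase = phase[ord])
  })
}

#' Write cytometry events as a single-column CSV
#'
#' @param events Tibble from [generate_cytometry_events()] or a numeric
#'   vector.
#' @param path Output path.
#' @export
write_cytometry_csv <- function(events, path) {
  x <- if (is.data.frame(events)) events$intensity else events
  readr::write_csv(tibble(intensity = x), path)
  invisible(path)
}
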