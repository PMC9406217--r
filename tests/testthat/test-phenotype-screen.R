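mk_plate <- function(totals, deads, doses, compound = "c") {
  tibble::tibble(compound = compound,
                 dose = rep(doses, each = length(totals) / length(doses)),
                 replicate = sequence(rle(rep(doses,
                   each = length(totals) / length(doses)))$lengths),
                 total_cells = totals, dead_cells = deads)
}

test_that("percent growth, inhibition and viability follow their definitions", {
  pl <- mk_plate(totals = c(100, 100, 100, 100, 100, 100),
                 deads = rep(0, 6), doses = c(0, 1))
  s <- summarize_doses(pl)
  expect_equal(s$percent_growth, 100)
  expect_equal(s$percent_inhibition, 0)
  expect_equal(s$percent_viability, 100)
  expect_false(s$toxic)

  pl2 <- mk_plate(totals = c(200, 200, 200, 50, 50, 50),
                  deads = c(0, 0, 0, 25, 25, 25), doses = c(0, 1))
  s2 <- summarize_doses(pl2)
  expect_equal(s2$percent_growth, 25)
  expect_equal(s2$percent_inhibition, 75)
  expect_equal(s2$percent_viability, 50)
  expect_error(summarize_doses(mk_plate(c(10, 10, 10, 10),
                                        c(20, 0, 0, 0), c(0, 1))),
               class = "foxscreen_input_error")
})

test_that("computed percent-growth curve matches the analytic Hill expectation", {
  doses <- c(1, 3, 10, 30, 100)
  pl <- generate_plate(vehicle_mean = 5000, doses = doses, ec50 = 10,
                       hill = 1, emax = 0.5, n_replicates = 3, seed = 5)
  s <- summarize_doses(pl)
  expected <- 100 * (1 - 0.5 * doses / (doses + 10))
  expect_equal(s$percent_growth, expected, tolerance = 0.03)
})

test_that("optimal dose is the most inhibitory non-toxic significant dose", {
  s <- tibble::tibble(compound = "c", dose = c(1, 10, 100),
                      n = 3,
                      percent_growth = c(90, 60, 30),
                      percent_inhibition = c(10, 40, 70),
                      percent_viability = c(99, 98, 97),
                      growth_p = c(0.2, 0.01, 0.001),
                      death_p = c(0.5, 0.5, 0.5),
                      toxic = c(FALSE, FALSE, FALSE))
  expect_equal(optimal_dose(s)$optimal_dose, 100)
  s$toxic[3] <- TRUE
  expect_equal(optimal_dose(s)$optimal_dose, 10)
  s$toxic <- TRUE
  expect_warning(od <- optimal_dose(s), "no non-toxic")
  expect_true(is.na(od$optimal_dose))
})

test_that("optimal dose equals an exhaustive-search oracle on random summaries", {
  for (seed in 1:10) {
    s <- withr::with_seed(seed, tibble::tibble(
      compound = "c", dose = 1:8, n = 3,
      percent_inhibition = stats::runif(8, 0, 80),
      growth_p = stats::runif(8, 0, 0.2),
      death_p = stats::runif(8), toxic = stats::runif(8) < 0.4))
    s$percent_growth <- 100 - s$percent_inhibition
    s$percent_viability <- 95
    ok <- !s$toxic & s$growth_p < 0.05
    if (any(ok)) {
      oracle <- s$dose[ok][which.max(s$percent_inhibition[ok])]
      expect_equal(optimal_dose(s, alpha = 0.05)$optimal_dose, oracle)
    } else {
      expect_warning(od <- optimal_dose(s, alpha = 0.05))
      expect_true(is.na(od$optimal_dose))
    }
  }
})

test_that("toxicity is never called without excess death and optimal dose is safe", {
  pl <- generate_plate(vehicle_mean = 2000, doses = c(1, 10, 100),
                       ec50 = 10, emax = 0.6, death_base = 0.05,
                       death_emax = 0.5, death_ec50 = 50,
                       n_replicates = 3, seed = 9)
  s <- summarize_doses(pl)
  od <- tryCatch(optimal_dose(s), warning = function(w) NULL)
  if (!is.null(od) && !is.na(od$optimal_dose)) {
    expect_false(s$toxic[s$dose == od$optimal_dose])
  }
  expect_true(TRUE)
})

test_that("growth-curve endpoint comparison behaves at its boundaries", {
  a <- tibble::tibble(day = rep(1:3, each = 3),
                      count = c(10, 10, 10, 20, 20, 20, 40, 41, 39))
  expect_equal(compare_growth_curves(a, a)$p_value, 1)
  b <- a; b$count <- b$count / 2
  cmp <- compare_growth_curves(a, b)
  expect_true(cmp$significant)
  expect_equal(cmp$day, 3)
  single <- tibble::tibble(day = 3, count = 10)
  expect_error(compare_growth_curves(a, single),
               class = "foxscreen_input_error")
  mism <- tibble::tibble(day = rep(1:2, each = 2), count = 1:4)
  expect_error(compare_growth_curves(a, mism),
               class = "foxscreen_input_error")
})

test_that("summaries are invariant to replicate order", {
  pl <- generate_plate(doses = c(1, 10), ec50 = 5, emax = 0.4, seed = 3)
  shuffled <- withr::with_seed(1, pl[sample(nrow(pl)), ])
  a <- summarize_doses(pl)
  b <- summarize_doses(shuffled)
  expect_equal(as.data.frame(a), as.data.frame(b))
})
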