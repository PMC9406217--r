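test_that("DE generator honours missingness, null fraction and determinism", {
  tbl <- generate_de_table(synth_de_config(n_genes = 100,
                                           frac_missing_padj = 0.1,
                                           seed = 4))
  expect_equal(sum(is.na(tbl$p_adj)), 10)

  null_tbl <- generate_de_table(synth_de_config(n_genes = 200,
                                                frac_differential = 0,
                                                seed = 5))
  expect_true(all(null_tbl$p_adj[!is.na(null_tbl$p_adj)] > 0.05))

  a <- generate_de_table(synth_de_config(n_genes = 300, seed = 11))
  b <- generate_de_table(synth_de_config(n_genes = 300, seed = 11))
  expect_identical(a, b)
  expect_error(synth_de_config(frac_differential = 1.2),
               class = "foxscreen_config_error")
})

test_that("classification recovers generator truth labels exactly", {
  tbl <- generate_de_table(synth_de_config(n_genes = 1000,
                                           frac_differential = 0.3,
                                           seed = 7))
  cls <- classify_de(tbl, quiet = TRUE)
  expect_identical(cls$status, cls$true_status)
  diff <- cls[cls$status == "differential", ]
  expect_identical(diff$direction, diff$true_direction)
})

test_that("promoter generator plants recoverable sites and validates offsets", {
  pwm <- test_pwm()
  cfg <- synth_promoter_config(
    n_promoters = 2, planted = data.frame(promoter = c(1, 1),
                                          offset = c(100, 180),
                                          strand = c("+", "+")), seed = 1)
  gen <- generate_promoters(cfg, pwm)
  expect_true(all(gen$truth$cluster_eligible))  # starts 80 apart
  hits <- scan_promoter(gen$sequences[[1]], pwm, promoter_id = "promoter_1")
  expect_true(all(c(100, 180) %in% hits$start))
  expect_true(all(hits$deficit[hits$start %in% c(100, 180)] < 1e-9))

  empty <- generate_promoters(synth_promoter_config(n_promoters = 2,
                                                    seed = 2), pwm)
  expect_equal(nrow(empty$truth), 0)
  expect_identical(
    generate_promoters(cfg, pwm)$sequences, gen$sequences)
  expect_error(
    generate_promoters(synth_promoter_config(
      n_promoters = 1, window_upstream = 100, window_downstream = 0,
      planted = data.frame(promoter = 1, offset = 99, strand = "+"),
      seed = 1), pwm),
    class = "foxscreen_config_error")
})

test_that("planted consensus sites are fully recovered across promoters", {
  pwm <- test_pwm()
  cfg <- synth_promoter_config(
    n_promoters = 50,
    planted = data.frame(promoter = 1:50,
                         offset = seq(10, 1500, length.out = 50),
                         strand = rep(c("+", "-"), 25)),
    seed = 9)
  gen <- generate_promoters(cfg, pwm)
  hits <- scan_promoters(gen$sequences, pwm, deficit_cutoff = 0.15)
  found <- dplyr::inner_join(gen$truth, hits,
                             by = c("promoter_id", "start"))
  expect_equal(nrow(found), 50)
  expect_gte(nrow(hits), 50)
})

test_that("cytometry generator matches its stated mixture construction", {
  pure <- generate_cytometry_events(
    synth_cytometry_config(n_events = 2000, fractions = c(1, 0, 0),
                           seed = 3))
  expect_true(all(pure$true_phase == "g1"))
  expect_equal(mean(pure$intensity), 100, tolerance = 0.01)

  ev <- generate_cytometry_events(
    synth_cytometry_config(n_events = 20000, g1_mean = 100, seed = 8))
  g2 <- ev$intensity[ev$true_phase == "g2m"]
  expect_equal(mean(g2), 200, tolerance = 0.01)
  expect_equal(sd(g2) / mean(g2), 0.03, tolerance = 0.15)
  expect_identical(ev, generate_cytometry_events(
    synth_cytometry_config(n_events = 20000, g1_mean = 100, seed = 8)))
  expect_error(synth_cytometry_config(fractions = c(0.5, 0.2, 0.2)),
               class = "foxscreen_config_error")
})

test_that("plate generator follows the Hill expectation", {
  pl <- generate_plate(vehicle_mean = 5000, doses = c(1, 10, 100),
                       ec50 = 10, hill = 1, emax = 0.5, seed = 2)
  veh <- pl[pl$dose == 0, ]
  expect_equal(unique(veh$expected_total), 5000)
  expect_equal(unique(pl$expected_total[pl$dose == 10]), 5000 * 0.75)
  flat <- generate_plate(doses = c(1, 10), emax = 0, ec50 = 10, seed = 3)
  expect_true(all(flat$expected_total == flat$expected_total[1]))
  # Poisson noise keeps per-well totals near expectation
  expect_true(all(abs(pl$total_cells - pl$expected_total) /
                    pl$expected_total < 0.1))
})

test_that("image generator emits consistent truth tables", {
  img <- generate_images(synth_image_config(size = 192, n_colonies = 5,
                                            seed = 6))
  expect_true(all(img$colonies$n_nuclei >= 1))  # frac_anuclear = 0
  expect_equal(nrow(img$nuclei), max(img$nuclei$object_id))
  expect_equal(sum(img$colonies$n_nuclei),
               length(unique(img$nuclei$parent_id)))

  blank <- generate_images(synth_image_config(size = 96, n_colonies = 0,
                                              seed = 1))
  expect_equal(nrow(blank$colonies), 0)
  expect_lt(max(blank$channels$calcein), 0.15)  # background + noise only

  again <- generate_images(synth_image_config(size = 192, n_colonies = 5,
                                              seed = 6))
  expect_identical(img$channels, again$channels)
  expect_identical(img$nuclei, again$nuclei)
})

test_that("anuclear colonies carry live signal but no nuclear objects", {
  img <- generate_images(synth_image_config(size = 256, n_colonies = 8,
                                            frac_anuclear = 1, seed = 4))
  expect_true(all(img$colonies$anuclear))
  expect_equal(nrow(img$nuclei), 0)
  expect_gt(max(img$channels$calcein), 0.4)
})
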