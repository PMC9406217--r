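disk_image <- function(size, centers, radii, value = 0.8) {
  m <- matrix(0.02, size, size)
  for (i in seq_along(radii)) {
    rows <- seq_len(size); cols <- seq_len(size)
    d <- outer((rows - centers[[i]][2])^2, (cols - centers[[i]][1])^2, "+")
    m[d <= radii[i]^2] <- value
  }
  m
}

test_that("disjoint disks segment into colonies with faithful areas", {
  cal <- disk_image(128, list(c(35, 35), c(95, 95)), c(12, 18))
  eth <- matrix(0.02, 128, 128)
  col <- segment_colonies(cal, eth)
  expect_equal(nrow(col), 2)
  expect_equal(sort(col$area), sort(c(pi * 12^2, pi * 18^2)),
               tolerance = 0.1)
  expect_true(all(col$live))

  eth2 <- disk_image(128, list(c(95, 95)), 18, value = 0.9)
  col2 <- segment_colonies(cal, eth2)
  expect_equal(sum(col2$dead), 1)
  expect_true(col2$dead[which.max(col2$area)])

  expect_warning(blank <- segment_colonies(matrix(0.02, 64, 64),
                                           matrix(0.02, 64, 64)),
                 "blank")
  expect_equal(nrow(blank), 0)
})

test_that("watershed splits touching nuclei and blank channels give none", {
  two <- disk_image(96, list(c(40, 48), c(56, 48)), c(9, 9))
  nuc <- segment_nuclei(two)
  expect_equal(nrow(nuc), 2)
  expect_equal(nrow(segment_nuclei(matrix(0.01, 64, 64))), 0)
})

test_that("segmentation counts are invariant to uniform intensity scaling", {
  img <- generate_images(synth_image_config(size = 256, n_colonies = 8,
                                            seed = 14))
  n0 <- nrow(segment_nuclei(img$channels$hoechst))
  n1 <- nrow(segment_nuclei(img$channels$hoechst * 0.5))
  expect_equal(n0, n1)
  c0 <- nrow(segment_colonies(img$channels$calcein, img$channels$ethd1))
  c1 <- nrow(segment_colonies(img$channels$calcein * 0.4,
                              img$channels$ethd1 * 0.4))
  expect_equal(c0, c1)
})

test_that("segmented counts and mean areas track generator truth", {
  img <- generate_images(synth_image_config(size = 384, n_colonies = 12,
                                            seed = 18))
  nuc <- segment_nuclei(img$channels$hoechst)
  col <- segment_colonies(img$channels$calcein, img$channels$ethd1)
  truth_nuc <- length(unique(img$nuclei$parent_id))
  expect_lt(abs(nrow(nuc) - truth_nuc) / truth_nuc, 0.1)
  expect_lt(abs(nrow(col) - nrow(img$colonies)) / nrow(img$colonies), 0.1)
  expect_equal(mean(nuc$area), mean(img$nuclei$area), tolerance = 0.15)
})

test_that("anuclear fractions equal raw-count ratios with whole-percent rounding", {
  img <- generate_images(synth_image_config(size = 384, n_colonies = 12,
                                            frac_anuclear = 0.5, seed = 19))
  col <- segment_colonies(img$channels$calcein, img$channels$ethd1)
  nuc <- segment_nuclei(img$channels$hoechst)
  an <- detect_anuclear(col, nuc)
  expect_equal(an$percent_anuclear,
               round(100 * an$n_anuclear / an$n_colonies))
  truth_frac <- mean(img$colonies$anuclear)
  expect_lt(abs(an$n_anuclear / an$n_colonies - truth_frac), 0.2)

  none <- generate_images(synth_image_config(size = 256, n_colonies = 8,
                                             seed = 20))
  an0 <- detect_anuclear(
    segment_colonies(none$channels$calcein, none$channels$ethd1),
    segment_nuclei(none$channels$hoechst))
  expect_equal(an0$percent_anuclear, 0)
})

test_that("fragmentation calls recover the planted fraction", {
  veh <- lapply(1:3, function(i) generate_images(
    synth_image_config(size = 512, n_colonies = 25, seed = 300 + i)))
  frg <- lapply(1:3, function(i) generate_images(
    synth_image_config(size = 512, n_colonies = 25,
                       frac_fragmented = 0.3, seed = 310 + i)))
  nv <- dplyr::bind_rows(lapply(veh, function(x)
    segment_nuclei(x$channels$hoechst)))
  nf <- dplyr::bind_rows(lapply(frg, function(x)
    segment_nuclei(x$channels$hoechst)))
  cf <- classify_fragmented(nf, nv)
  truth <- mean(unlist(lapply(frg, function(x)
    tapply(x$nuclei$fragmented, x$nuclei$parent_id, any))))
  expect_lt(abs(cf$n_fragmented / cf$n_nuclei - truth), 0.07)
  expect_equal(cf$percent_fragmented,
               round(100 * cf$n_fragmented / cf$n_nuclei))
  # nuclei drawn whole and equal to the vehicle median are never flagged
  same <- classify_fragmented(nv, nv)
  expect_lt(same$n_fragmented / same$n_nuclei, 0.1)
  expect_error(classify_fragmented(nf, nv[0, ]),
               class = "foxscreen_input_error")
})

test_that("morphology comparison reports signed folds with the stated convention", {
  v <- withr::with_seed(5, stats::rlnorm(500, log(100), 0.3))
  same <- compare_morphology(v, v)
  expect_equal(same$signed_fold, 1)
  expect_false(same$significant)

  halved <- compare_morphology(v / 2, v)
  expect_equal(halved$signed_fold, -2, tolerance = 1e-9)
  expect_true(halved$significant)
  expect_equal(halved$test, "z")

  expect_warning(small <- compare_morphology(v[1:10], v[1:12]),
                 "falling back")
  expect_equal(small$test, "t")

  cnt <- compare_counts(150, 100)
  expect_equal(cnt$statistic, 50 / sqrt(250))
  expect_equal(cnt$signed_fold, 1.5)
})

test_that("a planted 2.6-fold nuclear-size increase is estimated faithfully", {
  v <- generate_images(synth_image_config(size = 512, n_colonies = 25,
                                          nucleus_area_mean = 100,
                                          nucleus_area_sd = 30, seed = 5))
  t <- generate_images(synth_image_config(size = 512, n_colonies = 18,
                                          nucleus_area_mean = 260,
                                          nucleus_area_sd = 78, seed = 6))
  cmp <- compare_morphology(segment_nuclei(t$channels$hoechst),
                            segment_nuclei(v$channels$hoechst))
  expect_gt(cmp$signed_fold, 2.4)
  expect_lt(cmp$signed_fold, 2.8)
  expect_true(cmp$significant)
})
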