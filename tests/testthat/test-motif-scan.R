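test_that("degenerate and single-base matrices behave as forced", {
  uni <- build_pwm(pfm(matrix(1, 4, 6), "uniform"))
  expect_true(all(uni$logodds == 0))
  expect_equal(uni$s_max, 0)
  expect_equal(uni$s_min, 0)

  counts <- matrix(0, 4, 5)
  counts[cbind(c(1, 3, 4, 2, 1), 1:5)] <- 10
  single <- build_pwm(pfm(counts, "single"))
  expect_equal(single$consensus, "AGTCA")
  expect_error(build_pwm(pfm(matrix(c(rep(1, 16), rep(0, 4)), 4, 5,
                                    byrow = FALSE))),
               class = "foxscreen_input_error")
})

test_that("best achievable score equals brute-force maximum over all words", {
  counts <- withr::with_seed(21, matrix(stats::rpois(32, 8), 4, 8))
  pwm <- build_pwm(pfm(counts, "rand8"))
  # enumerate all 4^8 words via base-4 digits
  idx <- 0:(4^8 - 1)
  best <- -Inf
  digits <- sapply(0:7, function(j) (idx %/% 4^j) %% 4 + 1)
  scores <- rowSums(sapply(1:8, function(j) pwm$logodds[cbind(digits[, j], j)]))
  expect_equal(pwm$s_max, max(scores), tolerance = 1e-12)
  expect_equal(pwm$s_min, min(scores), tolerance = 1e-12)
})

test_that("consensus plants hit at deficit 0 and core mismatches never hit", {
  pwm <- test_pwm()
  bg <- strrep("A", 60)
  seq <- paste0(substr(bg, 1, 20), pwm$consensus,
                substr(bg, 1, 40))
  hits <- scan_promoter(seq, pwm, both_strands = FALSE)
  expect_true(20 %in% hits$start)
  expect_equal(hits$deficit[hits$start == 20], 0)

  cons <- strsplit(pwm$consensus, "")[[1]]
  core_pos <- which(pwm$core)[1]
  cons[core_pos] <- setdiff(c("A", "C", "G", "T"), cons[core_pos])[1]
  seq2 <- paste0(substr(bg, 1, 20), paste(cons, collapse = ""),
                 substr(bg, 1, 40))
  hits2 <- scan_promoter(seq2, pwm, deficit_cutoff = 1,
                         both_strands = FALSE)
  expect_false(20 %in% hits2$start)
})

test_that("windows containing N are skipped and short sequences return empty", {
  pwm <- test_pwm()
  expect_equal(nrow(scan_promoter("ACGT", pwm)), 0)
  seqN <- paste0(strrep("A", 20), "N", strrep("A", 20))
  hits <- scan_promoter(seqN, pwm, deficit_cutoff = 1)
  bad <- (21 - pwm$width):20  # 0-based starts whose window covers the N
  expect_false(any(hits$start %in% bad))
})

test_that("scanner agrees with the brute-force oracle on random promoters", {
  pwm <- test_pwm()
  for (seed in 1:5) {
    seq <- withr::with_seed(seed, paste(
      sample(c("A", "C", "G", "T"), 1500, replace = TRUE,
             prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""))
    got <- scan_promoter(seq, pwm, deficit_cutoff = 0.15)
    exp <- oracle_scan(seq, pwm, cutoff = 0.15)
    key <- function(d) sort(paste(d$start, d$strand))
    expect_identical(key(got), key(exp))
    if (nrow(got)) {
      m <- merge(as.data.frame(got), exp, by = c("start", "strand"))
      expect_equal(m$score.x, m$score.y, tolerance = 1e-9)
      expect_equal(m$deficit.x, m$deficit.y, tolerance = 1e-9)
    }
  }
})

test_that("scanning the reverse complement swaps strands but keeps the hit set", {
  pwm <- test_pwm()
  seq <- withr::with_seed(31, paste(
    sample(c("A", "C", "G", "T"), 800, replace = TRUE), collapse = ""))
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
              collapse = "")
  fwd <- scan_promoter(seq, pwm, deficit_cutoff = 0.3)
  rev <- scan_promoter(rc, pwm, deficit_cutoff = 0.3)
  # a + hit at start s maps to a - hit at L - w - s on the reverse complement
  remapped <- sort(800 - pwm$width - rev$start)
  expect_equal(sort(fwd$start), remapped)
  expect_equal(sort(fwd$score), sort(rev$score), tolerance = 1e-9)
})

test_that("cluster chaining is inclusive at the window and matches the oracle", {
  mk_hits <- function(starts) tibble::tibble(
    promoter_id = "p", start = as.integer(starts),
    end = as.integer(starts + 8), strand = "+", score = 1, deficit = 0)
  expect_equal(nrow(find_clusters(mk_hits(c(10, 110)), window = 100)), 1)
  expect_equal(nrow(find_clusters(mk_hits(c(10, 111)), window = 100)), 0)

  for (seed in 1:5) {
    starts <- withr::with_seed(seed, sort(sample(0:1500, 25)))
    got <- find_clusters(mk_hits(starts), window = 100)
    exp <- oracle_clusters(starts, window = 100)
    got_sets <- lapply(got$starts, sort)
    expect_equal(length(got_sets), length(exp))
    expect_true(all(vapply(exp, function(e)
      any(vapply(got_sets, identical, logical(1), e)), logical(1))))
  }
})

test_that("promoter windows orient by strand and truncate with a warning", {
  expect_equal(unlist(promoter_window(5000, strand = "+")[1, 1:2]),
               c(start = 3500, end = 5500))
  expect_equal(unlist(promoter_window(5000, strand = "-")[1, 1:2]),
               c(start = 4500, end = 6500))
  expect_warning(w <- promoter_window(1000, upstream = 1500, strand = "+"),
                 "truncated")
  expect_equal(unlist(w[1, 1:2]), c(start = 0, end = 1500))
  expect_true(w$truncated)
})

test_that("pwm tidiers expose the scoring matrix faithfully", {
  pwm <- test_pwm()
  td <- tidy(pwm)
  expect_equal(nrow(td), 4 * pwm$width)
  expect_equal(matrix(td$log_odds, 4), unname(pwm$logodds))
  gl <- glance(pwm)
  expect_equal(gl$consensus, pwm$consensus)
  expect_equal(gl$n_core, sum(pwm$core))
})
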