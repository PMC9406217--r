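#' Configuration for synthetic promoter sequences
#'
#' Background sequence is i.i.d. with configurable GC content (the simplest
#' null; no repeat structure). Motif instances are planted at stated offsets
#' by writing the matrix consensus word (exact, hence deficit 0 by
#' construction) unless a per-base `mutation_rate` is supplied.
#'
#' @param n_promoters Number of promoters.
#' @param window_upstream,window_downstream Window extents in bp; total
#'   sequence length is their sum (defaults 1500 + 500).
#' @param gc_content GC fraction of the background.
#' @param planted Data frame of planted sites with columns `promoter`
#'   (1-based index), `offset` (0-based start within the window) and
#'   `strand` (`"+"`/`"-"`); NULL for none.
#' @param mutation_rate Per-base probability of mutating a planted site.
#' @param seed Integer seed; identical seed gives identical FASTA output.
#' @return A `synth_promoter_config` list.
#' @export
synth_promoter_config <- function(n_promoters = 50, window_upstream = 1500,
                                  window_downstream = 500, gc_content = 0.4,
                                  planted = NULL, mutation_rate = 0,
                                  seed = 1L) {
  assert_count(n_promoters, "n_promoters")
  assert_count(window_upstream, "window_upstream", min = 0)
  assert_count(window_downstream, "window_downstream", min = 0)
  assert_fraction(gc_content, "gc_content")
  assert_fraction(mutation_rate, "mutation_rate")
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    stopifnot(all(c("promoter", "offset", "strand") %in% names(planted)))
    if (any(planted$promoter < 1 | planted$promoter > n_promoters)) {
      abort("planted promoter index out of range",
            class = "foxscreen_config_error")
    }
  }
  structure(list(n_promoters = as.integer(n_promoters),
                 window_upstream = as.integer(window_upstream),
                 window_downstream = as.integer(window_downstream),
                 gc_content = gc_content, planted = planted,
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "synth_promoter_config")
}

#' Generate synthetic promoters with planted motif instances
#'
#' @param cfg A [synth_promoter_config()].
#' @param pwm A [build_pwm()] object whose consensus is planted.
#' @return List with `sequences` (named character vector,
#'   `promoter_<i>` names), and `truth` — a tibble of planted sites
#'   (`promoter_id`, `start`, `strand`, `cluster_eligible` under the
#'   default 100 bp start-to-start rule).
#' @export
#' @examples
#' p <- build_pwm(pfm(matrix(c(9, 0, 0, 1), 4, 8), "ex"))
#' gen <- generate_promoters(synth_promoter_config(n_promoters = 3, seed = 2),
#'                           p)
generate_promoters <- function(cfg, pwm) {
  stopifnot(inherits(cfg, "synth_promoter_config"),
            inherits(pwm, "foxd_pwm"))
  len <- cfg$window_upstream + cfg$window_downstream
  if (pwm$width > len) abort("matrix wider than the promoter window",
                             class = "foxscreen_config_error")
  planted <- cfg$planted
  if (!is.null(planted) &&
      any(planted$offset < 0 | planted$offset + pwm$width > len)) {
    abort("planted offset outside the promoter window",
          class = "foxscreen_config_error")
  }
  probs <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
             G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
  cons <- strsplit(pwm$consensus, "")[[1]]
  rc <- function(x) rev(chartr("ACGT", "TGCA", x))
  with_seed(cfg$seed, {
    seqs <- vapply(seq_len(cfg$n_promoters), function(i) {
      paste(sample(BASES, len, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("promoter_%d", seq_len(cfg$n_promoters))
    if (!is.null(planted) && nrow(planted)) {
      for (r in seq_len(nrow(planted))) {
        word <- if (planted$strand[r] == "+") cons else rc(cons)
        if (cfg$mutation_rate > 0) {
          mut <- runif(length(word)) < cfg$mutation_rate
          word[mut] <- vapply(which(mut), function(j) {
            sample(setdiff(BASES, word[j]), 1)
          }, character(1))
        }
        i <- planted$promoter[r]
        s <- strsplit(seqs[[i]], "")[[1]]
        s[(planted$offset[r] + 1):(planted$offset[r] + pwm$width)] <- word
        seqs[[i]] <- paste(s, collapse = "")
      }
    }
    truth <- if (is.null(planted) || !nrow(planted)) {
      tibble(promoter_id = character(), start = integer(),
             strand = character(), cluster_eligible = logical())
    } else {
      planted |>
        mutate(promoter_id = sprintf("promoter_%d", .data$promoter),
               start = as.integer(.data$offset)) |>
        group_by(.data$promoter_id) |>
        mutate(cluster_eligible = vapply(seq_len(n()), function(j) {
          any(abs(.data$start[-j] - .data$start[j]) <= 100)
        }, logical(1))) |>
        ungroup() |>
        select("promoter_id", "start", "strand", "cluster_eligible")
    }
    list(sequences = seqs, truth = truth)
  })
}

#' Write promoter sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output FASTA path.
#' @export
write_promoters_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
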