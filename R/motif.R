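BASES <- c("A", "C", "G", "T")

#' Construct a position frequency matrix
#'
#' @param counts Numeric matrix of base counts, 4 rows in A, C, G, T order
#'   (rownames optional) by motif width columns.
#' @param name Matrix name.
#' @return A `pfm` object.
#' @export
pfm <- function(counts, name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("a PFM needs 4 rows (A, C, G, T)",
                               class = "foxscreen_input_error")
  if (ncol(counts) < 4) abort("PFM width must be at least 4",
                              class = "foxscreen_input_error")
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("PFM counts must be finite and non-negative",
          class = "foxscreen_input_error")
  }
  rownames(counts) <- BASES
  structure(list(counts = counts, name = name), class = "pfm")
}

#' Read a position frequency matrix in JASPAR text format
#'
#' Accepts the JASPAR flat format: a `>` header line followed by four rows of
#' counts, either bracketed (`A [ 1 2 3 ]`) or bare numbers in A, C, G, T
#' order.
#'
#' @param path Path to the matrix file.
#' @return A [pfm()] object.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  name <- "motif"
  if (startsWith(lines[[1]], ">")) {
    name <- trimws(sub("^>", "", lines[[1]]))
    lines <- lines[-1]
  }
  if (length(lines) < 4) abort("expected 4 count rows in JASPAR matrix",
                               class = "foxscreen_input_error")
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
    l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (length(unique(lengths(rows))) != 1) {
    abort("JASPAR matrix rows have unequal widths",
          class = "foxscreen_input_error")
  }
  pfm(do.call(rbind, rows), name = name)
}

#' Build a log-odds scoring matrix from a PFM
#'
#' Column probabilities are `(count + pseudocount) / (column total + 4 *
#' pseudocount)`; scores are log2 odds against the background. The object
#' carries the best and worst achievable window scores, the consensus word
#' (per-column argmax, ties to the earlier base in A<C<G<T), and a core mask
#' marking positions whose information content reaches `core_ic` bits. Core
#' positions must match the consensus exactly during scanning, mirroring a
#' mismatch tolerance that applies only outside the core consensus.
#'
#' @param x A [pfm()] object.
#' @param pseudocount Pseudocount added to every cell (default 1).
#' @param background Background base frequencies (A, C, G, T); must sum to 1.
#' @param core_ic Information-content threshold (bits) defining core
#'   positions (default 1).
#' @return A `foxd_pwm` object.
#' @export
#' @examples
#' m <- pfm(matrix(c(10, 0, 0, 0), 4, 6), "polyA")
#' pwm <- build_pwm(m)
#' pwm$consensus
build_pwm <- function(x, pseudocount = 1,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      core_ic = 1.0) {
  stopifnot(inherits(x, "pfm"))
  if (pseudocount < 0) abort("pseudocount must be non-negative",
                             class = "foxscreen_input_error")
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0)) {
    abort("background frequencies must be positive and sum to 1",
          class = "foxscreen_input_error")
  }
  counts <- x$counts
  totals <- colSums(counts)
  if (any(totals == 0)) abort("PFM has a zero-total column",
                              class = "foxscreen_input_error")
  w <- ncol(counts)
  probs <- sweep(counts + pseudocount, 2, totals + 4 * pseudocount, "/")
  logodds <- log2(sweep(probs, 1, background, "/"))
  rownames(logodds) <- BASES
  # information content per column against a uniform background
  ic <- 2 + colSums(probs * log2(probs))
  cons_idx <- apply(logodds, 2, which.max)
  structure(list(
    logodds = logodds,
    width = w,
    s_max = sum(apply(logodds, 2, max)),
    s_min = sum(apply(logodds, 2, min)),
    consensus_idx = as.integer(cons_idx),
    consensus = paste(BASES[cons_idx], collapse = ""),
    core = ic >= core_ic,
    ic = ic,
    name = x$name,
    pseudocount = pseudocount,
    background = background
  ), class = "foxd_pwm")
}

#' @export
print.foxd_pwm <- function(x, ...) {
  cat(sprintf("<foxd_pwm> %s  width=%d  consensus=%s  core=%s\n",
              x$name, x$width, x$consensus,
              paste(ifelse(x$core, "*", "."), collapse = "")))
  cat(sprintf("  score range [%.3f, %.3f]\n", x$s_min, x$s_max))
  invisible(x)
}

encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  m <- match(chars, BASES)   # N or anything else -> NA
  m
}

# score every window of coded sequence against a logodds matrix;
# returns list(score, core_ok); windows touching an NA base score NA
score_windows <- function(codes, logodds, cons_idx, core) {
  w <- ncol(logodds)
  n_win <- length(codes) - w + 1
  if (n_win < 1) return(list(score = numeric(0), core_ok = logical(0)))
  score <- numeric(n_win)
  core_ok <- rep(TRUE, n_win)
  for (j in seq_len(w)) {
    b <- codes[j:(j + n_win - 1)]
    score <- score + logodds[cbind(b, j)]
    if (core[j]) core_ok <- core_ok & !is.na(b) & b == cons_idx[j]
  }
  list(score = score, core_ok = core_ok & !is.na(score))
}

revcomp_pwm <- function(pwm) {
  lo <- pwm$logodds[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  rownames(lo) <- BASES
  list(logodds = lo,
       consensus_idx = rev(5L - pwm$consensus_idx),
       core = rev(pwm$core))
}

#' Scan a promoter sequence for motif hits under a deficit cutoff
#'
#' Slides the scoring matrix over every window of the sequence (both strands
#' by default). A window is a hit when (a) every core position matches the
#' consensus base and (b) its deficit `(S_max - S) / (S_max - S_min)` is at
#' most `deficit_cutoff`. Windows containing `N` are skipped. Reverse-strand
#' hits are reported with forward-strand window-start coordinates (0-based).
#'
#' @param seq A single nucleotide sequence (character scalar over ACGTN).
#' @param pwm A [build_pwm()] object.
#' @param deficit_cutoff Maximum allowed deficit (default 0.15).
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @param promoter_id Identifier recorded in the output.
#' @return Tibble with `promoter_id`, `start`, `end` (half-open, 0-based),
#'   `strand`, `score`, `deficit`; empty when the sequence is shorter than
#'   the matrix.
#' @export
scan_promoter <- function(seq, pwm, deficit_cutoff = 0.15,
                          both_strands = TRUE, promoter_id = "promoter") {
  stopifnot(inherits(pwm, "foxd_pwm"))
  assert_fraction(deficit_cutoff, "deficit_cutoff")
  codes <- encode_dna(seq)
  rng <- pwm$s_max - pwm$s_min
  strands <- if (both_strands) c("+", "-") else "+"
  res <- lapply(strands, function(st) {
    mats <- if (st == "+") {
      list(logodds = pwm$logodds, consensus_idx = pwm$consensus_idx,
           core = pwm$core)
    } else {
      revcomp_pwm(pwm)
    }
    sw <- score_windows(codes, mats$logodds, mats$consensus_idx, mats$core)
    if (!length(sw$score)) return(NULL)
    deficit <- if (rng > 0) pmax((pwm$s_max - sw$score) / rng, 0) else
      ifelse(is.na(sw$score), NA_real_, 0)
    keep <- which(sw$core_ok & !is.na(deficit) & deficit <= deficit_cutoff)
    if (!length(keep)) return(NULL)
    tibble(promoter_id = promoter_id,
           start = keep - 1L,
           end = keep - 1L + pwm$width,
           strand = st,
           score = sw$score[keep],
           deficit = deficit[keep])
  })
  out <- bind_rows(res)
  if (!nrow(out)) {
    return(tibble(promoter_id = character(), start = integer(),
                  end = integer(), strand = character(),
                  score = numeric(), deficit = numeric()))
  }
  arrange(out, .data$start, .data$strand)
}

#' Scan many promoters
#'
#' @param sequences Named character vector (or data frame with `promoter_id`
#'   and `sequence` columns) of promoter sequences.
#' @inheritParams scan_promoter
#' @return Row-bound tibble of [scan_promoter()] results.
#' @export
scan_promoters <- function(sequences, pwm, deficit_cutoff = 0.15,
                           both_strands = TRUE) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$promoter_id)
  }
  ids <- names(sequences) %||% sprintf("promoter_%d", seq_along(sequences))
  bind_rows(map2(unname(sequences), ids, function(s, id) {
    scan_promoter(s, pwm, deficit_cutoff, both_strands, promoter_id = id)
  }))
}

#' Detect clustered motif hits within a promoter window
#'
#' Single-linkage chaining of hits ordered by start: consecutive starts no
#' more than `window` apart (inclusive, start-to-start by default) join one
#' cluster; clusters with at least two member hits are reported. With
#' `measure = "edge"` the gap between the end of one hit and the start of
#' the next is used instead.
#'
#' @param hits Tibble from [scan_promoter()]/[scan_promoters()] (may cover
#'   several promoters; clustering is per promoter).
#' @param window Maximum distance in bp (default 100, inclusive).
#' @param measure Distance convention: `"start"` (start-to-start, default)
#'   or `"edge"` (end-to-start gap).
#' @return Tibble with one row per cluster: `promoter_id`, `cluster_id`,
#'   `n_hits`, `start_min`, `start_max`, `span`, and a `starts` list-column.
#' @export
find_clusters <- function(hits, window = 100, measure = c("start", "edge")) {
  measure <- match.arg(measure)
  if (!nrow(hits)) {
    return(tibble(promoter_id = character(), cluster_id = integer(),
                  n_hits = integer(), start_min = integer(),
                  start_max = integer(), span = integer(),
                  starts = list()))
  }
  hits |>
    group_by(.data$promoter_id) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$start, .data$strand)
      gap <- if (measure == "start") diff(df$start) else
        df$start[-1] - df$end[-nrow(df)]
      cl <- cumsum(c(1L, as.integer(gap > window)))
      df |>
        mutate(cluster_id = cl) |>
        group_by(.data$cluster_id) |>
        summarise(n_hits = n(),
                  start_min = min(.data$start),
                  start_max = max(.data$start),
                  starts = list(.data$start), .groups = "drop") |>
        filter(.data$n_hits >= 2) |>
        mutate(span = .data$start_max - .data$start_min)
    }) |>
    ungroup() |>
    select("promoter_id", "cluster_id", "n_hits", "start_min",
           "start_max", "span", "starts")
}

#' Promoter scan window around a transcription start site
#'
#' Returns the 0-based half-open interval covering `upstream` bp upstream and
#' `downstream` bp downstream of the TSS, oriented by strand. Windows
#' extending past the sequence start are truncated with a warning.
#'
#' @param tss TSS coordinate(s), 0-based.
#' @param upstream,downstream Window extents in bp (defaults 1500 and 500).
#' @param strand `"+"` or `"-"` (recycled).
#' @param seq_length Optional sequence length for right-truncation.
#' @return Tibble with `start`, `end`, `truncated`.
#' @export
#' @examples
#' promoter_window(5000, strand = "+")  # [3500, 5500)
#' promoter_window(5000, strand = "-")  # [4500, 6500)
promoter_window <- function(tss, upstream = 1500, downstream = 500,
                            strand = "+", seq_length = NULL) {
  if (any(tss < 0)) abort("tss must be non-negative",
                          class = "foxscreen_input_error")
  strand <- rep_len(strand, length(tss))
  start <- ifelse(strand == "+", tss - upstream, tss - downstream)
  end <- ifelse(strand == "+", tss + downstream, tss + upstream)
  truncated <- start < 0
  if (!is.null(seq_length)) {
    truncated <- truncated | end > seq_length
    end <- pmin(end, seq_length)
  }
  start <- pmax(start, 0)
  if (any(truncated)) warn("promoter window truncated at sequence boundary")
  tibble(start = as.integer(start), end = as.integer(end),
         truncated = truncated)
}

#' Write motif hits as BED-like text
#'
#' @param hits Tibble from [scan_promoters()].
#' @param path Output path.
#' @export
write_hits_bed <- function(hits, path) {
  readr::write_tsv(
    tibble(chrom = hits$promoter_id, start = hits$start, end = hits$end,
           name = sprintf("hit_%d", seq_len(nrow(hits))),
           score = round(hits$deficit, 6), strand = hits$strand),
    path, col_names = FALSE)
  invisible(path)
}
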