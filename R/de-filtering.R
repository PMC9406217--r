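#' Classify differential-expression records
#'
#' Assigns each row exactly one status: `uninterpretable` when the adjusted
#' p-value is missing (such rows are discarded from all downstream stages),
#' `differential` when the adjusted p-value is at or below `alpha` (the
#' boundary is inclusive), and `equal` otherwise. Differential genes are
#' split by direction: `up` when fold change exceeds 1, `down` when below 1.
#' Fold changes are stored as reference line over knockout, so a positive
#' log fold change marks a gene downregulated in the knockout.
#'
#' @param records Data frame with columns `gene_id`, `fold_change`,
#'   `log_fold_change`, `p`, `p_adj` (missing as `NA`).
#' @param alpha Adjusted-p cutoff (default 0.05, inclusive).
#' @param quiet Suppress the status-count message.
#' @return The input as a tibble with `status` and `direction` columns added.
#' @export
#' @examples
#' tbl <- generate_de_table(synth_de_config(n_genes = 50, seed = 1))
#' classify_de(tbl)
classify_de <- function(records, alpha = 0.05, quiet = FALSE) {
  records <- as_tibble(records)
  req <- c("gene_id", "fold_change", "p_adj")
  if (!all(req %in% names(records))) {
    abort(paste("missing required columns:",
                paste(setdiff(req, names(records)), collapse = ", ")),
          class = "foxscreen_input_error")
  }
  bad_fc <- !is.na(records$fold_change) & records$fold_change <= 0
  if (any(bad_fc)) {
    abort("fold_change must be positive where present",
          class = "foxscreen_input_error")
  }
  out <- records |>
    mutate(
      status = dplyr::case_when(
        is.na(.data$p_adj) ~ "uninterpretable",
        .data$p_adj <= alpha ~ "differential",
        TRUE ~ "equal"
      ),
      direction = dplyr::case_when(
        .data$status != "differential" ~ "none",
        .data$fold_change > 1 ~ "up",
        .data$fold_change < 1 ~ "down",
        TRUE ~ "none"
      )
    )
  if (any(out$status == "differential" & out$direction == "none")) {
    warn("differential gene(s) with fold change exactly 1 assigned direction 'none'")
  }
  if (!quiet) {
    cnt <- table(factor(out$status,
                        c("differential", "equal", "uninterpretable")))
    inform(sprintf("classified %d genes: %d differential, %d equal, %d uninterpretable (discarded downstream)",
                   nrow(out), cnt[["differential"]], cnt[["equal"]],
                   cnt[["uninterpretable"]]))
  }
  out
}

#' Top-ranked differential genes in one direction
#'
#' Returns the `k` differential genes with the largest absolute log fold
#' change in the requested direction. Ties are broken by smaller adjusted p,
#' then lexicographic gene id, so the order is fully deterministic.
#'
#' @param genes Classified table from [classify_de()].
#' @param k Number of genes to keep (default 100).
#' @param direction `"up"` or `"down"`.
#' @param rank_by Ranking metric: absolute log fold change (default) or raw
#'   fold-change magnitude (identical ordering; exposed for transparency).
#' @return Tibble of at most `k` rows with a `rank` column; warns and
#'   returns the full pool when fewer than `k` genes are available.
#' @export
top_ranked <- function(genes, k = 100, direction = c("up", "down"),
                       rank_by = c("log_fold_change", "fold_change")) {
  direction <- match.arg(direction)
  rank_by <- match.arg(rank_by)
  assert_count(k, "k")
  if (!"status" %in% names(genes)) {
    abort("`genes` must be classified first (see classify_de())",
          class = "foxscreen_input_error")
  }
  pool <- genes |>
    filter(.data$status == "differential", .data$direction == !!direction)
  metric <- if (rank_by == "log_fold_change") {
    abs(pool$log_fold_change)
  } else {
    ifelse(pool$fold_change >= 1, pool$fold_change, 1 / pool$fold_change)
  }
  pool <- pool[order(-metric, pool$p_adj, pool$gene_id), , drop = FALSE]
  if (nrow(pool) < k) {
    warn(sprintf("only %d %sregulated differential genes available (k = %d); returning all",
                 nrow(pool), direction, k))
  }
  pool |>
    slice_head(n = min(k, nrow(pool))) |>
    mutate(rank = row_number())
}
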