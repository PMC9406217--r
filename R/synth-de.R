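#' Configuration for a synthetic differential-expression table
#'
#' Describes a synthetic table shaped like standard DE output (gene id, fold
#' change, log2 fold change, raw and adjusted p), with ground-truth status
#' labels. A stated fraction of rows carries a missing adjusted p-value,
#' emulating genes for which the DE fit reports no adjusted p (independent
#' filtering); those rows are "uninterpretable" downstream.
#'
#' @param n_genes Number of genes (rows).
#' @param frac_differential Fraction of genes drawn as truly differential
#'   (adjusted p placed at or below 0.05 by construction).
#' @param frac_missing_padj Fraction of rows with missing adjusted p.
#' @param lfc_sd Standard deviation of log2 fold changes.
#' @param seed Integer seed; identical seed gives an identical table.
#' @return A `synth_de_config` list.
#' @export
#' @examples
#' cfg <- synth_de_config(n_genes = 200, frac_differential = 0.2, seed = 1)
#' tbl <- generate_de_table(cfg)
synth_de_config <- function(n_genes = 1000, frac_differential = 0.3,
                            frac_missing_padj = 0.05, lfc_sd = 1.5, seed = 1L) {
  assert_count(n_genes, "n_genes")
  assert_fraction(frac_differential, "frac_differential")
  assert_fraction(frac_missing_padj, "frac_missing_padj")
  assert_positive(lfc_sd, "lfc_sd")
  structure(list(n_genes = as.integer(n_genes),
                 frac_differential = frac_differential,
                 frac_missing_padj = frac_missing_padj,
                 lfc_sd = lfc_sd, seed = as.integer(seed)),
            class = "synth_de_config")
}

#' Generate a synthetic differential-expression table with truth labels
#'
#' Exactly `round(frac_missing_padj * n_genes)` rows receive a missing
#' adjusted p-value. Among the remaining rows, `round(frac_differential *
#' n_genes)` (capped at the available rows) are drawn differential: their
#' adjusted p is placed in (0, 0.05], all others in (0.05, 1). Log2 fold
#' changes are Normal(0, `lfc_sd`); `fold_change = 2^log_fold_change`, so a
#' fold change above 1 means higher expression in the reference line than in
#' the knockout.
#'
#' @param cfg A [synth_de_config()].
#' @return A tibble with columns `gene_id`, `fold_change`,
#'   `log_fold_change`, `p`, `p_adj` plus truth columns `true_status`
#'   (`differential`/`equal`/`uninterpretable`) and `true_direction`
#'   (`up`/`down`/`none`).
#' @export
generate_de_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_de_config"))
  n <- cfg$n_genes
  with_seed(cfg$seed, {
    n_miss <- round(cfg$frac_missing_padj * n)
    n_diff <- min(round(cfg$frac_differential * n), n - n_miss)
    status <- c(rep("uninterpretable", n_miss),
                rep("differential", n_diff),
                rep("equal", n - n_miss - n_diff))
    status <- sample(status)
    lfc <- rnorm(n, 0, cfg$lfc_sd)
    # truly differential genes get a clear effect; lfc == 0 has probability 0
    p_adj <- ifelse(status == "differential",
                    runif(n, 0, 0.05),
                    runif(n, 0.0500001, 1))
    p_adj[status == "uninterpretable"] <- NA_real_
    p <- p_adj * runif(n, 0.2, 1)
    # uninterpretable rows keep a raw p: only the adjusted p drives the cutoff
    p[status == "uninterpretable"] <- runif(sum(status == "uninterpretable"))
    tibble(
      gene_id = sprintf("GENE%05d", seq_len(n)),
      fold_change = 2^lfc,
      log_fold_change = lfc,
      p = p,
      p_adj = p_adj,
      true_status = status,
      true_direction = ifelse(status != "differential", "none",
                              ifelse(lfc > 0, "up", "down"))
    )
  })
}
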