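#' Configuration for an end-to-end synthetic screen run
#'
#' Collects every stage parameter in one object. Defaults are the screen's
#' operating constants: adjusted-p cutoff 0.05, top-100 ranking per
#' direction, deficit cutoff 0.15, 100 bp cluster window, promoter window
#' 1500 bp upstream / 500 bp downstream, the four database weights and a
#' selection threshold of 2.
#'
#' @param seed Master seed for every stage.
#' @param stages Stages to run, in dependency order, among `"de"`,
#'   `"motif"`, `"score"`, `"targets"`.
#' @param alpha Adjusted-p cutoff for the DE classification.
#' @param top_k Genes kept per direction.
#' @param deficit_cutoff Motif-scan deficit cutoff.
#' @param cluster_window Clustered-motif window in bp.
#' @param window_upstream,window_downstream Promoter window extents in bp.
#' @param score_threshold Candidate-selection score threshold.
#' @param weights Named gene-set weights.
#' @param de List of [synth_de_config()] arguments (minus the seed).
#' @param promoters List with `n_promoters`, `gc_content`,
#'   `frac_with_motif` (promoters given one planted site) and
#'   `frac_clustered` (promoters given a clustered pair).
#' @param pfm_path Path to a JASPAR-format matrix; default the bundled
#'   synthetic forkhead-like example.
#' @return A `screen_config` list.
#' @export
screen_config <- function(seed = 1L,
                          stages = c("de", "motif", "score", "targets"),
                          alpha = 0.05, top_k = 100, deficit_cutoff = 0.15,
                          cluster_window = 100, window_upstream = 1500,
                          window_downstream = 500, score_threshold = 2,
                          weights = default_set_weights(),
                          de = list(n_genes = 2000, frac_differential = 0.3,
                                    frac_missing_padj = 0.05, lfc_sd = 1.5),
                          promoters = list(n_promoters = 60,
                                           gc_content = 0.4,
                                           frac_with_motif = 0.5,
                                           frac_clustered = 0.15),
                          pfm_path = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(seed = as.integer(seed), stages = stages, alpha = alpha,
                 top_k = top_k, deficit_cutoff = deficit_cutoff,
                 cluster_window = cluster_window,
                 window_upstream = window_upstream,
                 window_downstream = window_downstream,
                 score_threshold = score_threshold,
                 weights = as.list(weights), de = de,
                 promoters = promoters, pfm_path = pfm_path),
            class = "screen_config")
}

#' Write/read a screen configuration as YAML
#'
#' The round-trip is lossless: `read_screen_config(write_screen_config(cfg,
#' f))` reproduces `cfg`.
#'
#' @param cfg A [screen_config()].
#' @param path YAML file path.
#' @return `write_screen_config()` the path, invisibly;
#'   `read_screen_config()` a `screen_config`.
#' @export
write_screen_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "screen_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_screen_config
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(screen_config, c(
    raw[setdiff(names(raw), "weights")],
    list(weights = unlist(raw$weights))
  ))
}

#' Run the synthetic screen end-to-end
#'
#' Executes the enabled stages in dependency order on fully synthetic
#' inputs: DE simulation and classification, top-k ranking, promoter
#' simulation with planted motifs, scanning and clustering, weighted
#' candidate scoring, and target-annotation simulation with panel assembly.
#' Each stage consumes only its upstream stage's tables, so the composition
#' equals running the stage functions by hand with the same parameters.
#'
#' @param cfg A [screen_config()].
#' @param out_dir Optional directory; when given, per-stage TSVs and a JSON
#'   manifest with md5 hashes of every output are written. Identical
#'   config and seed give identical hashes.
#' @param quiet Suppress stage messages.
#' @return List of stage tables (`de`, `top_up`, `top_down`, `hits`,
#'   `clusters`, `candidates`, `decisions`, `panel`, `summary` as enabled)
#'   plus `manifest`.
#' @export
#' @examples
#' res <- run_screen(screen_config(seed = 42,
#'                                 de = list(n_genes = 300),
#'                                 promoters = list(n_promoters = 10)))
#' res$manifest
run_screen <- function(cfg, out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(cfg, "screen_config"))
  needs <- function(stage, dep) {
    if (stage %in% cfg$stages && !(dep %in% cfg$stages)) {
      abort(sprintf("stage '%s' requires stage '%s'", stage, dep),
            class = "foxscreen_dependency_error")
    }
  }
  needs("motif", "de"); needs("score", "de"); needs("score", "motif")
  needs("targets", "score")
  res <- list()
  log <- list()

  if ("de" %in% cfg$stages) {
    de_args <- cfg$de
    de_cfg <- do.call(synth_de_config, c(de_args, list(seed = cfg$seed)))
    de <- classify_de(generate_de_table(de_cfg), alpha = cfg$alpha,
                      quiet = quiet)
    res$de <- de
    res$top_up <- suppressWarnings(top_ranked(de, k = cfg$top_k, "up"))
    res$top_down <- suppressWarnings(top_ranked(de, k = cfg$top_k, "down"))
    log$de <- c(n_genes = nrow(de),
                n_differential = sum(de$status == "differential"),
                n_top_up = nrow(res$top_up),
                n_top_down = nrow(res$top_down))
  }

  if ("motif" %in% cfg$stages) {
    pfm_path <- cfg$pfm_path %||%
      system.file("extdata", "forkhead_synthetic.pfm", package = "foxscreen")
    pwm <- build_pwm(read_jaspar_pfm(pfm_path))
    pr <- cfg$promoters
    len <- cfg$window_upstream + cfg$window_downstream
    planted <- with_seed(cfg$seed + 1L, {
      rows <- list()
      for (i in seq_len(pr$n_promoters)) {
        u <- runif(1)
        if (u < pr$frac_clustered) {
          o1 <- sample.int(len - pwm$width - 80, 1)
          rows[[length(rows) + 1L]] <-
            tibble(promoter = i, offset = c(o1, o1 + 60),
                   strand = c("+", "+"))
        } else if (u < pr$frac_clustered + pr$frac_with_motif) {
          rows[[length(rows) + 1L]] <-
            tibble(promoter = i,
                   offset = sample.int(len - pwm$width, 1),
                   strand = sample(c("+", "-"), 1))
        }
      }
      bind_rows(rows)
    })
    pcfg <- synth_promoter_config(
      n_promoters = pr$n_promoters, window_upstream = cfg$window_upstream,
      window_downstream = cfg$window_downstream, gc_content = pr$gc_content,
      planted = planted, seed = cfg$seed + 2L)
    gen <- generate_promoters(pcfg, pwm)
    # promoter i stands for the i-th gene of the DE table
    gene_of <- setNames(res$de$gene_id[seq_len(pr$n_promoters)],
                        names(gen$sequences))
    hits <- scan_promoters(gen$sequences, pwm,
                           deficit_cutoff = cfg$deficit_cutoff)
    clusters <- find_clusters(hits, window = cfg$cluster_window)
    res$promoter_truth <- gen$truth
    res$hits <- hits |> mutate(gene_id = gene_of[.data$promoter_id])
    res$clusters <- clusters |>
      mutate(gene_id = gene_of[.data$promoter_id])
    log$motif <- c(n_promoters = pr$n_promoters, n_hits = nrow(hits),
                   n_clustered = length(unique(clusters$promoter_id)))
  }

  if ("score" %in% cfg$stages) {
    motif_pool <- unique(res$hits$gene_id)
    clustered <- unique(res$clusters$gene_id)
    universe <- unique(c(res$top_up$gene_id, res$top_down$gene_id,
                         motif_pool, clustered))
    sets <- with_seed(cfg$seed + 3L, {
      lapply(setNames(nm = names(cfg$weights)), function(s) {
        sample(universe, max(1, round(0.15 * length(universe))))
      })
    })
    collection <- gene_set_collection(sets, unlist(cfg$weights))
    res$candidates <- assemble_candidates(
      res$top_up, res$top_down, motif_pool, clustered,
      collection, threshold = cfg$score_threshold)
    log$score <- c(n_universe = length(universe),
                   n_selected = sum(res$candidates$selected))
  }

  if ("targets" %in% cfg$stages) {
    sel <- filter(res$candidates, .data$selected)
    lfc <- res$de$log_fold_change[match(sel$gene_id, res$de$gene_id)]
    ann <- with_seed(cfg$seed + 4L, {
      tibble(gene_id = sel$gene_id,
             log_fold_change = lfc,
             inhibitor_exists = runif(nrow(sel)) < 0.6,
             inhibitor_is_antibody = runif(nrow(sel)) < 0.1,
             secreted = runif(nrow(sel)) < 0.3,
             recombinant_exists = runif(nrow(sel)) < 0.5,
             activator_exists = runif(nrow(sel)) < 0.3,
             is_growth_factor = runif(nrow(sel)) < 0.1,
             is_ecm = runif(nrow(sel)) < 0.1,
             known_or_contradictory = runif(nrow(sel)) < 0.1)
    })
    res$annotations <- ann
    res$decisions <- decide_targets(ann)
    pb <- build_panel(res$decisions)
    res$panel <- pb$panel
    res$summary <- pb$summary
    log$targets <- c(n_candidates = nrow(ann), n_panel = nrow(pb$panel))
  }

  manifest <- list(parameters = unclass(cfg), stage_log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tbls <- res[vapply(res, is.data.frame, logical(1))]
    files <- character(0)
    for (nm in names(tbls)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      tbl <- tbls[[nm]]
      tbl[] <- lapply(tbl, function(col)
        if (is.list(col)) vapply(col, paste, character(1), collapse = ",")
        else col)
      readr::write_tsv(tbl, f)
      files[nm] <- f
    }
    manifest$outputs <- lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res$manifest <- manifest
  res
}
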