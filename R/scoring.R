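#' Default phenotype-database weights
#'
#' Mitotic G2-G2/M phases +2, human kinome +1, matrisome +0.5, cell
#' adhesion +0.5; a total weighted score of 2 or more selects a candidate.
#'
#' @export
default_set_weights <- function() {
  c(g2m = 2, kinome = 1, matrisome = 0.5, adhesion = 0.5)
}

#' A weighted gene-set collection
#'
#' @param sets Named list of character vectors of gene identifiers. Names
#'   must match the names of `weights`.
#' @param weights Named numeric vector of strictly positive set weights
#'   (default [default_set_weights()]).
#' @return A `gene_set_collection` object; identifiers are uppercased and
#'   matched as exact strings.
#' @export
#' @examples
#' sets <- gene_set_collection(list(g2m = c("CDK1"), kinome = c("CDK1"),
#'                                  matrisome = "FN1", adhesion = "ITGA1"))
#' score_genes(c("CDK1", "FN1"), sets)
gene_set_collection <- function(sets, weights = default_set_weights()) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a uniquely named list", class = "foxscreen_input_error")
  }
  if (!all(names(sets) %in% names(weights))) {
    abort(paste("no weight for set(s):",
                paste(setdiff(names(sets), names(weights)), collapse = ", ")),
          class = "foxscreen_input_error")
  }
  weights <- weights[names(sets)]
  if (any(weights <= 0)) abort("weights must be strictly positive",
                               class = "foxscreen_input_error")
  structure(list(sets = lapply(sets, function(g) unique(toupper(g))),
                 weights = weights),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path (set name, description, members per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Score genes against a weighted gene-set collection
#'
#' Each gene's score is the sum of the weights of the sets it belongs to;
#' genes absent from every set score 0. A gene is selected when its score
#' reaches `threshold` (default 2).
#'
#' @param genes Character vector of gene identifiers, or a data frame with a
#'   `gene_id` column.
#' @param collection A [gene_set_collection()].
#' @param threshold Selection threshold on the score (default 2).
#' @return Tibble with `gene_id`, `memberships` (comma-joined set names),
#'   `score`, `selected`, sorted by descending score then gene id.
#' @export
score_genes <- function(genes, collection, threshold = 2) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.data.frame(genes)) genes <- genes$gene_id
  genes <- unique(toupper(genes))
  member <- vapply(collection$sets, function(s) genes %in% s,
                   logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, names(collection$sets)))
  score <- as.numeric(member %*% collection$weights)
  tibble(
    gene_id = genes,
    memberships = apply(member, 1, function(m)
      paste(names(collection$sets)[m], collapse = ",")),
    score = score,
    selected = score >= threshold
  ) |>
    arrange(desc(.data$score), .data$gene_id)
}

#' Assemble the candidate list from ranked genes, motif pool and clustered genes
#'
#' Takes the union of the supplied gene pools, scores every gene against the
#' collection, and selects (i) genes reaching the score threshold and (ii)
#' all clustered-motif genes, which bypass the threshold. Duplicates collapse
#' to a single record; a gene that is also clustered keeps the
#' `clustered_motif` source tag.
#'
#' @param top_up,top_down,motif_pool,clustered Character vectors of gene ids
#'   (or data frames with a `gene_id` column).
#' @param collection A [gene_set_collection()].
#' @param threshold Selection threshold (default 2).
#' @return Tibble with `gene_id`, `source`, `memberships`, `score`,
#'   `selected`, sorted by descending score then gene id.
#' @export
assemble_candidates <- function(top_up = character(), top_down = character(),
                                motif_pool = character(),
                                clustered = character(),
                                collection, threshold = 2) {
  getids <- function(x) {
    if (is.data.frame(x)) x <- x$gene_id
    unique(toupper(x))
  }
  top_up <- getids(top_up); top_down <- getids(top_down)
  motif_pool <- getids(motif_pool); clustered <- getids(clustered)
  universe <- unique(c(top_up, top_down, motif_pool, clustered))
  if (!length(universe)) {
    return(tibble(gene_id = character(), source = character(),
                  memberships = character(), score = numeric(),
                  selected = logical()))
  }
  scored <- score_genes(universe, collection, threshold)
  scored |>
    mutate(
      source = dplyr::case_when(
        .data$gene_id %in% clustered ~ "clustered_motif",
        .data$gene_id %in% top_up ~ "top100_up",
        .data$gene_id %in% top_down ~ "top100_down",
        TRUE ~ "motif_pool"
      ),
      selected = .data$selected | .data$source == "clustered_motif"
    ) |>
    select("gene_id", "source", "memberships", "score", "selected") |>
    arrange(desc(.data$score), .data$gene_id)
}
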