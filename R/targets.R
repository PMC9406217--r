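#' Classify candidate targets as requiring inhibition or activation
#'
#' Applies the actionability decision tree to annotated candidates. A
#' positive log fold change (gene downregulated in the knockout) calls for
#' inhibition; a negative one for activation. On the inhibit branch a known
#' inhibitor gives a small-molecule (or antibody) modality; failing that, a
#' secreted target with an available recombinant ligand can be inhibited via
#' recombinant protein. On the activate branch a secreted protein with an
#' available recombinant is supplied as recombinant protein, otherwise a
#' known activator/agonist is used; if nothing exists the modality is
#' `none_found`. Refinement then removes secreted growth factors, ECM
#' components and targets with known or contradictory effects from the
#' panel.
#'
#' The literature/annotation searches behind the boolean flags are inputs,
#' not computations, which keeps the tree deterministic and testable.
#'
#' @param annotations Data frame with columns `gene_id`, `log_fold_change`
#'   and logical flags `inhibitor_exists`, `secreted`, `recombinant_exists`,
#'   `activator_exists`, `is_growth_factor`, `is_ecm`,
#'   `known_or_contradictory`; optional `inhibitor_is_antibody` (default
#'   FALSE) and `compound`.
#' @param refine Apply the panel-refinement exclusions (default TRUE).
#' @return Tibble with `gene_id` (and `compound` if given), `action`
#'   (`inhibit`/`activate`, `NA` for log fold change 0, which is flagged),
#'   `modality`, `in_panel`, `exclusion_reason`.
#' @export
#' @examples
#' ann <- read_target_annotations(
#'   system.file("extdata", "table2_annotations.tsv", package = "foxscreen"))
#' decide_targets(ann)
decide_targets <- function(annotations, refine = TRUE) {
  ann <- as_tibble(annotations)
  flags <- c("inhibitor_exists", "secreted", "recombinant_exists",
             "activator_exists", "is_growth_factor", "is_ecm",
             "known_or_contradictory")
  req <- c("gene_id", "log_fold_change", flags)
  if (!all(req %in% names(ann))) {
    abort(paste("missing annotation column(s):",
                paste(setdiff(req, names(ann)), collapse = ", ")),
          class = "foxscreen_input_error")
  }
  if (!"inhibitor_is_antibody" %in% names(ann)) {
    ann$inhibitor_is_antibody <- FALSE
  }
  if (any(ann$log_fold_change == 0)) {
    warn("annotation(s) with log fold change 0 are undecidable and excluded")
  }
  out <- ann |>
    mutate(
      action = dplyr::case_when(
        .data$log_fold_change > 0 ~ "inhibit",
        .data$log_fold_change < 0 ~ "activate",
        TRUE ~ NA_character_
      ),
      modality = dplyr::case_when(
        is.na(.data$action) ~ "none_found",
        .data$action == "inhibit" & .data$inhibitor_exists &
          .data$inhibitor_is_antibody ~ "antibody",
        .data$action == "inhibit" & .data$inhibitor_exists ~
          "small_molecule_inhibitor",
        .data$action == "inhibit" & .data$secreted &
          .data$recombinant_exists ~ "recombinant_protein",
        .data$action == "activate" & .data$secreted &
          .data$recombinant_exists ~ "recombinant_protein",
        .data$action == "activate" & .data$activator_exists ~ "agonist",
        TRUE ~ "none_found"
      ),
      exclusion_reason = dplyr::case_when(
        is.na(.data$action) ~ "undecidable_lfc",
        .data$modality == "none_found" ~ "no_compound",
        !refine ~ NA_character_,
        .data$secreted & .data$is_growth_factor ~ "secreted_factor",
        .data$is_ecm ~ "ecm_component",
        .data$known_or_contradictory ~ "known_effect",
        TRUE ~ NA_character_
      ),
      in_panel = is.na(.data$exclusion_reason)
    )
  keep <- intersect(c("compound", "gene_id", "log_fold_change", "action",
                      "modality", "in_panel", "exclusion_reason"),
                    names(out))
  out[keep]
}

#' Build the compound panel and its summary counts
#'
#' @param decisions Tibble from [decide_targets()].
#' @return List with `panel` (decisions with `in_panel = TRUE`) and
#'   `summary` (a tibble of counts per action).
#' @export
build_panel <- function(decisions) {
  panel <- filter(decisions, .data$in_panel)
  summary <- panel |>
    count(.data$action, name = "n_targets") |>
    arrange(desc(.data$n_targets))
  list(panel = panel, summary = summary)
}

#' Read a target-annotation table
#'
#' @param path TSV with the columns documented in [decide_targets()].
#' @return Tibble of annotations with logical flags.
#' @export
read_target_annotations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    mutate(across(dplyr::any_of(c(
      "inhibitor_exists", "inhibitor_is_antibody", "secreted",
      "recombinant_exists", "activator_exists", "is_growth_factor",
      "is_ecm", "known_or_contradictory")), as.logical))
}
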