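# Independent oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

BASES4 <- c("A", "C", "G", "T")
RC_MAP <- c(A = "T", C = "G", G = "C", T = "A")

# brute-force rescoring of every window on both strands
oracle_scan <- function(seq, pwm, cutoff = 0.15, both_strands = TRUE) {
  chars <- strsplit(toupper(seq), "")[[1]]
  w <- pwm$width
  cons <- strsplit(pwm$consensus, "")[[1]]
  rng <- pwm$s_max - pwm$s_min
  out <- list()
  if (length(chars) < w) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric(), deficit = numeric()))
  }
  strands <- if (both_strands) c("+", "-") else "+"
  for (start in seq_len(length(chars) - w + 1)) {
    win <- chars[start:(start + w - 1)]
    if (any(!win %in% BASES4)) next
    for (st in strands) {
      word <- if (st == "+") win else rev(unname(RC_MAP[win]))
      sc <- 0
      for (j in seq_len(w)) sc <- sc + pwm$logodds[word[j], j]
      core_ok <- all(word[pwm$core] == cons[pwm$core])
      deficit <- if (rng > 0) max((pwm$s_max - sc) / rng, 0) else 0
      if (core_ok && deficit <= cutoff) {
        out[[length(out) + 1L]] <- data.frame(start = start - 1L,
                                              strand = st, score = sc,
                                              deficit = deficit)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric(), deficit = numeric()))
  }
  do.call(rbind, out)
}

# O(n^2) transitive closure of the pairwise within-window relation
oracle_clusters <- function(starts, window = 100) {
  n <- length(starts)
  if (n < 2) return(list())
  adj <- abs(outer(starts, starts, "-")) <= window
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comps <- split(starts, comp)
  Filter(function(x) length(x) >= 2, unname(lapply(comps, sort)))
}

# exhaustive evaluation of the actionability tree for one annotation row
oracle_decision <- function(r) {
  if (r$log_fold_change > 0) {
    action <- "inhibit"
    if (r$inhibitor_exists) {
      modality <- if (isTRUE(r$inhibitor_is_antibody)) "antibody" else
        "small_molecule_inhibitor"
    } else if (r$secreted && r$recombinant_exists) {
      modality <- "recombinant_protein"
    } else modality <- "none_found"
  } else if (r$log_fold_change < 0) {
    action <- "activate"
    if (r$secreted && r$recombinant_exists) {
      modality <- "recombinant_protein"
    } else if (r$activator_exists) {
      modality <- "agonist"
    } else modality <- "none_found"
  } else {
    return(list(action = NA_character_, in_panel = FALSE))
  }
  in_panel <- modality != "none_found" &&
    !(r$secreted && r$is_growth_factor) && !r$is_ecm &&
    !r$known_or_contradictory
  list(action = action, modality = modality, in_panel = in_panel)
}

random_annotations <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      gene_id = sprintf("G%03d", seq_len(n)),
      log_fold_change = stats::rnorm(n),
      inhibitor_exists = stats::runif(n) < 0.5,
      inhibitor_is_antibody = stats::runif(n) < 0.2,
      secreted = stats::runif(n) < 0.5,
      recombinant_exists = stats::runif(n) < 0.5,
      activator_exists = stats::runif(n) < 0.5,
      is_growth_factor = stats::runif(n) < 0.2,
      is_ecm = stats::runif(n) < 0.2,
      known_or_contradictory = stats::runif(n) < 0.2
    )
  })
}

test_pwm <- function() {
  build_pwm(read_jaspar_pfm(
    system.file("extdata", "forkhead_synthetic.pfm", package = "foxscreen")))
}

example_collection <- function() {
  gene_set_collection(read_gmt(
    system.file("extdata", "example_sets.gmt", package = "foxscreen")))
}
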