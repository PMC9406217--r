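# foxscreen

A tidyverse-native R package for running a transcription-factor
target-discovery screen and validating the cellular phenotypes it predicts.
The motivating application is the search for druggable effector pathways
downstream of FOXD1 in clear cell renal cell carcinoma (ccRCC), where loss
of the transcription factor delays the G2/M cell-cycle transition; the
package implements the analysis stages of that screen as reusable,
deterministic, tested functions that consume standard tabular and image
inputs.

## What it computes

**Candidate discovery.** Starting from a differential-expression table
(gene id, fold change, log2 fold change, p, adjusted p):

- `classify_de()` partitions genes into *differential* (adjusted p ≤ 0.05,
  boundary inclusive), *equal*, and *uninterpretable* (missing adjusted p,
  discarded downstream); `top_ranked()` keeps the 100 largest
  |log2 fold change| genes per direction with deterministic tie-breaking.
- `build_pwm()` turns a position frequency matrix (JASPAR text format,
  `read_jaspar_pfm()`) into a log2-odds scoring matrix with a *core mask*
  (positions with information content ≥ 1 bit). `scan_promoter()` slides it
  over promoter windows (−1.5 kb/+0.5 kb of the TSS, `promoter_window()`)
  on both strands; a window is a hit when every core position matches the
  consensus and its *deficit*

  `deficit = (S_max − S) / (S_max − S_min)`

  is at most 0.15 — a 15% tolerance for mismatches outside the core
  consensus. `find_clusters()` chains hits whose starts lie within 100 bp
  (inclusive) and reports clusters of two or more motifs, the
  high-stringency "clustered motif" class.
- `score_genes()` cross-references candidates against four weighted
  phenotype gene sets — mitotic G2-G2/M (+2), human kinome (+1), matrisome
  (+0.5), cell adhesion (+0.5) — and selects genes with total score ≥ 2;
  `assemble_candidates()` unions the ranked, motif-pool and clustered gene
  lists, with clustered genes bypassing the threshold.
- `decide_targets()` applies the actionability tree (positive log fold
  change → inhibit, negative → activate; modality from
  inhibitor/recombinant/agonist availability flags) and refines the panel
  by removing secreted growth factors, ECM components and targets with
  known or contradictory effects; `build_panel()` reports the dispositions.

**Phenotype validation.** `summarize_doses()` computes percent growth
inhibition and percent viability per dose with one-sided toxicity calls
against vehicle wells, and `optimal_dose()` picks the greatest inhibition
without toxicity. `fit_g1()`/`gate_phases()` gate DNA-content events using
a synchronized control: the G2/M gate center is exactly twice the fitted G1
center, S phase is everything in between. `segment_colonies()`,
`segment_nuclei()`, `detect_anuclear()`, `classify_fragmented()` and
`compare_morphology()` quantify 3-channel 3D-culture images (Otsu
threshold, despeckle median filter, distance-transform watershed,
live/dead overlap calls, z-tests on nuclear areas with signed fold
changes).

**Synthetic data.** Every stage has a paired generator with ground truth
(`generate_de_table()`, `generate_promoters()`,
`generate_cytometry_events()`, `generate_plate()`, `generate_images()`,
`generate_morphometry_study()`), so the whole pipeline is testable at desk
scale; `run_screen()` chains the stages end-to-end from one
`screen_config()` and writes TSVs plus a hashed manifest.

## Worked example

```r
library(foxscreen)

de <- classify_de(generate_de_table(synth_de_config(n_genes = 2000, seed = 1)))
#> classified 2000 genes: 600 differential, 1300 equal,
#> 100 uninterpretable (discarded downstream)

pwm <- build_pwm(read_jaspar_pfm(
  system.file("extdata", "forkhead_synthetic.pfm", package = "foxscreen")))
pwm
#> <foxd_pwm> forkhead_synthetic ...  width=8  consensus=GTAAACAA  core=..****..
#>   score range [-18.264, 11.779]

gen <- generate_promoters(synth_promoter_config(
  n_promoters = 20,
  planted = data.frame(promoter = c(1, 1, 2), offset = c(400, 470, 900),
                       strand = "+"),
  seed = 2), pwm)
hits <- scan_promoters(gen$sequences, pwm, deficit_cutoff = 0.15)
find_clusters(hits, window = 100)[1, ]
#> # A tibble: 1 × 7
#>   promoter_id cluster_id n_hits start_min start_max  span starts
#>   <chr>            <int>  <int>     <int>     <int> <int> <list>
#> 1 promoter_1           1      2       400       470    70 <int [2]>
```

The two sites planted 70 bp apart in `promoter_1` come back as a motif
cluster; the remaining clusters in the full output are chance pairings of
weak background hits, which is why clustered-motif calls are combined with
the scoring stage rather than used alone.

```r
sets <- gene_set_collection(read_gmt(
  system.file("extdata", "example_sets.gmt", package = "foxscreen")))
score_genes(c("CDK1", "FN1", "EGFR"), sets)
#> # A tibble: 3 × 4
#>   gene_id memberships        score selected
#> 1 CDK1    g2m,kinome             3 TRUE
#> 2 EGFR    kinome                 1 FALSE
#> 3 FN1     matrisome,adhesion     1 FALSE

ann <- read_target_annotations(system.file(
  "extdata", "table2_annotations.tsv", package = "foxscreen"))
build_panel(decide_targets(ann))$summary
#> # A tibble: 2 × 2
#>   action   n_targets
#> 1 inhibit         12
#> 2 activate         6
```

CDK1 (G2/M +2, kinome +1) scores 3 and is selected; the bundled 18-target
annotation fixture resolves to 12 inhibition and 6 activation targets, all
panel-eligible.

## Vignette

`vignettes/foxscreen-methods.Rmd` documents the models and assumptions,
every tunable parameter with its default and rationale, what the synthetic
generators do and do not emulate, and known limitations.
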