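---
title: "foxscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foxscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxscreen)
```

This vignette is the package's own account of its methods: the models each
stage implements, the assumptions behind them, the tunable parameters and
why their defaults are what they are, what the synthetic-data generators do
and do not emulate, and the numerical choices made where the design was
genuinely open.

## The screen

The screen searches for actionable effector genes downstream of a
transcription factor whose loss produces a measurable cellular phenotype
(the motivating case: FOXD1 in ccRCC cells, where knockout delays the G2/M
cell-cycle transition). It combines two candidate streams — extreme
differential expression and promoter motif evidence — scores candidates
against phenotype-relevant gene sets, classifies the survivors by the
pharmacological action required, and validates compounds against the
knockout phenotype with dose-response, cell-cycle and 3D-culture imaging
assays.

## Differential-expression filtering

`classify_de()` implements a three-way partition. A gene is *differential*
when its adjusted p-value is at or below `alpha` (default 0.05 — the
boundary is inclusive), *uninterpretable* when the adjusted p is missing
(these rows are excluded from every downstream stage, since no error
control is available for them), and *equal* otherwise. Missing adjusted p
with a present raw p still counts as uninterpretable: the adjusted value is
the only one the cutoff uses.

Fold changes are oriented as reference line over knockout, so fold change
> 1 (log fold change > 0) means the gene is *down* in the knockout and its
product is a candidate for *inhibition*. This orientation makes the DE
classification and the actionability tree consistent by construction; it is
a storage convention, not a computation, and inputs with the opposite
orientation only need their ratios inverted.

`top_ranked()` ranks by |log2 fold change| within a direction. Ties are
broken by smaller adjusted p, then lexicographic gene id, so the top-k set
is reproducible run to run. Ranking by raw fold-change magnitude is
equivalent in ordering and available via `rank_by` for transparency. When
fewer than `k` genes exist the full pool is returned with a warning rather
than an error, since short pools are expected in subsetted analyses.

## Motif scanning

`build_pwm()` converts count matrices to log2-odds scores with column
probabilities `(count + pseudocount) / (total + 4·pseudocount)`
(pseudocount 1 by default) against a configurable background (uniform by
default). The best and worst achievable window sums, `S_max` and `S_min`,
normalize every window score into a *deficit*:

$$\mathrm{deficit} = \frac{S_{\max} - S}{S_{\max} - S_{\min}} \in [0, 1].$$

A window is a hit when (a) its deficit is at most the cutoff (default
0.15) and (b) every *core* position matches the consensus base exactly.
The core is defined as positions with information content ≥ 1 bit
(configurable); this operationalizes a mismatch tolerance that applies
only *outside* a core consensus, without requiring a published definition
of the core. The range-normalized deficit is monotone in score and makes a
"15% tolerance" statement matrix-independent. Degenerate matrices with
`S_max = S_min` (e.g. uniform counts) are assigned deficit 0 everywhere.
Tiny negative deficits from floating-point cancellation are clamped to 0.

Both strands are scanned by default; reverse-strand hits are reported at
forward-strand window-start coordinates (0-based, half-open), and all
overlapping hits are retained — no greedy masking, so the hit set is
symmetric under reverse complementation. Windows containing `N` are
skipped. The scanner is verified against a brute-force per-window
rescoring oracle in the test suite.

`find_clusters()` chains hits by single linkage: consecutive sorted starts
at most `window` apart (default 100 bp, inclusive — "within 100 bp" is
read as ≤ 100) join one cluster, and clusters need ≥ 2 members. Distance
is start-to-start by default; an edge-to-edge mode (`measure = "edge"`) is
provided because the two conventions differ for adjacent hits and the
choice is a genuine open question. Single-linkage chaining equals the
transitive closure of the pairwise relation, which the tests verify
against an O(n²) oracle.

`promoter_window()` returns −1500/+500 bp windows (defaults) around a TSS,
oriented by strand, truncating at sequence boundaries with a warning.

## Candidate scoring and panel assembly

`score_genes()` sums membership weights over four databases — mitotic
G2-G2/M +2, kinome +1, matrisome +0.5, adhesion +0.5 — and selects genes
with score ≥ 2. The weights encode the screen's priority: G2/M membership
alone suffices, kinome alone does not, and the small structural sets only
select in combination. Identifier matching is exact string comparison
after uppercasing; alias resolution is out of scope because database
cross-referencing conventions vary and silent aliasing is worse than a
missed match.

`assemble_candidates()` takes the union of the ranked up/down lists, the
motif pool, and the clustered-motif genes. Clustered genes bypass the score
threshold — clustering of binding sites is treated as sufficient evidence
on its own. Duplicates collapse to one record that keeps the
`clustered_motif` source tag; union-with-deduplication is the only
arithmetic-consistent reading of combining overlapping candidate streams.
Gene sets load from GMT files (`read_gmt()`, via fgsea); the bundled GMT is
a small synthetic example for tests and demonstrations, and real database
snapshots are user-supplied inputs since their contents change over time.

## Target actionability

`decide_targets()` is a deterministic decision tree over annotation flags.
The sign of the log fold change alone fixes the action (positive →
inhibit, negative → activate). Modality then depends only on the flags:
on the inhibit branch a known inhibitor gives a small-molecule (or
antibody) modality, failing that a secreted target with an available
recombinant ligand can be inhibited through that ligand (the pattern of
supplying a pathway's natural ligand to shut down the target's signaling);
on the activate branch secreted-with-recombinant precedes agonist search.
Refinement removes secreted growth factors, ECM components and targets
with known or contradictory effects — exclusions established by the
screen's control experiments (conditioned-media and native-ECM growth
assays, `compare_growth_curves()`), not recomputed here.

The literature and annotation searches behind the flags are *inputs*: they
are judgments, and modeling them as data keeps the tree total, auditable
and testable (the suite checks it against an independently written
truth-table oracle over all flag combinations). A bundled 18-target
annotation fixture demonstrates the tree end-to-end and resolves to 12
inhibition and 6 activation dispositions.

## Dose-response screening

`summarize_doses()` computes, per compound and dose, percent growth
(100 × mean treated total / mean vehicle total), percent inhibition (its
complement) and percent viability (100 × mean dead-negative count / mean
total, within the treated wells). Growth is compared to vehicle with a
two-sided t-test on per-well totals. Toxicity is a *one-sided* test for an
increase in the per-well dead fraction: the screen's purpose is to find
doses that reduce proliferation *without* excess death, so only an
increase matters and reduced death must not count as toxicity. Welch's
unequal-variance t-test is the default wherever a t-test is named, since
count-derived quantities rarely have equal variances; a pooled-variance
switch (`var_equal`) allows exact replication of classic Student tests.
Zero-variance groups (e.g. all-zero dead counts) are handled by a direct
mean comparison instead of an undefined t statistic. No multiple-testing
correction is applied across doses or compounds by default, matching
screening practice where per-compound decisions are made independently.

`optimal_dose()` returns the greatest percent inhibition among doses that
are both non-toxic and significantly growth-inhibitory; ties go to the
lowest dose, and no qualifying dose yields `NA` with a warning rather than
a silent fallback.

## Cell-cycle gating

`fit_g1()` estimates the G1 center from a synchronized control in which
all cells are in G1: the dominant kernel-density mode anchors a local
Gaussian fit (mean and SD of events within ±25% of the mode). A control
with a second density peak of at least half the main peak's height, more
than 20% of the mode away, is rejected as unsynchronized — a cheap,
deliberate guard against feeding an async population as the anchor.

`build_gates()` places the G1 gate at μ ± kσ and the G2/M gate at exactly
2μ ± 2kσ: replicated genomes double the DNA signal, so both the center and
the spread double. S phase is the *open* interval between the gates ("all
values in between"), and events below G1 or above G2/M are excluded
rather than assigned, so sub-G1 debris cannot inflate the G1 fraction.

The default half-width is k = 2. This is an analytic choice, not a fitted
one: gating a Normal(μ, cv·μ) + Uniform(μ, 2μ) + Normal(2μ, 2·cv·μ)
mixture with hard gates loses uniform S mass inside the closed gates
(≈ 0.09·k·cv of the S interval) while Gaussian tail mass beyond kσ
(2Φ(−k) per component) spills into the S interval. The first error grows
with k, the second shrinks, and at cv ≈ 0.03 they balance near k = 2,
where every phase's bias stays below about 0.02 for a 0.6/0.2/0.2
mixture. Larger k (e.g. 2.5) makes the S-phase bias exceed 0.04. k is
configurable; the gates error out if kσ is large enough to make G1 and
G2/M overlap. Fractions are invariant to global intensity rescaling
because gates and events scale together.

`compare_g2m()` runs a one-sided test for an *increase* in per-replicate
G2/M fractions — the selection criterion for compounds that delay the
G2/M transition.

## Image morphometry

The imaging stage mirrors a standard FIJI workflow with automatic
equivalents of its interactive tools: Otsu thresholding stands in for the
interactive threshold tool (method configurable), "despeckle" is a 3×3
median filter (its documented behavior), and touching nuclei are split by
a distance-transform watershed (tolerance 1). Components below a minimum
area (10 px² for nuclei, 50 px² for colonies by default) are discarded as
debris.

Colonies come from the live-cell channel, which covers whole cell bodies
and therefore defines the regions of interest; a colony is *dead* when at
least 50% of its pixels are positive in the binarized dead-cell channel —
the overlap fraction is configurable since the underlying live/dead
designation is qualitative. A colony is *anuclear* when no nucleus
centroid falls inside its mask. A nucleus is *fragmented* when its area is
below 0.3 × the median vehicle nucleus area; this ratio operationalizes a
judgment otherwise made by eye, is configurable, and is reported alongside
every result. Fractions are reported as rounded whole percents with their
raw counts (e.g. 115/186 → 62%, 191/377 → 51%), and always equal the raw
count ratios exactly.

`compare_morphology()` uses a two-sample z-test on mean areas (the
large-sample comparison appropriate for hundreds of nuclei per
condition), falling back to Welch's t with a warning below 30 objects per
arm. Fold changes are *signed*: the ratio when ≥ 1, minus its reciprocal
otherwise, so a halving reports −2 rather than 0.5. Colony-count
comparisons use the standardized Poisson-count z-test
`(c₁ − c₂)/√(c₁ + c₂)`.

## Synthetic data: what it emulates, and what it does not

Every generator is seeded and byte-reproducible, and emits a ground-truth
table sufficient to score its analysis stage without re-deriving labels.

- **DE tables** place adjusted p-values on the correct side of the cutoff
  by construction and force the exact missing-p count by rounding; they
  emulate the *shape* of DE output, not dispersion estimation or p-value
  distributions under a specific model.
- **Promoters** are i.i.d. background with configurable GC content — no
  repeat structure, CpG islands or chromatin context (the simplest null
  for scanner validation). Planted sites are exact consensus words
  (deficit 0) unless a mutation rate is requested.
- **Cytometry events** are the Gaussian/uniform/Gaussian mixture described
  above; no doublets, no aggregates, no instrument drift.
- **Plates** draw Poisson totals around a Hill inhibition curve with
  binomial deaths; they emulate well-to-well counting noise, not edge
  effects or spatial plate artifacts.
- **Images** draw blurred disks with Poisson noise: one disk per nucleus,
  one blob per colony, dead-channel disks for dead colonies. Fragmented
  nuclei are connected chains of 2–4 small disks inside the parent
  footprint, each ~10% of the parent area with the total capped at 28%, so
  a fragment union stays below the 30% fragmentation threshold by
  construction and planted truth is recoverable. Anuclear colonies have
  live-channel signal and no nuclear disks. Real 3D-culture images differ
  in depth (these are single-plane), texture, uneven illumination and
  clumping — passing tests demonstrate that the *algorithms* recover known
  truth under controlled conditions, not that segmentation of any real
  image is accurate.

`generate_morphometry_study()` is the default two-condition study used by
the nuclear-size analyses: six 512×512 images per arm, ~25 colonies and ~5
nuclei per colony per image, yielding well over 500 nuclei per condition —
the scale at which large-sample z-tests on nuclear area are appropriate —
with a planted 2.6-fold area increase in the treated arm (SD scaled
proportionally so the lognormal shape is preserved).

Generator defaults are free parameters of the synthetic model chosen to be
realistic for the assay class, not estimates of any particular
experiment's data.

## Pipeline

`run_screen()` executes the enabled stages in dependency order from one
`screen_config()` whose defaults are the screen's operating constants
(alpha 0.05, top-100, deficit 0.15, 100 bp cluster window, −1.5 kb/+0.5 kb
windows, the four weights, threshold 2). It introduces no hidden state:
the composition equals calling the stage functions by hand with the same
seeds, which the tests verify. Runs log record counts at each funnel step
and, when an output directory is given, write per-stage TSVs and a JSON
manifest with md5 hashes — identical configuration and seed give identical
hashes. Configurations round-trip losslessly through YAML.

## Problem sizes and test design

The test suite builds all fixtures in code at run time. Representative
sizes, chosen to keep the suite fast while leaving sampling error well
below the tolerances being checked: DE tables of 300–2000 genes; scanner
oracle comparisons on 100 promoters of 0.5–2 kb; 16-combination
score enumeration; 10⁴-event cytometry mixtures over 100 seeds;
1000 simulated null plates for toxicity-call calibration; 20 image seeds
for count recovery plus the 12-image morphometry study. The acceptance
script (`scripts/acceptance.R`) recomputes the headline quantities from
scratch at the same scales.

## Known limitations

- Motif scanning covers a single matrix over supplied promoter sequences;
  genome-wide TSS lookup from annotation, multi-matrix scanning and motif
  discovery are out of scope.
- The exact internal scoring of interactive TFBS tools cannot be
  reproduced from their published descriptions; the deficit and core
  definitions here are documented, configurable approximations.
- Cell-cycle gating is hard-interval gating, not mixture-model fitting
  (no Dean–Jett–Fox or Watson models, no doublet discrimination); the
  analytic bias bound above applies to well-separated peaks with small CV.
- Image analysis is 2D single-plane; volumetric segmentation and
  time-course tracking are not attempted, and the fragmentation and
  dead-colony rules are explicit operationalizations of qualitative
  judgments.
- Dose-response summarisation deliberately does not fit EC50/IC50 curves;
  doses are compared, not modeled.
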