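---
title: "kspnet: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kspnet: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kspnet)
```

# The problem

A phosphosite is a serine, threonine or tyrosine residue observed to be
phosphorylated, represented throughout this package as a 15-mer: the
residue plus ±7 flanking amino acids, padded with `_` at protein termini.
Given a query site, the task is to rank candidate kinases. `kspnet`
scores candidates through three channels — a network affinity, a motif
likelihood and a nearest-neighbour vote — and combines them additively
after per-site normalization.

# Network affinity

## The integrated network

Known kinase–substrate pairs and a PPI edge list are merged into one
weighted undirected graph; only the largest connected component is kept
(ties broken deterministically by the component containing the
lexicographically smallest node id). The sources say only that edge
weights reflect "the number of identified interactions"; we make that
concrete as:

* kinase–substrate edge: the number of distinct phosphosites of that
  substrate catalyzed by the kinase (site counts carry the catalytic
  evidence);
* PPI edge: weight 1 (binary evidence);
* a pair supported by both: the larger of the two.

## Path-product terms and walk semantics

KS0–KS3 sum edge-weight products over connections of length 1–4 between
the kinase and the protein. The printed nested neighbourhood sums admit
degenerate walks that revisit an endpoint (for instance a length-3 walk
k–n–v–n when k and n are adjacent); whether the original implementation
excluded them is not stated. We therefore provide both semantics:

* **simple** (default): intermediate nodes exclude both endpoints and
  are pairwise distinct — each term sums over genuine simple paths.
  Degenerate walks only recycle KS0/KS1 information, and the method's
  motivation is support "by interactions among neighbours", which simple
  paths capture; hence the default.
* **literal**: the nested sums exactly as printed. Because the graph has
  no self-loops, each printed constraint is enforced by a zero weight,
  and the four sums equal the (k, n) entries of the 1st–4th powers of
  the weighted adjacency matrix; that is how the mode is computed. Both
  modes are verified against independent brute-force enumerators in the
  test suite.

Simple mode is computed by one depth-limited DFS per kinase that
accumulates path products for every endpoint simultaneously, so building
the full bipartite affinity graph costs one traversal per kinase rather
than one per pair.

## Degree penalty

p_d(x) = 1 for degree ≤ 2, otherwise
1 − 0.2·(log₂d_x − min log₂d)/(max log₂d − min log₂d), with min/max over
all nodes of the integrated network. It shrinks hub kinases' scores by up
to 20%, counteracting the literature bias toward well-studied kinases.
Two numerical guards: a network whose log-degrees are all equal would
give 0/0 and returns 1 instead; the result is clamped to [0.8, 1] because
floating-point subtraction can land infinitesimally below 0.8 at the
maximum-degree node.

## The β vector

Default β = (0.25, 0.225, 0.1875, 0.1875), weighting shorter connections
more. The accompanying text asserts the components "add up to 1", yet the
printed default sums to 0.85. We use the printed default verbatim and do
not renormalize: rankings are invariant to a global rescaling of β, so
the discrepancy is inert for prediction, but reproducing the stated
default exactly keeps scores comparable with the original tool. Users
are free to pass any non-negative β.

# Sequence scorers

## Position weight matrices

Per kinase with **more than** `min_sites` (default 15) distinct site
peptides, counts per (residue, position) over the aligned 15-mers are
converted to log₂ likelihoods against a background:
M[a, j] = log₂((count + α) / ((N_j + 20α)·b_a)), where N_j counts
peptides with a real residue at position j (padding contributes no
counts, so truncated windows renormalize over what was observed).
Choices the sources leave open:

* **Background b** (default: pooled). Frequencies pooled over all
  training peptides' non-padding residues, shared by every kinase model,
  reflecting the compositional bias of phosphosite flanks; a uniform
  1/20 background is available. A zero pooled frequency (tiny corpora)
  is smoothed minimally to keep all log-likelihoods finite.
* **Pseudocount α** (default 0, with a floor). log₂(0) is undefined;
  with α = 0 an unobserved cell is floored at −10 rather than −Inf. The
  floor preserves the printed formula on observed cells while keeping
  every peptide score finite; any α > 0 is accepted and then no cell is
  floored.
* **Scoring padding/unknown residues**: they contribute 0 at their
  position (skipped, not penalized); a fully padded query scores 0.

## BLOSUM62 nearest neighbours (CBS)

Peptide similarity is the positionwise sum of substitution scores over
the 15 columns, using the bundled NCBI BLOSUM62 (alternative matrices in
NCBI text format can be loaded). A window with fewer than 7 real
residues on either side is defined to have similarity 0 to everything —
truncated flanks carry too little signal for this scorer. The
neighbourhood size is k = max(1, round(0.075·|corpus|)) with half-up
rounding (7.5% is the published default; the tested grid 1–7.5% is not
re-explored here). Ties at the k-th neighbour are broken
lexicographically by (peptide, kinase id) — deterministic rather than
random, so repeated runs agree. CBSScore(kᵢ) is the fraction of the k
neighbours labelled kᵢ.

# Combination

Raw scores are min–max normalized **per site across its candidate
kinases** (the sources say only "normalized"; min–max is parameter-free,
bounded, order-preserving and shift-invariant, matching an additive
combination; whether the original normalized per site or globally is
unstated — per-site is our choice and is documented in the output).
Constant score vectors map to all zeros. Then

* SequenceScore = normPWM + normCBS ∈ [0, 2]
* OverallScore = normKSP + SequenceScore ∈ [0, 3]

The network typically scores many more kinases than have sequence models
(370 vs 113 in the original data). OverallScore is restricted to the
intersection of the two candidate sets by default; `candidates =
"union"` scores everything, treating missing components as 0. A
substrate absent from the network yields a sequence-only ranking with a
provenance flag instead of an error.

# Evaluation protocol

* **k-fold CV** (default 10): pairs are shuffled into near-equal folds
  by a seeded permutation; all models are rebuilt from each training
  fold only; fold accuracy is the fraction of held-out sites whose true
  kinase is in the top k (default 10) of the requested ranking.
* **Per-kinase splits**: a kinase's sites are split 7:3
  (test = floor(0.3·n); the rounding is our choice, unstated in the
  sources), and the balanced 1:1 negative test set is drawn half from
  other kinases' sites and half from non-phospho S/T/Y windows, topping
  up from the larger pool when one is short (the 50/50 composition is
  our choice; it is recorded in the split metadata).
* **Metrics**: TPR/FPR/TNR/FNR/accuracy/precision/recall/F1 from
  confusion counts, with zero-denominator metrics reported as `NA`; the
  test suite reproduces both published per-kinase panels to all six
  printed decimals.
* **Curves**: ROC and PR by a descending threshold sweep with tied
  scores grouped; trapezoidal AUROC equals the concordant-pair fraction
  (ties counted ½), which the tests verify against an all-pairs oracle.

No multiple-testing correction is applied anywhere (raw metrics only).

# The synthetic world

`fixture_spec()` describes a planted-structure generator so every scorer
and the full protocol run without any external download:

* each substrate belongs to one true kinase; each kinase plants
  `sites_per_kinase` (default 30) sites on its own substrates;
* the PPI layer is a preferential-attachment background over all
  proteins (heavy-tailed degrees, like real interactomes) **plus**
  functional modules: each substrate interacts with ~2 other substrates
  of its own kinase. The modules matter: a PPI layer independent of
  kinase ownership would violate the path score's core assumption (true
  relations supported by neighbourhood interactions) and make the
  network channel uninformative by construction;
* each kinase draws a motif: per position, residue probabilities from a
  Dirichlet with concentration 20·b/`motif_sharpness`, centre fixed to
  the kinase's S/T/Y preference (~20% tyrosine kinases). Large
  sharpness gives near-deterministic consensus motifs, small values give
  background-like columns;
* negatives are background-composition 15-mers with S/T/Y centres.

Defaults — 20 kinases, 400 substrates, 40 bystanders, 30 sites/kinase —
were fixed a priori: 20 kinases make a top-10 cut a genuine cut, and
~1.5 sites per kinase–substrate pair mean a 70/30 held-out split deletes
a realistic share of direct edges, so the network channel is informative
but imperfect, as on real data. `motif_sharpness = 0.5` was then
calibrated (scan over 0.3/0.5/1 at fixed seed) so that neither single
channel saturates at the lenient top-10-of-20 cut — the regime the
end-to-end recovery property is about: at the defaults the combined
OverallScore ranking strictly beats both the network-only and the
sequence-only rankings, and all channels beat chance by ≥ 5×.

What a green end-to-end test does **not** establish: the generator
plants exactly one kinase per substrate, independent sites, no kinase
families with shared motifs, no promiscuous substrates, and uniform
database coverage — all untrue of real phosphoproteomes. Green means the
machinery recovers planted structure of this kind; it is not a
performance claim for real data, and the published real-data accuracies
are not reproducible without the original database snapshots.

# Numerical and degenerate-input choices

* Score comparisons in every ranking use exact floating-point ordering
  with lexicographic kinase-id tie-breaks; no epsilon bucketing.
* Dedup of site peptides is exact string identity (the original used
  CD-HIT clustering; at 15 residues and high identity the two nearly
  coincide, and exact identity is deterministic and dependency-free).
* Positions are 1-based inclusive everywhere; windows are closed
  intervals [pos−7, pos+7].
* Empty inputs are hard errors; malformed rows are skipped and counted;
  a query substrate missing from the network degrades to sequence-only
  with a flag.
* All randomness (splits, folds, generators) flows from single integer
  seeds, restored after use, so runs are reproducible and side-effect
  free.

# Known limitations

* Accession strings are opaque keys; no identifier mapping between
  databases is attempted.
* KS terms stop at path length 4 by design; β has exactly four
  components.
* The DFS-based simple mode is exponential in the worst case for very
  dense graphs; the literal mode (matrix powers) is the practical choice
  on dense networks.
* CBSScore covers only kinases present in the query's neighbourhood;
  kinases outside it get 0, which is indistinguishable from "never
  trained" in union mode.
* The CLI takes plain flags only (no YAML configuration mirror).
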