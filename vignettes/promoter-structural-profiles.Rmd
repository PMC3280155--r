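---
title: "Structural profiles of core promoters: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural profiles of core promoters: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promstruct)
```

# The model

A core-promoter window is the 251-nt sequence from 200 bp upstream to
50 bp downstream of a transcription start site (TSS), with position 0 the
TSS base itself. The working hypothesis is that promoters are recognized
partly through sequence-encoded *structure*: duplex stability, bending
stiffness, denaturation propensity and related biophysical quantities,
which concentrate their promoter-specific behaviour near the TATA region
(around −30) and the initiator at the TSS.

Each structural feature is a conversion schema: a total map from
dinucleotides (or trinucleotides, for bendability and nucleosome
positioning) to a measured quantity — kcal/mol for the energies, degrees
for the twists, dimensionless preferences otherwise. Sliding the map along
a window gives a raw profile (one value per k-mer, anchored at the k-mer's
first base), which is smoothed by a centered 3-nt moving average with
step 1 bp. Stacking the thirteen smoothed profiles and min–max-normalizing
each to [0, 1] yields a 13 × 251 = 3263-dimensional feature vector per
sequence; a Boolean promoter label completes the dataset.

Discriminative *positions* (dimensions) are then selected either by filter
criteria — information gain and χ² on supervised-discretized columns,
ReliefF, and CFS merit under genetic search — or by a genetic-algorithm
wrapper whose fitness is the cross-validated accuracy of the target
classifier (SVM or kNN). Selected subsets are evaluated with stratified
5-fold cross-validation: sensitivity Se = TP/(TP+FN), "specificity"
Sp = TP/(TP+FP) (deliberately TP-based — the promoter-prediction
literature's convention, elsewhere called precision), the harmonic
F-measure, and the rank-based ROC score. For genome-scale predictions, a
prediction within 500 bp (inclusive) of an annotated TSS counts as a true
positive under greedy nearest-first one-to-one matching.

# Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| window (up, down) | 200, 50 bp | the canonical core-promoter window; 251 positions |
| smoothing window / step | 3 nt / 1 bp | the profile-smoothing convention this pipeline follows |
| normalization | scale extrema | deterministic, train/test-identical (see below) |
| MDL discretization | Fayyad–Irani | supervised, parameter-free preprocessing for IG/χ² |
| ReliefF | k = 10 hits/misses, all instances, Manhattan diff | the common published defaults |
| GA | pop 20, 20 generations, crossover 0.6, mutation 0.033/bit, elitism 1 | classic data-mining-toolkit defaults; all overridable |
| SVM | RBF, C = 1, γ = 1/D | unstated upstream; standard neutral choice, logged in every report |
| kNN | k = 5, majority vote | unstated upstream; standard neutral choice |
| CV | 5 folds, stratified, pooled counts | micro-averaged confusion over held-out folds |
| TSS matching | tol = 500 bp, inclusive | `distance == 500` is a hit; 501 is not |

# The synthetic world

Real training data for this problem are TSS collections (experimentally
validated 5' ends) plus genome sequence; neither is bundled or downloaded.
The generator replaces them with a *stated world*:

* **Negatives** — first-order Markov chains. This is exactly the
  dinucleotide-frequency-preserving shuffle used to build randomized
  non-promoter sets: a 4 × 4 transition matrix fitted from sequence
  counts, sampled i.i.d. per sequence. One model is fitted globally (not
  per sequence); a Laplace pseudocount of 1 on the dinucleotide counts
  keeps all transitions reachable so negatives have full support. The
  default background is near-uniform with a depleted CpG transition, the
  one strong compositional bias of human DNA we emulate.
* **Positives** — the same background chains with core elements
  overwritten: a TATA-like box (`TATAAA`) with its start at −30, and an
  Inr-like element (`TCAGTT`) starting at −2 so it spans the TSS with the
  canonical pyrimidine–purine step at (−1, 0). `plant_prob` scales the
  per-element planting probability: 1 is the fully signalled world used
  for recovery tests, 0 is an exact null (labels independent of
  features).

What a green test establishes: planted AT-rich elements produce the
expected trough/peak shapes in stability-type averaged profiles at the
planted positions; selection criteria concentrate their top dimensions
around those positions; classifiers separate planted data (ROC > 0.9) and
stay at chance (ROC 0.5 ± 0.05) on the null. What it does **not**
establish: performance on real promoters, whose signals are weaker,
heterogeneous (TATA-less, CpG-island classes), position-variable, and
embedded in isochore-scale composition the simulator does not model.

A note on the bundled conversion tables: seven are transcribed published
scales; six (`*.synthetic.tsv`: DNA denaturation, A-philicity, B-DNA
twist, protein deformation, bendability, nucleosome position) are
deterministic, physically plausible stand-ins generated by
`data-raw/make_scales.R` — correct in units, sign and AT/GC ordering, but
not the published measurements. The nucleosome-positioning table is a
constant stand-in by design: re-deriving it from in vivo nucleosome maps
is out of scope. All code is scale-agnostic, so corrected TSVs can be
swapped in without touching the pipeline.

# Numerical and design choices

* **251 dimensions from 250/249 raw values.** A 251-nt window yields
  250 dinucleotide (249 trinucleotide) raw values, yet every feature
  block has 251 dimensions. We anchor raw value *i* at its k-mer's first
  base and replicate the terminal raw value `k − 1` times on the right
  before smoothing, preserving TSS-anchored coordinates and the stated
  13 × 251 dimensionality. This is one consistent reading of an
  under-specified convention, fixed here once.
* **Smoothing edges.** End-replication padding of (window−1)/2 values per
  side, so smoothing preserves length. Profiles are smoothed
  *per sequence*, then averaged (whether averaging precedes smoothing is
  unstated upstream; per-sequence smoothing makes single-sequence and
  averaged profiles consistent).
* **Ambiguous bases.** A k-mer containing a non-ACGT character takes the
  scale's mean value; sequences with more than 10% ambiguous bases are
  rejected — near-complete windows survive, junk does not.
* **Normalization bounds** come from each scale's theoretical extrema,
  not the observed data: construction is deterministic, idempotent, and
  identical for train and test. (Per-dataset normalization is the main
  alternative reading; it couples the matrix to the sample.)
* **Tie-breaking.** `top_k` breaks score ties by lower dimension index;
  ratios and subsets are reproducible.
* **CFS/wrapper subset sizes are emergent** — whatever the genetic search
  returns — rather than forced to a requested size.
* **Wrapper evaluation.** GA fitness is inner-CV *accuracy*; the reported
  metrics come from an outer cross-validation on a different fold split,
  since the maximized fitness itself is optimistically biased (winner's
  curse over evaluated subsets).
* **Classifier backends.** The environment this package targets ships no
  SVM or kNN implementation, so both are implemented here: the SVM is a
  least-squares SVM (kernel ridge on ±1 targets with bias; RBF kernel,
  C = 1, γ = 1/D) — deterministic, exact at these sample sizes, and
  interchangeable with a soft-margin SVM for ranking purposes — and kNN
  is plain k = 5 majority vote with the vote fraction as score.
* **Markov pseudocount.** Default 1 (full support for generated
  negatives); maximum-likelihood hand examples use `pseudocount = 0`
  explicitly.
* **Local RNG.** Every seeded routine saves and restores the caller's RNG
  stream, so fixing a routine's seed never silently couples later
  user-level randomness.
* **F-measure consistency checks.** Published Se/Sp/F triples are
  checked as |F(Se, Sp) − F_printed| < 0.001 — one unit in the last
  printed digit — because the printed Se/Sp are themselves rounded. One
  published row (SVM without selection: 0.720/0.733/0.731) is internally
  inconsistent with its own Se/Sp (formula gives 0.726) and its check is
  deliberately left failing as documentation of the defect.

# Known limitations

* The simulator plants fixed-position consensus motifs; it does not
  emulate CpG islands, positional jitter, TATA-less promoter classes or
  higher-order chromatin signals, so absolute performance numbers on it
  say nothing about real genomes.
* ReliefF materializes the full sample distance matrix (O(n²) memory):
  fine for thousands of samples, not for genome-scale sets.
* The six synthetic stand-in scales reproduce the *shape* physics
  (AT-rich instability) but not published values; analyses whose
  conclusions hinge on a specific scale's magnitudes should replace the
  stand-ins with the measured tables.
* MDL discretization can reject all cuts at small n, collapsing
  dimensions to one bin and zeroing IG/χ² scores — conservative rather
  than anti-conservative.

# Minimal end-to-end run

```r
sim <- simulate_dataset(n_per_class = 100, plant_prob = 1, seed = 7)
fm <- build_matrix(sim$set, default_scales())
disc <- discretize_mdl(fm$X, fm$y)
sel <- top_k(ig_scores(disc$Xd, fm$y), sizes = c(100, 200))
cross_validate(fm, subset = sel[["200"]], classifier = "svm",
               folds = 5, seed = 1)
feature_ratio(sel[["200"]], fm)
```
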