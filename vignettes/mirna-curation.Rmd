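---
title: "Curating insect miRNA complements with Dicer-1 knockdown support"
author: "mirCurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating insect miRNA complements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirCurate)
```

## The problem

Upstream miRNA predictors (miRDeep-family tools) emit thousands of
candidate hairpin loci per genome, most of them false positives.
This package implements the downstream decision layer that turns such
a candidate list plus small RNA-seq evidence into a curated miRNA
complement, exploiting a biological lever: mature miRNAs are products
of Dicer-1, so depleting Dicer-1 by RNAi must reduce their read counts,
while Dicer-independent RNA fragments stay flat.

A candidate is accepted as a *bona fide* novel miRNA only if it passes
all of:

1. **c1 — both arms expressed.** Reads on mature *and* star arm
   (Drosha/Dicer processing releases a duplex, so a real locus leaves
   reads on both sides).
2. **c2 — Dicer-1 response.** Mature-arm
   `log2FC = log2(mean depleted RPM + p) - log2(mean control RPM + p)`
   strictly below −0.5.
3. **c3 — 5′ homogeneity.** Mature reads share their 5′ end (the seed
   would otherwise be scrambled); the fraction of reads at the modal
   5′ offset must reach a threshold (default 0.66 — the published rule
   is qualitative, so the value is exposed as configuration, not
   asserted as anyone's measurement).
4. **c4 — hairpin shape.** A single-stem hairpin: exactly one terminal
   loop, with a sane loop length.
5. **c5 — folding energy** strictly below −22 kcal/mol.
6. **c6 — duplex pairing.** More than 16 (≥ 17) nucleotides paired
   between mature and star.
7. **c7 — processing signature.** A 2-nt 3′ overhang on each arm of
   the duplex.

Two further gates are not numbered criteria: a support filter (≥ 1
read on both arms in *every* control library) and an
assembly-artifact check (identical precursor plus identical ±50 nt
context at two loci = one mis-assembled copy; the lowest-coordinate
locus is kept). Candidates homologous to a known mature (an ungapped
alignment of ≥ 19 columns with ≤ 1 mismatch) are *conserved* and are
validated by homology rather than by c2–c7.

Accepted genes are grouped into families by exact seed identity.
The seed is the hexamer at mature positions 2–7: the published
family-defining seeds are six-mers, so 2–7 is the default and 2–8 is
available by configuration (both give the same grouping of the
13-gene worked example shipped as `bgeNovelMatures()`).

## Folding model

The internal folding backend computes the **maximum-pairing**
pseudoknot-free structure (minimum hairpin loop 3, Watson–Crick + GU).
Among count-optimal structures it selects the one with the lowest
nearest-neighbour stack energy; this tie-break is what keeps designed
or biological helices intact instead of scattering isolated pairs.
The selected structure is scored as

* sum of stack free energies over adjacent pairs (an embedded
  Turner-style 6×6 table over AU/UA/GC/CG/GU/UG), plus
* +0.3 kcal/mol per unpaired base enclosed by at least one pair
  (exterior unstructured bases are free, so a fully unpaired sequence
  scores 0).

This model is deliberately simple and is **not** mfold-equivalent; it
is labelled as such, and `foldHairpin(..., backend = "external")`
delegates to ViennaRNA's `RNAfold` (raising an explicit error when the
binary is absent — never a silent fallback) for users who want a
thermodynamically serious energy. All criteria thresholds shipped as
defaults are calibrated against the internal model's scale.

One caveat is worth recording: the invariant "adding a closing
complementary pair never raises the energy" holds for stem-loops
(the new pair stacks onto the existing outer helix) but *not* for
arbitrary sequences under this model — closing a pair around an
unstructured stretch converts free exterior bases into penalised loop
bases. The test suite therefore checks the monotone-stacking property
on stem-loops, which is the domain where it is meaningful.

## What the synthetic generator emulates

`plantMirnaLoci()` builds a toy genome with planted hairpins:

* true loci: a perfectly complementary stem (pair *i* ↔ *L*−1−*i*),
  arm length 20–25 nt centred on 22, loop 10–20 nt (mode 14–15) —
  echoing the observed mature-length and loop-length distributions —
  with the canonical 2-nt 3′ overhang geometry;
* decoys, each violating exactly one criterion:
  `no_star_reads` (star arm silent → c1), `dicer_independent`
  (full depth in depleted libraries → c2), `bad_fold` (two
  side-branch hairpins → c4), `low_pairing` (a symmetric internal
  loop leaving exactly 16 duplex pairs → c6), `no_overhang`
  (blunt-ended duplex → c7).

Deliberately unpaired letters (loops, internal-loop mismatches) are
drawn from {A, C}, a mutually non-pairing alphabet, so the designed
structure is the fold's optimum; every drawn hairpin is nevertheless
folded and verified against its expected criterion pattern before
acceptance, making the construction valid for any seed.

`simulateReadLibraries()` emulates the four-library knockdown design
(two control, two Dicer-1-depleted): mature arms draw ~`depth` reads
per control library (star arms 35% of that), Dicer-dependent loci are
scaled by the knockdown factor in depleted libraries, 5′ ends wobble
by ±1 nt with a 0.8 modal fraction, and read lengths vary by ±1 nt.
A Dicer-independent background dominates each library (densely tiled
windows — the negative-control material: several regions < 500 nt at
≥ 10× in every control — plus a scattered background at least 50 nt
away from planted loci). Background dominance matters: since RPM
normalises by total mapped reads and miRNA reads shrink under
depletion, a miRNA-heavy library would push negative-control log2FC
visibly positive; with miRNAs a ~10% minority the residual bias is
small, mirroring the slightly negative-to-near-zero medians seen in
real knockdown libraries.

Features of real data deliberately *not* emulated: sequencing errors,
adapter remnants, multi-mapping repeat families, minus-strand loci
(the generator plants `+`-strand loci; strand handling itself is
exercised through the GFF3/genome readers), expression heterogeneity
across tissues, and Dicer-independent *bona fide* miRNAs (mirtrons).
Passing the recovery test therefore shows the decision logic is
correct under the stated model, not that the thresholds are optimal
for any particular real library.

## Other numerical and design choices

* **Pseudocount 0.25 RPM** in the fold change: zero depleted counts
  would otherwise give −∞; small, symmetric, standard practice.
* **Replicates are averaged on the RPM scale** before the ratio; the
  source analyses do not state a per-replicate pairing, and pooled
  means are symmetric with the RPM normalisation.
* **Arm assignment tolerance 2 nt** at the 5′ end (isomiR wobble),
  consistent with the 5′-homogeneity emphasis of criterion 3; for
  co-mature duplexes (arm ratio < 2) the more abundant arm carries
  the c2/c3 tests.
* **Cluster `max_gap` 20 kb**: large enough to keep the known
  Mir-71/Mir-2 cluster with its > 12 kb internal gap intact, small
  enough not to chain across typical intergenic distances; the
  clustering rule is not stated in the source analyses, so the gap is
  configurable. Chaining is single-linkage, strand-agnostic, and
  singletons are not emitted as clusters.
* **Dollo conventions**: each family is gained once, on the edge
  subtending the MRCA of its carriers ("root" when that is the root
  node); root-constrained families (ancient complements whose origin
  predates the tree) contribute losses only. Losses are the stems of
  maximal all-absent subtrees inside the gain clade, which is the
  unique minimum given a fixed single gain. Genomic presence without
  expression counts as presence.
* **Mock miRNAs**: both the 20-nt and the 22-nt variants appear in
  the source material (main text vs figure caption); the generator
  takes `length` explicitly and the package asserts neither as the
  "true" setting. Mock draws must not share a seed with any excluded
  catalogue sequence.
* **Negative-control monotonicity**: lowering `min_cov` grows the
  maximal ≥-coverage runs, so a previously selected region is always
  *contained* in a new run — but the grown run may now exceed
  `max_len` and drop out. The monotonicity test therefore separates
  the two knobs (length filter inert when varying `min_cov`).
* **Target predictor**: one internal algorithm (perfect Watson–Crick
  seed match at positions 2–7, ungapped WC/GU extension scored with
  the same stack table, cutoff −12 kcal/mol). The published
  three-algorithm trio is supported as pre-computed pair tables
  ingested with the same −12 cutoff and intersected; re-implementing
  RNAhybrid/miRanda/RNA22 is out of scope, the intersection logic and
  the mock baseline are the analysis this package owns.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
so the whole suite completes in about a minute: 50 kb toy genomes,
10 true + 10 decoy loci, depth 200 reads per locus per control
library, 20 seeded simulation replicates for the negative-control
baseline, 200 random sequences (≤ 30 nt) against the brute-force
folding oracle, and all 127 non-empty presence patterns on the
seven-leaf tree against the exhaustive Dollo oracle.

## Worked example

```{r example, eval = FALSE}
library(mirCurate)

run <- runSyntheticPipeline(n_true = 10, n_decoy = 10,
                            genome_length = 50000,
                            knockdown_factor = 0.25,
                            depth_per_locus = 200, rng_seed = 1)
table(run$verdicts$status, run$truth@labels)
run$decoy_flags                     # which criterion each decoy failed
median(run$negctrl_log2fc)          # baseline, near 0

## the published 13-gene worked example
fams <- groupFamilies(bgeNovelMatures())
table(fams$family)

## gains and losses at the origin of complete metamorphosis
tree <- insectSpeciesTree()
pats <- endopterygotePresencePatterns()
m <- buildPresenceMatrix(lapply(setNames(tree$tip.label,
                                         tree$tip.label),
  function(sp) names(pats)[vapply(pats, function(p) sp %in% p, TRUE)]))
dolloGainLoss(m, tree)
```

## Known limitations

* The internal energy model is a teaching-grade nearest-neighbour
  approximation; absolute energies are comparable only within this
  package (the −22 kcal/mol gate was checked to hold for its own
  synthetic constructs, with `RNAfold` available as the fidelity
  backend).
* Read assignment is exact-match substring counting against the
  precursor — appropriate for collapsed, adapter-trimmed desk-scale
  data, not a replacement for a genome aligner on real libraries.
* `detectAssemblyArtifacts()` compares loci pairwise within identical
  precursor groups; for genome-scale candidate lists a hashed grouping
  would be needed.
* Reciprocal antisense loci and cross-species census bookkeeping
  (distinct loci expressing one mature) are conventions of the
  reporting layer, not enforced by the data model.
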