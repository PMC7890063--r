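---
title: "Methods: active-site profiling and kinetic characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active-site profiling and kinetic characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketprofile)
```

`pocketprofile` predicts enzyme function from the residues lining a
template-defined binding pocket, classifies candidates with similarity
networks and neighbor-joining trees, and characterizes enzyme kinetics
from pyrophosphate-release assays. This vignette documents the model
conventions, default parameters, numerical choices, and what the
synthetic-data generators do and do not emulate.

## Pocket extraction

A template is a protein structure with a bound ligand (substrate or
substrate analog; for class I terpene synthases typically a prenyl
diphosphate, its fluorinated analog, or the pyrophosphate/carbocation-mimic
pair). The **active site** is the set of polymer residues whose minimum
heavy-atom distance to any ligand heavy atom is at most the cutoff.

Conventions, chosen where the underlying rule admits variants:

* **Distance rule.** Minimum over heavy-atom pairs, boundary inclusive
  (`d <= cutoff`). Hydrogens (and deuteriums) are ignored, as crystal
  structures usually lack them. Default cutoff 6.0 Å — the radius at
  which class I TPS templates yield pockets of roughly 21–22 residues per
  template, large enough to cover both the metal-binding motifs and the
  hydrophobic tail region.
* **Ligand selection.** By default every hetero group except waters
  (HOH/WAT/DOD) and monatomic ions (NA, CL, K, ZN, CA, and the catalytic
  MG/MN). The magnesium ions are genuine cofactors, so they can be
  whitelisted with `include = "MG"`; the default treats "the substrate"
  as the organic ligand(s). When several organic groups are present
  (e.g. a pyrophosphate plus a cation mimic) the default union of both
  maximizes pocket coverage. Groups are reported ranked by heavy-atom
  count.
* **Alternate locations.** The highest-occupancy conformer wins; ties go
  to the first alt-loc label alphabetically. HETATM records of standard
  residues (selenomethionine MSE) are folded into the polymer. Unknown
  residue codes become `X` with a warning.
* **Chains.** Pockets are restricted to the chain contributing the most
  pocket residues unless `span_chains = TRUE`; crystal templates are
  commonly homodimers whose second chain only brushes the ligand.
* **Indexing.** All sequence positions in the R API are 1-based and
  inclusive, matching R conventions. Author residue numbering and
  insertion codes are preserved for reporting.

Parsing is delegated to `bio3d::read.pdb` (first MODEL only); the module
surface (`parse_structure`, `select_ligands`, `extract_pocket`,
`pocket_environment`) is independent of that backend.

## Cross-template union and profile projection

With two templates, the second template's pocket positions are mapped
onto the first through their global pairwise alignment. Positions landing
on a position already in the first pocket are merged (both sources
recorded); positions landing elsewhere on template 1 are added in
template-1 coordinates; positions aligned to a gap in template 1 are
appended anchored on their own template. The ordering is anchored on the
first-listed template. Templates aligning below 10% identity trigger a
warning — the union is still computed but residue correspondence through
a sequence alignment that weak is unreliable.

A candidate's **active-site profile** is the string of its residues
aligned to the union positions, `-` where the candidate has a gap.
**Active-site identity** between two profiles is
`100 x identical / comparable`, where comparable positions are those with
residues in both profiles. Gaps therefore reduce coverage, not identity;
the fixed-denominator percentage (gaps count as mismatches) is reported
alongside. Reported percentages are additionally rounded half-up to
integers, matching the "95% (36/38)" reporting style.

## Alignment and identity conventions

Global (Needleman–Wunsch) alignment with affine gaps via
`Biostrings::pairwiseAlignment`; BLOSUM62, gap open −10, gap extend −1 (a
gap of length L costs 10 + L). The ambiguity code `X` is rescored to 0
against everything so unknown residues are identity-neutral. Percent
identity defaults to the gap-excluded aligned-pair denominator (the
convention of Clustal-style reports); `alignment_length` and
`shorter_seq` denominators are exposed because published identity figures
rarely state their convention — reproducing a printed identity to better
than a couple of percentage points requires knowing the original
aligner's exact denominator, which is why the real-data identity checks
carry a ±2-point contract rather than an exact one.

## Motif filtering and function calls

Class I terpene synthases require two metal-binding elements: the
aspartate-rich motif `D(D/E)XXD` and the NSE triad
`(N/D)Dxx(S/T)xxxE`. `scan_motifs` reports every start position
(overlaps allowed); a sequence is *complete* with at least one hit of
each. `predict_function` labels a query by its highest
active-site-identity reference only when that identity reaches the
threshold (default 90%) **and** the motif set is complete; everything
else is `unassigned` with the reason recorded. The full-sequence
identity to the nearest reference is reported with a >50% "high
similarity" flag, but does not gate the call — conserved pockets, not
overall similarity, carry the functional signal. Ties report all tied
references.

## Networks and trees

* **SSN.** Nodes are enzymes, an undirected edge joins two nodes iff
  their alignment score is at or above the threshold; isolated nodes are
  retained. The widely used EFI-EST "alignment score of 16" is a
  −log10-E-value-like quantity from BLAST statistics; this package
  exposes a raw pairwise-score threshold instead of emulating BLAST
  statistics. The two are monotonically related for fixed-length
  comparisons but not numerically interchangeable — when no external
  threshold is given, `score_gap_threshold` places the cutoff in the
  widest gap of the sorted off-diagonal scores, the elbow a practitioner
  finds by eye. Output: GraphML and edge-list TSV (Cytoscape-ready).
* **Neighbor joining.** Canonical Saitou–Nei agglomeration via
  `ape::nj`, on `1 − identity_fraction` distances by default. Negative
  branch-length estimates (possible on non-additive matrices) are
  clamped to zero and flagged. On exactly additive matrices the planted
  tree is recovered exactly (verified on random trees up to 12 taxa).
  The scientific contract for published trees is clade membership, not
  branch lengths: pairwise-distance NJ is a reproducible stand-in for a
  progressive-multiple-alignment tree, and only cluster/clade structure
  is asserted in tests.

## Kinetics

The assay measures pyrophosphate release over time. The model chain is:

1. **Standard curve.** Piecewise-linear interpolation of signal to
   concentration over the kit's calibrated range (0–60 µM by default).
   Signals outside the calibrated signal range raise an error — no
   silent extrapolation.
2. **Initial rate.** Least-squares slope over the longest prefix of
   timepoints with R² ≥ 0.95 (minimum 3 points). The published
   procedure says only "initial rate"; the longest-linear-prefix rule is
   this package's concrete realization of it. Negative slopes are floored
   at zero with a warning; an all-zero series has rate 0.
3. **Michaelis–Menten fit.** `v = vmax*S/(Km+S)` by Levenberg–Marquardt
   nonlinear least squares (`minpack.lm::nlsLM`), initialized at
   `vmax0 = max(v)`, `Km0 = median(S)`, parameter tolerance 1e−10.
   `kcat = vmax/E0`, efficiency `kcat/Km`. Standard errors come from the
   Gauss–Newton covariance approximation; the efficiency SE uses the
   delta method. A Km collapsing to zero is flagged as suspect.
4. **Efficiency table.** Efficiencies are computed at full precision and
   displayed rounded half-up to one decimal; fold ratios between enzymes
   are computed from the *unrounded* efficiencies and displayed as
   integers. This ordering matters: a 21-fold advantage computed from
   full-precision values becomes 16-fold if recomputed from the rounded
   table entries. One published efficiency (0.05-level) is printed at
   two decimals in its source; the display here uses a uniform
   one-decimal rule and keeps full precision in the `efficiency` column.
   One published fold ("3-fold") computes to 2.7 before display
   rounding — a rounding-convention edge reported at both precisions.

An optional enzyme-purity correction was considered and deliberately not
applied by default: published kcat values do not state whether rates were
purity-corrected, and defaulting to no correction keeps the pipeline
faithful to the reported numbers (purity is carried as metadata only).

## Synthetic data: what it emulates, and what it does not

* `make_toy_structure` builds a linear chain of single-heavy-atom
  residues at 3.8 Å spacing with ligand atoms placed at height
  `sqrt(cutoff² − spacing²/2)` above each planted position — within the
  cutoff of exactly that residue, outside it for all others. This makes
  the planted pocket the provable ground truth for the distance rule
  (construction is infeasible, and errors, when `cutoff² ≤ spacing²/2`).
  It is deliberately *not* a realistic fold: no side chains, no chain
  curvature, no crystallographic noise. Passing the pocket oracle on
  these structures validates the distance computation, not biological
  pocket realism.
* `make_homolog_family` mutates non-pocket positions at a higher
  per-position probability than pocket positions (defaults: 350-residue
  protein, a 38-position active site — the size of the two-template
  union in the motivating study —, six homologs, background mutation
  0.35 vs pocket 0.02). This reproduces the statistical signal the
  workflow exploits (active-site identity > full-sequence identity) but
  not indels, domain architecture, or phylogenetic correlation between
  homologs (each homolog is an independent draw from the reference).
* `simulate_assay` generates linear standard curves and time courses
  with initial slope `vmax*S/(Km+S)` and multiplicative Gaussian noise
  per observation. Defaults mirror the motivating assay: substrate
  levels {6.5, 10, 15, 20, 30, 40} µM, standards 0–60 µM, E₀ = 0.25 µM,
  Km = 3.8 µM, kcat = 6/min (vmax = 1.5 µM/min), 0–10 min sampling. The
  time courses are linear by construction — substrate depletion and
  product inhibition are not modeled — so the initial-rate window rule
  is exercised separately on constructed saturating series.

Randomness follows R convention: generators draw from the session RNG,
so `set.seed()` before the call makes any fixture reproducible;
`make_toy_structure` is fully deterministic.

## Problem sizes and test design

The property suites run at sizes chosen to finish a full check in about a
minute while still exercising every code path: alignment oracle pairs up
to length 30; 100 random toy structures for the pocket oracle; 50 planted
additive trees up to 12 taxa; 1,000 random sequences for the motif
oracle; 200 replicate assays at 5% noise for Km recovery. Under those
conditions the median relative Km error is ~9% — dominated not by the 5%
signal noise (which the 11-point initial-rate regression attenuates) but
by the design itself: the true Km (3.8 µM) lies below the smallest
assayed substrate concentration (6.5 µM), so the curvature that pins Km
is only partially observed. That is a property of the emulated assay
design, faithfully reproduced rather than optimized away.

## Known limitations

* Printed identity percentages from other tools can differ by a point or
  two from `percent_identity` because aligner, matrix, and denominator
  conventions differ; all three denominators are exposed.
* The union template orders gap-anchored (template-2-only) positions
  after template-1 positions; without the original supplementary
  active-site tables, column ordering against published profiles is not
  pinned.
* The SSN threshold is a raw alignment score, not an E-value-derived
  score; thresholds from EFI-EST cannot be transplanted numerically.
* Pocket correspondence is sequence-alignment-based; structure
  superposition (which can rescue correspondence below ~20% identity) is
  out of scope.
* NMR multi-model averaging, mmCIF input, and hydrogen placement are not
  supported; the first MODEL of a PDB file is used.
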