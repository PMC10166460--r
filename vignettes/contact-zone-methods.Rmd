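---
title: "Microhomology, contact zones, and the mtDNA deletion spectrum: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microhomology, contact zones, and the mtDNA deletion spectrum: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the package's tests demonstrate. It is the
place where design decisions that were genuinely open are argued.

## The scientific model

Large mtDNA deletions arise predominantly in the major arc (5781–16,569 bp
on the rCRS), the segment whose parental heavy strand stays single-stranded
for long periods during asynchronous replication. The package models the
probability that a given pair of 100-bp windows `(i, j)` of the major arc
harbours a deletion (5′ breakpoint in window i, 3′ breakpoint in window j)
as a logistic function of two predictors:

* **MS**, the microhomology similarity: the global alignment score between
  the two windows' sequences, z-standardized across cells. Higher local
  similarity means more substrate for replication slippage.
* **CZ**, the contact-zone indicator: 1 when window i's center lies in
  6–9 kb and window j's in 13–16 kb — the region pair hypothesised to be
  juxtaposed when the single-stranded arc folds back on itself.

so `logit p(i,j) = β0 + β_MS · MS + β_CZ · CZ`. A data-driven variant
replaces CZ by the standardized Euclidean distance (in bp, on the
window-center plane) from a candidate contact point `(i0, j0)`; fitting one
such model per candidate cell and minimising AIC over all 4005 candidates
locates the best-supported contact point without assuming the zone
boundaries.

Supporting analyses ask whether the deletion spectrum is compatible with
these forces: deletion centers should be over-clustered relative to uniform
placement (randomization test), breakpoints should form density clusters,
repeats that are actually used ("realized") should sit disproportionately
inside the contact zone and closer to it than unused copies of the same
motif, and window pairs that hybridize strongly in vitro-style
thermodynamic calculations should carry more inverted-repeat density.

## Coordinates, grid, and cell table

Coordinates are 1-based inclusive throughout (the rCRS/MitoBreak
convention); BED-style conversion happens only at export. The window grid
defaults to 100 windows of 100 bp on [6001, 16000]. The major arc itself
spans 10,789 bp, so a 10-kb grid must choose an anchor; [6001, 16000] puts
window centers on the x·100 + 50.5 pattern so that the windows containing
7550 and 15,150 bp — the natural contact-point coordinates on this grid —
are exact window centers, and it yields C(100, 2) = 4950 unordered window
pairs. Grid start, window length and count are all arguments of
`build_grid()`.

Cells with `|i − j| ≤ 10` windows (≈ 1 kb) are excluded from every
regression: breakpoint pairs that close are dominated by small rearranged
molecules and by the trivial similarity of overlapping sequence. The band
width reproduces 4950 − 945 = 4005 included cells and is configurable. MS
is standardized over included cells only; a deletion contributes to exactly
one cell, and deletions falling in the excluded band are dropped from the
regression but kept everywhere else.

The intercept of the MS-only model should sit near `logit` of the realized
cell fraction; on synthetic tables this agreement is tested as an
invariant. Whether the binary CZ enters raw or z-scored is a reporting
choice (it changes the coefficient's scale, not the fit): `fit_ms_cz_model`
defaults to the raw indicator, whose coefficient reads directly as extra
log-odds inside the zone, and offers `standardize_cz = TRUE` for
magnitude-comparable coefficients.

## Alignment scoring

Microhomology uses Needleman–Wunsch scores with EMBOSS-Needle-style
parameters: match +5, mismatch −4 (the EDNAFULL values), gap open 10, gap
extend 0.5 with a length-L gap costing `open + L·ext`. End gaps are free by
default, matching Needle's `endweight = false` default; a flag penalises
them. With all four end gaps free on both sequences, the optimum equals the
best single aligned segment (a Smith–Waterman maximum under the same
scoring), a fact the test suite exploits by cross-checking against
Biostrings' local alignment as well as a purpose-written exhaustive DP. N
residues never count as matches. Scores of identical windows are exactly
`5 × window_length`, which pins the matrix diagonal.

## Repeat detection

Degraded repeats are defined ungapped: two arms of equal length ≥ 10 bp
whose aligned columns agree at ≥ 80%, arms non-overlapping, inverted arms
compared against the reverse complement. Rather than heuristic
seed-and-extend (whose exact-seed requirement can miss a 10-bp arm with two
mismatches), detection scans every (anti)diagonal of the self-comparison
exhaustively in C++, reporting each *maximal* window: one that cannot be
extended by a single position at either end without breaking the identity
threshold, the region bounds, the arm-overlap constraint, or the `max_arm`
cap (default 100 bp; mtDNA repeat arms are an order of magnitude shorter).
Identity thresholds are compared in exact integer arithmetic (scaled by
10^6) so boundary cases like 8/10 = 0.80 are never lost to floating-point
noise. Completeness makes the scanner testable against a brute-force
enumeration, and `min_identity = 1` reproduces the perfect-repeat scan
exactly.

Repeat density matrices count, for each window pair, the nucleotides lying
in an arm whose partner arm intersects the other window; a genome position
is counted once per cell even when several repeats cover it.

## Duplex energies

Fine-scale contact strength between windows is approximated by the minimum
free energy of an intermolecular DNA duplex under the unified
nearest-neighbor parameter set at 37 °C (packaged as an editable TSV:
16 stack increments, duplex initiation 1.96 kcal/mol, terminal A:T penalty
0.05 kcal/mol). Interior loops and bulges carry an affine penalty (open
4.0, extend 0.5 kcal/mol per skipped base, configurable); intramolecular
structure, multiloops, and salt/temperature corrections are out of scope.
Every downstream use of these energies is rank-based (Spearman correlation
with repeat density, identification of the most negative cells), so the
absolute kcal/mol calibration matters less than the ordering. Stronger
contact means more negative ΔG, so correlations with density use −ΔG;
duplexes that cannot reach a negative energy report 0. Whole-molecule
folds from external tools can be imported (dense matrix or base-pair list
with G·C = 3, A·T = 2 hydrogen bonds) and aggregated onto the grid by the
windows containing each partner nucleotide.

## Randomization test

The center-dispersion test keeps each deletion's length and redraws its
position uniformly in the arc (integer 5′ positions on the feasible
range), collecting the SD of midpoints per replicate; the one-sided
empirical p-value uses add-one smoothing so p = 0 is never reported. The
replicate stream is drawn against length-sorted deletions, making the
result invariant to row order under a fixed seed. The wording of the
underlying procedure admits a second reading (dispersion of replicate mean
midpoints); it is available behind `statistic = "sd_of_means"` but the
per-replicate midpoint SD is the default and the tested path.

## Breakpoint clustering

No density-based clustering package ships with this stack, so the package
carries a compact HDBSCAN implementation: core distances at
`min_samples`, mutual-reachability distances, a Prim MST, a condensed tree
at `min_cluster_size`, and excess-of-mass cluster selection. Two choices
deserve note. Selection ties favour the parent cluster, so a fully
degenerate point set (all points identical) condenses to a single cluster
rather than to noise. And points are processed in a canonical coordinate
order, making labels (up to renaming) independent of input order.
Defaults `min_cluster_size = 20`, `min_samples = 10` suit catalogues of
roughly a thousand deletions; a sweep helper reports how cluster counts
move across a parameter grid, since density parameters are the one place
where reasonable analysts differ.

## Realized repeats

A repeat is *realized* when a deletion's 5′ breakpoint lies within arm1 ±
tolerance and its 3′ breakpoint within arm2 ± tolerance. The default
tolerance of 5 bp absorbs the ambiguity of placing a breakpoint inside
repeated sequence; calls are monotone in the tolerance. Motif clusters
group repeats by exact motif string (an optional Hamming radius widens
families; "similar motifs" has no canonical definition, and exact identity
is the conservative default). A cluster is analysable when it has at least
three distinct arms and at least one realized pair; contrasts pair each
realized repeat with non-realized repeats of the same cluster that share
an arm, difference their 5′ starts, 3′ ends, and inter-arm gaps, and test
the shifts with the paired Wilcoxon test. Both the number of pairs and
the number of clusters are reported, since a cluster can contribute
several admissible pairs. Enrichment of realized repeats inside the
contact zone is tested with Fisher's exact test; the conditional-MLE odds
ratio is reported alongside the cross-product estimate, which falls back
to the Haldane–Anscombe correction (flagged) when a margin is zero.

## The synthetic-data generator

The generator exists so every stage can be verified against known ground
truth. Genomes are i.i.d. with configurable GC (0.44 by default, matching
human mtDNA); planted repeat pairs write a motif at two chosen positions
(reverse-complemented for inverted plants) with a chosen number of
mismatches. Deletion tables are drawn from the logistic model itself: each
included cell realizes a deletion with `p = plogis(β0 + β_MS·ms_z +
β_CZ·cz)` — defaults β = (−2.38, 0.33, 0.91), the regime of the fitted
two-predictor model — with breakpoints uniform within the realized cell's
windows. A distance-decay variant (`contact_point`, `beta_dist`, default
−1) replaces the zone indicator with proximity to a planted point and is
the ground truth for scan-recovery checks; the closure tests use a steep
decay (β_dist = −2 with β0 = −2.6, ≈ 700 deletions concentrated in a
few-hundred-bp hotspot) because the minimum-AIC argmin localises a planted
point only as precisely as the signal allows — at gentler decay the
argmin's sampling noise is ± 3 windows, which says nothing about
correctness, so the recovery check is run in the regime where ± 2-window
localisation is informative. What the generator does **not** emulate:
dinucleotide composition, mutational hotspots, length-dependent deletion
ascertainment, or inter-study duplication in real catalogues. Passing
tests therefore demonstrate correctness of the machinery and
recoverability of the model's parameters, not that real mtDNA obeys the
model.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic
data: a 16,569-bp genome, the default 100-window grid (4950 alignments,
4005 regression cells), 100–200 generator replicates for coefficient
recovery, 5–10 seeds of the full 4005-candidate scan, and 200–500 outer
replicates at 99 inner replicates for randomization-test calibration —
sizes chosen so the whole suite completes in minutes on one CPU while
keeping every binomial/KS check well-powered. Logistic fits use IRLS
(`glm.fit`) with tolerance 1e-8; quasi-perfect separation (|linear
predictor| > 30) is an error rather than a silent huge coefficient;
candidate scan fits that fail are recorded as missing and excluded from
the argmin. Standardization stores its mean/sd for exact inversion.

## Known limitations

* Repeats spanning the origin (wrapping through position 1/16,569) are not
  searched; the major arc does not wrap, so this only matters for
  whole-genome scans.
* The duplex model is intermolecular only; it cannot represent nested
  intramolecular structure of a full 10-kb strand. External fold import is
  the bridge.
* The breakpoint rotation ambiguity inside repeats is deliberately not
  normalised — coordinates are used as reported, and the realization
  tolerance absorbs small discrepancies.
* Real-catalogue idiosyncrasies (duplicate reports across studies,
  platform-specific breakpoint calling) are handled only by optional
  deduplication.
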