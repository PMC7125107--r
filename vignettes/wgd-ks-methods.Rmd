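---
title: "Methods: Ks-based detection, dating and placement of whole-genome duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Ks-based detection, dating and placement of whole-genome duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdplacer)
```

This vignette documents the statistical model behind each stage of
`wgdplacer`, the assumptions it makes, and the reasoning behind its
numerical choices. Every quantitative claim here is verified by the test
suite (`tests/testthat/`, in particular `test-acceptance.R`); the vignette
itself makes no empirical claims beyond those.

## 1. Ks estimation

`ng86_ks()` implements a counting estimator of synonymous (Ks) and
nonsynonymous (Ka) distances:

* **Site counting** (`count_sites()`): each codon position contributes the
  fraction of its single-nucleotide neighbours that are synonymous, with
  mutations into stop codons excluded from the denominator (not counted as
  nonsynonymous opportunities). A codon thus contributes `s + n = 3` sites.
  Pairwise site totals are the average of the two codons' counts.
* **Difference counting**: for codons differing at 2–3 positions, observed
  synonymous/nonsynonymous differences are averaged over all orderings of
  the single changes whose intermediates avoid stop codons. If every
  ordering passes through a stop, the codon pair is excluded (counted in
  `n_excluded`).
* **Multiple-hit correction**: the proportions `ps = Sd/S`, `pn = Nd/N` are
  corrected with the single-parameter formula
  `d = -(3/4) ln(1 - (4/3) p)`. Proportions at or above 3/4 are saturated:
  the corresponding distance is `NA` and a flag is set.

Assumptions: equal base frequencies and no transition/transversion bias in
the correction (the classical counting model), independence across codons,
and in-frame, gap-aligned input. The estimator is verified against an
independent brute-force enumeration oracle over exhaustive single-codon
panels and random 2–3-codon sequences, and for consistency on sequence
pairs evolved to a known Ks by `evolve_codon_pair()`.

## 2. Redundancy-corrected age distributions

A family of `n` paralogs yields `n(n-1)/2` pairwise Ks values but arose
through only `n - 1` duplication events; using raw pairs would let large
families swamp the distribution. `build_distribution()` therefore:

1. splits each family into subfamilies by complete-linkage clustering,
   cutting so that no within-subfamily Ks exceeds 5 (beyond that, Ks is
   saturated and distances are unreliable; missing/saturated entries are
   treated as exceeding the cutoff);
2. reconstructs each subfamily's duplication history by average-linkage
   (UPGMA) clustering, so every internal node's height is the mean Ks over
   its `m` cross-clade pairs;
3. emits all `m` pair values with weight `1/m`, so each duplication node
   contributes exactly total weight 1 and each subfamily of size `n`
   contributes `n - 1`.

Both clusterings are written in the package (rather than `hclust`) because
the partition must be deterministic under tied merge criteria: ties are
broken by the lexicographically smallest gene-id pair, making the output
invariant to member input order. Weight conservation is asserted to machine
precision over 1,000 random families in the acceptance suite.

The default analysis range `[0.05, 5]` excludes near-zero pairs (alleles,
assembly artifacts, tandem duplicates still under concerted evolution) and
saturated values; the upper bound coincides with the subfamily cutoff.

## 3. Density estimation and peak detection

The weighted samples are binned (width 0.01) and a smooth curve is fitted
to the **bin counts**, not the bin heights. The default smoother is an
adaptive penalized regression spline under a quasi-Poisson model with REML
smoothness selection (`mgcv::gam(counts ~ s(mids, bs = "ad"), family =
quasipoisson)`). Two properties motivated this choice over the more common
cubic smoothing spline with generalized cross-validation:

* Histogram counts are heteroscedastic (variance roughly proportional to
  the mean). A least-squares spline treats the near-empty tail bins as
  having the same noise scale as the peak region; GCV then under-smooths,
  and the tail sprouts dozens of spurious local maxima (observed directly:
  effective df ≈ 70 on ~500 bins for the two-WGD fixture). The
  quasi-Poisson likelihood models the count noise on the right scale.
* WGD peaks are locally sharp while the SSD background is smooth; an
  adaptive penalty lets smoothness vary along the axis instead of
  compromising globally.

The GCV smoothing spline remains available (`smoother = "spline"`): inside
a narrow window around a single peak its failure mode is irrelevant and it
is about fifty times faster, which is what the bootstrap needs (below).
Fitted curves are clipped at zero and normalized so the curve is invariant
to rescaling all weights by a constant.

`find_peaks()` uses a windowed local-maximum rule (half-width 3 grid steps
by default): a point is a peak when strictly higher than everything in the
left window and at least as high as everything in the right window, so a
flat-topped peak reports its leftmost point, and boundary points are never
peaks. The implementation is tested against a brute-force oracle on random
height vectors.

**Bootstrap CIs** (`bootstrap_peak_ci()`): the peak's window is bounded by
the nearest flanking local minima of the fitted curve (fallback: peak ±
0.2). In-window samples are resampled with probability proportional to
weight, 100 times by default; each replicate's mode is found by refitting
within the window with the fast spline smoother. The 95% CI is the
2.5/97.5 percentile of replicate modes. With fewer than 50 in-window
samples the CI is reported as undefined rather than pretending precision.
Coverage is verified at ≥88% over 200 simulated datasets (Monte-Carlo
tolerance around the nominal 95%).

## 4. Rate correction

Ortholog Ks distributions are summarized by their mode (`kde_mode()`:
Gaussian KDE, Silverman bandwidth, ~0.001 grid). For focal species A,
comparison B and outgroup O, the relative rate test decomposes the observed
A–B mode:

```
dA = (dAB + dOA - dOB) / 2,   dB = (dAB + dOB - dOA) / 2
```

so `dA + dB = dAB` exactly. `2*dA` is the A–B divergence re-expressed as if
both lineages evolved at A's rate, directly comparable with peaks in A's
paranome. A negative `dA`/`dB` (non-additive triplet, usually
mode-estimation noise) is clamped to zero and flagged. The outgroup must
have diverged **before** the A–B split; choosing an outgroup nested inside
the pair's clade biases `dA` upward by the shared path to the outgroup's
true branch point.

## 5. Ks trees and peak placement

`estimate_ks_branch_lengths()` solves for non-negative branch lengths such
that tip-to-tip path lengths match the pairwise divergence modes
(non-negative least squares). Tip-to-tip distances determine only the
*sum* of the two root-adjacent branches of a rooted binary tree; that sum
is one column in the design matrix and is split equally between the two
edges afterwards. Path residuals are unaffected by the split; an additive
input metric is reproduced exactly (residual < 1e-10, asserted).

`map_peak_to_branch()` walks `peak/2` from the tip toward the root —
duplicate copies are assumed to evolve at similar rates, so each
accumulates half the pairwise distance. A value exactly at a node boundary
is assigned rootward; a value beyond the tip-to-root depth sets
`beyond_root`. CI endpoints are mapped the same way, and `ci_spans_nodes`
records placement uncertainty across branches.

Placement from a species' own tip needs no rate correction: the tip's path
in the Ks tree is already in that lineage's scale. Correction matters when
transferring a peak observed in lineage X onto the focal tip's path:
`rescale_peak_to_focal(peak, d_focal, d_other)` multiplies by the ratio of
post-divergence per-lineage distances. The acceptance suite contains a
deterministic fixture where the uncorrected transfer lands on the wrong
branch and the corrected one on the right branch.

`classify_shared()` compares a WGD peak's CI against a corrected divergence
peak (`2 * d_focal`): entirely above → shared (the WGD predates the split),
entirely below → independent, otherwise unresolved.
`multi_lineage_synthesis()` merges same-branch placements with overlapping
CIs into single candidate events.

## 6. The synthetic generator

`simulation_config()` + `simulate_paranome()` / `simulate_ortholog_ks()`
define the generative model used throughout the tests:

* **Rates are per branch**: a tip's rate multiplier applies to its terminal
  branch; internal branches default to rate 1 and can be overridden via
  node labels. (Applying a tip's multiplier to its entire root path would
  make triplet distances non-additive whenever rates differ, breaking the
  relative rate test by construction — the bias grows with outgroup depth.)
* A WGD on a branch at age `t` produces pairs with Ks drawn from a normal
  centred at twice the rate-integrated path depth to `t`, truncated at
  zero; a configurable fraction is emitted as anchor pairs.
* SSD duplication ages are exponential (default mean 1.0 in Ks units);
  events are assembled into families (fixed, geometric or uniform size
  distributions) whose full pairwise tables are exactly consistent with the
  duplication history, so node weighting can be checked exactly.
* Ortholog Ks values are centred on the sum of the two lineages'
  rate-integrated depths since their divergence, plus truncated Gaussian
  noise; for sister species with terminal rates `r_a`, `r_b` and divergence
  time `T` the location is exactly `(r_a + r_b) T`.
* `evolve_codon_pair()` evolves third positions of four-fold degenerate
  codons under Jukes–Cantor to a target Ks, for end-to-end estimator tests.

All randomness flows from one integer seed through deterministic
substreams, so every dataset is exactly reproducible.

**Not modelled**: gene loss and fractionation, tandem arrays, codon-usage
or GC bias, rate variation within a branch, finite-sequence Ks noise in the
paranome generator (available separately via `evolve_codon_pair`), and
incomplete lineage sorting. Conclusions drawn from this generator are
about the correctness of the inference chain, not about any real genome.

## 7. Orchestration

`validate_config()` reads a YAML run configuration (defaults: cutoff 5, bin
width 0.01, 100 bootstrap replicates, range `[0.05, 5]`) and checks inputs
up front; `run_pipeline()` executes distribution → peaks → rate profile →
Ks tree → placement → classification → synthesis with per-stage status
logging (a failed stage skips its dependents explicitly), and
`write_result_bundle()` writes all tables. The `analysis/` scripts in the
source repository run the same chain as a narrated, numbered workflow.
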