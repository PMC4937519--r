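---
title: "Scoring structural models with crosslinking restraints: SASD and MNXL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring structural models with crosslinking restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlwalk)
```

## The problem

Amine-reactive crosslinkers such as BS3 and DSS covalently join two lysine
side chains (or a lysine and the protein N-terminus) that are close in the
folded protein. After digestion and mass spectrometry, the identified
residue pairs become distance restraints for model selection: a candidate
model inconsistent with many observed crosslinks is unlikely to be
near-native. Two subtleties make naive use of these restraints misleading:

1. **The linker travels over the surface.** The reactive groups must both be
   solvent accessible, and the linker cannot pass through protein mass. The
   straight-line (Euclidean) Cα–Cα distance therefore underestimates the
   span a crosslink needs; the appropriate measure is the *solvent
   accessible surface distance* (SASD), the shortest path between the two
   residues that stays in solvent.
2. **Absence of a path is information.** If an observed crosslink has *no*
   SASD on a model — an endpoint buried, or no connecting solvent channel —
   the model disagrees with the experiment even though no distance was ever
   measured. Euclidean treatments have no such concept.

`xlwalk` implements both the SASD computation and a scoring function, MNXL
(matched + non-accessible crosslink score), that exploits both kinds of
information, together with the standard comparison scores and the evaluation
machinery needed to benchmark them.

## SASD on a voxel grid

`build_grid()` places the structure on a cubic grid (default spacing `h = 1`
Å, the resolution at which surface detail and run time balance for typical
domains). Every voxel whose center lies within
`round_to_voxel(r_vdW(element) + 0.7)` of an atom's grid point is marked
solvent-excluded; 0.7 Å is half the van der Waals radius of a water molecule
(`water_probe_increment()`), and rounding is to the nearest multiple of `h`
with ties upward so borderline-exposed residues are not lost to grid blur.
The grid extends 4 voxels (or one voxel more than the largest sphere radius,
whichever is larger) beyond the atom bounding box on every face, so no
sphere is ever clipped.

**Self-blocking exclusions.** Atoms along which the crosslinker attaches
must not bury themselves. Excluded from the expansion are: the lysine
side-chain atoms CB, CG, CD, CE, NZ; the side chain *and* CA of each chain's
first residue (the N-terminus is probed at its CA, whose own sphere would
otherwise always cover the probe sphere — the same rounded radius — and no
N-terminus could ever be accessible); and the CA of a lysine whose side
chain is missing from the coordinates, for the same reason. Whether the
exclusion should begin at CB or CG is not settled; CB is used because the
entire side chain beyond the backbone is the attachment arm.

**Accessibility.** `find_accessible_residues()` centres a probe sphere of
radius `round_to_voxel(r_vdW(N) + 0.7)` on each lysine's NZ (falling back to
the CA when the side chain is absent) and on each chain N-terminus's CA. A
residue is solvent accessible when at least one voxel inside the sphere is
unoccupied; those free voxels are the start voxels of the path search.
Residues with neither NZ nor CA are reported unevaluable and treated as not
accessible.

**Search.** `compute_sasd()` reports, for every requested pair,

$$\mathrm{SASD}(i,j) \;=\; \min_{s_i,\,s_j}\;
  \lVert \mathrm{CA}_i - s_i\rVert \;+\; \mathrm{path}(s_i \to s_j)
  \;+\; \lVert s_j - \mathrm{CA}_j\rVert,$$

where the grid path is confined to solvent voxels. The default move set is
the 26-neighbourhood with Euclidean step costs ($h$, $h\sqrt2$, $h\sqrt3$),
explored with a priority-queue (Dijkstra) traversal implemented in C++.
Plain layer-counting breadth-first search is only equivalent to a geometric
shortest path on the 6-connected grid, where every step has equal cost; that
variant is available as `metric = "bfs6"` for strict emulation of
layer-by-layer searching, but the weighted 26-neighbour metric is the
default because it approximates Euclidean geodesics far better (overestimate
at most ~8 % in free space, versus up to 73 % for axis-only moves). One
multi-seeded search per source residue covers all its partners: each start
voxel is seeded with its CA connection as initial cost, so the searched
field already contains the inner minimum, and the search stops early once
every partner's start voxels are finalized (provably identical distances to
a full sweep). Pairs with a buried endpoint report
`nonaccessible_endpoint`; accessible pairs without a connecting solvent path
(or beyond `max_distance`, unlimited by default) report `no_path`.

Correctness is checked against an entirely independent oracle
(`grid_oracle()`): an explicit weighted graph over the free voxels solved
with igraph's shortest-path routines, exact on grids up to ~64³.

## MNXL

Given an experimental (or theoretical) crosslink set, each crosslink on a
model is classified (`classify_crosslinks()`):

| category            | condition                   | score                                 |
|---------------------|-----------------------------|---------------------------------------|
| satisfied           | SASD ≤ 33 Å                | normal density $N(d;\mu,\sigma)$       |
| violating           | SASD > 33 Å                | −0.1                                   |
| non-accessible      | no SASD on the model        | −0.1                                   |

Raw MNXL is the sum over the crosslink set (`score_mnxl()`, higher =
better); `normalize_ensemble()` min–max rescales an ensemble so the best
model scores 0 and the worst 1 (all-equal ensembles map to all zeros, and a
distance exactly at the cutoff falls on the non-penalized side). Crosslinkable
pairs *absent* from the experimental set are deliberately not penalized:
typical experiments recover well under a third of the theoretically possible
crosslinks, so absence of evidence is not evidence of absence.

Parameters and defaults:

* `cutoff = 33` Å — the maximum-bound beyond which a crosslink counts as
  violated. 22.4 Å is the physical maximum for an 11.4 Å linker with two
  extended lysine side chains (`max_crosslink_length()`); the larger working
  bound absorbs backbone flexibility, and 33 Å is where score–quality
  correlation peaks in cutoff scans (`cutoff_scan()` reproduces that
  experiment on any benchmark).
* `mu`, `sigma` — mean and **sample (n−1)** standard deviation of reference
  SASDs at or below the cutoff, via `fit_sasd_distribution()`. The intended
  reference is a curated database of experimentally observed crosslinks
  (XLdb-style); no fitted values are published for such a curated set, so the
  package requires either a user-supplied SASD table or explicit `mu`/`sigma`.
  The synthetic benchmarks fit the distribution from the reference
  structure's own theoretical SASDs.
* `penalty_violation`, `penalty_nonaccessible` — both −0.1 by default but
  separately configurable.
* `density` — the positive scoring term is the plain normal density (the
  natural reading of "scored by its probability distribution"); it is
  exposed as a pluggable function so a log-density or a renormalized form
  can be swapped in without touching the classification.

Comparison scores on the same classification: `score_nov()` (count of
violations; lower = better), `score_sovd()` (summed excess over the cutoff;
`sovd = 0` exactly when `nov = 0`), `score_nov_nonacc()` (violations plus
non-accessible crosslinks). SoVD is *not* combined with non-accessible
counts: Ångströms and counts have no principled common scale. Euclidean
distance modes (`euclidean_distances()`, `distance_mode =
"euclidean_surface"` / `"euclidean_all"`) reproduce the comparison between
surface-aware and naive Euclidean scoring; in `euclidean_all` mode the
non-accessible category is empty by construction. The Euclidean modes use the
same 33 Å cutoff by default so the distance metrics are compared like for
like.

## Evaluating a scoring function

* `calpha_rmsd()` — Cα-RMSD over shared (chain, residue) pairs after optimal
  rigid superposition (Kabsch, via bio3d); superposition is always applied
  since model ensembles need not share a frame.
* `pearson()` — product-moment correlation of the normalized score (0 =
  best) with RMSD; an ideal score gives +1. Zero-variance input is reported
  as `NA` with a warning rather than silently propagated.
* `precision_top_k()` — TP/(TP+FP) over the `k = 20` best-ranked models,
  TP meaning RMSD ≤ 4 Å. Integer-valued scores (NoV) produce large rank
  ties; when the k-th boundary falls inside a tie cluster (scores equal
  within 1e-9 after normalization) the remaining slots are drawn uniformly
  without replacement from the cluster and the precision averaged over
  `resamples = 1000` draws — converging to the hypergeometric expectation —
  while tie-free rankings are evaluated deterministically.
* `bootstrap_recovery()` — emulates partial crosslink recovery: for each
  percentage of the ladder (default 90…1 %), `n_boot = 1000` uniform subsets
  of size `round(pN/100)` (never below 1, so even 1 % of a small set tests
  something) are drawn, every model re-scored per subset, and mean
  correlation/precision reported. Per-crosslink MNXL contributions are
  precomputed per model, making a subset score a row sum — the curve over
  1000 × 11 subsets costs seconds. Fully reproducible from its seed.
* `cutoff_scan()` — re-scores the ensemble at each cutoff (20–80 Å by
  default; distances are computed once, only the classification changes),
  optionally refitting `mu`/`sigma` from a reference SASD vector at each
  cutoff, and tabulates correlation and precision.
* `make_theoretical_dataset()` — all lysine/N-terminus pairs with reference
  SASD strictly below the cutoff: a "100 % recovery" experiment. Bootstrap
  percentages are applied to this set after curation (post-filter, e.g.
  after removing inter-domain links).
* The "+2σ separation" of an ideal score's best model is reported by
  `evaluate_scores()` as a diagnostic flag, not enforced.

## Crosslink curation

`curate_crosslinks()` applies, in order and with per-rule removal counts so
audits are reproducible: residues absent from the structure; self-links;
endpoints that are neither lysine nor a chain N-terminus; duplicate
unordered pairs (canonicalized lexicographically by chain, then residue
number); and, when a domain table is supplied, pairs crossing a domain
boundary. Curation is idempotent and never adds records. Monolinks carry
accessibility rather than distance information and are accepted but ignored
by the scoring functions.

Structure input follows crystallographic conventions: altloc groups resolve
to the highest-occupancy location (ties to altloc "A"), hydrogens are
dropped by default (crystal structures mostly lack them), waters are always
dropped, and other het groups are excluded unless requested as obstacles.
The bundled van der Waals radii are a standard Bondi-style element table
(`vdw_table()`); unknown elements fall back to the carbon radius.

## The synthetic data generator

`make_fixture()` produces structures whose ground truth is known by
construction, so every claim above is testable offline:

* `free_pair` / `wall` / `buried` — controlled geometry for the search: a
  pair with a known Cα separation; the same pair separated by a finite
  carbon slab (2 Å lattice, contiguous at 1 Å voxels) forcing a detour with
  a computable lower bound; a lysine whose NZ sits inside a solid carbon
  shell dense enough that every probe voxel is occupied.
* `helix` — an ideal α-helix (1.5 Å rise, 100° twist) for I/O round trips.
* `perturbed_ensemble` — a reference "protein" of 12 lysines on a 12 Å
  sphere around a carbon core, plus models whose residues are displaced by
  seeded Gaussian noise with per-model σ evenly spaced from 0 to 15 Å. This
  stands in for comparative-model ensembles spanning ~0–30 Å Cα-RMSD
  (per-coordinate noise σ yields RMSD ≈ σ√3). Sizes were chosen as a
  realistic small domain: a dozen surface lysines and a few-nanometre
  diameter mirror the lower-middle range of published crosslink benchmarks.

What the generator does *not* emulate: real side-chain packing and rotamers,
correlated (domain-level) deformations, sequence-dependent surface
chemistry, and experimental noise in crosslink identification (false
positives). Passing tests on these fixtures therefore demonstrate the
correctness of the geometry, classification and statistics, and the
qualitative superiority of SASD/MNXL under controlled degradation — not the
quantitative benchmark values attainable only with real comparative-model
ensembles and experimentally curated crosslink sets.

## Numerical choices and degenerate inputs

* Atom → voxel mapping: nearest grid point, ties toward the lower index.
* Sphere radii: rounded to the nearest voxel multiple, ties upward.
* Equal-cost paths: broken deterministically by voxel index; the distance is
  unaffected, the traced path geometry may differ between metrics.
* Searches per source are independent (safe to parallelize) and early
  termination is exact; repeated runs are bit-identical.
* `fit_sasd_distribution()` refuses fewer than 2 usable values or zero
  variance; `normalize_ensemble()` maps an all-equal ensemble to zeros;
  `precision_top_k()` refuses ensembles smaller than `k`; empty crosslink
  sets score 0.
* All stochastic procedures take explicit seeds and restore the caller's RNG
  state.

## Problem sizes

The shipped tests and the acceptance script run, in a few minutes total: the
exhaustive-oracle comparison on twenty 20³ random grids; fixture geometry at
1 Å (and 0.5 Å for accessibility stability); the 50-model benchmark with its
18-crosslink theoretical set (~1 minute of SASD computation); bootstrap
curves at 200 sets per percentage with 50 tie-resamples inside; and
1000-resample tie-precision checks. Larger problems scale linearly in models
and in free-voxel count per search.

## Known limitations

* SASD quality is limited by the voxel resolution: measured distances carry
  an O(voxel) discretization slack (the invariant enforced in tests is
  `SASD ≥ Euclidean − 2h`) and the 26-neighbour metric overestimates true
  geodesics by up to ~8 %.
* Accessibility is binary (any free probe voxel); no per-atom solvent
  accessible surface areas are computed.
* The normal-density reward assumes the reference SASD distribution is
  adequately summarized by its first two moments below the cutoff.
* Flexibility is not modelled: all SASDs are computed on static coordinates,
  so genuinely flexible proteins can violate crosslinks even in their
  crystal structure.
* mmCIF input, spectra-level identification and crosslink-confidence
  weighting are out of scope.
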