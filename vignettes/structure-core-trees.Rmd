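---
title: "Common structural cores and structure-based distance trees"
author: "structcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common structural cores and structure-based distance trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structcore)
```

## Scope and model

`structcore` classifies sets of distantly related protein structures —
the motivating case being a protease clan whose families share a
conserved fold around the catalytic site while their sequences have
diverged to near-random identity. The pipeline has five stages:
curation, pairwise structural alignment, agglomerative core
identification, a core-restricted distance tree, and a simplified
jackknife. This vignette records the model behind each stage, the
tunable parameters with their defaults and rationale, the numerical
choices, and what the synthetic validation does and does not show.

## Curation

A structure enters the analysis as one chain's Cα trace
(`read_structure()`), ordered by author numbering with insertion codes
sorting after their base number. Alternate locations keep the
highest-occupancy conformer (ties: first encountered). Missing residues
are counted from SEQRES when present (declared minus modeled length),
else from author-numbering gaps — both signals occur in real files, and
gaps are the safer fallback.

`filter_dataset()` applies three thresholds, chosen for a clan of
double-β-barrel protease domains: at least 138 modeled residues (large
enough to span both barrels), at most 10 missing residues, and
resolution at most 4.0 Å. Structures with unknown resolution (NMR
models) pass, since the filter targets poorly determined
crystallographic models. Catalytic-site completeness is a judgment call
no automatic rule captures; the per-model report therefore names every
failed rule so a manual exclusion list can be layered on top.

Redundancy is removed by greedy incremental clustering
(`identity_cluster()`) in decreasing length order, joining a model to
the first representative sharing identity above the cap (default 70%).
Identity is the Smith–Waterman local-alignment definition: identical
aligned positions over aligned positions including gaps, under
BLOSUM62 with gap open 11 / extend 1. Note a property of this
definition worth knowing: because the alignment is local, even
unrelated sequences typically show 15–50% "identity" over some short
well-matching segment; thresholds are meaningful for near-duplicates,
not as an evolutionary distance.

## Pairwise alignment

Each residue carries five properties (`compute_properties()`): the
amino-acid letter; the pseudo-bond angle θ over Cα(i−1), Cα(i), Cα(i+1)
(degrees, [0, 180]); the pseudo-dihedral τ over Cα(i−1..i+2) (degrees,
(−180, 180]); the unit backbone direction Cα(i)→Cα(i+1); and the number
of Cα atoms within 10 Å excluding sequence neighbors ±2. Properties
undefined at chain termini are flagged and excluded from scoring — a
missing term's weight is renormalized over the defined terms, never
zero-filled.

`align_pair()` seeds with the gapless fragment pair (length 8) of
minimal superposition rmsd, found by exhaustive scan; if no fragment
pair superposes below 5 Å the structures are reported unalignable
(empty map, score 0). It then iterates: superpose on the current
equivalences (Kabsch), score all residue pairs as

  S(i,j) = w_aa·sim_aa + w_geo·sim_geo + w_dir·sim_dir + w_dist·(1 − d_ij/d_cut),

align globally with affine gaps, and accept the matched pairs. The
similarity terms all live in [0, 1]: `sim_aa` is BLOSUM62 rescaled so
that every self-substitution scores exactly 1 (each pair is scaled
against the larger self-score; a global rescale would make
`sim(Ala, Ala)` ≈ 0.5 and identical sequences look dissimilar);
`sim_geo = 1 − (|Δθ| + |Δτ|/2)/270°` with the circular τ difference;
`sim_dir = (1 + cos α)/2` for the angle α between direction vectors
after rotation into the common frame.

Default weights are `w_aa = w_geo = w_dir = 1, w_dist = 2`, gap open 2,
gap extend 0.2. The rationale: the spatial term is the only one that is
always defined and the only one anchored in the superposition, so it
carries double weight; gap penalties are set well below the typical
per-match gain (≈ 3–5 score units) so that family-specific insertions
are skipped rather than force-matched. All of these are exposed in
`align_params()` and can be scanned with `parameter_scan()`, which
ranks settings by core size (descending) then average rmsd (ascending)
— the two criteria by which such parameters are conventionally chosen —
and always emits the full table.

Three numerical choices matter here:

* **Free-ended alignment.** The dynamic program is global in the
  matched span but free at both ends (and may skip unmatched stretches
  of both chains via gap–gap transitions, each paying a fresh gap
  open). Diverged termini and decorations then cost nothing, which is
  the correct behavior when only part of each chain is homologous.
* **Working-cutoff anneal.** A superposition fitted to an 8-residue
  seed is locally tight but globally tilted: on a 100 Å-long chain the
  far end can sit several Å off even when a near-perfect global fit
  exists. The first four iterations therefore accept candidate pairs in
  a widened band (2×, 1.6×, 1.3×, 1.1× `d_cut`) before the final band
  applies. Only pair sets pruned to the true `d_cut` contract are ever
  scored or returned.
* **Convergence.** Iteration stops when a pair set repeats or after
  `max_iter` (50); the best pair set seen, ranked by
  `merge_score = n_eq/(1 + rmsd)`, is returned, so oscillation cannot
  degrade the result. Dynamic-programming ties break deterministically
  (diagonal, then up, then left), making the whole aligner a pure
  function of its inputs.

`d_cut` defaults to 3.8 Å — one Cα–Cα bond length, the natural scale
below which two superposed residues can be called the "same position".

## Core identification

`build_hierarchy()` aligns all pairs, then repeatedly merges the
active pair with the highest `merge_score`; the merged core represents
the pair in later iterations and is realigned against all remaining
active nodes. Ties break on the lexicographically smallest pair of node
labels (a node's label is its smallest member id), which makes the
result invariant to input order — verified by shuffle tests.

Merging is strict intersection: a column survives only if every member
of both children contributes a residue, so core size is non-increasing
toward the root (asserted on every merge). A core's representative
coordinates are the mean of its superposed members; representative
properties are arithmetic means (circular mean for τ, renormalized mean
for directions, majority letter for the amino acid, ties alphabetical).
Member superpositions are composed through the merge tree into the
frame of the first-merged member.

## Distance matrix and tree

`pair_core_distance()` compares two original structures at the core
columns only: superpose the pair on those residues, then

  d(a, b) = w_xyz · mean per-column Cα deviation + w_prop · mean per-column property dissimilarity,

with the property dissimilarity of a column the mean of the defined
terms among amino-acid dissimilarity, geometry difference, direction
difference and relative neighbor-count difference, each in [0, 1].
Defaults `w_xyz = w_prop = 1`. This is a premetric — non-negative,
symmetric, zero exactly for members identical up to a rigid motion
(deviations below 10⁻¹² are snapped to zero so round-off cannot make
identical members differ) — but the triangle inequality is not
guaranteed and not assumed. The matrix is normalized to a unit maximum;
an all-zero matrix is returned un-normalized with a warning flag.

`fitch_margoliash_tree()` minimizes the weighted least-squares
criterion Σ (d − p)²/d² with weights floored at d = 10⁻⁶ for identical
pairs. The search is deterministic and standard: neighbor-joining start
topology, weighted least-squares branch lengths with negative estimates
clamped to zero and one refit of the rest, then best-improvement
nearest-neighbor-interchange until no move lowers the criterion (the
trace of accepted objectives is attached to the result and is
non-increasing by construction). On additive matrices the procedure
recovers the generating topology and branch lengths to machine
precision, which the tests assert on random 4–6-taxon instances. Trees
are unrooted; rooting is a display choice out of scope.

## Jackknife

`run_jackknife()` forms one replicate per family/subfamily unit
(subfamily where defined, else family), removing the unit's
lexicographically first member by default (or a seeded random member),
and reruns core → matrix → tree on the remainder. Units with a single
member are skipped with a warning, since removal would empty them.
Stability of a group is the fraction of replicate trees in which its
remaining members form a clade under unrooted bipartition semantics —
some edge splits exactly them from the rest; groups reduced below two
present members are trivially stable. Removing a member can only relax
the all-member intersection, so replicate cores are never smaller than
the full-data core, a useful cross-check the tests assert.

## The synthetic clan generator

`generate_clan()` stands in for a downloaded clan dataset and defines
the conditions under which the pipeline is validated:

* **Ancestral core** — a self-avoiding Cα trace, spacing exactly
  3.8 Å, bend angles uniform in [80°, 160°], non-consecutive contacts
  below 4.0 Å rejected and resampled. The trace is generated with 1 Å
  of extra clearance so family-level deformation has headroom before
  hitting the clash limit.
* **Families** — each family deforms the core with smooth
  (moving-average-filtered) Gaussian noise followed by bond-length
  renormalization, so local spacing is preserved exactly while the
  global fold shifts; and splices in decorations (2 per family by
  default): terminal extensions or internal loops with geometric
  lengths (mean 10, truncated at 25 so loop closure stays tractable),
  generated as goal-directed self-avoiding walks that reconnect at bond
  distance. Family sequences mutate at rate 0.4 — clan families are
  nearly unrecognizable by sequence, and the default mirrors that.
* **Members** — i.i.d. Gaussian coordinate noise, point mutations at
  rate 0.05, and with probability 0.25 per decoration a short deletion
  (geometric, mean 2) confined to decorations by default so the
  ground-truth core map stays complete. Both noise scales
  (`family_shift_sigma = 1.0`, `member_sigma = 0.5`) are RMS
  displacement magnitudes of the 3D perturbation vector (each axis gets
  σ/√3) — the convention in which "a member sits 0.5 Å from its family
  chain" reads off directly.

All randomness flows from one seed; identical specs give byte-identical
PDB files. Default layout: 4 families × 4 members over a 60-residue
core.

What passing the synthetic validation shows: the aligner, merge logic,
distance, tree and jackknife machinery recover a known core and known
family structure under realistic noise-to-divergence ratios, with no
hidden dependence on input order or run-to-run state. What it does not
show: performance on real β-barrel topologies (the generator makes no
secondary structure), on domain-swapped or circularly permuted
relatives (the aligner is strictly sequential), or at full clan scale
(143 chains); the desk-scale problem sizes — 16 structures of 60–90
residues, 4 jackknife replicates — were chosen so the whole validation
runs in minutes on one CPU.

## Known limitations

* Alignment is sequential and rigid: no topology-independent matching,
  no hinge/flexible superposition.
* The property weights are a calibration, not a fit; the original
  method's tuned values are not published, so ours are chosen from the
  term ranges and exposed for scanning rather than claimed optimal.
* The per-pair core distance mirrors the alignment score's property
  families for coherence; other choices (e.g. pure rmsd) are possible
  and would change branch lengths, though not the within/between family
  separation the tests assert.
* `pairwise_identity()` inherits the quirks of local-alignment percent
  identity discussed above.
* Trees come from a deterministic NJ + WLS + NNI search; for matrices
  far from additivity a different local optimum than exhaustive
  Fitch–Margoliash search cannot be excluded.
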