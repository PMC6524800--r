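# structcore

Structure-based classification of distantly related proteins: common
structural cores and distance trees from C-alpha coordinates.

## The problem

Protein clans such as the chymotrypsin-like (PA) proteases span families
whose sequences have diverged almost beyond recognition — pairwise
identities of a few percent — while the fold around the catalytic site
is strongly conserved. At that distance, sequence-based phylogenetics
runs out of signal, but the three-dimensional structures still align.
`structcore` implements the structure-first route to classifying such a
clan:

1. **Curation** — read PDB chains, trim to the domain of interest, drop
   structures that are too short, too incomplete (missing residues) or
   too low-resolution, and remove redundant entries by greedy
   Smith–Waterman identity clustering.
2. **Pairwise structural alignment** — residues are described by
   amino-acid type, local C-alpha geometry (pseudo-bond angle θ and
   pseudo-dihedral τ), backbone direction, and spatial neighborhood; two
   structures are aligned by iterated optimal superposition and dynamic
   programming over the property similarity
   `S(i,j) = w_aa·sim_aa + w_geo·sim_geo + w_dir·sim_dir + w_dist·(1 − d_ij/d_cut)`,
   with matches forbidden beyond the equivalence cutoff `d_cut`
   (default 3.8 Å, one Cα–Cα bond).
3. **Common core** — the two most similar structures are merged into a
   core that represents them from then on (columns survive only if every
   member contributes a residue); iterating to a single root yields the
   clan-wide common core, the structural analogue of the reliable
   columns of a multiple sequence alignment.
4. **Distance tree** — pairwise distances between the original
   structures, restricted to the homologous core positions (mean Cα
   deviation plus mean property dissimilarity), are normalized and
   converted to an unrooted tree with the Fitch–Margoliash weighted
   least-squares criterion `Σ_{i<j} (d_ij − p_ij)² / d_ij²`
   (neighbor-joining start, non-negative WLS branch lengths,
   nearest-neighbor-interchange hill climbing).
5. **Jackknife** — one structure per family/subfamily is removed in
   turn, the whole pipeline is rerun, and each group's stability is the
   fraction of replicate trees in which its remaining members form a
   clade (unrooted bipartition semantics).

Because real clan-scale datasets require downloading a hundred-plus PDB
chains, the package ships a first-class synthetic clan generator with
known ground truth: families share a self-avoiding Cα core trace,
decorated with family-specific loops and extensions, deformed smoothly
per family, perturbed per member. Every stage of the pipeline is
validated against that truth.

## Worked example

```r
library(structcore)

clan <- generate_clan(synthetic_spec(seed = 1))   # 4 families x 4 members
root <- build_hierarchy(clan$models)              # agglomerative core
core <- root_core(root)
core_size(core)                                   # 60
core_average_rmsd(core)                           # 1.30 (Angstrom)
core_recovery_metrics(core, clan$truth)           # precision 1.0, recall 1.0

dm   <- build_distance_matrix(core)
tree <- fitch_margoliash_tree(dm)
family_recovery_metrics(tree, clan$truth)         # all families TRUE

jk <- run_jackknife(clan$models)
jk$stability                                      # F01..F04 all 1.0
```

The numbers above are what the code prints for seed 1: the 60-residue
simulated core is recovered completely at an average pairwise rmsd of
1.30 Å, all four families are monophyletic in the Fitch–Margoliash tree,
and every family persists as a clade in every jackknife replicate.

The same pipeline as a step-by-step analysis (PDB files on disk, TSV and
Newick outputs under `results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_curate.R
Rscript analysis/03_core.R
Rscript analysis/04_tree.R
Rscript analysis/05_jackknife.R
```

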