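# Fixtures and independent oracles used across the suite.

# StructureModel straight from coordinates + sequence.
make_model <- function(xyz, aa = NULL, id = "M1", family = "",
                       subfamily = "", resolution = NA_real_,
                       res_seq = NULL, icode = "") {
  n <- nrow(xyz)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(res_seq)) res_seq <- seq_len(n)
  structcore:::new_structure_model(
    id,
    data.frame(chain_id = "A", res_seq = res_seq, icode = icode,
               aa = aa, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               b_factor = 0, stringsAsFactors = FALSE),
    resolution = resolution, family_label = family,
    subfamily_label = subfamily)
}

# Random sequence over a restricted alphabet; disjoint alphabets give
# controlled near-zero local-alignment identity between segments.
segment_seq <- function(n, letters_pool, seed) {
  set.seed(seed)
  paste(sample(letters_pool, n, replace = TRUE), collapse = "")
}

# Ideal straight C-alpha chain along x.
make_straight <- function(n, spacing = 3.8) {
  cbind(spacing * (seq_len(n) - 1), 0, 0)
}

# Regular helix with consecutive spacing close to `spacing`.
make_helix <- function(n, radius = 2.3, rise = 1.5, step = 100 * pi / 180) {
  t <- (seq_len(n) - 1) * step
  cbind(radius * cos(t), radius * sin(t), rise * (seq_len(n) - 1))
}

# Random self-avoiding trace from the package generator, under a seed.
make_trace <- function(n, seed) {
  structcore:::with_seed(seed, structcore:::.gen_trace(n))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  rbind(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc)),
        c(2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b)),
        c(2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 - b^2 - cc^2 + d^2))
}

rigid_move <- function(xyz, R = random_rotation(), t = rnorm(3, 0, 10)) {
  sweep(xyz %*% R, 2, t, "+")
}

# Independent superposition oracle: Horn's closed-form quaternion method
# (largest eigenvalue of the 4x4 key matrix), a route through rotation
# space entirely separate from the SVD-based implementation.
horn_rmsd <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  M <- crossprod(b0, a0)
  N <- matrix(c(
    M[1, 1] + M[2, 2] + M[3, 3], M[2, 3] - M[3, 2],
    M[3, 1] - M[1, 3], M[1, 2] - M[2, 1],
    M[2, 3] - M[3, 2], M[1, 1] - M[2, 2] - M[3, 3],
    M[1, 2] + M[2, 1], M[3, 1] + M[1, 3],
    M[3, 1] - M[1, 3], M[1, 2] + M[2, 1],
    -M[1, 1] + M[2, 2] - M[3, 3], M[2, 3] + M[3, 2],
    M[1, 2] - M[2, 1], M[3, 1] + M[1, 3],
    M[2, 3] + M[3, 2], -M[1, 1] - M[2, 2] + M[3, 3]), 4, 4,
    byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  msd <- (sum(a0^2) + sum(b0^2) - 2 * lam) / nrow(a)
  sqrt(max(msd, 0))
}

# Random binary unrooted tree with known branch lengths and its exact
# (additive) leaf distance matrix.
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::unroot(ape::rtree(n_taxa, br = function(k) runif(k, 0.5, 3)))
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  m <- ape::cophenetic.phylo(tree)
  m <- m[tree$tip.label, tree$tip.label]
  list(tree = tree, m = m)
}

# Minimal StructuralCore stand-in for the recovery metrics (which only
# consult `members` and `columns`).
fake_core <- function(columns) {
  structure(list(members = colnames(columns), columns = columns),
            class = "StructuralCore")
}

fake_truth <- function(clan_core_map, family_label = NULL) {
  if (is.null(family_label))
    family_label <- setNames(rep("F01", ncol(clan_core_map)),
                             colnames(clan_core_map))
  structure(list(clan_core_map = clan_core_map,
                 family_label = family_label,
                 spec = NULL),
            class = "GroundTruth")
}

# PDB text fixture with two altloc conformers for residue 2.
altloc_pdb_lines <- function(occ_a = 0.60, occ_b = 0.40) {
  c(sprintf("ATOM  %5d  CA %s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            1L, " ", "ALA", "A", 1L, 0, 0, 0, 1.00, 10.0),
    sprintf("ATOM  %5d  CA %s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            2L, "A", "GLY", "A", 2L, 3.8, 0, 0, occ_a, 10.0),
    sprintf("ATOM  %5d  CA %s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            3L, "B", "GLY", "A", 2L, 9.9, 9.9, 9.9, occ_b, 10.0),
    sprintf("ATOM  %5d  CA %s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            4L, " ", "SER", "A", 3L, 7.6, 0, 0, 1.00, 10.0),
    "END")
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# Small two-family clan used by several tests (fast to align).
small_clan <- function(seed = 1, n_families = 2, members = 3,
                       core = 40, decorations = 1,
                       member_sigma = 0.5) {
  generate_clan(synthetic_spec(
    n_families = n_families, members_per_family = members,
    core_length = core, n_decorations = decorations,
    member_sigma = member_sigma, seed = seed))
}
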