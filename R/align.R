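#' Parameters of the property-based structural aligner
#'
#' The aligner scores candidate residue equivalences as a weighted sum of
#' four similarity terms: amino-acid type (`w_aa`, a BLOSUM62 similarity
#' rescaled to \[0, 1\]), local geometry (`w_geo`, from the C-alpha
#' pseudo-bond angle and pseudo-dihedral), backbone direction (`w_dir`,
#' from the angle between consecutive-C-alpha direction vectors after
#' rotation into a common frame), and spatial proximity (`w_dist`,
#' `1 - d/d_cut` for the post-superposition C-alpha distance `d`).  Pairs
#' farther apart than `d_cut` are forbidden.  `d_cut` defaults to 3.8
#' Angstrom, one C-alpha-C-alpha bond length.
#'
#' @param w_aa,w_geo,w_dir,w_dist non-negative term weights.
#' @param d_cut equivalence cut-off distance (Angstrom) between matched
#'   C-alpha atoms after superposition; must be positive.
#' @param gap_open,gap_extend affine gap penalties of the dynamic program
#'   (end gaps are free).
#' @param seed_window length of the gapless fragment pair used to
#'   initialize the superposition.
#' @param max_iter cap on superpose-align iterations.
#' @return an `AlignParams` list.
#' @export
align_params <- function(w_aa = 1, w_geo = 1, w_dir = 1, w_dist = 2,
                         d_cut = 3.8, gap_open = 2, gap_extend = 0.2,
                         seed_window = 8L, max_iter = 50L) {
  stopifnot(w_aa >= 0, w_geo >= 0, w_dir >= 0, w_dist >= 0,
            d_cut > 0, gap_open >= 0, gap_extend >= 0,
            seed_window >= 3, max_iter >= 1)
  structure(list(w_aa = w_aa, w_geo = w_geo, w_dir = w_dir,
                 w_dist = w_dist, d_cut = d_cut, gap_open = gap_open,
                 gap_extend = gap_extend,
                 seed_window = as.integer(seed_window),
                 max_iter = as.integer(max_iter)),
            class = "AlignParams")
}

# Internal common currency of the aligner: coordinates + property set,
# from either a StructureModel or a StructuralCore.
as_alignable <- function(x) {
  if (inherits(x, "StructureModel"))
    return(list(xyz = model_coords(x), props = compute_properties(x),
                label = x$model_id, n = length(x)))
  if (inherits(x, "StructuralCore"))
    return(list(xyz = x$rep_xyz, props = x$rep_props,
                label = x$members[1], n = nrow(x$rep_xyz)))
  if (is.list(x) && !is.null(x$xyz) && !is.null(x$props))
    return(x)
  stop("cannot align object of class ", paste(class(x), collapse = "/"))
}

# Similarity matrix between two alignable objects given the current
# superposition of b onto a.  Terms undefined at termini are excluded and
# the remaining weights renormalized; cells beyond the working cutoff
# d_work (>= d_cut; relaxed in early iterations so a locally fitted seed
# superposition cannot trap the alignment in one region) are forbidden.
.score_matrix <- function(a, b, b_xyz_fit, rotation, p,
                          d_work = p$d_cut) {
  B <- blosum_similarity()
  rn <- rownames(B)
  sim_aa <- B[match(a$props$aa, rn), match(b$props$aa, rn), drop = FALSE]
  dth <- abs(outer(a$props$theta, b$props$theta, "-"))
  dta <- abs(outer(a$props$tau, b$props$tau, "-"))
  dta <- pmin(dta, 360 - dta)
  sim_geo <- 1 - (dth + dta / 2) / 270
  dirb <- b$props$dir %*% rotation
  cosd <- tcrossprod(a$props$dir, dirb)
  sim_dir <- (1 + pmin(1, pmax(-1, cosd))) / 2
  d2 <- outer(rowSums(a$xyz^2), rowSums(b_xyz_fit^2), "+") -
    2 * tcrossprod(a$xyz, b_xyz_fit)
  d <- sqrt(pmax(d2, 0))
  sim_dist <- 1 - d / p$d_cut
  num <- p$w_aa * sim_aa + p$w_dist * sim_dist
  den <- p$w_aa + p$w_dist
  num <- num + ifelse(is.na(sim_geo), 0, p$w_geo * sim_geo)
  den <- den + p$w_geo * !is.na(sim_geo)
  num <- num + ifelse(is.na(sim_dir), 0, p$w_dir * sim_dir)
  den <- den + p$w_dir * !is.na(sim_dir)
  S <- (p$w_aa + p$w_geo + p$w_dir + p$w_dist) * num / den
  S[d > d_work] <- -1e15
  S
}

# Superpose on the given pairs, drop pairs violating the d_cut contract,
# and repeat until stable.  Returns NULL when fewer than 3 pairs survive.
.refine_pairs <- function(xa, xb, pairs, d_cut) {
  repeat {
    if (is.null(pairs) || nrow(pairs) < 3L) return(NULL)
    sup <- tryCatch(
      kabsch_superpose(xa[pairs[, 1], , drop = FALSE],
                       xb[pairs[, 2], , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(sup)) return(NULL)
    bt <- apply_superposition(xb[pairs[, 2], , drop = FALSE], sup)
    d <- sqrt(rowSums((xa[pairs[, 1], , drop = FALSE] - bt)^2))
    if (all(d <= d_cut + 1e-9))
      return(list(pairs = pairs, superposition = sup))
    pairs <- pairs[d <= d_cut + 1e-9, , drop = FALSE]
  }
}

new_equivalence_map <- function(pairs, superposition, score, d_cut,
                                label_a = NA, label_b = NA) {
  structure(list(pairs = pairs, superposition = superposition,
                 score = score, n_eq = nrow(pairs), d_cut = d_cut,
                 label_a = label_a, label_b = label_b),
            class = "EquivalenceMap")
}

empty_equivalence_map <- function(d_cut, label_a = NA, label_b = NA) {
  new_equivalence_map(matrix(integer(0), 0, 2), identity_superposition(),
                      0, d_cut, label_a, label_b)
}

#' Align two structures (or structural cores) by iterated superposition
#'
#' The engine of core identification.  A seed superposition is found by
#' exhaustive scan over all gapless fragment pairs of length
#' `seed_window`, keeping the pair of minimal superposition rmsd.  The
#' aligner then iterates: superpose on the current equivalences, build the
#' property similarity matrix, run a global dynamic program with affine
#' gaps (end gaps free) over it, and accept the matched pairs; iteration
#' stops when a pair set repeats or `max_iter` is reached, and the
#' best-scoring pair set seen (by `n_eq / (1 + rmsd)`) is returned.  Every
#' reported pair satisfies the post-superposition `d_cut` contract.
#' Deterministic for fixed inputs and parameters.
#'
#' If no seed fragment pair superposes below 5 Angstrom rmsd the
#' structures are deemed unalignable and an empty map with score 0 is
#' returned (not an error).
#'
#' @param a,b `StructureModel` or `StructuralCore` objects with at least
#'   `seed_window` residues/columns.
#' @param params an [align_params()].
#' @return an `EquivalenceMap`: `pairs` (m x 2 matrix of 1-based residue
#'   or column indices, strictly increasing in both columns),
#'   `superposition` (of `b` onto `a`), `score` (`n_eq / (1 + rmsd)`),
#'   `n_eq`, `d_cut`.
#' @export
align_pair <- function(a, b, params = align_params()) {
  stopifnot(inherits(params, "AlignParams"))
  A <- as_alignable(a)
  B <- as_alignable(b)
  if (A$n < params$seed_window || B$n < params$seed_window)
    stop("both inputs need at least seed_window (", params$seed_window,
         ") residues")
  seed <- .seed_scan_cpp(A$xyz, B$xyz, params$seed_window)
  if (!is.finite(seed$rmsd) || seed$rmsd >= 5)
    return(empty_equivalence_map(params$d_cut, A$label, B$label))
  pairs <- cbind(seed$i + 0:(params$seed_window - 1L),
                 seed$j + 0:(params$seed_window - 1L))
  best <- NULL
  best_score <- -Inf
  seen <- character(0)
  # working-cutoff schedule: the first iterations accept candidate pairs
  # in a wider band so the superposition can grow out of the seed region
  ramp <- c(2, 1.6, 1.3, 1.1)
  for (it in seq_len(params$max_iter)) {
    d_work <- params$d_cut * if (it <= length(ramp)) ramp[it] else 1
    sup <- tryCatch(
      kabsch_superpose(A$xyz[pairs[, 1], , drop = FALSE],
                       B$xyz[pairs[, 2], , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(sup)) break
    bt_all <- apply_superposition(B$xyz, sup)
    S <- .score_matrix(A, B, bt_all, sup$rotation, params, d_work)
    new_pairs <- .gotoh_semiglobal_cpp(S, params$gap_open,
                                       params$gap_extend)
    if (nrow(new_pairs) > 0L) {
      sc <- S[new_pairs]
      new_pairs <- new_pairs[sc > -1e14, , drop = FALSE]
    }
    if (d_work > params$d_cut) {
      # keep the wide-band pair set as the next iterate; only
      # contract-pruned sets are scored and recorded
      if (nrow(new_pairs) >= 3L) pairs <- new_pairs
      next
    }
    ref <- .refine_pairs(A$xyz, B$xyz, new_pairs, params$d_cut)
    if (is.null(ref)) break
    msc <- nrow(ref$pairs) / (1 + ref$superposition$rmsd)
    if (msc > best_score) {
      best_score <- msc
      best <- ref
    }
    key <- paste(ref$pairs[, 1], ref$pairs[, 2], sep = ":",
                 collapse = ",")
    if (key %in% seen) break
    seen <- c(seen, key)
    pairs <- ref$pairs
  }
  if (is.null(best))
    return(empty_equivalence_map(params$d_cut, A$label, B$label))
  new_equivalence_map(best$pairs, best$superposition, best_score,
                      params$d_cut, A$label, B$label)
}

#' Similarity score of an equivalence map
#'
#' The merge-ranking criterion combining the two quantities that govern
#' core quality: more equivalent residues and lower rmsd.  Defined as
#' `n_eq / (1 + rmsd)`; an empty map scores 0.
#'
#' @param m an `EquivalenceMap`.
#' @return non-negative real.
#' @export
merge_score <- function(m) {
  stopifnot(inherits(m, "EquivalenceMap"))
  if (m$n_eq == 0L) return(0)
  m$n_eq / (1 + m$superposition$rmsd)
}

#' Write an equivalence map as TSV with a JSON sidecar
#'
#' The TSV holds one row per equivalent pair: the two residue/column
#' indices (1-based) and the post-superposition C-alpha distance.  The
#' JSON sidecar (`<path>.json`) carries the score, rmsd, rotation and
#' translation.
#'
#' @param m an `EquivalenceMap` from [align_pair()].
#' @param a,b the aligned objects (needed to recompute the post-fit
#'   distances).
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_equivalence_tsv <- function(m, a, b, path) {
  stopifnot(inherits(m, "EquivalenceMap"))
  A <- as_alignable(a)
  B <- as_alignable(b)
  if (m$n_eq > 0L) {
    bt <- apply_superposition(B$xyz[m$pairs[, 2], , drop = FALSE],
                              m$superposition)
    d <- sqrt(rowSums((A$xyz[m$pairs[, 1], , drop = FALSE] - bt)^2))
  } else {
    d <- numeric(0)
  }
  df <- data.frame(index_a = m$pairs[, 1], index_b = m$pairs[, 2],
                   distance = round(d, 4))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(label_a = m$label_a, label_b = m$label_b, score = m$score,
         n_eq = m$n_eq, rmsd = m$superposition$rmsd,
         rotation = m$superposition$rotation,
         translation = m$superposition$translation, d_cut = m$d_cut),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.EquivalenceMap <- function(x, ...) {
  cat(sprintf("EquivalenceMap: %d pairs, rmsd %.3f A, score %.2f\n",
              x$n_eq, x$superposition$rmsd, x$score))
  invisible(x)
}
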