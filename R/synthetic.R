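#' Specification of a synthetic structure clan
#'
#' Describes a simulated "clan" of protein families for validating the
#' pipeline with known ground truth: all members share an ancestral
#' C-alpha core (a self-avoiding trace with 3.8 Angstrom spacing); each
#' family deforms that core smoothly (correlated noise of scale
#' `family_shift_sigma`, bond lengths re-normalized) and decorates it
#' with family-specific insertions and terminal extensions (loop lengths
#' geometric with the given mean, truncated at 25 residues so loop
#' closure stays tractable); each member adds i.i.d. Gaussian coordinate
#' noise of scale `member_sigma` and point mutations, and may delete
#' short stretches inside decorations.  The family/member split mirrors
#' divergence between families versus noise within them.
#'
#' @param n_families,members_per_family clan layout.
#' @param core_length number of shared core residues.
#' @param n_decorations decorations (insertions/extensions) per family.
#' @param decoration_mean_length mean decoration length (geometric).
#' @param family_shift_sigma family-level smooth deformation scale
#'   (Angstrom).  Both sigmas are RMS displacement magnitudes of the 3D
#'   perturbation vector (each coordinate axis gets `sigma / sqrt(3)`),
#'   so a member with `member_sigma = 0.5` sits 0.5 Angstrom RMS from
#'   its family chain.
#' @param member_sigma member-level i.i.d. Gaussian coordinate noise
#'   (Angstrom, RMS displacement).
#' @param mutation_rate_family,mutation_rate_member per-site substitution
#'   probabilities at the family and member level.
#' @param indel_in_decorations_only keep member deletions inside
#'   decorations so the ground-truth core map stays complete (default).
#'   When `FALSE`, deletions may hit core residues; the truth map then
#'   records `NA` for the affected member at those columns.
#' @param member_indel_prob probability that a given decoration of a
#'   given member suffers a deletion.
#' @param seed integer; the single source of all randomness.
#' @return a `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_families = 4L, members_per_family = 4L,
                           core_length = 60L, n_decorations = 2L,
                           decoration_mean_length = 10,
                           family_shift_sigma = 1.0, member_sigma = 0.5,
                           mutation_rate_family = 0.4,
                           mutation_rate_member = 0.05,
                           indel_in_decorations_only = TRUE,
                           member_indel_prob = 0.25, seed = 1L) {
  stopifnot(n_families >= 1, members_per_family >= 1, core_length >= 8,
            n_decorations >= 0, decoration_mean_length >= 1,
            family_shift_sigma >= 0, member_sigma >= 0,
            mutation_rate_family >= 0, mutation_rate_family <= 1,
            mutation_rate_member >= 0, mutation_rate_member <= 1,
            member_indel_prob >= 0, member_indel_prob <= 1)
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 core_length = as.integer(core_length),
                 n_decorations = as.integer(n_decorations),
                 decoration_mean_length = decoration_mean_length,
                 family_shift_sigma = family_shift_sigma,
                 member_sigma = member_sigma,
                 mutation_rate_family = mutation_rate_family,
                 mutation_rate_member = mutation_rate_member,
                 indel_in_decorations_only = indel_in_decorations_only,
                 member_indel_prob = member_indel_prob,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

.BOND <- 3.8
.CLASH <- 4.0

.unit <- function(v) v / sqrt(sum(v^2))
.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# Place the next chain point at bond length from `c`, bond angle
# `ang_deg` at c (relative to b), dihedral `dih_deg` about b->c
# (reference a); a may be NULL (arbitrary reference).
.place_next <- function(a, b, cc, ang_deg, dih_deg, bond = .BOND) {
  bc <- .unit(cc - b)
  if (is.null(a)) {
    ref <- if (abs(bc[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    nv <- .unit(.cross3(ref, bc))
  } else {
    ab <- b - a
    cr <- .cross3(ab, bc)
    if (sum(cr^2) < 1e-12) {
      ref <- if (abs(bc[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      cr <- .cross3(ref, bc)
    }
    nv <- .unit(cr)
  }
  mv <- .cross3(nv, bc)
  ang <- ang_deg * pi / 180
  dih <- dih_deg * pi / 180
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  cc + d2[1] * bc + d2[2] * mv + d2[3] * nv
}

.min_dist2 <- function(p, pts) {
  if (is.null(pts) || nrow(pts) == 0L) return(Inf)
  min(rowSums(sweep(pts, 2, p)^2))
}

# Self-avoiding C-alpha trace: 3.8 A spacing, bend angles U(80, 160),
# non-consecutive contacts below 4.0 A rejected and resampled.  The
# ancestral trace is generated with an extra 1 A of clearance so that
# family-level deformation has headroom before hitting the clash limit.
.gen_trace <- function(n, clearance = .CLASH + 1.0) {
  for (restart in 1:25) {
    pts <- matrix(NA_real_, n, 3)
    pts[1, ] <- c(0, 0, 0)
    pts[2, ] <- c(.BOND, 0, 0)
    ok <- TRUE
    for (i in 3:n) {
      placed <- FALSE
      for (try in 1:80) {
        p <- .place_next(if (i >= 4) pts[i - 3, ] else NULL,
                         pts[i - 2, ], pts[i - 1, ],
                         runif(1, 80, 160), runif(1, -180, 180))
        prev <- pts[seq_len(i - 2), , drop = FALSE]
        if (.min_dist2(p, prev) >= clearance^2) {
          pts[i, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pts)
  }
  stop("could not generate a self-avoiding trace of length ", n,
       "; try a shorter core")
}

# Smooth (moving-average-filtered) Gaussian noise of sd sigma.
.smooth_noise <- function(n, sigma, window = 5L) {
  z <- rnorm(n + window - 1L)
  s <- as.numeric(stats::filter(z, rep(1 / window, window), sides = 2))
  s <- s[!is.na(s)]
  sdev <- stats::sd(s)
  if (!is.finite(sdev) || sdev == 0) return(rep(0, n))
  s * sigma / sdev
}

# Smooth family deformation followed by bond renormalization: local
# spacing stays exactly 3.8 A while the global fold shifts gently.
# `sigma` is the RMS displacement magnitude of the 3D perturbation
# vector, so each axis gets sigma/sqrt(3).
.deform_chain <- function(pts, sigma) {
  if (sigma <= 0) return(pts)
  n <- nrow(pts)
  s_ax <- sigma / sqrt(3)
  q <- pts + cbind(.smooth_noise(n, s_ax), .smooth_noise(n, s_ax),
                   .smooth_noise(n, s_ax))
  out <- q
  for (i in 2:n) {
    v <- q[i, ] - q[i - 1, ]
    out[i, ] <- out[i - 1, ] + .BOND * .unit(v)
  }
  out
}

# Geometric sanity: exact 3.8 A consecutive spacing and no non-bonded
# contact below 4.0 A.  `exempt` lists index pairs that flank an inserted
# loop: they were bonded in the ancestral core, so they legitimately sit
# at bond distance although no longer consecutive.
.chain_ok <- function(pts, exempt = NULL) {
  n <- nrow(pts)
  b <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-n, , drop = FALSE])^2))
  if (any(abs(b - .BOND) > 0.01)) return(FALSE)
  d <- as.matrix(stats::dist(pts))
  d[abs(row(d) - col(d)) <= 1] <- Inf
  if (!is.null(exempt) && nrow(exempt) > 0) {
    if (any(d[exempt] < .BOND - 0.1)) return(FALSE)
    d[exempt] <- Inf
    d[exempt[, c(2, 1), drop = FALSE]] <- Inf
  }
  min(d) >= .CLASH
}

# Point at distance `bond` from both p and t (random position on the
# intersection circle); NULL when unreachable.
.close_loop_point <- function(p, t, bond = .BOND) {
  v <- t - p
  dd <- sqrt(sum(v^2))
  if (dd >= 2 * bond - 1e-6 || dd < 1e-6) return(NULL)
  mid <- (p + t) / 2
  r <- sqrt(bond^2 - (dd / 2)^2)
  axis <- .unit(v)
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- .unit(.cross3(axis, ref))
  e2 <- .cross3(axis, e1)
  phi <- runif(1, 0, 2 * pi)
  mid + r * (cos(phi) * e1 + sin(phi) * e2)
}

# Goal-directed bridge of k points between anchors a (preceded by
# a_prev) and t: 3.8 A steps that wander but are forced back as the
# remaining step budget tightens, closing exactly onto t.
.gen_bridge <- function(a_prev, a, t, k, existing) {
  for (attempt in 1:60) {
    pts <- matrix(NA_real_, k, 3)
    prev2 <- a_prev
    prev <- a
    ok <- TRUE
    for (i in seq_len(k)) {
      # clash set: everything except the candidate's bonded neighbors
      clash_pts <- rbind(existing,
                         pts[seq_len(max(i - 2, 0)), , drop = FALSE])
      if (i > 1L) clash_pts <- rbind(clash_pts, matrix(a, 1))
      if (i < k) clash_pts <- rbind(clash_pts, matrix(t, 1))
      if (i == k) {
        p <- NULL
        for (try in 1:30) {
          cand <- .close_loop_point(prev, t)
          if (is.null(cand)) break
          if (.min_dist2(cand, clash_pts) >= .CLASH^2) {
            p <- cand
            break
          }
        }
      } else {
        p <- NULL
        budget <- .BOND * (k - i + 1) - 0.5  # hops left incl. final one
        for (try in 1:60) {
          cand <- .place_next(NULL, prev2, prev,
                              runif(1, 80, 160), runif(1, -180, 180))
          dt <- sqrt(sum((cand - t)^2))
          if (dt > budget) next
          if (i == k - 1 && (dt >= 2 * .BOND - 0.3 || dt < 0.5)) next
          if (.min_dist2(cand, clash_pts) < .CLASH^2) next
          p <- cand
          break
        }
      }
      if (is.null(p)) { ok <- FALSE; break }
      pts[i, ] <- p
      prev2 <- prev
      prev <- p
    }
    if (ok) return(pts)
  }
  stop("could not close a decoration loop; shorten decorations")
}

# Terminal extension of k points continuing the chain past its last two
# points (b, cc).
.gen_extension <- function(b, cc, k, existing) {
  for (attempt in 1:60) {
    pts <- matrix(NA_real_, k, 3)
    prev2 <- b
    prev <- cc
    ok <- TRUE
    for (i in seq_len(k)) {
      clash_pts <- rbind(existing,
                         pts[seq_len(max(i - 2, 0)), , drop = FALSE])
      if (i > 1L) clash_pts <- rbind(clash_pts, matrix(cc, 1))
      p <- NULL
      for (try in 1:60) {
        cand <- .place_next(NULL, prev2, prev,
                            runif(1, 80, 160), runif(1, -180, 180))
        if (.min_dist2(cand, clash_pts) >= .CLASH^2) {
          p <- cand
          break
        }
      }
      if (is.null(p)) { ok <- FALSE; break }
      pts[i, ] <- p
      prev2 <- prev
      prev <- p
    }
    if (ok) return(pts)
  }
  stop("could not generate a terminal extension; shorten decorations")
}

.rand_aa <- function(n) sample(.AA20, n, replace = TRUE)

.mutate_seq <- function(aa, rate) {
  if (rate <= 0) return(aa)
  hit <- runif(length(aa)) < rate
  if (any(hit))
    aa[hit] <- vapply(aa[hit],
                      function(x) sample(setdiff(.AA20, x), 1L),
                      character(1))
  aa
}

# Assemble one family chain: deformed core + decorations.  Returns the
# chain coordinates, sequence, core positions (chain index of each core
# column) and decoration regions (start/end chain indices).
.build_family <- function(core_pts, core_aa, spec) {
  n <- nrow(core_pts)
  for (attempt in 1:30) {
    chain <- .deform_chain(core_pts, spec$family_shift_sigma)
    if (.chain_ok(chain)) break
    if (attempt == 30)
      stop("family deformation kept producing clashes; ",
           "lower family_shift_sigma")
  }
  core_pos <- seq_len(n)
  aa <- .mutate_seq(core_aa, spec$mutation_rate_family)
  regions <- list()
  anchors <- matrix(integer(0), 0, 2)
  if (spec$n_decorations > 0L) {
    junctions <- sort(sample(0:n, spec$n_decorations), decreasing = TRUE)
    lens <- pmin(1L + rgeom(spec$n_decorations,
                            1 / spec$decoration_mean_length), 25L)
    for (q in seq_along(junctions)) {
      j <- junctions[q]
      k <- lens[q]
      m <- nrow(chain)
      if (j == 0L) {
        seg <- .gen_extension(chain[2, ], chain[1, ], k,
                              chain[-1, , drop = FALSE])
        seg <- seg[rev(seq_len(k)), , drop = FALSE]
        chain <- rbind(seg, chain)
        ins_at <- 0L
      } else if (j == n) {
        seg <- .gen_extension(chain[m - 1, ], chain[m, ], k,
                              chain[-m, , drop = FALSE])
        chain <- rbind(chain, seg)
        ins_at <- m
      } else {
        pos <- core_pos[j]
        a_prev <- if (pos > 1L) chain[pos - 1, ] else
          chain[pos, ] + c(0, 0, .BOND)
        seg <- .gen_bridge(a_prev, chain[pos, ],
                           chain[pos + 1, ], k,
                           chain[-c(pos, pos + 1), , drop = FALSE])
        chain <- rbind(chain[seq_len(pos), , drop = FALSE], seg,
                       chain[(pos + 1):m, , drop = FALSE])
        ins_at <- pos
      }
      aa <- append(aa, .rand_aa(k), after = ins_at)
      core_pos[core_pos > ins_at] <- core_pos[core_pos > ins_at] + k
      regions <- lapply(regions, function(r) {
        if (r[1] > ins_at) r + k else r
      })
      anchors[anchors > ins_at] <- anchors[anchors > ins_at] + k
      regions <- c(regions, list(c(ins_at + 1L, ins_at + k)))
      if (j > 0L && j < n)
        anchors <- rbind(anchors, c(ins_at, ins_at + k + 1L))
    }
    if (!.chain_ok(chain, anchors))
      stop("assembled family chain failed geometric sanity checks")
  }
  list(chain = chain, aa = aa, core_pos = core_pos, regions = regions,
       anchors = anchors)
}

# One member: coordinate noise, point mutations, optional deletions.
.build_member <- function(fam, spec) {
  chain <- fam$chain
  aa <- .mutate_seq(fam$aa, spec$mutation_rate_member)
  core_pos <- fam$core_pos
  regions <- if (spec$indel_in_decorations_only) {
    fam$regions
  } else {
    list(c(1L, nrow(chain)))
  }
  del <- logical(nrow(chain))
  for (r in regions) {
    if (runif(1) >= spec$member_indel_prob) next
    rlen <- r[2] - r[1] + 1L
    dlen <- min(1L + rgeom(1, 0.5), rlen)
    start <- r[1] + sample.int(rlen - dlen + 1L, 1L) - 1L
    del[start:(start + dlen - 1L)] <- TRUE
  }
  if (any(del)) {
    keep <- which(!del)
    core_pos <- match(core_pos, keep)  # NA when a core residue was cut
    chain <- chain[keep, , drop = FALSE]
    aa <- aa[keep]
  }
  if (spec$member_sigma > 0)
    chain <- chain + matrix(rnorm(length(chain), 0,
                                  spec$member_sigma / sqrt(3)),
                            ncol = 3)
  list(chain = chain, aa = aa, core_pos = core_pos)
}

#' Generate a synthetic structure clan with known ground truth
#'
#' Draws an ancestral core trace, derives family chains and member
#' structures from it as described in [synthetic_spec()], and returns
#' the member `StructureModel`s together with the ground truth (the
#' chain position of every core column in every member, and the family
#' of every member).  All randomness comes from `spec$seed`: the same
#' spec yields byte-identical structures (and PDB files) on every run.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir optional directory; when given, one PDB file per
#'   member, `truth.json` and `labels.tsv` are written there.
#' @return list with `models` (list of `StructureModel`), `truth` (a
#'   `GroundTruth`: `clan_core_map` matrix of core-column chain indices,
#'   columns = members, `NA` only possible when deletions may hit the
#'   core; `family_label`; `spec`), and `files` (written paths or
#'   `NULL`).
#' @export
generate_clan <- function(spec = synthetic_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  res <- with_seed(spec$seed, {
    core_pts <- .gen_trace(spec$core_length)
    core_aa <- .rand_aa(spec$core_length)
    models <- list()
    core_map <- NULL
    fams <- character(0)
    for (f in seq_len(spec$n_families)) {
      fam <- .build_family(core_pts, core_aa, spec)
      fam_label <- sprintf("F%02d", f)
      for (mi in seq_len(spec$members_per_family)) {
        mem <- .build_member(fam, spec)
        id <- sprintf("F%02d_m%02d", f, mi)
        nres <- nrow(mem$chain)
        residues <- data.frame(
          chain_id = "A", res_seq = seq_len(nres), icode = "",
          aa = mem$aa, x = round(mem$chain[, 1], 3),
          y = round(mem$chain[, 2], 3), z = round(mem$chain[, 3], 3),
          b_factor = 0, stringsAsFactors = FALSE)
        models[[id]] <- new_structure_model(
          id, residues, resolution = NA_real_, n_missing = 0L,
          family_label = fam_label, subfamily_label = "")
        core_map <- cbind(core_map, mem$core_pos)
        fams <- c(fams, fam_label)
      }
    }
    colnames(core_map) <- names(models)
    list(models = models,
         truth = structure(list(clan_core_map = core_map,
                                family_label = setNames(fams,
                                                        names(models)),
                                spec = spec),
                           class = "GroundTruth"))
  })
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(res$models, function(m) {
      write_structure(m, file.path(out_dir, paste0(m$model_id, ".pdb")))
    }, character(1))
    write_ground_truth(res$truth, file.path(out_dir, "truth.json"))
    labels <- data.frame(
      model_id = names(res$models),
      family = res$truth$family_label,
      subfamily = "", stringsAsFactors = FALSE)
    utils::write.table(labels, file.path(out_dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, file.path(out_dir, "truth.json"),
               file.path(out_dir, "labels.tsv"))
  }
  list(models = res$models, truth = res$truth, files = files)
}

#' Write clan ground truth as JSON
#' @param truth a `GroundTruth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "GroundTruth"))
  payload <- list(
    clan_core_map = as.data.frame(truth$clan_core_map),
    family_label = as.list(truth$family_label),
    spec = unclass(truth$spec))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Precision and recall of a recovered core against ground truth
#'
#' A recovered core column counts as a true positive when its
#' member-to-residue assignments agree with some ground-truth core
#' column for at least 90% of the members.  Precision is TP over
#' recovered columns; recall is TP over true core columns.
#'
#' @param core a `StructuralCore` whose members all appear in the truth.
#' @param truth a `GroundTruth`.
#' @return named numeric vector `c(precision, recall)`.
#' @export
core_recovery_metrics <- function(core, truth) {
  stopifnot(inherits(core, "StructuralCore"),
            inherits(truth, "GroundTruth"))
  mm <- core$members
  if (!all(mm %in% colnames(truth$clan_core_map)))
    stop("core members absent from ground truth: ",
         paste(setdiff(mm, colnames(truth$clan_core_map)),
               collapse = ", "))
  tmap <- truth$clan_core_map[, mm, drop = FALSE]
  rec <- core$columns[, mm, drop = FALSE]
  tp <- 0L
  for (r in seq_len(nrow(rec))) {
    agree <- rowMeans(sweep(tmap, 2, rec[r, ], "==") &
                        !is.na(tmap))
    if (max(agree) >= 0.9 - 1e-9) tp <- tp + 1L
  }
  c(precision = tp / max(nrow(rec), 1L),
    recall = tp / nrow(tmap))
}

#' Which families are monophyletic in a tree
#'
#' Desk-scale analogue of checking that the structure-based tree follows
#' the known classification: per family, whether its members present in
#' the tree form an unrooted clade.
#'
#' @param tree a `phylo` tree whose tips are clan member ids.
#' @param truth a `GroundTruth`.
#' @return named logical vector, one entry per family.
#' @export
family_recovery_metrics <- function(tree, truth) {
  stopifnot(inherits(tree, "phylo"), inherits(truth, "GroundTruth"))
  fams <- sort(unique(truth$family_label))
  vapply(setNames(fams, fams), function(f) {
    members <- names(truth$family_label)[truth$family_label == f]
    clade_stability(list(tree), members) == 1
  }, logical(1))
}
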