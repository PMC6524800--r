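#' Structural cores
#'
#' A `StructuralCore` is an ordered set of columns, each mapping exactly
#' one residue of every member structure to a common (homologous)
#' position, with representative coordinates and properties (the mean
#' over superposed members) so that a core can itself be aligned like a
#' structure.  Leaf cores wrap a single structure; [merge_cores()] builds
#' larger cores from a pairwise alignment by intersection: a column
#' survives only if every member of both children contributes a residue.
#'
#' @name StructuralCore
NULL

# Leaf core: one structure, every residue a column, identity frame.
leaf_core <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  props <- compute_properties(model)
  id <- model$model_id
  columns <- matrix(seq_len(length(model)), ncol = 1,
                    dimnames = list(NULL, id))
  structure(
    list(members = id,
         columns = columns,
         rep_xyz = model_coords(model),
         rep_props = props,
         superpositions = setNames(list(identity_superposition()), id),
         member_data = setNames(list(list(
           xyz = model_coords(model), props = props,
           res_seq = model$residues$res_seq,
           family_label = model$family_label,
           subfamily_label = model$subfamily_label)), id)),
    class = "StructuralCore")
}

as_core <- function(x) {
  if (inherits(x, "StructuralCore")) return(x)
  if (inherits(x, "StructureModel")) return(leaf_core(x))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to a StructuralCore")
}

#' Number of columns of a structural core
#' @param core a `StructuralCore`.
#' @return integer column count.
#' @export
core_size <- function(core) {
  stopifnot(inherits(core, "StructuralCore"))
  nrow(core$columns)
}

#' @export
print.StructuralCore <- function(x, ...) {
  cat(sprintf("StructuralCore: %d columns over %d members\n",
              nrow(x$columns), length(x$members)))
  invisible(x)
}

#' Merge two structures or cores into a common structural core
#'
#' Given the pairwise alignment `m` of `a` onto `b`'s frame -- `m` must be
#' `align_pair(a, b, ...)` -- the merged core keeps exactly the matched
#' columns (intersection semantics: every member of both children
#' contributes a residue to every surviving column), composes the member
#' superpositions into the frame of `a`'s first member, and recomputes
#' representative coordinates and properties as (circular) means over all
#' members.  The merged size can therefore never exceed the smaller
#' child, which is asserted on every call.
#'
#' @param m `EquivalenceMap` from `align_pair(a, b)`.
#' @param a,b `StructureModel` or `StructuralCore`.
#' @return the merged `StructuralCore`.
#' @export
merge_cores <- function(m, a, b) {
  stopifnot(inherits(m, "EquivalenceMap"))
  if (m$n_eq == 0L) stop("cannot merge on an empty equivalence map")
  a <- as_core(a)
  b <- as_core(b)
  if (length(intersect(a$members, b$members)) > 0L)
    stop("children share members: ",
         paste(intersect(a$members, b$members), collapse = ", "))
  columns <- cbind(a$columns[m$pairs[, 1], , drop = FALSE],
                   b$columns[m$pairs[, 2], , drop = FALSE])
  nc <- nrow(columns)
  stopifnot(nc <= min(nrow(a$columns), nrow(b$columns)))
  if (nc >= 2L && any(apply(columns, 2, diff) <= 0))
    stop("merged columns are not strictly increasing in every member")
  sups <- c(a$superpositions,
            lapply(b$superpositions, compose_superposition,
                   s2 = m$superposition))
  member_data <- c(a$member_data, b$member_data)
  members <- c(a$members, b$members)
  core <- structure(
    list(members = members, columns = columns, rep_xyz = NULL,
         rep_props = NULL, superpositions = sups,
         member_data = member_data),
    class = "StructuralCore")
  .refresh_representatives(core)
}

# Mean coordinates and properties over superposed members.
.refresh_representatives <- function(core) {
  nc <- nrow(core$columns)
  nm <- length(core$members)
  xyz_sum <- matrix(0, nc, 3)
  theta <- tau_sin <- tau_cos <- matrix(NA_real_, nc, nm)
  dirsum <- matrix(0, nc, 3)
  dircnt <- numeric(nc)
  ncount <- matrix(NA_real_, nc, nm)
  aa <- matrix(NA_character_, nc, nm)
  for (k in seq_len(nm)) {
    id <- core$members[k]
    md <- core$member_data[[id]]
    sup <- core$superpositions[[id]]
    ix <- core$columns[, id]
    xyz_sum <- xyz_sum +
      apply_superposition(md$xyz[ix, , drop = FALSE], sup)
    theta[, k] <- md$props$theta[ix]
    tk <- md$props$tau[ix] * pi / 180
    tau_sin[, k] <- sin(tk)
    tau_cos[, k] <- cos(tk)
    dk <- md$props$dir[ix, , drop = FALSE] %*% sup$rotation
    okd <- !is.na(dk[, 1])
    dirsum[okd, ] <- dirsum[okd, , drop = FALSE] + dk[okd, , drop = FALSE]
    dircnt <- dircnt + okd
    ncount[, k] <- md$props$neighbor_count[ix]
    aa[, k] <- md$props$aa[ix]
  }
  rep_xyz <- xyz_sum / nm
  tau <- atan2(rowMeans(tau_sin, na.rm = TRUE),
               rowMeans(tau_cos, na.rm = TRUE)) * 180 / pi
  tau[rowSums(!is.na(tau_sin)) == 0L] <- NA_real_
  tau[!is.na(tau) & tau <= -180] <- 360 + tau[!is.na(tau) & tau <= -180]
  dir <- dirsum / pmax(dircnt, 1)
  nrm <- sqrt(rowSums(dir^2))
  bad <- dircnt == 0 | nrm < 1e-9
  dir <- dir / pmax(nrm, 1e-12)
  dir[bad, ] <- NA_real_
  consensus <- apply(aa, 1, function(v) {
    tb <- sort(table(v), decreasing = TRUE)
    names(tb)[1]
  })
  core$rep_xyz <- rep_xyz
  core$rep_props <- structure(
    list(aa = consensus,
         theta = rowMeans(theta, na.rm = TRUE),
         tau = tau, dir = dir,
         neighbor_count = rowMeans(ncount, na.rm = TRUE),
         n = nc),
    class = "PropertySet")
  core$rep_props$theta[rowSums(!is.na(theta)) == 0L] <- NA_real_
  core
}

#' Agglomeratively build the clan-wide common structural core
#'
#' Computes all pairwise structural alignments, then repeatedly merges
#' the most similar active pair (highest [merge_score()]; ties broken by
#' the lexicographically smallest pair of node labels, making the result
#' invariant to input order) into a common core that represents the pair
#' thereafter; the new core is realigned against all remaining active
#' nodes.  After n-1 merges a single clan-wide core remains.
#'
#' @param models list of `StructureModel` (>= 2, unique ids).
#' @param params an [align_params()].
#' @return the root `GuideTreeNode`: a binary merge tree whose leaves are
#'   the input structures; each internal node carries the merged
#'   `StructuralCore` as `payload` and its `merge_score`.  The clan core
#'   is `root$payload`.
#' @export
build_hierarchy <- function(models, params = align_params()) {
  n <- length(models)
  stopifnot(n >= 2L)
  ids <- vapply(models, function(m) m$model_id, character(1))
  if (anyDuplicated(ids)) stop("model ids must be unique")
  nodes <- list()
  for (m in models) {
    nodes[[m$model_id]] <- list(
      label = m$model_id,
      core = leaf_core(m),
      tree = structure(list(children = NULL, payload = m,
                            merge_score = NA_real_,
                            label = m$model_id,
                            core_size = length(m)),
                       class = "GuideTreeNode"))
  }
  maps <- new.env(parent = emptyenv())
  pair_key <- function(la, lb) paste(min(la, lb), max(la, lb), sep = "\r")
  align_nodes <- function(la, lb) {
    k <- pair_key(la, lb)
    if (is.null(maps[[k]])) {
      a <- nodes[[min(la, lb)]]$core
      b <- nodes[[max(la, lb)]]$core
      maps[[k]] <- align_pair(a, b, params)
    }
    maps[[k]]
  }
  labels <- sort(ids)
  for (i in seq_along(labels))
    for (j in seq_along(labels))
      if (i < j) align_nodes(labels[i], labels[j])
  scores0 <- vapply(labels, function(la) {
    max(vapply(setdiff(labels, la),
               function(lb) merge_score(align_nodes(la, lb)), numeric(1)))
  }, numeric(1))
  if (any(scores0 == 0))
    stop("unalignable structure(s): ",
         paste(labels[scores0 == 0], collapse = ", "))
  active <- labels
  while (length(active) > 1L) {
    best <- NULL
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i >= j) next
        la <- min(active[i], active[j])
        lb <- max(active[i], active[j])
        sc <- merge_score(align_nodes(la, lb))
        if (is.null(best) || sc > best$score ||
            (sc == best$score &&
             (la < best$la || (la == best$la && lb < best$lb)))) {
          best <- list(la = la, lb = lb, score = sc)
        }
      }
    }
    if (best$score == 0)
      stop("active nodes became unalignable at ", length(active),
           " clusters: ", best$la, " vs ", best$lb)
    m <- align_nodes(best$la, best$lb)
    merged_core <- merge_cores(m, nodes[[best$la]]$core,
                               nodes[[best$lb]]$core)
    merged_tree <- structure(
      list(children = list(nodes[[best$la]]$tree, nodes[[best$lb]]$tree),
           payload = merged_core, merge_score = best$score,
           label = best$la, core_size = nrow(merged_core$columns)),
      class = "GuideTreeNode")
    active <- setdiff(active, c(best$la, best$lb))
    stale <- Filter(function(k) {
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      any(parts %in% c(best$la, best$lb))
    }, ls(maps, all.names = TRUE))
    rm(list = stale, envir = maps)
    nodes[[best$lb]] <- NULL
    nodes[[best$la]] <- list(label = best$la, core = merged_core,
                             tree = merged_tree)
    for (lb in active) align_nodes(best$la, lb)
    active <- sort(c(active, best$la))
  }
  nodes[[active]]$tree
}

#' Extract the clan core from a guide tree root
#' @param node a `GuideTreeNode` (typically the root from
#'   [build_hierarchy()]).
#' @return the node's `StructuralCore` (leaf nodes are wrapped).
#' @export
root_core <- function(node) {
  stopifnot(inherits(node, "GuideTreeNode"))
  as_core(node$payload)
}

#' Core sizes along every root-to-leaf path of a guide tree
#'
#' Used to assert the intersection-semantics invariant: toward the root
#' the column count can only shrink or stay equal.
#'
#' @param node a `GuideTreeNode`.
#' @return data frame with `label`, `depth`, `core_size`,
#'   `parent_core_size` (`NA` at the root).
#' @export
guide_core_sizes <- function(node) {
  rec <- function(nd, depth, parent_size) {
    row <- data.frame(label = nd$label, depth = depth,
                      core_size = nd$core_size,
                      parent_core_size = parent_size,
                      stringsAsFactors = FALSE)
    if (is.null(nd$children)) return(row)
    rbind(row,
          rec(nd$children[[1]], depth + 1L, nd$core_size),
          rec(nd$children[[2]], depth + 1L, nd$core_size))
  }
  out <- rec(node, 0L, NA_integer_)
  rownames(out) <- NULL
  out
}

#' Guide tree in Newick form
#'
#' Internal nodes are labeled with their merge scores.
#'
#' @param node a `GuideTreeNode`.
#' @return single Newick string.
#' @export
guide_tree_newick <- function(node) {
  rec <- function(nd) {
    if (is.null(nd$children)) return(nd$label)
    sprintf("(%s,%s)%.4f", rec(nd$children[[1]]), rec(nd$children[[2]]),
            nd$merge_score)
  }
  paste0(rec(node), ";")
}

#' Average pairwise rmsd over the core columns
#'
#' The mean, over all unordered member pairs, of the optimal-superposition
#' rmsd restricted to the pair's core residues -- the headline "average
#' rmsd" of a common core.
#'
#' @param core a `StructuralCore` with >= 2 members.
#' @return mean rmsd in Angstrom.
#' @export
core_average_rmsd <- function(core) {
  stopifnot(inherits(core, "StructuralCore"))
  mm <- core$members
  if (length(mm) < 2L) stop("average rmsd needs at least 2 members")
  pairs <- combn(mm, 2)
  mean(apply(pairs, 2, function(p) {
    xa <- core$member_data[[p[1]]]$xyz[core$columns[, p[1]], , drop = FALSE]
    xb <- core$member_data[[p[2]]]$xyz[core$columns[, p[2]], , drop = FALSE]
    kabsch_superpose(xa, xb)$rmsd
  }))
}

#' Scan alignment parameter settings and rank them
#'
#' Runs [build_hierarchy()] for every parameter setting of a grid and
#' ranks the settings by core size (descending), ties broken by average
#' core rmsd (ascending) -- the two published selection criteria.  The
#' full table is returned; no hidden selection is performed.  Settings
#' that fail (e.g. make structures unalignable) are flagged and ranked
#' last.
#'
#' @param models list of `StructureModel`.
#' @param grid list of [align_params()] settings.
#' @return data frame with one row per setting: the parameter values,
#'   `core_size`, `avg_rmsd`, `failed`, `message`, `rank`.
#' @export
parameter_scan <- function(models, grid) {
  stopifnot(length(grid) >= 1L)
  rows <- lapply(seq_along(grid), function(k) {
    p <- grid[[k]]
    stopifnot(inherits(p, "AlignParams"))
    out <- data.frame(setting = k, w_aa = p$w_aa, w_geo = p$w_geo,
                      w_dir = p$w_dir, w_dist = p$w_dist, d_cut = p$d_cut,
                      gap_open = p$gap_open, gap_extend = p$gap_extend,
                      core_size = NA_integer_, avg_rmsd = NA_real_,
                      failed = FALSE, message = "",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      core <- root_core(build_hierarchy(models, p))
      list(size = nrow(core$columns), rmsd = core_average_rmsd(core))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$failed <- TRUE
      out$message <- conditionMessage(res)
    } else {
      out$core_size <- res$size
      out$avg_rmsd <- res$rmsd
    }
    out
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$failed
  rank_ok <- order(-tab$core_size[ok], tab$avg_rmsd[ok])
  tab$rank <- NA_integer_
  tab$rank[which(ok)[rank_ok]] <- seq_len(sum(ok))
  tab[order(tab$failed, tab$rank), , drop = FALSE]
}

#' Write a core's member superpositions as JSON
#'
#' One record per member: rotation (into the core frame) and
#' translation.
#'
#' @param core a `StructuralCore`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_core_json <- function(core, path) {
  stopifnot(inherits(core, "StructuralCore"))
  sups <- lapply(core$superpositions, function(s)
    list(rotation = s$rotation, translation = s$translation))
  jsonlite::write_json(list(members = core$members,
                            n_columns = nrow(core$columns),
                            superpositions = sups),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a structural core as TSV
#'
#' One row per core column; one column per member holding the residue's
#' author number (`res_seq`).
#'
#' @param core a `StructuralCore`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_core_tsv <- function(core, path) {
  stopifnot(inherits(core, "StructuralCore"))
  df <- data.frame(column = seq_len(nrow(core$columns)))
  for (id in core$members)
    df[[id]] <- core$member_data[[id]]$res_seq[core$columns[, id]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
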