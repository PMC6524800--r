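#' Fraction of trees in which a group forms a clade
#'
#' Clade membership is judged under unrooted bipartition semantics: the
#' group forms a clade in a tree when some edge splits exactly the
#' group's members present in that tree from all other leaves.  Groups
#' reduced to fewer than 2 present members (or covering all leaves) are
#' trivially stable.  Invariant under leaf-order permutation and
#' re-rooting.
#'
#' @param trees a list of `phylo` trees (or a `multiPhylo`).
#' @param group character vector of leaf labels; must intersect at least
#'   one tree.
#' @return fraction in `[0, 1]`.
#' @export
clade_stability <- function(trees, group) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1L, length(group) >= 1L)
  present_any <- any(vapply(trees, function(tr)
    length(intersect(group, tr$tip.label)) > 0L, logical(1)))
  if (!present_any)
    stop("group is disjoint from every tree")
  mean(vapply(trees, .is_split, logical(1), group = group))
}

.is_split <- function(tree, group) {
  present <- intersect(group, tree$tip.label)
  if (length(present) < 2L) return(TRUE)
  outside <- setdiff(tree$tip.label, present)
  if (length(outside) == 0L) return(TRUE)
  rooted <- ape::root(tree, outgroup = outside[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, present)
}

#' Simplified jackknife over family/subfamily units
#'
#' Robustness test for the structure-based distance tree: one structure
#' is removed from each family/subfamily unit in turn (unit = subfamily
#' where defined, else family), and the whole pipeline -- core
#' identification, distance matrix, Fitch-Margoliash tree -- is rerun on
#' the remaining structures.  Clade stability of each named group is the
#' fraction of replicate trees in which its remaining members form a
#' clade.  Units with a single member are skipped with a warning, since
#' removal would empty them.
#'
#' @param models list of labeled `StructureModel`s (every model needs a
#'   family label; >= 2 units).
#' @param params an [align_params()].
#' @param groups named list of label sets whose stability to report;
#'   default: one group per family.
#' @param remove `"first"` removes the lexicographically first id of each
#'   unit (deterministic default); `"random"` draws the removed member
#'   using `seed`.
#' @param seed integer seed for `remove = "random"`.
#' @param leave_one_out if `TRUE`, ignore units and run one replicate per
#'   structure (whole-dataset leave-one-out).
#' @param w_xyz,w_prop distance weights passed to
#'   [build_distance_matrix()].
#' @return a `JackknifeReport`: list with `replicates` (data frame:
#'   `unit`, `removed_id`, `core_size`, `avg_rmsd`), `trees` (named by
#'   removed id), `stability` (named fractions), `n_replicates`.
#' @export
run_jackknife <- function(models, params = align_params(), groups = NULL,
                          remove = c("first", "random"), seed = 1L,
                          leave_one_out = FALSE, w_xyz = 1, w_prop = 1) {
  remove <- match.arg(remove)
  ids <- vapply(models, function(m) m$model_id, character(1))
  fam <- vapply(models, function(m) m$family_label, character(1))
  sub <- vapply(models, function(m) m$subfamily_label, character(1))
  if (any(!nzchar(fam)))
    stop("every model needs a family label; missing for: ",
         paste(ids[!nzchar(fam)], collapse = ", "))
  unit <- ifelse(nzchar(sub), paste(fam, sub, sep = "/"), fam)
  names(models) <- ids
  if (leave_one_out) {
    units <- as.list(setNames(ids, ids))
  } else {
    units <- split(ids, unit)
    if (length(units) < 2L) stop("jackknife needs at least 2 units")
    single <- vapply(units, length, integer(1)) == 1L
    if (any(single)) {
      warning("skipping single-member unit(s): ",
              paste(names(units)[single], collapse = ", "))
      units <- units[!single]
    }
  }
  units <- units[order(names(units))]
  removed <- if (remove == "first") {
    vapply(units, function(u) sort(u)[1], character(1))
  } else {
    with_seed(seed,
              vapply(units, function(u) sample(u, 1L), character(1)))
  }
  reps <- vector("list", length(units))
  trees <- list()
  for (k in seq_along(units)) {
    rid <- removed[k]
    rest <- models[setdiff(ids, rid)]
    core <- root_core(build_hierarchy(rest, params))
    dm <- build_distance_matrix(core, w_xyz, w_prop)
    tree <- fitch_margoliash_tree(dm)
    trees[[rid]] <- tree
    reps[[k]] <- data.frame(unit = names(units)[k], removed_id = rid,
                            core_size = nrow(core$columns),
                            avg_rmsd = core_average_rmsd(core),
                            stringsAsFactors = FALSE)
  }
  replicates <- do.call(rbind, reps)
  rownames(replicates) <- NULL
  if (is.null(groups)) {
    groups <- lapply(split(ids, fam), identity)
  }
  stability <- vapply(groups, function(g) clade_stability(trees, g),
                      numeric(1))
  structure(list(replicates = replicates, trees = trees,
                 stability = stability,
                 n_replicates = length(units)),
            class = "JackknifeReport")
}

#' @export
print.JackknifeReport <- function(x, ...) {
  cat(sprintf("Jackknife: %d replicates\n", x$n_replicates))
  print(x$replicates)
  cat("Clade stability:\n")
  print(round(x$stability, 3))
  invisible(x)
}

#' Write a jackknife report as JSON
#'
#' Serializes the per-replicate summaries (with trees as Newick
#' strings) and the stability table.
#'
#' @param report a `JackknifeReport`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_jackknife_json <- function(report, path) {
  stopifnot(inherits(report, "JackknifeReport"))
  reps <- report$replicates
  reps$tree <- vapply(reps$removed_id, function(id)
    ape::write.tree(report$trees[[id]]), character(1))
  jsonlite::write_json(list(n_replicates = report$n_replicates,
                            replicates = reps,
                            stability = as.list(report$stability)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a jackknife stability table as TSV
#' @param report a `JackknifeReport`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stability_tsv <- function(report, path) {
  stopifnot(inherits(report, "JackknifeReport"))
  df <- data.frame(group = names(report$stability),
                   stability = report$stability,
                   n_replicates = report$n_replicates,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
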