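#' Fitch-Margoliash tree from a distance matrix
#'
#' Builds an unrooted weighted tree minimizing the Fitch-Margoliash
#' weighted least-squares criterion
#' `sum_{i<j} (d_ij - p_ij)^2 / d_ij^2`, where `p_ij` is the tree path
#' length between leaves i and j.  The search is the standard
#' deterministic pipeline: neighbor-joining start topology, non-negative
#' weighted least-squares branch lengths (negative estimates are clamped
#' to 0 and the remaining lengths re-fit once), then
#' nearest-neighbor-interchange hill climbing until no rearrangement
#' improves the criterion.  Zero distances have their weight denominator
#' floored at `eps` so identical pairs do not blow up the weights.
#'
#' @param m symmetric non-negative zero-diagonal matrix with labels as
#'   dimnames, >= 3 rows.  (Any scale is accepted; the matrix need not be
#'   normalized.)
#' @param eps floor for the weight denominator on zero distances.
#' @return an [ape::ape-package] `phylo` tree (unrooted, branch lengths
#'   >= 0) with attributes `wls_objective` (final criterion value) and
#'   `objective_trace` (criterion after the initial fit and after each
#'   accepted rearrangement, non-increasing).
#' @export
fitch_margoliash_tree <- function(m, eps = 1e-6) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 3L) stop("tree construction needs at least 3 labels")
  if (is.null(rownames(m))) stop("distance matrix must carry labels")
  if (ncol(m) != n || max(abs(m - t(m))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(m < 0)) stop("distance matrix must be non-negative")
  if (any(diag(m) != 0)) stop("distance matrix must have a zero diagonal")
  labels <- rownames(m)
  if (n == 3L) {
    tree <- ape::read.tree(text = paste0("(", labels[1], ",", labels[2],
                                         ",", labels[3], ");"))
  } else {
    tree <- ape::unroot(ape::nj(stats::as.dist(m)))
  }
  fit <- .wls_fit(tree, m, eps)
  trace <- fit$objective
  while (n >= 4L) {
    nbrs <- tryCatch(phangorn::nni(fit$tree), error = function(e) NULL)
    if (is.null(nbrs) || length(nbrs) == 0L) break
    cand <- lapply(nbrs, .wls_fit, m = m, eps = eps)
    objs <- vapply(cand, `[[`, numeric(1), "objective")
    k <- which.min(objs)
    if (objs[k] < fit$objective - 1e-12) {
      fit <- cand[[k]]
      trace <- c(trace, fit$objective)
    } else break
  }
  tree <- fit$tree
  attr(tree, "wls_objective") <- fit$objective
  attr(tree, "objective_trace") <- trace
  tree
}

# Weighted least-squares branch lengths on a fixed topology, with
# clamp-to-zero and one refit.  Returns the tree (postorder) with
# lengths and the criterion value.
.wls_fit <- function(tree, m, eps = 1e-6) {
  tree <- stats::reorder(tree, "postorder")
  labels <- rownames(m)
  A <- .path_design(tree, labels)
  pr <- combn(length(labels), 2)
  d <- m[cbind(pr[1, ], pr[2, ])]
  w <- 1 / pmax(d, eps)^2
  coef <- .wls_solve(A, d, w)
  if (any(coef < 0)) {
    free <- coef > 0
    coef[!free] <- 0
    if (any(free)) {
      coef2 <- .wls_solve(A[, free, drop = FALSE], d, w)
      coef[free] <- pmax(coef2, 0)
    }
  }
  tree$edge.length <- unname(coef)
  p <- as.numeric(A %*% coef)
  list(tree = tree, objective = sum(w * (d - p)^2))
}

.wls_solve <- function(A, d, w) {
  fit <- stats::lm.wfit(A, d, w)
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  coef
}

# Pair x edge incidence matrix: entry 1 when the edge lies on the path
# between the two leaves of the pair.  Pairs follow combn order over
# `labels`; edges follow tree$edge rows (tree must be in postorder).
.path_design <- function(tree, labels) {
  nt <- ape::Ntip(tree)
  edge <- tree$edge
  ne <- nrow(edge)
  tipsets <- vector("list", nt + tree$Nnode)
  for (t in seq_len(nt)) tipsets[[t]] <- t
  below <- matrix(FALSE, ne, nt)
  for (k in seq_len(ne)) {
    ch <- edge[k, 2]
    below[k, tipsets[[ch]]] <- TRUE
    par <- edge[k, 1]
    tipsets[[par]] <- c(tipsets[[par]], tipsets[[ch]])
  }
  pos <- match(labels, tree$tip.label)
  if (anyNA(pos)) stop("tree labels do not match matrix labels")
  pr <- combn(length(labels), 2)
  ii <- pos[pr[1, ]]
  jj <- pos[pr[2, ]]
  A <- matrix(0, ncol(pr), ne)
  for (k in seq_len(ne))
    A[, k] <- as.numeric(below[k, ii] != below[k, jj])
  A
}

#' Fitch-Margoliash criterion of a tree against a distance matrix
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param m distance matrix over the tree's tips.
#' @param eps weight floor for zero distances.
#' @return the weighted least-squares criterion value.
#' @export
wls_objective <- function(tree, m, eps = 1e-6) {
  .wls_fit2 <- stats::reorder(tree, "postorder")
  labels <- rownames(m)
  A <- .path_design(.wls_fit2, labels)
  pr <- combn(length(labels), 2)
  d <- m[cbind(pr[1, ], pr[2, ])]
  w <- 1 / pmax(d, eps)^2
  p <- as.numeric(A %*% .wls_fit2$edge.length)
  sum(w * (d - p)^2)
}

#' Tree path-length matrix
#'
#' Leaf-to-leaf path lengths of a weighted tree, labeled like the tips.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return symmetric labeled matrix.
#' @export
tree_path_lengths <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' Write a tree in Newick format
#'
#' Branch lengths are written in full precision; any internal node labels
#' (e.g. jackknife support fractions) are preserved, so
#' `read(write(tree))` reproduces topology, lengths and supports.
#'
#' @param tree a `phylo` tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
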