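#' Core-restricted structural distance between two members
#'
#' Compares two original structures at the homologous positions defined
#' by the clan core: the pair is optimally superposed on its core
#' residues, and the distance is
#' `w_xyz * (mean per-column C-alpha deviation, Angstrom) +
#'  w_prop * (mean per-column property dissimilarity)`,
#' where the property dissimilarity of a column is the mean of four
#' terms, each in \[0, 1\]: amino-acid dissimilarity (1 - rescaled
#' BLOSUM62), local-geometry difference (pseudo-angle and pseudo-dihedral
#' mismatch), backbone-direction difference after rotation, and relative
#' neighbor-count difference.  Terms undefined at chain termini are
#' skipped.  Symmetric, non-negative, and 0 for identical (or rigidly
#' moved) members by construction.
#'
#' @param core a `StructuralCore`.
#' @param a,b member ids (`a == b` allowed, giving 0).
#' @param w_xyz,w_prop non-negative term weights.
#' @return non-negative real.
#' @export
pair_core_distance <- function(core, a, b, w_xyz = 1, w_prop = 1) {
  stopifnot(inherits(core, "StructuralCore"))
  if (!a %in% core$members) stop("unknown member id: ", a)
  if (!b %in% core$members) stop("unknown member id: ", b)
  if (a == b) return(0)
  ia <- core$columns[, a]
  ib <- core$columns[, b]
  da <- core$member_data[[a]]
  db <- core$member_data[[b]]
  xa <- da$xyz[ia, , drop = FALSE]
  xb <- db$xyz[ib, , drop = FALSE]
  sup <- kabsch_superpose(xa, xb)
  dev <- sqrt(rowSums((xa - apply_superposition(xb, sup))^2))
  B <- blosum_similarity()
  t_aa <- 1 - B[cbind(match(da$props$aa[ia], rownames(B)),
                      match(db$props$aa[ib], rownames(B)))]
  dth <- abs(da$props$theta[ia] - db$props$theta[ib])
  dta <- abs(da$props$tau[ia] - db$props$tau[ib])
  dta <- pmin(dta, 360 - dta)
  t_geo <- (dth + dta / 2) / 270
  dir_b <- db$props$dir[ib, , drop = FALSE] %*% sup$rotation
  cosd <- rowSums(da$props$dir[ia, , drop = FALSE] * dir_b)
  t_dir <- (1 - pmin(1, pmax(-1, cosd))) / 2
  na_ <- da$props$neighbor_count[ia]
  nb_ <- db$props$neighbor_count[ib]
  t_nc <- abs(na_ - nb_) / pmax(na_, nb_, 1)
  dissim <- rowMeans(cbind(t_aa, t_geo, t_dir, t_nc), na.rm = TRUE)
  out <- w_xyz * mean(dev) + w_prop * mean(dissim)
  # members identical up to a rigid motion differ only by round-off
  if (out < 1e-12) out <- 0
  out
}

#' Normalized pairwise structure distance matrix over the core
#'
#' All pairwise [pair_core_distance()] values over the core members,
#' divided by the maximum entry so the largest distance is exactly 1.
#' If every distance is 0 the matrix is returned un-normalized with a
#' warning and `attr(, "all_zero") = TRUE`.
#'
#' @param core a `StructuralCore` with >= 3 members.
#' @param w_xyz,w_prop weights passed to [pair_core_distance()].
#' @return symmetric zero-diagonal matrix with member ids as dimnames;
#'   attribute `all_zero` flags the degenerate case.
#' @export
build_distance_matrix <- function(core, w_xyz = 1, w_prop = 1) {
  stopifnot(inherits(core, "StructuralCore"))
  mm <- core$members
  if (length(mm) < 3L) stop("distance matrix needs at least 3 members")
  n <- length(mm)
  d <- matrix(0, n, n, dimnames = list(mm, mm))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- pair_core_distance(core, mm[i], mm[j], w_xyz, w_prop)
      d[i, j] <- v
      d[j, i] <- v
    }
  }
  mx <- max(d)
  if (mx == 0) {
    warning("all pairwise core distances are zero; ",
            "matrix returned un-normalized")
    attr(d, "all_zero") <- TRUE
    return(d)
  }
  d <- d / mx
  attr(d, "all_zero") <- FALSE
  d
}

#' Write a distance matrix as square TSV or PHYLIP lower triangle
#' @param d symmetric labeled matrix.
#' @param path output file.
#' @param format `"square"` (TSV with header labels) or `"phylip"`
#'   (taxon count header, lower-triangle rows).
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path, format = c("square", "phylip")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(model_id = rownames(d),
                     formatC(d, format = "g", digits = 10),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    n <- nrow(d)
    lines <- c(sprintf("%5d", n),
               vapply(seq_len(n), function(i) {
                 vals <- if (i == 1) "" else
                   paste(formatC(d[i, seq_len(i - 1)], format = "g",
                                 digits = 10), collapse = "  ")
                 trimws(sprintf("%-10s  %s", rownames(d)[i], vals),
                        which = "right")
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}
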