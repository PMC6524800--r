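#' Per-residue property vectors from a C-alpha trace
#'
#' Computes the residue-level properties the structural aligner scores:
#' amino-acid type (one-letter code, looked up in a similarity table),
#' local geometry as the C-alpha pseudo-bond angle `theta` over residues
#' (i-1, i, i+1) and pseudo-dihedral `tau` over (i-1 .. i+2), the backbone
#' direction as the unit vector from Calpha(i) to Calpha(i+1), and the
#' burial proxy `neighbor_count`, the number of C-alpha atoms within 10
#' Angstrom excluding sequence neighbors within +/-2.  Properties that are
#' undefined at the termini are `NA` and are excluded from alignment
#' scoring rather than zero-filled.
#'
#' @param model a `StructureModel` with at least 2 residues (4 for any
#'   dihedral to be defined).
#' @return a `PropertySet` list: `aa` (characters), `theta` (degrees, in
#'   `[0, 180]`, `NA` at both termini), `tau` (degrees, in `(-180, 180]`,
#'   `NA` where the four-residue window is incomplete), `dir` (N x 3 unit
#'   rows, `NA` in the last row), `neighbor_count` (integers), `n`.
#' @export
compute_properties <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  x <- model_coords(model)
  n <- nrow(x)
  if (n < 2L) stop("property computation needs at least 2 residues")
  props_from_coords(x, model$residues$aa)
}

# Internal: property set from raw coordinates + letters (also used for
# core representatives).
props_from_coords <- function(x, aa) {
  n <- nrow(x)
  b <- x[-1, , drop = FALSE] - x[-n, , drop = FALSE]  # bond vectors i -> i+1
  blen <- sqrt(rowSums(b^2))
  dir <- matrix(NA_real_, n, 3)
  dir[seq_len(n - 1), ] <- b / blen
  theta <- rep(NA_real_, n)
  if (n >= 3) {
    u <- -b[seq_len(n - 2), , drop = FALSE]  # i -> i-1
    v <- b[2:(n - 1), , drop = FALSE]        # i -> i+1
    cosang <- rowSums(u * v) /
      (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
    theta[2:(n - 1)] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }
  tau <- rep(NA_real_, n)
  if (n >= 4) {
    b1 <- b[seq_len(n - 3), , drop = FALSE]
    b2 <- b[2:(n - 2), , drop = FALSE]
    b3 <- b[3:(n - 1), , drop = FALSE]
    n1 <- .rowcross(b1, b2)
    n2 <- .rowcross(b2, b3)
    m1 <- .rowcross(n1, b2 / sqrt(rowSums(b2^2)))
    xx <- rowSums(n1 * n2)
    yy <- rowSums(m1 * n2)
    tt <- atan2(yy, xx) * 180 / pi
    tt[tt <= -180] <- tt[tt <= -180] + 360
    tau[2:(n - 2)] <- tt
  }
  d2 <- as.matrix(stats::dist(x))^2
  near <- d2 <= 100                        # 10 A
  ii <- row(near); jj <- col(near)
  near[abs(ii - jj) <= 2] <- FALSE         # exclude sequence neighbors
  structure(list(aa = aa, theta = theta, tau = tau, dir = dir,
                 neighbor_count = as.integer(rowSums(near)), n = n),
            class = "PropertySet")
}

.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# BLOSUM62 rescaled to [0, 1] over the 20 standard letters + X, cached.
# Each pair is scaled against the larger of the two self-scores so that
# sim(x, x) = 1 exactly: identical residues are maximally similar and
# property distances vanish on identical sequences.
.prop_cache <- new.env(parent = emptyenv())
blosum_similarity <- function() {
  if (is.null(.prop_cache$b01)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    keep <- c(.AA20, "X")
    B <- e$BLOSUM62[keep, keep]
    dg <- diag(B)
    denom <- outer(dg, dg, pmax) - min(B)
    .prop_cache$b01 <- pmin((B - min(B)) / denom, 1)
  }
  .prop_cache$b01
}

# Circular mean of angles in degrees (NA-dropping); NA if all NA.
circ_mean_deg <- function(deg) {
  deg <- deg[!is.na(deg)]
  if (length(deg) == 0L) return(NA_real_)
  r <- deg * pi / 180
  out <- atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
  if (out <= -180) out <- out + 360
  out
}
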