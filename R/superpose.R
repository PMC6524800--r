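#' Optimal rigid-body superposition of paired coordinate sets
#'
#' Least-squares fit of one set of paired C-alpha coordinates onto another
#' (the Kabsch procedure): the proper rotation (determinant +1, reflections
#' excluded) and translation minimizing the root-mean-square deviation of
#' `coords_b` transformed onto `coords_a`.
#'
#' Coordinates are row vectors; the fitted transform of a point `x` is
#' `x %*% rotation + translation`.  The rmsd is computed from the closed
#' form `(Ga + Gb - 2*(s1 + s2 +/- s3)) / N`; mean-square deviations below
#' 1e-12 of the mean-square radius of the inputs are below double precision
#' and are reported as exactly 0.
#'
#' @param coords_a,coords_b numeric N x 3 matrices (Angstrom), paired rows.
#' @return an object of class `Superposition`: list with `rotation` (3 x 3,
#'   orthonormal, det +1), `translation` (length-3), `rmsd` (Angstrom) and
#'   `n` (number of fitted pairs).
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' s <- kabsch_superpose(a, a + 5)   # pure translation
#' s$rmsd
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a)
  b <- as.matrix(coords_b)
  if (!is.numeric(a) || !is.numeric(b) || ncol(a) != 3L || ncol(b) != 3L)
    stop("coordinates must be numeric N x 3 matrices")
  n <- nrow(a)
  if (nrow(b) != n) stop("coordinate sets must have the same number of rows")
  if (n < 3L) stop("superposition needs at least 3 paired points")
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b)))
    stop("coordinates must be finite")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  if (.coord_rank(a0) < 2L || .coord_rank(b0) < 2L)
    stop("degenerate input: points are collinear, rotation is not determined")
  C <- crossprod(b0, a0)
  sv <- svd(C)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  ga <- sum(a0 * a0); gb <- sum(b0 * b0)
  msd <- (ga + gb - 2 * (sv$d[1] + sv$d[2] + d * sv$d[3])) / n
  scale2 <- (ga + gb) / (2 * n)
  if (msd < 1e-12 * max(scale2, 1e-12)) msd <- 0
  structure(
    list(rotation = R,
         translation = as.numeric(ca - cb %*% R),
         rmsd = sqrt(max(msd, 0)),
         n = n),
    class = "Superposition")
}

.coord_rank <- function(x0) {
  s <- svd(x0, nu = 0, nv = 0)$d
  sum(s > 1e-8 * max(s[1], 1e-12))
}

#' Apply a superposition to coordinates
#'
#' @param coords N x 3 matrix of points (rows).
#' @param sup a `Superposition`.
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(coords, sup) {
  stopifnot(inherits(sup, "Superposition"))
  sweep(as.matrix(coords) %*% sup$rotation, 2, sup$translation, "+")
}

# Compose two superpositions: first s1 (into an intermediate frame), then
# s2.  x %*% R1 + t1 then %*% R2 + t2  ==  x %*% (R1 R2) + (t1 R2 + t2).
compose_superposition <- function(s1, s2) {
  structure(
    list(rotation = s1$rotation %*% s2$rotation,
         translation = as.numeric(s1$translation %*% s2$rotation) +
           s2$translation,
         rmsd = NA_real_, n = NA_integer_),
    class = "Superposition")
}

identity_superposition <- function() {
  structure(list(rotation = diag(3), translation = numeric(3),
                 rmsd = 0, n = NA_integer_),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Rigid superposition: rmsd %.4f A over %s pairs\n",
              x$rmsd, x$n))
  invisible(x)
}
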