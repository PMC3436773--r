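#' Root mean square deviation of two corresponded point sets
#'
#' `sqrt(mean(||a_i - b_i||^2))` over positional pairs.  The inputs are taken
#' as already superposed: this operation does *not* fit.  Use [superpose()]
#' for the least-squares optimal value.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices (n >= 1), Angstrom.
#' @return rmsd in Angstrom.
#' @export
rmsd <- function(coords_a, coords_b) {
  coords_a <- .as_coords(coords_a)
  coords_b <- .as_coords(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) {
    stop("coordinate sets differ in length: ", nrow(coords_a), " vs ",
         nrow(coords_b))
  }
  if (nrow(coords_a) == 0) stop("need at least one point pair")
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

.as_coords <- function(x) {
  x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, ncol = 3, byrow = TRUE)
  if (ncol(x) != 3) stop("coordinates must be n x 3")
  storage.mode(x) <- "double"
  x
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the rmsd of
#' `coords_b %*% R + t` against `coords_a` over all rigid motions.  The SVD
#' solution with determinant sign correction is used, so reflections are
#' excluded: a mirror image cannot be fitted to rmsd 0.
#'
#' @param coords_a,coords_b Numeric n x 3 matrices, n >= 3, corresponded
#'   positionally.
#' @return A `superposition` object: list with `rotation` (3 x 3, determinant
#'   +1), `translation` (length 3) and `rmsd` (Angstrom, after applying the
#'   transform to `coords_b`).
#' @seealso [apply_transform()], [backbone_rmsd()]
#' @examples
#' a <- matrix(rnorm(15), ncol = 3)
#' b <- sweep(a, 2, c(1, 2, 3), "+")   # pure translation
#' superpose(a, b)$rmsd                # ~0
#' @export
superpose <- function(coords_a, coords_b) {
  a <- .as_coords(coords_a)
  b <- .as_coords(coords_b)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in length")
  if (nrow(a) < 3) stop("superposition needs at least 3 point pairs")

  ca <- colMeans(a)
  cb <- colMeans(b)
  ac <- sweep(a, 2, ca)
  bc <- sweep(b, 2, cb)

  h <- crossprod(bc, ac)         # 3x3: t(bc) %*% ac
  sv <- svd(h)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  r <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  t <- ca - as.vector(cb %*% r)

  fitted <- sweep(b %*% r, 2, t, "+")
  structure(
    list(rotation = r, translation = t, rmsd = rmsd(a, fitted)),
    class = "superposition"
  )
}

#' Apply a superposition transform to coordinates
#'
#' @param coords Numeric n x 3 matrix.
#' @param sp A `superposition` from [superpose()].
#' @return Transformed n x 3 matrix (`coords %*% rotation + translation`).
#' @export
apply_transform <- function(coords, sp) {
  stopifnot(inherits(sp, "superposition"))
  sweep(.as_coords(coords) %*% sp$rotation, 2, sp$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A\n", x$rmsd))
  cat("rotation:\n")
  print(round(x$rotation, 4))
  cat("translation:", paste(round(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

#' Backbone rmsd between two residue selections
#'
#' Collects the backbone atoms (by default N, CA, C, O) of the paired
#' residues, superposes the two resulting point sets by [superpose()], and
#' returns the least-squares rmsd.  Atom pairs where either residue lacks the
#' atom are dropped; the number dropped is attached as attribute `dropped`
#' (and the number used as `n_atoms`).  Fewer than 3 usable pairs is an
#' error.
#'
#' @param model_a,model_b `structure_model` objects (may be the same model).
#' @param residues_a,residues_b Equal-length residue key vectors, paired in
#'   the given order.
#' @param atoms Backbone atom names to collect.
#' @return rmsd in Angstrom, with attributes `n_atoms` and `dropped`.
#' @export
backbone_rmsd <- function(model_a, residues_a, model_b, residues_b,
                          atoms = c("N", "CA", "C", "O")) {
  residues_a <- normalize_res_key(residues_a)
  residues_b <- normalize_res_key(residues_b)
  if (length(residues_a) != length(residues_b)) {
    stop("residue selections differ in length")
  }
  pa <- list()
  pb <- list()
  dropped <- 0L
  for (i in seq_along(residues_a)) {
    for (at in atoms) {
      a <- get_atom(model_a, residues_a[i], at)
      b <- get_atom(model_b, residues_b[i], at)
      if (is.null(a) || is.null(b)) {
        dropped <- dropped + 1L
        next
      }
      pa[[length(pa) + 1]] <- a
      pb[[length(pb) + 1]] <- b
    }
  }
  if (length(pa) < 3) {
    stop("fewer than 3 usable backbone atom pairs (", dropped, " dropped)")
  }
  sp <- superpose(do.call(rbind, pa), do.call(rbind, pb))
  structure(sp$rmsd, n_atoms = length(pa), dropped = dropped)
}

#' Internal distance matrix of a point set
#'
#' The n x n symmetric matrix of all pairwise Euclidean distances, zero on
#' the diagonal.  Encodes the 3D configuration up to mirror symmetry.
#'
#' @param coords Numeric n x 3 matrix.
#' @return n x n matrix of Angstrom distances.
#' @export
distance_matrix <- function(coords) {
  as.matrix(dist(.as_coords(coords)))
}

#' Distance-matrix similarity
#'
#' Sum over all entries of the absolute difference of two equal-size internal
#' distance matrices; 0 iff the matrices are identical.  A pseudometric on
#' configurations: it is blind to rigid motion and to mirror reflection.
#'
#' @param dm_a,dm_b Equal-dimension distance matrices (see
#'   [distance_matrix()]).
#' @return Non-negative number (Angstrom, summed over all ordered pairs).
#' @export
dm_similarity <- function(dm_a, dm_b) {
  dm_a <- as.matrix(dm_a)
  dm_b <- as.matrix(dm_b)
  if (!all(dim(dm_a) == dim(dm_b))) stop("distance matrices differ in dimension")
  sum(abs(dm_a - dm_b))
}
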