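# Exact null-space and row-space computations.
#
# The loop-law dichotomy is exact: a sign pattern either admits a loop or a
# certificate, never both and never neither.  Floating-point rank decisions
# can flip that dichotomy near degeneracy, so the primary path here is
# exact rational Gauss-Jordan elimination with fixed column order.  A
# floating-point SVD path exists only for user-supplied non-rational input.

# reduced row echelon form of an rq matrix; deterministic (first nonzero
# pivot in fixed column order)
rq_rref <- function(M) {
  Mn <- M$n
  Md <- M$d
  nr <- nrow(Mn)
  nc <- ncol(Mn)
  pivots <- integer(0)
  r <- 1L
  for (cc in seq_len(nc)) {
    if (r > nr) break
    sub <- which(Mn[r:nr, cc] != 0)
    if (!length(sub)) next
    p <- r + sub[1L] - 1L
    if (p != r) {
      tmp <- Mn[r, ]; Mn[r, ] <- Mn[p, ]; Mn[p, ] <- tmp
      tmp <- Md[r, ]; Md[r, ] <- Md[p, ]; Md[p, ] <- tmp
    }
    piv <- list(n = Mn[r, cc], d = Md[r, cc])
    row <- rq_mul(list(n = Mn[r, ], d = Md[r, ]), list(n = piv$d, d = piv$n))
    Mn[r, ] <- row$n
    Md[r, ] <- row$d
    for (i in seq_len(nr)) {
      if (i == r || Mn[i, cc] == 0) next
      f <- list(n = Mn[i, cc], d = Md[i, cc])
      prod <- rq_mul(list(n = row$n, d = row$d), f)
      upd <- rq_sub(list(n = Mn[i, ], d = Md[i, ]), prod)
      Mn[i, ] <- upd$n
      Md[i, ] <- upd$d
    }
    pivots <- c(pivots, cc)
    r <- r + 1L
  }
  list(n = Mn, d = Md, pivots = pivots, rank = length(pivots))
}

rq_matrix_from_num <- function(A) {
  A <- as.matrix(A)
  rq_from_num(A)
}

# exact rank of a numeric (rational-representable) matrix
matrix_rank_exact <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) == 0 || ncol(A) == 0) return(0L)
  rq_rref(rq_matrix_from_num(A))$rank
}

#' Exact null-space basis of a rational matrix
#'
#' Computes a basis of \eqn{\{x : Ax = 0\}} by reduced row echelon form in
#' exact rational arithmetic.  Basis vectors are returned in smallest
#' integer form with a positive first nonzero entry, one per free column
#' of the echelon form, so the result is deterministic for a given matrix.
#'
#' For a stoichiometric internal matrix this is the matrix usually written
#' \eqn{N_{int}}: the loop space of the network.
#'
#' @param A numeric matrix with exactly rational entries (integers, or
#'   ratios recoverable by continued fractions, e.g. 0.5).
#' @param exact if `TRUE` (default) use exact rational elimination.  If
#'   `FALSE`, use a floating-point SVD with singular values below
#'   `1e-10 * max(singular value)` treated as zero; intended only for
#'   genuinely non-rational input and never used by the package's own
#'   decision procedures.
#' @return an object of class `nullspace_basis`: a list with `basis`
#'   (an `ncol(A)` x k matrix whose columns span the null space), `rank`
#'   (the exact rank of `A`), and `exact`.
#' @examples
#' cyc <- internal_submatrix(figure2_network())
#' nullspace_basis(cyc)  # one basis vector: (1, 1, 1)
#' @export
nullspace_basis <- function(A, exact = TRUE) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (!exact) {
    if (nrow(A) == 0 || n == 0) {
      return(structure(list(basis = diag(1, n), rank = 0L, exact = FALSE),
                       class = "nullspace_basis"))
    }
    sv <- svd(A, nu = 0, nv = n)
    thr <- 1e-10 * max(sv$d, 0)
    rank <- sum(sv$d > thr)
    basis <- sv$v[, seq_len(n - rank), drop = FALSE]
    if (n - rank > 0) basis <- sv$v[, (rank + 1):n, drop = FALSE]
    else basis <- matrix(0, n, 0)
    return(structure(list(basis = basis, rank = as.integer(rank), exact = FALSE),
                     class = "nullspace_basis"))
  }
  if (n == 0) {
    return(structure(list(basis = matrix(0, 0, 0), rank = 0L, exact = TRUE),
                     class = "nullspace_basis"))
  }
  if (nrow(A) == 0) {
    return(structure(list(basis = diag(1, n), rank = 0L, exact = TRUE),
                     class = "nullspace_basis"))
  }
  R <- rq_rref(rq_matrix_from_num(A))
  free <- setdiff(seq_len(n), R$pivots)
  basis <- matrix(0, n, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    vn <- numeric(n)
    vd <- rep(1, n)
    vn[f] <- 1
    if (R$rank > 0) {
      vn[R$pivots] <- -R$n[seq_len(R$rank), f]
      vd[R$pivots] <- R$d[seq_len(R$rank), f]
    }
    basis[, k] <- rq_smallest_int(rq_canon(vn, vd), positive_first = TRUE)
  }
  if (!is.null(colnames(A))) rownames(basis) <- colnames(A)
  structure(list(basis = basis, rank = as.integer(R$rank), exact = TRUE),
            class = "nullspace_basis")
}

#' @export
print.nullspace_basis <- function(x, ...) {
  cat(sprintf("Exact null-space basis: rank %d, nullity %d\n",
              x$rank, ncol(x$basis)))
  if (ncol(x$basis) > 0) print(x$basis)
  invisible(x)
}

#' Exact membership test for the row space of a matrix
#'
#' Decides whether `g` lies in \eqn{image(A^T)} by comparing the exact rank
#' of `A` with the rank of `A` augmented with `g` as an extra row.  By the
#' fundamental theorem of linear algebra this is equivalent to `g` being
#' orthogonal to the null space of `A` (see
#' [nullspace_orthogonality_check()], which must agree on every input).
#'
#' @param A numeric matrix with rational entries.
#' @param g numeric vector, `length(g) == ncol(A)`.
#' @return logical scalar.
#' @export
in_row_space <- function(A, g) {
  A <- as.matrix(A)
  if (length(g) != ncol(A)) {
    stop(sprintf("length(g) = %d but ncol(A) = %d", length(g), ncol(A)),
         call. = FALSE)
  }
  if (all(g == 0)) return(TRUE)
  if (nrow(A) == 0) return(FALSE)
  matrix_rank_exact(A) == matrix_rank_exact(rbind(A, as.numeric(g)))
}

#' Orthogonality of a vector to the null space of a matrix
#'
#' Returns `TRUE` iff \eqn{b \cdot g = 0} exactly for every null-space
#' basis vector `b` of `A` — the constraint written
#' \eqn{null(S_{int}) \cdot G = 0} in the null-space formulation of the
#' loopless constraints.  Agrees with [in_row_space()] on every input.
#'
#' @inheritParams in_row_space
#' @return logical scalar.
#' @export
nullspace_orthogonality_check <- function(A, g) {
  A <- as.matrix(A)
  if (length(g) != ncol(A)) {
    stop(sprintf("length(g) = %d but ncol(A) = %d", length(g), ncol(A)),
         call. = FALSE)
  }
  B <- nullspace_basis(A)$basis
  if (ncol(B) == 0) return(TRUE)
  grq <- rq_from_num(as.numeric(g))
  for (k in seq_len(ncol(B))) {
    dp <- rq_dot(rq_from_num(B[, k]), grq)
    if (dp$n != 0) return(FALSE)
  }
  TRUE
}
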