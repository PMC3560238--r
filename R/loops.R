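# Loop detection.
#
# A flux distribution v contains a loop iff some nonzero x, zero on
# exchange reactions and sign-consistent with v on internal ones,
# satisfies S_int %*% x = 0.  Two independent routes decide this:
#
#   * find_loop(): an LP with bounded auxiliary variables t_i <= d_i*x_i,
#     t_i in [0,1]; the optimum of sum(t) is positive iff a loop exists.
#     Solved by the package's exact simplex, so "> 0" is decided exactly.
#   * enumerate_loops_bruteforce(): exhaustive support enumeration.  Every
#     sign-consistent kernel vector decomposes over the extreme rays of
#     the cone {x : A x = 0, sign-consistent}, and each extreme ray has a
#     one-dimensional, strictly signed kernel on its own support.  So it
#     suffices to scan all column subsets, keep those whose restricted
#     kernel is one-dimensional with no zero entry (the "circuits"), and
#     match their sign vectors against d.  No LP is involved, which keeps
#     this oracle independent of the simplex route.

#' Construct a loop vector
#'
#' @param values numeric vector (smallest-integer witness), named by
#'   reaction/column id where available.
#' @param pattern the [sign_pattern()] the witness is consistent with.
#' @return an object of class `loop_vector`.
#' @export
loop_vector <- function(values, pattern = NULL) {
  structure(list(values = values,
                 support = which(values != 0),
                 pattern = pattern),
            class = "loop_vector")
}

#' @export
print.loop_vector <- function(x, ...) {
  cat("Loop vector (support size", length(x$support), "):\n")
  print(x$values[x$support])
  invisible(x)
}

#' Test whether a vector is a loop of a network
#'
#' `x` is a loop iff it is nonzero, vanishes on every exchange reaction,
#' and satisfies \eqn{S_{int} x_{int} = 0} exactly.  Note this is a
#' statement about the *internal* matrix: it must not be confused with
#' the steady-state condition \eqn{S v = 0} over the full matrix, and a
#' steady-state flux distribution can perfectly well contain a loop.
#'
#' @param network a `stoich_network`.
#' @param x numeric vector of length n (or named by reaction id), or a
#'   `loop_vector`.
#' @return logical scalar.
#' @export
is_loop <- function(network, x) {
  stopifnot(inherits(network, "stoich_network"))
  if (inherits(x, "loop_vector")) x <- x$values
  vals <- match_flux(network, x)
  if (all(vals == 0)) return(FALSE)
  if (any(vals[!network$internal] != 0)) return(FALSE)
  A <- internal_submatrix(network)
  if (ncol(A) == 0) return(FALSE)
  xr <- rq_from_num(as.numeric(vals[network$internal]))
  for (i in seq_len(nrow(A))) {
    dp <- rq_dot(rq_from_num(A[i, ]), xr)
    if (dp$n != 0) return(FALSE)
  }
  TRUE
}

#' Enumerate the circuits of a rational matrix
#'
#' A circuit is a minimal-support nonzero kernel vector: a column subset S
#' such that the kernel of `A[, S]` is one-dimensional and strictly
#' nonzero on S, reported in smallest integer form with positive first
#' entry.  Circuits are the extreme rays (up to sign) of every
#' sign-constrained kernel cone of `A`, so all loop questions about `A`
#' reduce to sign-matching against this list.  Computed once per matrix,
#' it can be passed to [enumerate_loops_bruteforce()] and
#' [check_dichotomy()] to avoid recomputation across sign patterns.
#'
#' @param A numeric matrix with rational entries, at most 12 columns.
#' @return a list of circuits, each a list with `support` (column
#'   indices) and `values` (length `ncol(A)` integer vector).
#' @export
loop_circuits <- function(A) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (n > 12) {
    stop("brute-force enumeration refuses matrices with more than 12 columns",
         call. = FALSE)
  }
  circuits <- list()
  supports <- list()
  if (n == 0) return(circuits)
  for (k in seq_len(n)) {
    for (S in utils::combn(n, k, simplify = FALSE)) {
      # a superset of a circuit support can never be a circuit itself
      skip <- FALSE
      for (sp in supports) {
        if (all(sp %in% S)) { skip <- TRUE; break }
      }
      if (skip) next
      nb <- nullspace_basis(A[, S, drop = FALSE])
      if (ncol(nb$basis) != 1L) next
      b <- nb$basis[, 1]
      if (any(b == 0)) next
      vals <- numeric(n)
      vals[S] <- b
      if (!is.null(colnames(A))) names(vals) <- colnames(A)
      circuits[[length(circuits) + 1L]] <- list(support = S, values = vals)
      supports[[length(supports) + 1L]] <- S
    }
  }
  circuits
}

#' Brute-force enumeration of sign-consistent loop vectors
#'
#' The independent oracle for the loop side of the Gordan dichotomy: for
#' the sign pattern `d`, returns every minimal-support nonzero kernel
#' vector of `A` whose signs agree with `d` on its support (in smallest
#' integer form, oriented to match `d`).  The list is empty iff no
#' sign-consistent loop exists.
#'
#' @param A numeric matrix with rational entries (typically the internal
#'   stoichiometric matrix), at most 12 columns.
#' @param d a [sign_pattern()] (or -1/0/+1 vector) of length `ncol(A)`.
#' @param circuits optional precomputed [loop_circuits()] of `A`.
#' @return list of [loop_vector()] witnesses (possibly empty).
#' @export
enumerate_loops_bruteforce <- function(A, d, circuits = NULL) {
  A <- as.matrix(A)
  d <- as_sign_pattern(d)
  if (length(d) != ncol(A)) {
    stop(sprintf("sign pattern has length %d but A has %d columns",
                 length(d), ncol(A)), call. = FALSE)
  }
  if (is.null(circuits)) circuits <- loop_circuits(A)
  out <- list()
  for (circ in circuits) {
    s <- sign(circ$values[circ$support])
    dt <- unclass(d)[circ$support]
    if (all(s == dt)) {
      out[[length(out) + 1L]] <- loop_vector(circ$values, d)
    } else if (all(-s == dt)) {
      out[[length(out) + 1L]] <- loop_vector(-circ$values, d)
    }
  }
  out
}

#' Find a loop in a flux distribution
#'
#' Decides whether `v` contains a loop and, if so, returns a witness.
#' The decision LP maximizes \eqn{\sum_i t_i} subject to
#' \eqn{S_{int} x = 0}, \eqn{x_i = 0} where \eqn{d_i = 0},
#' \eqn{0 \le t_i \le d_i x_i} and \eqn{t_i \le 1} on active reactions
#' (\eqn{d_i = sign(v_i)}).  The feasible set is a cone, so the optimum is
#' positive iff some sign-consistent kernel vector is nonzero; with the
#' exact simplex that sign is decided exactly, with no magnitude cutoff.
#'
#' The all-zero flux distribution trivially contains no loop and returns
#' `NULL`; callers that must treat v = 0 specially (it always survives
#' the loopless constraints) should test for it explicitly, as the
#' command-line report does.
#'
#' @param network a `stoich_network`.
#' @param v a [flux_distribution()] or numeric flux vector.
#' @return a [loop_vector()] witness (exact-verified by [is_loop()] and
#'   sign-checked against `v`), or `NULL` when `v` is loop-free.
#' @export
find_loop <- function(network, v) {
  stopifnot(inherits(network, "stoich_network"))
  vals <- match_flux(network, v)
  tol <- if (inherits(v, "flux_distribution")) v$tolerance else 1e-9
  d_full <- sign_pattern(vals, tolerance = tol)
  A <- internal_submatrix(network)
  n_int <- ncol(A)
  if (n_int == 0) return(NULL)
  d_int <- unclass(d_full)[network$internal]
  act <- which(d_int != 0)
  if (!length(act)) return(NULL)

  na <- length(act)
  # variables: x over active internal reactions, then t over the same
  nv <- 2L * na
  ds <- d_int[act]
  Aact <- A[, act, drop = FALSE]
  m <- nrow(Aact)
  mat <- matrix(0, m + na, nv)
  mat[seq_len(m), seq_len(na)] <- Aact
  for (k in seq_len(na)) {
    # t_k - d_k * x_k <= 0
    mat[m + k, k] <- -ds[k]
    mat[m + k, na + k] <- 1
  }
  dir <- c(rep("=", m), rep("<=", na))
  rhs <- numeric(m + na)
  lower <- c(ifelse(ds > 0, 0, -Inf), rep(0, na))
  upper <- c(ifelse(ds > 0, Inf, 0), rep(1, na))
  obj <- c(numeric(na), rep(1, na))
  sol <- lp_exact(obj, mat, dir, rhs, lower, upper, maximize = TRUE)
  if (sol$status != "optimal") {
    stop(sprintf("loop-detection LP failed with status '%s'", sol$status),
         call. = FALSE)
  }
  if (sol$objective_rq$n <= 0) return(NULL)
  x_rq <- list(n = sol$x_rq$n[seq_len(na)], d = sol$x_rq$d[seq_len(na)])
  xi <- rq_smallest_int(x_rq)
  witness <- numeric(length(network$reaction_ids))
  names(witness) <- network$reaction_ids
  witness[which(network$internal)[act]] <- xi
  # exact post-verification: mass balance and sign consistency
  if (!is_loop(network, witness)) {
    stop("internal error: LP witness failed exact loop verification", call. = FALSE)
  }
  ws <- sign(witness)
  if (!all(ws == 0 | ws == unclass(d_full))) {
    stop("internal error: LP witness is not sign-consistent with v", call. = FALSE)
  }
  loop_vector(witness, d_full)
}
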