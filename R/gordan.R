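# Gordan certificates.
#
# Gordan's theorem of the alternative: for any matrix A, exactly one of
#   (a) a nonzero x >= 0 with A x = 0 exists,
#   (b) a y with A^T y > 0 exists.
# Reduced through the sign pattern d of a flux distribution (drop inactive
# columns, negate backward ones), side (a) becomes "v contains a loop" and
# side (b) becomes the loopless-COBRA constraint: metabolite potentials y
# whose induced reaction energies G = S_int^T y strictly oppose every
# active flux direction.  The strict inequalities are encoded as >= 1,
# which is lossless because the solution set is an open cone.

#' Column reduction of a matrix by a sign pattern
#'
#' Builds the matrix \eqn{\hat A}: columns of `A` with \eqn{d_i = 0}
#' removed and columns with \eqn{d_i = -1} negated, order preserved.
#' This reduction carries both sides of Gordan's theorem between the
#' all-nonnegative form and the sign-consistent form.
#'
#' @param A numeric matrix.
#' @param d a [sign_pattern()] (or -1/0/+1 vector) of length `ncol(A)`.
#' @return an object of class `reduced_matrix`: list with `matrix`
#'   (\eqn{\hat A}) and `column_map` (original index of each retained
#'   column).
#' @export
reduce_matrix <- function(A, d) {
  A <- as.matrix(A)
  d <- as_sign_pattern(d)
  if (length(d) != ncol(A)) {
    stop(sprintf("sign pattern has length %d but A has %d columns",
                 length(d), ncol(A)), call. = FALSE)
  }
  keep <- which(unclass(d) != 0)
  Ahat <- A[, keep, drop = FALSE]
  neg <- unclass(d)[keep] == -1L
  if (any(neg)) Ahat[, neg] <- -Ahat[, neg, drop = FALSE]
  structure(list(matrix = Ahat, column_map = keep), class = "reduced_matrix")
}

#' Construct a Gordan certificate object
#'
#' @param y metabolite potential vector (analog of formation energies).
#' @param G reaction energy vector `t(A) %*% y` (analog of reaction Gibbs
#'   energies).
#' @param pattern the certified [sign_pattern()].
#' @param verified logical: did the exact sign check pass.
#' @return object of class `gordan_certificate`.
#' @export
gordan_certificate <- function(y, G, pattern, verified = FALSE) {
  structure(list(y = y, G = G, pattern = pattern, verified = verified),
            class = "gordan_certificate")
}

#' @export
print.gordan_certificate <- function(x, ...) {
  cat(sprintf("Gordan certificate (%sverified)\n", if (x$verified) "" else "NOT "))
  cat("  y:", paste(format(x$y), collapse = " "), "\n")
  cat("  G:", paste(format(x$G), collapse = " "), "\n")
  invisible(x)
}

#' Find a certificate of looplessness for a sign pattern
#'
#' Searches for metabolite potentials `y` such that for every active
#' column i (\eqn{d_i \ne 0}) the reaction energy \eqn{(A^T y)_i} has
#' sign \eqn{-d_i}.  The search LP asks for \eqn{\hat A^T(-y) \ge 1}
#' componentwise on the reduced matrix; the unit lower bound is valid
#' because any strictly positive solution of the open cone scales to it.
#' The returned `y` is scaled to smallest integer form (certificates are
#' scale-free) and re-verified exactly.
#'
#' @inheritParams reduce_matrix
#' @return a verified [gordan_certificate()], or `NULL` when none exists
#'   (equivalently: when the sign pattern admits a loop).
#' @export
find_certificate <- function(A, d) {
  A <- as.matrix(A)
  d <- as_sign_pattern(d)
  red <- reduce_matrix(A, d)
  m <- nrow(A)
  if (ncol(red$matrix) == 0) {
    # vacuous: no constrained component
    y <- numeric(m)
    G <- numeric(ncol(A))
    return(gordan_certificate(y, G, d, verified = TRUE))
  }
  mat <- -t(red$matrix)
  sol <- lp_exact(numeric(m), mat, rep(">=", ncol(red$matrix)),
                  rep(1, ncol(red$matrix)), lower = -Inf, upper = Inf)
  if (sol$status == "infeasible") return(NULL)
  if (sol$status != "optimal") {
    stop(sprintf("certificate LP failed with status '%s'", sol$status), call. = FALSE)
  }
  y <- rq_smallest_int(sol$x_rq)
  G <- exact_mat_t_vec(A, y)
  ok <- verify_certificate(A, d, y)
  if (!ok) stop("internal error: certificate LP solution failed exact verification", call. = FALSE)
  gordan_certificate(y, G, d, verified = TRUE)
}

# exact t(A) %*% y for rational inputs, returned as numeric
exact_mat_t_vec <- function(A, y) {
  A <- as.matrix(A)
  yr <- rq_from_num(as.numeric(y))
  out <- numeric(ncol(A))
  for (j in seq_len(ncol(A))) {
    out[j] <- rq_to_num(rq_dot(rq_from_num(A[, j]), yr))
  }
  names(out) <- colnames(A)
  out
}

#' Verify a certificate of looplessness
#'
#' Exact check that \eqn{sign((A^T y)_i) = -d_i} for every i with
#' \eqn{d_i \ne 0}.  Components with \eqn{d_i = 0} are unconstrained.
#'
#' @inheritParams reduce_matrix
#' @param y candidate potential vector of length `nrow(A)`.
#' @return logical scalar.
#' @export
verify_certificate <- function(A, d, y) {
  A <- as.matrix(A)
  d <- as_sign_pattern(d)
  if (length(d) != ncol(A)) {
    stop("sign pattern length does not match ncol(A)", call. = FALSE)
  }
  if (length(y) != nrow(A)) {
    stop(sprintf("y has length %d but A has %d rows", length(y), nrow(A)),
         call. = FALSE)
  }
  yr <- rq_from_num(as.numeric(y))
  for (i in which(unclass(d) != 0)) {
    Gi <- rq_dot(rq_from_num(A[, i]), yr)
    if (sign(Gi$n) != -unclass(d)[i]) return(FALSE)
  }
  TRUE
}

#' Check the Gordan dichotomy for a matrix and sign pattern
#'
#' Runs both the brute-force loop enumeration (side (a)) and the
#' certificate search (side (b)) and returns which side holds.  By
#' Gordan's theorem exactly one must; observing both or neither is an
#' implementation bug, never a valid state, and raises an error carrying
#' a diagnostic dump of both artifacts.
#'
#' @inheritParams enumerate_loops_bruteforce
#' @return `"loop_exists"` or `"certificate_exists"`, with the witness
#'   attached as attribute `witness`.
#' @export
check_dichotomy <- function(A, d, circuits = NULL) {
  A <- as.matrix(A)
  d <- as_sign_pattern(d)
  loops <- enumerate_loops_bruteforce(A, d, circuits)
  cert <- find_certificate(A, d)
  has_loop <- length(loops) > 0
  has_cert <- !is.null(cert)
  if (has_loop == has_cert) {
    stop(paste0("Gordan dichotomy violated (implementation bug): ",
                if (has_loop) "both a loop and a certificate exist"
                else "neither a loop nor a certificate exists",
                "\nA = ", paste(capture_matrix(A), collapse = "; "),
                "\nd = ", paste(unclass(d), collapse = " ")),
         call. = FALSE)
  }
  if (has_loop) {
    structure("loop_exists", witness = loops[[1]])
  } else {
    structure("certificate_exists", witness = cert)
  }
}

capture_matrix <- function(A) {
  apply(A, 1, function(r) paste(r, collapse = " "))
}

#' Map metabolite potentials to reaction energies
#'
#' Computes \eqn{G = S_{int}^T y} for a network: the reaction-energy
#' vector induced on internal reactions by metabolite potentials `y`.
#' By construction `G` lies in the row space of \eqn{S_{int}}, so
#' [nullspace_orthogonality_check()] on it is always `TRUE`.
#'
#' @param network a `stoich_network`.
#' @param y numeric vector of length m (one potential per metabolite).
#' @return numeric vector `G` of length n_int, named by internal reaction
#'   id.
#' @export
potentials_to_reaction_energies <- function(network, y) {
  stopifnot(inherits(network, "stoich_network"))
  if (length(y) != length(network$metabolite_ids)) {
    stop(sprintf("y has length %d but the network has %d metabolites",
                 length(y), length(network$metabolite_ids)), call. = FALSE)
  }
  exact_mat_t_vec(internal_submatrix(network), y)
}

#' Serialize a certificate to JSON
#'
#' @param cert a [gordan_certificate()].
#' @return a JSON string `{pattern, y, G, verified}`.
#' @export
certificate_to_json <- function(cert) {
  stopifnot(inherits(cert, "gordan_certificate"))
  jsonlite::toJSON(list(pattern = as.integer(unclass(cert$pattern)),
                        y = cert$y,
                        G = cert$G,
                        verified = cert$verified),
                   auto_unbox = TRUE, digits = NA)
}
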