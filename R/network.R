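# Core data model: stoichiometric networks, flux distributions and sign
# patterns.
#
# Conventions follow constraint-based modeling practice: rows of S are
# metabolites, columns are reactions, S %*% v = 0 is the steady-state
# condition over the *full* matrix, and the internal/exchange partition
# selects the submatrix S_int to which the loop law applies.  Reactions
# and metabolites are identified by string ids and every vector is keyed,
# so a permuted flux vector is an error rather than a silent bug.

#' Construct a stoichiometric network
#'
#' @param stoich numeric m x n matrix (rows = metabolites, columns =
#'   reactions) of exactly rational stoichiometric coefficients.
#' @param internal logical vector of length n: `TRUE` marks internal
#'   reactions (the columns of \eqn{S_{int}}).  If `NULL`, the
#'   single-nonzero-column heuristic of [classify_reactions()] is applied.
#' @param lower,upper flux bounds per reaction, recycled; defaults
#'   `-1000`/`1000` (the usual COBRA convention for "effectively
#'   unbounded").
#' @param metabolite_ids,reaction_ids identifiers; taken from `dimnames`
#'   when present, otherwise `M1..Mm` / `R1..Rn`.
#' @return an object of class `stoich_network` with fields
#'   `metabolite_ids`, `reaction_ids`, `stoich`, `internal`, `lower`,
#'   `upper`.
#' @examples
#' net <- figure2_network()
#' net
#' internal_submatrix(net)
#' @export
stoichiometric_network <- function(stoich, internal = NULL,
                                   lower = -1000, upper = 1000,
                                   metabolite_ids = NULL, reaction_ids = NULL) {
  stoich <- as.matrix(stoich)
  m <- nrow(stoich)
  n <- ncol(stoich)
  if (m < 1 || n < 1) stop("network needs at least one metabolite and one reaction", call. = FALSE)
  if (is.null(metabolite_ids)) metabolite_ids <- rownames(stoich)
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(m))
  if (is.null(reaction_ids)) reaction_ids <- colnames(stoich)
  if (is.null(reaction_ids)) reaction_ids <- paste0("R", seq_len(n))
  if (length(metabolite_ids) != m || length(reaction_ids) != n) {
    stop("id vectors do not match the matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(metabolite_ids)) stop("duplicated metabolite ids", call. = FALSE)
  if (anyDuplicated(reaction_ids)) stop("duplicated reaction ids", call. = FALSE)
  rq_from_num(stoich)  # validates exact representability
  if (is.null(internal)) {
    internal <- classify_reactions(stoich)
  } else {
    internal <- rep_len(as.logical(internal), n)
    zero_cols <- which(colSums(stoich != 0) == 0)
    if (length(zero_cols)) {
      stop(sprintf("reaction '%s' has an all-zero stoichiometry column",
                   reaction_ids[zero_cols[1]]), call. = FALSE)
    }
  }
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (any(lower > upper)) {
    bad <- which(lower > upper)[1]
    stop(sprintf("reaction '%s': lower bound exceeds upper bound", reaction_ids[bad]),
         call. = FALSE)
  }
  dimnames(stoich) <- list(metabolite_ids, reaction_ids)
  names(internal) <- reaction_ids
  names(lower) <- reaction_ids
  names(upper) <- reaction_ids
  structure(list(metabolite_ids = metabolite_ids,
                 reaction_ids = reaction_ids,
                 stoich = stoich,
                 internal = internal,
                 lower = lower,
                 upper = upper),
            class = "stoich_network")
}

#' @export
print.stoich_network <- function(x, ...) {
  cat(sprintf("Stoichiometric network: %d metabolites x %d reactions (%d internal, %d exchange)\n",
              length(x$metabolite_ids), length(x$reaction_ids),
              sum(x$internal), sum(!x$internal)))
  invisible(x)
}

#' Internal-reaction submatrix
#'
#' Returns the columns of the full stoichiometric matrix that belong to
#' internal reactions, in original column order: the matrix \eqn{S_{int}}
#' whose null space is the loop space of the network.
#'
#' @param network a `stoich_network`.
#' @return an m x n_int numeric matrix (possibly with zero columns when no
#'   reaction is internal).
#' @export
internal_submatrix <- function(network) {
  stopifnot(inherits(network, "stoich_network"))
  network$stoich[, network$internal, drop = FALSE]
}

#' Heuristic internal/exchange classification
#'
#' A column with exactly one nonzero entry moves a single metabolite
#' across the system boundary and is classified as an exchange reaction;
#' every other column is internal.  This is a community convention for
#' unlabeled models, not a property of the loop law; explicit labels
#' passed to [stoichiometric_network()] always take precedence.
#'
#' @param stoich numeric stoichiometric matrix.
#' @return logical vector, `TRUE` for internal reactions.
#' @export
classify_reactions <- function(stoich) {
  stoich <- as.matrix(stoich)
  if (nrow(stoich) == 0 || ncol(stoich) == 0) stop("empty stoichiometric matrix", call. = FALSE)
  nnz <- colSums(stoich != 0)
  if (any(nnz == 0)) {
    bad <- which(nnz == 0)[1]
    id <- colnames(stoich)[bad]
    if (is.null(id)) id <- paste0("column ", bad)
    stop(sprintf("reaction '%s' has an all-zero stoichiometry column", id), call. = FALSE)
  }
  out <- nnz != 1
  if (!is.null(colnames(stoich))) names(out) <- colnames(stoich)
  out
}

#' Construct a flux distribution
#'
#' A flux vector keyed by reaction id, together with the nonnegative
#' tolerance used to classify the sign of each (generally floating-point)
#' flux value.
#'
#' @param values numeric vector, ideally named by reaction id.
#' @param tolerance nonnegative threshold: `|value| <= tolerance` is
#'   treated as zero flux.  Default `1e-9`, matching typical LP solver
#'   feasibility tolerances.
#' @return an object of class `flux_distribution`.
#' @export
flux_distribution <- function(values, tolerance = 1e-9) {
  if (!is.numeric(values)) stop("flux values must be numeric", call. = FALSE)
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance < 0) {
    stop("tolerance must be a single nonnegative number", call. = FALSE)
  }
  structure(list(values = values, tolerance = tolerance),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("Flux distribution over %d reactions (sign tolerance %g)\n",
              length(x$values), x$tolerance))
  print(x$values)
  invisible(x)
}

# align a flux distribution (or numeric vector) with a network's reactions
match_flux <- function(network, v) {
  vals <- if (inherits(v, "flux_distribution")) v$values else v
  n <- length(network$reaction_ids)
  if (!is.null(names(vals))) {
    missing <- setdiff(network$reaction_ids, names(vals))
    if (length(missing)) {
      stop(sprintf("flux vector is missing reactions: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    extra <- setdiff(names(vals), network$reaction_ids)
    if (length(extra)) {
      stop(sprintf("flux vector has unknown reactions: %s",
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    vals <- vals[network$reaction_ids]
  } else if (length(vals) != n) {
    stop(sprintf("flux vector has length %d but the network has %d reactions",
                 length(vals), n), call. = FALSE)
  } else {
    names(vals) <- network$reaction_ids
  }
  vals
}

#' Sign pattern of a flux distribution
#'
#' Maps each flux value to -1, 0 or +1: `+1` if `value > tolerance`, `-1`
#' if `value < -tolerance`, `0` otherwise.  Only these signs — never the
#' magnitudes — enter any loop-law decision, so the pattern is invariant
#' under positive rescaling of the fluxes.
#'
#' @param v a [flux_distribution()], or a numeric vector.
#' @param tolerance sign threshold used when `v` is a bare numeric vector
#'   (a `flux_distribution` carries its own).
#' @return an object of class `sign_pattern`: an integer vector with
#'   entries in \{-1, 0, +1\}.
#' @export
sign_pattern <- function(v, tolerance = 1e-9) {
  if (inherits(v, "sign_pattern")) return(v)
  if (inherits(v, "flux_distribution")) {
    tolerance <- v$tolerance
    v <- v$values
  }
  if (!is.numeric(v)) stop("cannot compute a sign pattern from this object", call. = FALSE)
  s <- integer(length(v))
  s[v > tolerance] <- 1L
  s[v < -tolerance] <- -1L
  names(s) <- names(v)
  structure(s, class = "sign_pattern")
}

#' Coerce a -1/0/+1 vector to a sign pattern
#'
#' @param x numeric or integer vector with entries in \{-1, 0, +1\}.
#' @return a `sign_pattern`.
#' @export
as_sign_pattern <- function(x) {
  if (inherits(x, "sign_pattern")) return(x)
  if (!all(x %in% c(-1, 0, 1))) {
    stop("sign pattern entries must be -1, 0 or +1", call. = FALSE)
  }
  structure(as.integer(x), names = names(x), class = "sign_pattern")
}

#' @export
print.sign_pattern <- function(x, ...) {
  cat("Sign pattern: ")
  cat(paste0(c("-", "0", "+")[unclass(x) + 2L], collapse = ""), "\n")
  invisible(x)
}
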