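# Loopless flux balance analysis.
#
# Plain FBA maximizes an objective flux under S v = 0 and bounds.  The
# loopless variant additionally requires, per internal reaction, a
# reaction energy G_i of sign opposite to v_i whenever v_i != 0, with G
# constrained either to be orthogonal to null(S_int) ("nullspace"
# formulation) or to lie in image(S_int^T) via free metabolite potentials
# y ("image" formulation, the default: models usually have fewer
# metabolites than reactions).  The two formulations are equivalent by
# the fundamental theorem of linear algebra, and
# check_formulation_equivalence() verifies that on concrete inputs.
#
# The direction binaries are handled by explicit enumeration/branching
# over sign assignments, each node an exact LP, rather than by a big-M
# MILP solver: the environment ships none, the problems are desk-scale,
# and enumeration keeps the arithmetic exact.  The big-M/energy-bound
# parameters are validated and used in the LP-format export, which
# mirrors the conventional indicator encoding.

#' Plain flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction under the
#' steady-state constraint \eqn{S v = 0} over the full matrix and the
#' network's flux bounds.  Solved by the exact simplex.
#'
#' @param network a `stoich_network`.
#' @param objective reaction id to optimize.
#' @param maximize logical, default `TRUE`.
#' @return list with `status`, `flux` (a [flux_distribution()]) and
#'   `objective_value`.
#' @export
solve_fba <- function(network, objective, maximize = TRUE) {
  stopifnot(inherits(network, "stoich_network"))
  oi <- match(objective, network$reaction_ids)
  if (is.na(oi)) stop(sprintf("unknown objective reaction '%s'", objective), call. = FALSE)
  n <- length(network$reaction_ids)
  obj <- numeric(n)
  obj[oi] <- 1
  sol <- lp_exact(obj, network$stoich, rep("=", nrow(network$stoich)),
                  numeric(nrow(network$stoich)),
                  lower = network$lower, upper = network$upper,
                  maximize = maximize)
  if (sol$status != "optimal") {
    return(list(status = sol$status, flux = NULL, objective_value = NA_real_))
  }
  v <- sol$x
  names(v) <- network$reaction_ids
  list(status = "optimal",
       flux = flux_distribution(v),
       objective_value = sol$objective,
       objective_rq = sol$objective_rq)
}

#' Build a loopless-FBA problem
#'
#' Assembles the mixed-integer problem that maximizes an objective flux
#' subject to \eqn{S v = 0}, flux bounds, one direction binary
#' \eqn{a_i} per internal reaction (\eqn{a_i = 1}: \eqn{v_i \ge 0} and
#' \eqn{G_i \le -1}; \eqn{a_i = 0}: \eqn{v_i \le 0} and
#' \eqn{G_i \ge 1}, with \eqn{|G_i| \le K}), and the formulation-specific
#' coupling of G: `"nullspace"` adds one row \eqn{b \cdot G = 0} per
#' null-space basis vector of \eqn{S_{int}}; `"image"` adds free
#' potentials y and the identity \eqn{G = S_{int}^T y}.
#'
#' @param network a `stoich_network`.
#' @param objective reaction id to maximize.
#' @param formulation `"image"` (default) or `"nullspace"`.
#' @param big_m big-M constant coupling binaries to fluxes in the
#'   exported MILP encoding; default 1000.  A warning is issued when flux
#'   bounds exceed it.
#' @param energy_bound bound K on `|G_i|`; default 1000.  Certificates
#'   live on a cone, so the unit lower magnitude costs no generality,
#'   but an extreme spread of energy ratios beyond K:1 would; at desk
#'   scale this does not occur.
#' @return an object of class `loopless_problem`.
#' @export
build_loopless_milp <- function(network, objective,
                                formulation = c("image", "nullspace"),
                                big_m = 1000, energy_bound = 1000) {
  stopifnot(inherits(network, "stoich_network"))
  formulation <- match.arg(formulation)
  oi <- match(objective, network$reaction_ids)
  if (is.na(oi)) stop(sprintf("unknown objective reaction '%s'", objective), call. = FALSE)
  if (!is.numeric(big_m) || big_m <= 0) stop("big_m must be positive", call. = FALSE)
  if (!is.numeric(energy_bound) || energy_bound <= 0) stop("energy_bound must be positive", call. = FALSE)
  if (any(abs(c(network$lower, network$upper))[is.finite(c(network$lower, network$upper))] > big_m)) {
    warning("some flux bounds exceed big_m; the exported MILP encoding would truncate them")
  }
  n_int <- sum(network$internal)
  nb <- if (n_int > 0) nullspace_basis(internal_submatrix(network)) else NULL
  structure(list(network = network,
                 objective = objective,
                 objective_index = oi,
                 formulation = formulation,
                 big_m = big_m,
                 energy_bound = energy_bound,
                 n_int = n_int,
                 nullspace = nb,
                 type = if (n_int > 0) "loopless" else "fba"),
            class = "loopless_problem")
}

#' @export
print.loopless_problem <- function(x, ...) {
  cat(sprintf("Loopless-FBA problem: objective '%s', %s formulation, %d direction binaries\n",
              x$objective, x$formulation, x$n_int))
  invisible(x)
}

# LP for one fixed assignment of direction binaries.
# a: 0/1 vector over internal reactions.
.loopless_node_lp <- function(problem, a) {
  net <- problem$network
  n <- length(net$reaction_ids)
  n_int <- problem$n_int
  m <- length(net$metabolite_ids)
  Sint <- internal_submatrix(net)
  int_idx <- which(net$internal)
  K <- problem$energy_bound
  image <- problem$formulation == "image"
  ny <- if (image) m else 0
  nv <- n + n_int + ny  # v, G, (y)

  lower <- c(net$lower, ifelse(a == 1, -K, 1), rep(-Inf, ny))
  upper <- c(net$upper, ifelse(a == 1, -1, K), rep(Inf, ny))
  lower[int_idx] <- pmax(net$lower[int_idx], ifelse(a == 1, 0, -Inf))
  upper[int_idx] <- pmin(net$upper[int_idx], ifelse(a == 1, Inf, 0))
  if (any(lower > upper)) return(list(status = "infeasible"))

  rows <- list()
  Sfull <- matrix(0, m, nv)
  Sfull[, seq_len(n)] <- net$stoich
  dirs <- rep("=", m)
  rhs <- numeric(m)
  if (image) {
    # G - S_int^T y = 0
    C <- matrix(0, n_int, nv)
    C[, n + seq_len(n_int)] <- diag(1, n_int)
    C[, n + n_int + seq_len(m)] <- -t(Sint)
    Sfull <- rbind(Sfull, C)
    dirs <- c(dirs, rep("=", n_int))
    rhs <- c(rhs, numeric(n_int))
  } else {
    B <- problem$nullspace$basis
    if (ncol(B) > 0) {
      C <- matrix(0, ncol(B), nv)
      C[, n + seq_len(n_int)] <- t(B)
      Sfull <- rbind(Sfull, C)
      dirs <- c(dirs, rep("=", ncol(B)))
      rhs <- c(rhs, numeric(ncol(B)))
    }
  }
  obj <- numeric(nv)
  obj[problem$objective_index] <- 1
  sol <- lp_exact(obj, Sfull, dirs, rhs, lower, upper, maximize = TRUE)
  sol$n <- n
  sol$n_int <- n_int
  sol$ny <- ny
  sol
}

#' Solve a loopless-FBA problem
#'
#' Enumerates direction-binary assignments (branching over the sign of
#' each internal reaction), solves each node as an exact LP, and returns
#' the best loop-free optimum.  As a fast path, if the plain-FBA optimum
#' is already loop-free it is returned directly, and enumeration stops
#' early once a node reaches the plain-FBA bound.  The returned flux
#' distribution is re-verified loop-free by [find_loop()]; a failure
#' there raises instead of returning (it would be a bug, not data).
#'
#' @param problem a [build_loopless_milp()] problem.
#' @return an object of class `loopless_solution`: list with `status`,
#'   `flux`, `objective_value`, `plain_objective`, `formulation`,
#'   `binaries`, `G`, `y`, `trivial` (is v identically zero) and
#'   `loop_free` (result of the post-hoc exact loop check).
#' @export
solve_loopless_fba <- function(problem) {
  stopifnot(inherits(problem, "loopless_problem"))
  net <- problem$network
  plain <- solve_fba(net, problem$objective)
  if (plain$status != "optimal") {
    return(structure(list(status = plain$status, flux = NULL,
                          objective_value = NA_real_,
                          plain_objective = NA_real_,
                          formulation = problem$formulation),
                     class = "loopless_solution"))
  }
  if (problem$type == "fba" ||
      is.null(find_loop(net, flux_distribution(plain$flux$values, tolerance = 0)))) {
    v <- plain$flux$values
    return(structure(list(status = "optimal",
                          flux = plain$flux,
                          objective_value = plain$objective_value,
                          plain_objective = plain$objective_value,
                          formulation = problem$formulation,
                          binaries = NULL, G = NULL, y = NULL,
                          trivial = all(v == 0),
                          loop_free = TRUE),
                     class = "loopless_solution"))
  }
  n_int <- problem$n_int
  if (n_int > 16) {
    stop("refusing to enumerate more than 2^16 direction assignments; genome-scale performance is a non-goal",
         call. = FALSE)
  }
  best <- NULL
  unbounded <- FALSE
  assignments <- lapply(0:(2^n_int - 1), function(code) {
    as.integer(intToBits(code))[seq_len(n_int)]
  })
  # try the assignment suggested by the plain-FBA signs first
  keys <- vapply(assignments, paste, "", collapse = "")
  first_key <- paste(as.integer(plain$flux$values[net$internal] >= 0), collapse = "")
  assignments <- assignments[order(keys != first_key)]
  for (a in assignments) {
    sol <- .loopless_node_lp(problem, a)
    if (sol$status == "unbounded") { unbounded <- TRUE; break }
    if (sol$status != "optimal") next
    if (is.null(best) || rq_cmp(sol$objective_rq, best$objective_rq) > 0) {
      best <- sol
      best$binaries <- a
    }
    if (rq_cmp(best$objective_rq, plain$objective_rq) >= 0) break
  }
  if (unbounded) {
    return(structure(list(status = "unbounded", flux = NULL,
                          objective_value = NA_real_,
                          plain_objective = plain$objective_value,
                          formulation = problem$formulation),
                     class = "loopless_solution"))
  }
  if (is.null(best)) {
    return(structure(list(status = "infeasible", flux = NULL,
                          objective_value = NA_real_,
                          plain_objective = plain$objective_value,
                          formulation = problem$formulation),
                     class = "loopless_solution"))
  }
  n <- best$n
  v <- best$x[seq_len(n)]
  names(v) <- net$reaction_ids
  G <- best$x[n + seq_len(n_int)]
  names(G) <- net$reaction_ids[net$internal]
  y <- if (best$ny > 0) best$x[n + n_int + seq_len(best$ny)] else NULL
  if (!is.null(y)) names(y) <- net$metabolite_ids
  fd <- flux_distribution(v, tolerance = 0)
  if (!is.null(find_loop(net, fd))) {
    stop("loopless-FBA returned a flux distribution that still contains a loop (implementation bug)",
         call. = FALSE)
  }
  structure(list(status = "optimal",
                 flux = flux_distribution(v),
                 objective_value = best$objective,
                 plain_objective = plain$objective_value,
                 formulation = problem$formulation,
                 binaries = best$binaries,
                 G = G, y = y,
                 trivial = all(v == 0),
                 loop_free = TRUE),
            class = "loopless_solution")
}

#' @export
print.loopless_solution <- function(x, ...) {
  cat(sprintf("Loopless-FBA solution: status %s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", objective %g (plain FBA: %g), %s formulation",
                x$objective_value, x$plain_objective, x$formulation))
    if (isTRUE(x$trivial)) cat(" [trivial v = 0]")
  }
  cat("\n")
  if (!is.null(x$flux)) print(x$flux$values)
  invisible(x)
}

#' Check equivalence of the two loopless formulations
#'
#' For a fixed sign pattern `d` over the internal reactions, tests
#' feasibility of the reaction-energy system in both forms: G orthogonal
#' to every null-space basis vector of \eqn{S_{int}} (nullspace
#' formulation) versus \eqn{G = S_{int}^T y} with free y (image
#' formulation), in both cases with \eqn{sign(G_i) = -d_i} on active
#' reactions (encoded as \eqn{|G_i| \ge 1}, lossless on a cone).
#' Returns `TRUE` iff the two feasibility verdicts agree — which the
#' fundamental theorem of linear algebra says they always must.
#'
#' @param network a `stoich_network`.
#' @param d a [sign_pattern()] over internal reactions (length n_int), or
#'   over all reactions (length n; exchange entries are ignored).
#' @return logical, with attributes `nullspace` and `image` carrying the
#'   two feasibility verdicts.
#' @export
check_formulation_equivalence <- function(network, d) {
  stopifnot(inherits(network, "stoich_network"))
  Sint <- internal_submatrix(network)
  n_int <- ncol(Sint)
  if (n_int < 1) stop("network has no internal reactions", call. = FALSE)
  d <- as_sign_pattern(d)
  if (length(d) == length(network$reaction_ids)) {
    d <- as_sign_pattern(unclass(d)[network$internal])
  }
  if (length(d) != n_int) {
    stop("sign pattern must cover the internal reactions", call. = FALSE)
  }
  ds <- unclass(d)
  g_lower <- ifelse(ds == 1, -Inf, ifelse(ds == -1, 1, -Inf))
  g_upper <- ifelse(ds == 1, -1, ifelse(ds == -1, Inf, Inf))

  # nullspace formulation: variables G
  B <- nullspace_basis(Sint)$basis
  ns_sol <- if (ncol(B) > 0) {
    lp_exact(numeric(n_int), t(B), rep("=", ncol(B)), numeric(ncol(B)),
             lower = g_lower, upper = g_upper)
  } else {
    lp_exact(numeric(n_int), NULL, character(), numeric(),
             lower = g_lower, upper = g_upper)
  }
  ns_feasible <- ns_sol$status == "optimal"

  # image formulation: variables y, constraints on (S_int^T y)_i
  m <- nrow(Sint)
  act <- which(ds != 0)
  im_feasible <- if (!length(act)) {
    TRUE
  } else {
    mat <- t(Sint)[act, , drop = FALSE]
    dirs <- ifelse(ds[act] == 1, "<=", ">=")
    rhs <- ifelse(ds[act] == 1, -1, 1)
    im_sol <- lp_exact(numeric(m), mat, dirs, rhs, lower = -Inf, upper = Inf)
    im_sol$status == "optimal"
  }
  structure(ns_feasible == im_feasible,
            nullspace = ns_feasible, image = im_feasible)
}

#' Would a flux distribution survive the loopless constraints?
#'
#' `TRUE` iff a Gordan certificate exists for the sign pattern of `v`,
#' i.e. iff the loopless constraints admit `v`.  The package's central
#' contract — soundness and completeness of the loopless constraints —
#' is that this agrees with `is.null(find_loop(network, v))` for every
#' `v`: the constraints remove loops and nothing more.
#'
#' The trivial distribution v = 0 is admissible (vacuous certificate) and
#' flagged via attribute `trivial`.
#'
#' @param network a `stoich_network`.
#' @param v a [flux_distribution()] or numeric flux vector.
#' @return logical, with attributes `certificate` (a
#'   [gordan_certificate()] or `NULL`) and `trivial`.
#' @export
flux_admissible <- function(network, v) {
  stopifnot(inherits(network, "stoich_network"))
  vals <- match_flux(network, v)
  tol <- if (inherits(v, "flux_distribution")) v$tolerance else 1e-9
  d_full <- sign_pattern(vals, tolerance = tol)
  trivial <- all(unclass(d_full) == 0)
  Sint <- internal_submatrix(network)
  d_int <- as_sign_pattern(unclass(d_full)[network$internal])
  cert <- if (ncol(Sint) > 0) find_certificate(Sint, d_int) else
    gordan_certificate(numeric(nrow(network$stoich)), numeric(0),
                       d_int, verified = TRUE)
  structure(!is.null(cert), certificate = cert, trivial = trivial)
}

#' Export a loopless-FBA problem in LP text format
#'
#' Writes the conventional big-M indicator encoding (CPLEX LP format)
#' of the problem, including the binary direction variables, for
#' solver-independent debugging.  The in-package solver does not consume
#' this file; it branches over the binaries exactly.
#'
#' @param problem a [build_loopless_milp()] problem.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_problem_lp <- function(problem, path) {
  stopifnot(inherits(problem, "loopless_problem"))
  net <- problem$network
  n <- length(net$reaction_ids)
  vnames <- paste0("v_", gsub("[^A-Za-z0-9_]", "_", net$reaction_ids))
  int_ids <- net$reaction_ids[net$internal]
  gnames <- paste0("G_", gsub("[^A-Za-z0-9_]", "_", int_ids))
  anames <- paste0("a_", gsub("[^A-Za-z0-9_]", "_", int_ids))
  M <- problem$big_m
  K <- problem$energy_bound
  lines <- c("\\ loopless-FBA big-M encoding", "Maximize",
             sprintf(" obj: %s", vnames[problem$objective_index]),
             "Subject To")
  term <- function(coefs, vars) {
    keep <- coefs != 0
    paste(sprintf("%+g %s", coefs[keep], vars[keep]), collapse = " ")
  }
  for (i in seq_len(nrow(net$stoich))) {
    if (all(net$stoich[i, ] == 0)) next
    lines <- c(lines, sprintf(" mb_%d: %s = 0", i, term(net$stoich[i, ], vnames)))
  }
  int_idx <- which(net$internal)
  for (k in seq_along(int_idx)) {
    vi <- vnames[int_idx[k]]
    lines <- c(lines,
               sprintf(" vub_%d: %s %+g %s <= 0", k, vi, -M, anames[k]),
               sprintf(" vlb_%d: %s %+g %s >= %g", k, vi, -M, anames[k], -M),
               sprintf(" gub_%d: %s %+g %s <= %g", k, gnames[k], K + 1, anames[k], K),
               sprintf(" glb_%d: %s %+g %s >= %g", k, gnames[k], K + 1, anames[k], 1))
  }
  if (problem$formulation == "nullspace") {
    B <- problem$nullspace$basis
    for (j in seq_len(ncol(B))) {
      lines <- c(lines, sprintf(" ns_%d: %s = 0", j, term(B[, j], gnames)))
    }
  } else {
    Sint <- internal_submatrix(net)
    ynames <- paste0("y_", gsub("[^A-Za-z0-9_]", "_", net$metabolite_ids))
    for (k in seq_along(int_idx)) {
      lines <- c(lines, sprintf(" im_%d: %s %s = 0", k, gnames[k],
                                term(-Sint[, k], ynames)))
    }
  }
  lines <- c(lines, "Bounds")
  for (j in seq_len(n)) {
    lines <- c(lines, sprintf(" %g <= %s <= %g", net$lower[j], vnames[j], net$upper[j]))
  }
  for (k in seq_along(int_idx)) {
    lines <- c(lines, sprintf(" %g <= %s <= %g", -K, gnames[k], K))
  }
  if (problem$formulation == "image") {
    ynames <- paste0("y_", gsub("[^A-Za-z0-9_]", "_", net$metabolite_ids))
    lines <- c(lines, sprintf(" %s free", ynames))
  }
  lines <- c(lines, "Binary", paste(" ", anames, collapse = ""), "End")
  writeLines(lines, path)
  invisible(path)
}
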