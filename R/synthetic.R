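# Synthetic test networks.
#
# Everything the test suites need is generated in code: the classic
# three-metabolite cycle toy network, parametric k-cycles, and random
# integer-stoichiometry networks with loops planted by construction.
# Randomness comes from a dedicated Lehmer generator owned by this
# module, so generation is bit-reproducible for a given seed and never
# touches R's global random state.

# minimal-standard Lehmer LCG; returns a function drawing uniform
# integers in 1..k
.lcg <- function(seed) {
  state <- (abs(as.numeric(seed)) %% 2147483646) + 1
  function(k) {
    state <<- (16807 * state) %% 2147483647
    as.integer(floor((state - 1) / 2147483646 * k)) + 1L
  }
}

# Fisher-Yates sample of `k` distinct values from 1..n using rng
.lcg_sample <- function(rng, n, k) {
  pool <- seq_len(n)
  out <- integer(k)
  for (i in seq_len(k)) {
    j <- rng(length(pool))
    out[i] <- pool[j]
    pool <- pool[-j]
  }
  out
}

#' The three-metabolite cycle toy network
#'
#' Three metabolites connected in a directed cycle by three internal
#' reactions (`x2`: M1 -> M2, `x3`: M2 -> M3, `x4`: M3 -> M1) plus one
#' exchange reaction `x1` feeding M1.  The internal submatrix has a
#' one-dimensional null space spanned by (1, 1, 1): running all three
#' cycle reactions at equal rate transforms nothing, which is exactly
#' the thermodynamically infeasible loop the loop law forbids.
#'
#' @return a `stoich_network`.
#' @examples
#' net <- figure2_network()
#' nullspace_basis(internal_submatrix(net))
#' @export
figure2_network <- function() {
  S <- matrix(c(1, -1,  0,  1,
                0,  1, -1,  0,
                0,  0,  1, -1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("M1", "M2", "M3"),
                              c("x1", "x2", "x3", "x4")))
  stoichiometric_network(S, internal = c(FALSE, TRUE, TRUE, TRUE))
}

#' Parametric directed-cycle network
#'
#' Generalizes [figure2_network()] to a k-cycle: k metabolites, k
#' internal reactions `I1..Ik` with `Ii`: Mi -> M(i+1) (indices wrapping),
#' and one exchange reaction feeding M1.  The null space of the internal
#' submatrix is spanned by the all-ones vector.
#'
#' @param k integer >= 2, cycle length.
#' @return a `stoich_network`.
#' @export
make_cycle_network <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 2 || k != round(k)) {
    stop("k must be an integer >= 2", call. = FALSE)
  }
  k <- as.integer(k)
  S <- matrix(0, k, k + 1,
              dimnames = list(paste0("M", seq_len(k)),
                              c(paste0("I", seq_len(k)), "EX1")))
  for (i in seq_len(k)) {
    S[i, i] <- -1
    S[i %% k + 1, i] <- 1
  }
  S[1, k + 1] <- 1
  stoichiometric_network(S, internal = c(rep(TRUE, k), FALSE))
}

#' Random network with planted loops
#'
#' Generates an integer-stoichiometry network (entries in -2..2):
#' `n_planted_loops` directed cycles of length 2 or 3 built from disjoint
#' internal reaction columns (so each planted loop vector is known by
#' construction), the remaining internal columns filled with random
#' coefficients (always at least two nonzeros, so the exchange heuristic
#' never misfires), and `n_exch` single-entry exchange columns.
#' Internal columns are shuffled to avoid positional artifacts.
#'
#' Planting guarantees *presence* of the recorded loops, never absence of
#' others: random columns can close accidental cycles, so loop-freeness
#' of `n_planted_loops = 0` instances must be certified post hoc by
#' [enumerate_loops_bruteforce()], which is exactly what the property
#' suites do.
#'
#' @param m number of metabolites (>= 2).
#' @param n_int number of internal reactions (>= 2 * `n_planted_loops`).
#' @param n_exch number of exchange reactions (>= 0).
#' @param n_planted_loops number of planted cycles.
#' @param seed integer seed for the module's own generator.
#' @return an object of class `planted_network`: list with `network`,
#'   `planted_loops` (list of [loop_vector()], each exact-verified by
#'   [is_loop()] at generation time) and `seed`.
#' @export
random_network <- function(m, n_int, n_exch = 1, n_planted_loops = 0, seed = 1) {
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  if (n_int < 1) stop("n_int must be >= 1", call. = FALSE)
  if (n_planted_loops < 0 || n_int < 2 * n_planted_loops) {
    stop("need n_int >= 2 * n_planted_loops", call. = FALSE)
  }
  if (n_exch < 0) stop("n_exch must be >= 0", call. = FALSE)
  rng <- .lcg(seed)
  cols <- list()
  loop_members <- list()
  used <- 0L
  for (j in seq_len(n_planted_loops)) {
    left <- n_planted_loops - j
    room <- n_int - used - 2L * left
    len <- if (room >= 3 && m >= 3 && rng(2) == 2) 3L else 2L
    mets <- .lcg_sample(rng, m, len)
    idx <- integer(len)
    for (s in seq_len(len)) {
      col <- numeric(m)
      col[mets[s]] <- -1
      col[mets[s %% len + 1]] <- 1
      cols[[length(cols) + 1L]] <- col
      idx[s] <- length(cols)
    }
    loop_members[[j]] <- idx
    used <- used + len
  }
  vals <- c(-2, -1, 1, 2)
  while (length(cols) < n_int) {
    nnz <- min(m, 1L + rng(2))  # 2 or 3 nonzeros
    rows <- .lcg_sample(rng, m, nnz)
    col <- numeric(m)
    for (r in rows) col[r] <- vals[rng(4)]
    cols[[length(cols) + 1L]] <- col
  }
  perm <- .lcg_sample(rng, n_int, n_int)
  inv <- order(perm)
  Sint <- do.call(cbind, cols)[, perm, drop = FALSE]
  Sx <- matrix(0, m, n_exch)
  for (e in seq_len(n_exch)) {
    Sx[rng(m), e] <- c(-1, 1)[rng(2)]
  }
  S <- cbind(Sint, Sx)
  rownames(S) <- paste0("M", seq_len(m))
  colnames(S) <- c(paste0("I", seq_len(n_int)),
                   if (n_exch > 0) paste0("E", seq_len(n_exch)))
  net <- stoichiometric_network(S, internal = c(rep(TRUE, n_int), rep(FALSE, n_exch)))
  planted <- list()
  for (j in seq_along(loop_members)) {
    w <- numeric(n_int + n_exch)
    names(w) <- colnames(S)
    w[inv[loop_members[[j]]]] <- 1
    lv <- loop_vector(w, sign_pattern(w, tolerance = 0))
    if (!is_loop(net, lv)) {
      stop("internal error: planted loop failed exact verification", call. = FALSE)
    }
    planted[[j]] <- lv
  }
  structure(list(network = net, planted_loops = planted, seed = seed),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  print(x$network)
  cat(sprintf("Planted loops: %d (seed %s)\n", length(x$planted_loops),
              format(x$seed)))
  invisible(x)
}
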