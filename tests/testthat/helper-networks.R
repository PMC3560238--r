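# Shared fixtures and generators for the property suites.
# Everything is built in code; seeds are fixed per test block.

# internal matrix of the three-reaction cycle (columns x2, x3, x4)
cycle3_matrix <- function() {
  internal_submatrix(figure2_network())
}

# random integer matrix with entries in -2..2 (the paper-scale fuzz class)
random_small_matrix <- function(m = sample(2:4, 1), n = sample(2:5, 1)) {
  matrix(sample(-2:2, m * n, replace = TRUE), m, n)
}

# all 3^n sign patterns over n columns, one per row
all_sign_patterns <- function(n) {
  as.matrix(expand.grid(rep(list(-1:1), n)))
}

# a steady-state vertex of the flux polytope, found by maximizing a random
# objective; exact LP, so the result satisfies S v = 0 exactly
sample_steady_flux <- function(network, cvec = NULL) {
  S <- network$stoich
  n <- ncol(S)
  if (is.null(cvec)) {
    repeat {
      cvec <- sample(-2:2, n, replace = TRUE)
      if (any(cvec != 0)) break
    }
  }
  sol <- lp_exact(cvec, S, rep("=", nrow(S)), numeric(nrow(S)),
                  lower = network$lower, upper = network$upper, maximize = TRUE)
  if (sol$status != "optimal") return(NULL)
  v <- sol$x
  names(v) <- network$reaction_ids
  flux_distribution(v, tolerance = 0)
}

# figure-2 cycle plus a drain exchange on M2, so plain FBA has throughput
# and the internal cycle is a free (loop) direction
throughput_network <- function() {
  S <- matrix(c(1, -1, 0, 1, 0,
                0, 1, -1, 0, -1,
                0, 0, 1, -1, 0), 3, 5, byrow = TRUE,
              dimnames = list(c("M1", "M2", "M3"),
                              c("x1", "x2", "x3", "x4", "EX_M2")))
  stoichiometric_network(S, internal = c(FALSE, TRUE, TRUE, TRUE, FALSE),
                         lower = c(0, -1000, -1000, -1000, 0),
                         upper = c(10, 1000, 1000, 1000, 1000))
}
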