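test_that("the toy cycle network has the documented structure", {
  net <- figure2_network()
  expect_equal(length(net$metabolite_ids), 3L)
  expect_equal(sum(net$internal), 3L)
  nb <- nullspace_basis(internal_submatrix(net))
  expect_equal(unname(nb$basis), matrix(c(1, 1, 1), 3, 1))
})

test_that("make_cycle_network generalizes the toy network", {
  expect_error(make_cycle_network(1), ">= 2")
  n2 <- make_cycle_network(2)
  expect_equal(unname(nullspace_basis(internal_submatrix(n2))$basis),
               matrix(c(1, 1), 2, 1))
  n3 <- make_cycle_network(3)
  expect_identical(unname(internal_submatrix(n3)),
                   unname(internal_submatrix(figure2_network())))
  n6 <- make_cycle_network(6)
  expect_equal(unname(nullspace_basis(internal_submatrix(n6))$basis),
               matrix(1, 6, 1))
})

test_that("random networks are reproducible and structurally valid", {
  a <- random_network(4, 5, 2, 1, seed = 99)
  b <- random_network(4, 5, 2, 1, seed = 99)
  expect_identical(a$network$stoich, b$network$stoich)
  expect_identical(a$planted_loops, b$planted_loops)
  c1 <- random_network(4, 5, 2, 1, seed = 100)
  expect_false(identical(a$network$stoich, c1$network$stoich))

  for (seed in 1:15) {
    pn <- random_network(m = 3, n_int = 4, n_exch = 2,
                         n_planted_loops = sample(0:2, 1), seed = seed)
    S <- pn$network$stoich
    expect_true(all(colSums(S[, pn$network$internal, drop = FALSE] != 0) >= 2))
    expect_true(all(abs(S) <= 2))
    for (lv in pn$planted_loops) {
      expect_true(is_loop(pn$network, lv))
    }
  }
  expect_error(random_network(1, 4), "m must")
  expect_error(random_network(3, 3, n_planted_loops = 2), "n_planted_loops")
})

test_that("planted loops are recovered by the brute-force oracle", {
  for (seed in 1:10) {
    pn <- random_network(m = 4, n_int = 4, n_exch = 1, n_planted_loops = 1,
                         seed = seed)
    A <- internal_submatrix(pn$network)
    lv <- pn$planted_loops[[1]]
    d <- as_sign_pattern(sign(lv$values[pn$network$internal]))
    oracle <- enumerate_loops_bruteforce(A, d)
    expect_gt(length(oracle), 0)
    supports <- lapply(oracle, function(w) which(w$values != 0))
    expect_true(any(vapply(supports, function(s) {
      all(s %in% which(lv$values[pn$network$internal] != 0))
    }, logical(1))))
  }
})

test_that("loop-freeness of unplanted instances is certified, not assumed", {
  found_free <- 0
  for (seed in 21:35) {
    pn <- random_network(m = 4, n_int = 4, n_exch = 1, n_planted_loops = 0,
                         seed = seed)
    A <- internal_submatrix(pn$network)
    # all-positive pattern: the oracle is the ground truth either way
    loops <- enumerate_loops_bruteforce(A, as_sign_pattern(rep(1, ncol(A))))
    if (length(loops) == 0) found_free <- found_free + 1
    for (lv in loops) {
      full <- numeric(length(pn$network$reaction_ids))
      names(full) <- pn$network$reaction_ids
      full[pn$network$internal] <- lv$values
      expect_true(is_loop(pn$network, full))  # accidental cycles are real loops
    }
  }
  expect_gt(found_free, 0)  # generation does bias toward loop-freeness
})
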