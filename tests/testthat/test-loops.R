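test_that("is_loop checks nonzeroness, exchange support and mass balance", {
  net <- figure2_network()
  expect_true(is_loop(net, c(x1 = 0, x2 = 1, x3 = 1, x4 = 1)))
  expect_false(is_loop(net, c(x1 = 0, x2 = 0, x3 = 0, x4 = 0)))
  expect_false(is_loop(net, c(x1 = 0, x2 = 1, x3 = 1, x4 = 0)))
  expect_false(is_loop(net, c(x1 = 1, x2 = 1, x3 = 1, x4 = 1)))  # exchange flux
  expect_error(is_loop(net, c(1, 1)), "length")
})

test_that("find_loop reproduces the toy-network outcomes", {
  net <- figure2_network()
  w <- find_loop(net, c(x1 = 0, x2 = 1, x3 = 1, x4 = 1))
  expect_s3_class(w, "loop_vector")
  expect_equal(unname(w$values), c(0, 1, 1, 1))
  expect_true(is_loop(net, w))

  expect_null(find_loop(net, c(x1 = 1, x2 = 1, x3 = 1, x4 = 0)))
  expect_null(find_loop(net, c(x1 = 0, x2 = 0, x3 = 0, x4 = 0)))
  # reversed cycle is a loop in the other orientation
  wr <- find_loop(net, c(x1 = 0, x2 = -1, x3 = -1, x4 = -1))
  expect_equal(unname(wr$values), c(0, -1, -1, -1))
})

test_that("a steady-state flux distribution can still contain a loop", {
  # S v = 0 over the full matrix holds, yet the internal cycle circulates:
  # the loop definition concerns S_int only
  net <- figure2_network()
  v <- c(x1 = 0, x2 = 5, x3 = 5, x4 = 5)
  expect_true(all(net$stoich %*% v == 0))
  expect_false(is.null(find_loop(net, v)))

  net2 <- throughput_network()
  v2 <- c(x1 = 10, x2 = 17, x3 = 7, x4 = 7, EX_M2 = 10)
  expect_true(all(net2$stoich %*% v2 == 0))
  w2 <- find_loop(net2, v2)
  expect_false(is.null(w2))
  expect_true(is_loop(net2, w2))
})

test_that("brute-force enumeration matches the worked example", {
  A <- cycle3_matrix()
  loops <- enumerate_loops_bruteforce(A, as_sign_pattern(c(1, 1, 1)))
  expect_length(loops, 1)
  expect_equal(unname(loops[[1]]$values), c(1, 1, 1))

  expect_length(enumerate_loops_bruteforce(A, as_sign_pattern(c(1, 1, 0))), 0)
  expect_length(enumerate_loops_bruteforce(A, as_sign_pattern(c(0, 0, 0))), 0)
  expect_error(enumerate_loops_bruteforce(matrix(0, 1, 13), rep(0, 13)),
               "12 columns")
})

test_that("LP route and brute-force oracle agree over random instances", {
  set.seed(23)
  for (i in 1:50) {
    pn <- random_network(m = sample(2:4, 1), n_int = sample(2:5, 1),
                         n_exch = sample(1:2, 1),
                         n_planted_loops = sample(0:1, 1), seed = i)
    net <- pn$network
    A <- internal_submatrix(net)
    circ <- loop_circuits(A)
    pats <- all_sign_patterns(ncol(A))
    rows <- sample(nrow(pats), min(12, nrow(pats)))
    for (r in rows) {
      d <- as_sign_pattern(pats[r, ])
      v <- numeric(length(net$reaction_ids))
      v[net$internal] <- unclass(d) * 2.5   # any representative magnitudes
      names(v) <- net$reaction_ids
      w <- find_loop(net, flux_distribution(v, tolerance = 0))
      oracle <- enumerate_loops_bruteforce(A, d, circ)
      expect_identical(!is.null(w), length(oracle) > 0,
                       label = sprintf("net %d pattern %s", i,
                                       paste(unclass(d), collapse = ",")))
      if (!is.null(w)) {
        expect_true(is_loop(net, w))
        ws <- sign(w$values[net$internal])
        expect_true(all(ws == 0 | ws == unclass(d)))
      }
      for (lv in oracle) {
        full <- numeric(length(net$reaction_ids))
        names(full) <- net$reaction_ids
        full[net$internal] <- lv$values
        expect_true(is_loop(net, full))
      }
    }
  }
})

test_that("loop status is invariant under positive flux rescaling", {
  net <- throughput_network()
  set.seed(29)
  for (i in 1:10) {
    v <- sample(-3:3, 5, replace = TRUE)
    names(v) <- net$reaction_ids
    base <- is.null(find_loop(net, flux_distribution(v, tolerance = 0)))
    for (cc in c(0.01, 3, 1000)) {
      expect_identical(
        is.null(find_loop(net, flux_distribution(cc * v, tolerance = 0))),
        base)
    }
  }
})
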