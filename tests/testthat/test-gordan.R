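test_that("reduce_matrix drops inactive columns and negates backward ones", {
  A <- cycle3_matrix()
  r1 <- reduce_matrix(A, as_sign_pattern(c(1, 1, 1)))
  expect_identical(unname(r1$matrix), unname(A))
  expect_equal(r1$column_map, 1:3)

  r2 <- reduce_matrix(A, as_sign_pattern(c(1, -1, 0)))
  expect_equal(unname(r2$matrix), unname(cbind(A[, 1], -A[, 2])))
  expect_equal(r2$column_map, 1:2)

  r3 <- reduce_matrix(A, as_sign_pattern(c(0, 0, 0)))
  expect_equal(ncol(r3$matrix), 0L)
  expect_length(r3$column_map, 0)
  expect_error(reduce_matrix(A, c(1, 1)), "length")
})

test_that("find_certificate matches the worked example", {
  A <- cycle3_matrix()
  expect_null(find_certificate(A, as_sign_pattern(c(1, 1, 1))))

  cert <- find_certificate(A, as_sign_pattern(c(1, 1, 0)))
  expect_s3_class(cert, "gordan_certificate")
  expect_true(cert$verified)
  expect_true(verify_certificate(A, as_sign_pattern(c(1, 1, 0)), cert$y))
  expect_equal(cert$G, as.numeric(t(A) %*% cert$y), ignore_attr = TRUE)

  # vacuous pattern: y = 0 certifies everything
  cv <- find_certificate(A, as_sign_pattern(c(0, 0, 0)))
  expect_true(cv$verified)
  expect_equal(cv$y, numeric(3))
})

test_that("verify_certificate demands opposing signs on active reactions", {
  A <- cycle3_matrix()
  d <- as_sign_pattern(c(1, 1, 0))
  # hand example: y = (0,1,2) gives A^T y = (1,1,-2); need sign -d, so -y works
  expect_false(verify_certificate(A, d, c(0, 1, 2)))
  expect_true(verify_certificate(A, d, -c(0, 1, 2)))
  expect_false(verify_certificate(A, d, c(0, 0, 0)))
  for (i in 1:5) {
    expect_false(verify_certificate(A, as_sign_pattern(c(1, 1, 1)),
                                    sample(-5:5, 3, replace = TRUE)))
  }
  expect_error(verify_certificate(A, d, 1:2), "length")
})

test_that("check_dichotomy returns exactly one side with a witness", {
  A <- cycle3_matrix()
  r1 <- check_dichotomy(A, as_sign_pattern(c(1, 1, 1)))
  expect_equal(as.character(r1), "loop_exists")
  expect_s3_class(attr(r1, "witness"), "loop_vector")

  r2 <- check_dichotomy(A, as_sign_pattern(c(1, 1, 0)))
  expect_equal(as.character(r2), "certificate_exists")
  expect_true(attr(r2, "witness")$verified)

  r3 <- check_dichotomy(A, as_sign_pattern(c(0, 0, 0)))
  expect_equal(as.character(r3), "certificate_exists")
})

test_that("dichotomy holds on random matrices across all sign patterns", {
  set.seed(31)
  for (i in 1:40) {
    A <- random_small_matrix()
    circ <- loop_circuits(A)
    pats <- all_sign_patterns(ncol(A))
    for (r in seq_len(nrow(pats))) {
      expect_no_error(check_dichotomy(A, as_sign_pattern(pats[r, ]), circ))
    }
  }
})

test_that("certificate existence is symmetric under pattern negation", {
  set.seed(37)
  for (i in 1:25) {
    A <- random_small_matrix()
    d <- sample(-1:1, ncol(A), replace = TRUE)
    c1 <- find_certificate(A, as_sign_pattern(d))
    c2 <- find_certificate(A, as_sign_pattern(-d))
    expect_identical(is.null(c1), is.null(c2))
    if (!is.null(c1)) {
      # y <-> -y carries one certificate to the other, and both are scale-free
      expect_true(verify_certificate(A, as_sign_pattern(-d), -c1$y))
      for (cc in c(2, 7, 1000)) {
        expect_true(verify_certificate(A, as_sign_pattern(d), cc * c1$y))
      }
    }
  }
})

test_that("column reduction preserves both sides of the dichotomy", {
  # statement (a) for the reduced matrix == statement (1a) for (A, d),
  # checked by brute force in both forms
  set.seed(41)
  for (i in 1:25) {
    A <- random_small_matrix()
    d <- sample(-1:1, ncol(A), replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    red <- reduce_matrix(A, as_sign_pattern(d))
    loops_A <- enumerate_loops_bruteforce(A, as_sign_pattern(d))
    loops_red <- if (ncol(red$matrix) > 0) {
      enumerate_loops_bruteforce(red$matrix,
                                 as_sign_pattern(rep(1, ncol(red$matrix))))
    } else list()
    expect_identical(length(loops_A) > 0, length(loops_red) > 0)
  }
})

test_that("potentials map to reaction energies in the row space", {
  net <- figure2_network()
  expect_equal(unname(potentials_to_reaction_energies(net, c(0, 0, 0))),
               numeric(3))
  G <- potentials_to_reaction_energies(net, c(0, 1, 2))
  expect_equal(unname(G), c(1, 1, -2))
  A <- internal_submatrix(net)
  set.seed(43)
  for (i in 1:10) {
    y <- sample(-5:5, 3, replace = TRUE)
    G <- potentials_to_reaction_energies(net, y)
    expect_true(in_row_space(A, G))
    expect_true(nullspace_orthogonality_check(A, G))
  }
  expect_error(potentials_to_reaction_energies(net, 1:2), "metabolites")
})

test_that("certificates serialize to the documented JSON schema", {
  cert <- find_certificate(cycle3_matrix(), as_sign_pattern(c(1, 1, 0)))
  parsed <- jsonlite::fromJSON(certificate_to_json(cert))
  expect_named(parsed, c("pattern", "y", "G", "verified"))
  expect_true(parsed$verified)
  expect_equal(parsed$y, cert$y)
})
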