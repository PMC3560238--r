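test_that("problem construction validates its inputs", {
  net <- figure2_network()
  expect_error(build_loopless_milp(net, "nope"), "unknown objective")
  expect_error(build_loopless_milp(net, "x1", big_m = -1), "big_m")
  expect_error(build_loopless_milp(net, "x1", energy_bound = 0), "energy_bound")
  p <- build_loopless_milp(net, "x1")
  expect_equal(p$formulation, "image")
  expect_equal(p$n_int, 3L)

  # no internal reactions -> plain FBA, no binaries
  S <- matrix(c(1, -1), 1, 2, dimnames = list("M1", c("in", "out")))
  exch <- stoichiometric_network(S, internal = c(FALSE, FALSE),
                                 lower = c(0, 0), upper = c(5, 1000))
  p2 <- build_loopless_milp(exch, "out")
  expect_equal(p2$type, "fba")
  s2 <- solve_loopless_fba(p2)
  expect_equal(s2$objective_value, 5)
  expect_equal(s2$objective_value, solve_fba(exch, "out")$objective_value)
})

test_that("loopless FBA removes the cycle's redundant circulation", {
  net <- throughput_network()
  for (f in c("image", "nullspace")) {
    sol <- solve_loopless_fba(build_loopless_milp(net, "EX_M2", f))
    expect_equal(sol$status, "optimal")
    expect_equal(sol$objective_value, 10)          # same throughput as plain FBA
    expect_equal(sol$objective_value, sol$plain_objective)
    expect_true(sol$loop_free)
    v <- sol$flux$values
    expect_null(find_loop(net, flux_distribution(v, tolerance = 0)))
    # the redundant direction around the cycle is inactive
    expect_true(any(v[c("x3", "x4")] == 0) || all(v[c("x2", "x3", "x4")] >= 0))
  }
})

test_that("forced-zero networks return the trivial solution, flagged", {
  # only the cycle, no exchange with throughput: x1 pinned to 0
  net <- figure2_network()
  net$lower["x1"] <- 0
  net$upper["x1"] <- 0
  sol <- solve_loopless_fba(build_loopless_milp(net, "x2"))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0)
  expect_true(sol$trivial)
  expect_true(sol$loop_free)
})

test_that("infeasible bounds are reported distinctly", {
  net <- throughput_network()
  net$lower["x1"] <- 20  # demands more input than the exchange cap allows
  net$upper["x1"] <- 20
  net$upper["EX_M2"] <- 5
  sol <- solve_loopless_fba(build_loopless_milp(net, "EX_M2"))
  expect_equal(sol$status, "infeasible")
})

test_that("the two formulations are feasibility-equivalent on patterns", {
  net <- figure2_network()
  for (r in seq_len(nrow(all_sign_patterns(3)))) {
    d <- as_sign_pattern(all_sign_patterns(3)[r, ])
    eq <- check_formulation_equivalence(net, d)
    expect_true(as.logical(eq))
  }
  eq1 <- check_formulation_equivalence(net, as_sign_pattern(c(1, 1, 1)))
  expect_false(attr(eq1, "nullspace"))  # full cycle: both infeasible
  eq2 <- check_formulation_equivalence(net, as_sign_pattern(c(1, 1, 0)))
  expect_true(attr(eq2, "nullspace"))
  eq3 <- check_formulation_equivalence(net, as_sign_pattern(c(0, 0, 0)))
  expect_true(attr(eq3, "image"))
})

test_that("flux_admissible is the complement of find_loop", {
  net <- figure2_network()
  expect_false(flux_admissible(net, c(x1 = 0, x2 = 1, x3 = 1, x4 = 1)))
  adm <- flux_admissible(net, c(x1 = 1, x2 = 1, x3 = 1, x4 = 0))
  expect_true(adm)
  expect_true(attr(adm, "certificate")$verified)
  zero <- flux_admissible(net, c(x1 = 0, x2 = 0, x3 = 0, x4 = 0))
  expect_true(zero)
  expect_true(attr(zero, "trivial"))
})

test_that("loopless solutions are sound and admissibility is complete", {
  set.seed(47)
  for (i in 1:20) {
    pn <- random_network(m = sample(2:4, 1), n_int = sample(2:4, 1),
                         n_exch = 2, n_planted_loops = sample(0:1, 1),
                         seed = 100 + i)
    net <- pn$network
    objective <- sample(net$reaction_ids, 1)
    sol <- solve_loopless_fba(build_loopless_milp(net, objective))
    if (sol$status == "optimal") {
      # soundness: returned flux has no loop, exactly
      expect_null(find_loop(net, flux_distribution(sol$flux$values, tolerance = 0)))
      # never better than plain FBA
      expect_lte(sol$objective_value, sol$plain_objective + 1e-12)
    }
    # completeness: admissibility == looplessness on sampled steady states
    for (k in 1:2) {
      v <- sample_steady_flux(net)
      if (is.null(v)) break
      expect_identical(as.logical(flux_admissible(net, v)),
                       is.null(find_loop(net, v)))
    }
  }
})

test_that("loopless objectives agree across formulations", {
  set.seed(53)
  for (i in 1:8) {
    pn <- random_network(m = 3, n_int = sample(2:4, 1), n_exch = 2,
                         n_planted_loops = 1, seed = 200 + i)
    net <- pn$network
    objective <- sample(net$reaction_ids, 1)
    s1 <- solve_loopless_fba(build_loopless_milp(net, objective, "image"))
    s2 <- solve_loopless_fba(build_loopless_milp(net, objective, "nullspace"))
    expect_identical(s1$status, s2$status)
    if (s1$status == "optimal") {
      expect_equal(s1$objective_value, s2$objective_value, tolerance = 1e-6)
    }
  }
})

test_that("LP-format export writes a parseable problem file", {
  net <- throughput_network()
  p <- build_loopless_milp(net, "EX_M2", "image")
  path <- withr::local_tempfile(fileext = ".lp")
  write_problem_lp(p, path)
  txt <- readLines(path)
  expect_true(any(grepl("^Maximize", txt)))
  expect_true(any(grepl("Binary", txt)))
  expect_true(any(grepl("a_x2", txt)))
  p2 <- build_loopless_milp(net, "EX_M2", "nullspace")
  write_problem_lp(p2, path)
  expect_true(any(grepl("ns_1", readLines(path))))
})

test_that("bounds beyond big_m trigger the documented warning", {
  net <- throughput_network()
  expect_warning(build_loopless_milp(net, "EX_M2", big_m = 10), "big_m")
})
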