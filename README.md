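# looplaw

Loop-law constraints and Gordan certificates for stoichiometric
metabolic networks.

## The problem

Constraint-based models predict metabolic phenotypes as steady-state
flux distributions: vectors `v` with `S v = 0`, where `S` is the
m × n stoichiometric matrix (metabolites × reactions), subject to flux
bounds. Plain flux balance analysis (FBA) happily returns solutions in
which a set of *internal* reactions circulates material around a closed
cycle with no net transformation. Such internal cycles violate a "loop
law" analogous to Kirchhoff's second law: around any closed cycle the
reaction Gibbs energies must sum to zero, so all of them cannot be
negative, so flux cannot run all the way around.

Formally, writing `S_int` for the submatrix of internal reactions, a
flux distribution `v` **contains a loop** iff

```
∃ x ≠ 0 :  sign(x_i) ∈ {sign(v_i), 0} ∀i  ∧  S_int x = 0
```

(note `S_int`, not `S` — this must not be confused with the
steady-state condition, and a steady-state `v` can contain a loop).
The loopless-COBRA constraints exclude such solutions by demanding
reaction energies `G` with

```
∃ G :  null(S_int) · G = 0  ∧  sign(G_i) = −sign(v_i) whenever v_i ≠ 0
```

By **Gordan's theorem of the alternative** — for any matrix `A` exactly
one of (a) `∃ x ≥ 0, x ≠ 0, A x = 0` and (b) `∃ y, Aᵀ y > 0` holds —
these two systems are exact complements: a sign pattern admits a loop
*or* a certificate `y` of metabolite potentials with
`G = S_intᵀ y` opposing every active flux direction, never both, never
neither. The constraints therefore remove loops *and nothing more*.
Since `null(S_int)` is the orthogonal complement of `image(S_intᵀ)`,
the null-space form (`null(S_int)·G = 0`) and the image form
(`G = S_intᵀ y`, free `y`) are interchangeable; with m < n the image
form is the smaller one.

This package implements the whole machinery with **exact rational
arithmetic** (an in-package exact simplex and exact null-space
computation), so the dichotomy is decided exactly rather than up to a
solver tolerance:

* loop detection (`find_loop`) plus an LP-free brute-force oracle
  (`enumerate_loops_bruteforce`, `loop_circuits`);
* Gordan certificates (`find_certificate`, `verify_certificate`,
  `check_dichotomy`);
* loopless FBA in both formulations (`build_loopless_milp`,
  `solve_loopless_fba`, `check_formulation_equivalence`,
  `flux_admissible`);
* synthetic networks (`figure2_network`, `make_cycle_network`,
  `random_network`), TSV/SBML readers and a CLI.

## Worked example

The toy network: metabolites M1–M3 in a directed cycle via internal
reactions `x2: M1→M2`, `x3: M2→M3`, `x4: M3→M1`, plus exchange `x1`.

```r
library(looplaw)
net <- figure2_network()

# all three cycle reactions active: a loop
find_loop(net, c(x1 = 0, x2 = 1, x3 = 1, x4 = 1))
#> Loop vector (support size 3 ):
#> x2 x3 x4
#>  1  1  1
flux_admissible(net, c(x1 = 0, x2 = 1, x3 = 1, x4 = 1))
#> [1] FALSE

# x4 inactive: no loop, and a certificate of looplessness exists
v <- c(x1 = 1, x2 = 1, x3 = 1, x4 = 0)
find_certificate(internal_submatrix(net), sign_pattern(v)[net$internal])
#> Gordan certificate (verified)
#>   y: 2 1 0
#>   G: -1 -1  2
```

The witness `(1, 1, 1)` is the smallest integer vector spanning
`null(S_int)`: running the three cycle reactions at equal rate
transforms nothing. The certificate assigns potentials
`y = (2, 1, 0)` to M1–M3; the induced energies `G = S_intᵀ y =
(−1, −1, 2)` are negative on both active (forward) reactions, which by
Corollary-style reasoning proves no sign-consistent loop can exist.

Loopless FBA on the cycle with an added drain `EX_M2` (uptake capped at
10): plain FBA may circulate arbitrary extra flux around the cycle;
the loopless solution keeps the same throughput but switches the
redundant direction off:

```r
S <- matrix(c(1, -1, 0, 1, 0,
              0, 1, -1, 0, -1,
              0, 0, 1, -1, 0), 3, 5, byrow = TRUE,
            dimnames = list(c("M1", "M2", "M3"),
                            c("x1", "x2", "x3", "x4", "EX_M2")))
net2 <- stoichiometric_network(S, internal = c(FALSE, TRUE, TRUE, TRUE, FALSE),
                               lower = c(0, -1000, -1000, -1000, 0),
                               upper = c(10, 1000, 1000, 1000, 1000))
solve_fba(net2, "EX_M2")$objective_value
#> [1] 10
sol <- solve_loopless_fba(build_loopless_milp(net2, "EX_M2"))
#> Loopless-FBA solution: status optimal, objective 10 (plain FBA: 10), image formulation
#>    x1    x2    x3    x4 EX_M2
#>    10    10     0     0    10
```

## Command line

```sh
Rscript inst/cli/looplaw.R detect-loops --network path/stem --flux flux.tsv
Rscript inst/cli/looplaw.R certify      --network path/stem --flux flux.tsv
Rscript inst/cli/looplaw.R llfba        --network model.xml --objective EX_M2 --formulation image
```

JSON on stdout, logs on stderr; exit codes: 0 no loop / success,
1 loop found, 2 error. Networks are read from a TSV pair
(`<stem>.reactions.tsv`, `<stem>.stoich.tsv`, coefficients as exact
fraction strings) or from SBML (read-only, core + fbc bounds).

## Vignette

`vignettes/loop-law.Rmd` describes the model, the exact-arithmetic
design, the synthetic-data generator and known limitations.
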