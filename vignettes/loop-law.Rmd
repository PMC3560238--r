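---
title: "Loop-law constraints, Gordan certificates, and exact arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop-law constraints, Gordan certificates, and exact arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(looplaw)
```

## The model

A stoichiometric network is an m × n matrix $S$ (metabolites ×
reactions) with a partition of reactions into *internal* (chemistry
inside the system boundary) and *exchange* (transport across it), flux
bounds $l \le v \le u$, and the steady-state condition $S v = 0$.

The loop law concerns only the internal submatrix $S_{int}$. A flux
distribution $v$ *contains a loop* iff

$$\exists\, x \ne 0:\quad \mathrm{sign}(x_i) \in \{\mathrm{sign}(v_i), 0\}\ \forall i,
\qquad S_{int}\, x = 0 .$$

Such an $x$ circulates material around internal reactions, in the
directions $v$ already uses, with zero net transformation — running
chemistry downhill all the way around a closed cycle, which the second
law of thermodynamics forbids. The equation looks like the
steady-state condition but is not: it uses $S_{int}$, and the test
suite includes steady-state distributions (full $S v = 0$) that do
contain loops.

The loopless constraints demand reaction energies $G$ (the analog of
$\Delta_r G$) with

$$\mathrm{null}(S_{int}) \cdot G = 0
\quad\wedge\quad \mathrm{sign}(G_i) = -\mathrm{sign}(v_i)\ \text{whenever}\ v_i \ne 0 .$$

Because $\mathrm{null}(A)$ is the orthogonal complement of
$\mathrm{image}(A^\top)$, the first condition says exactly
$G = S_{int}^\top y$ for some metabolite potentials $y$ (the analog of
$\Delta_f G$). Gordan's theorem of the alternative, pushed through the
sign pattern $d_i = \mathrm{sign}(v_i)$ by column reduction (drop
$d_i = 0$ columns, negate $d_i = -1$ ones), says the loop system and
the certificate system are exact complements: precisely one is
solvable. `check_dichotomy()` machine-checks this on every instance the
property suites generate, treating "both" and "neither" as fatal bugs.

## Why exact rational arithmetic

The dichotomy is exact; a floating-point rank or feasibility decision
near degeneracy could report "both" or "neither" and corrupt every
downstream guarantee. All decision paths therefore run on exact
rationals:

* numerators/denominators held in doubles (exact for integers up to
  $2^{52}$, guarded — at desk scale the guard never fires), reduced by
  gcd after every operation;
* null spaces and ranks by exact Gauss–Jordan elimination with fixed
  column order, basis vectors normalized to smallest integer form with
  positive leading entry (deterministic outputs);
* linear programs by an in-package two-phase simplex with Bland's rule
  — termination guaranteed, no feasibility or optimality tolerance
  anywhere. This also removes the need to rationalize solver floats:
  witnesses and certificates come out exactly rational and are
  re-verified exactly anyway.

A floating-point SVD path exists in `nullspace_basis(exact = FALSE)`
(threshold $10^{-10} \cdot \sigma_{max}$) for genuinely non-rational
input only; no property suite uses it.

The only tolerance in the package is the *sign tolerance* of a
`flux_distribution` (default `1e-9`), classifying floating-point flux
values from external solvers into $\{-1, 0, +1\}$. Once a pattern is
fixed, everything downstream is exact and scale-invariant.

## Decision procedures

**`find_loop`** maximizes $\sum_i t_i$ subject to $S_{int} x = 0$,
$x_i = 0$ on inactive reactions, sign bounds on active ones, and
$0 \le t_i \le d_i x_i$, $t_i \le 1$. The feasible set is a cone, so
the optimum is positive iff a sign-consistent nonzero kernel vector
exists; the auxiliary $t_i$ encode "strictly nonzero somewhere"
without any magnitude cutoff. Witnesses are scaled to smallest integer
form and re-verified by `is_loop`.

**`enumerate_loops_bruteforce`** is the independent oracle and uses no
LP at all. Any sign-consistent kernel vector decomposes over the
extreme rays of the cone $\{x : S_{int} x = 0,\ x\ \text{sign-consistent}\}$,
and each extreme ray is strictly signed with a one-dimensional kernel
on its own support. So the oracle scans all column subsets (supersets
of found circuits pruned; refused above 12 columns), keeps those whose
restricted kernel is one-dimensional and strictly nonzero — the
*circuits* — and matches circuit signs against $d$. `loop_circuits()`
exposes the per-matrix scan so that suites iterating over all $3^n$
patterns of one matrix pay for it once.

**`find_certificate`** solves $\hat A^\top (-y) \ge 1$ on the reduced
matrix. The solution set of the strict system is an open cone, so the
unit bound loses nothing and introduces no epsilon. Certificates are
scaled to smallest integer form (also lossless on a cone) and
re-verified sign by sign.

**Loopless FBA.** `build_loopless_milp()` carries the conventional
indicator encoding (binary $a_i$ per internal reaction; $a_i = 1
\Rightarrow v_i \ge 0,\ G_i \le -1$; $a_i = 0 \Rightarrow v_i \le 0,\
G_i \ge 1$) plus the formulation-specific coupling of $G$. No MILP
solver is available in the target environment, and none is needed at
desk scale: `solve_loopless_fba()` branches over the binaries
explicitly — each assignment fixes the bounds, leaving an exact LP —
starting from the assignment suggested by the plain-FBA signs and
stopping as soon as a node reaches the plain-FBA bound (loopless can
never exceed it). The big-M constant therefore never enters the
arithmetic; it appears only in the LP-format export
(`write_problem_lp()`), where the encoding is written for external
solvers. Assignments are capped at $2^{16}$; genome-scale performance
is a non-goal.

Forcing $|G_i| \ge 1$ for *inactive* internal reactions (as the binary
encoding does) is harmless here because no internal column is all-zero:
the certificate cone is open, so potentials can always be perturbed to
make every $G_i$ nonzero, and scaled into $[1, K]$. A pathological
model needing an energy spread beyond $K : 1$ (default $K = 1000$)
would be cut; none arises at desk scale.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tolerance` (flux sign) | `1e-9` | threshold for classifying float fluxes; dimension of flux |
| `big_m` | `1000` | flux coupling constant in the exported MILP text; warned when bounds exceed it |
| `energy_bound` K | `1000` | cap on dimensionless certificate energies; unit lower magnitude is lossless |
| `formulation` | `"image"` | $G = S_{int}^\top y$; fewer variables when m < n, and the certificate $y$ comes out directly |
| flux bounds | ±1000 | community convention for "effectively unbounded" |

The energies $y$ and $G$ are *analogs* of formation/reaction Gibbs
energies: their signs are meaningful, their magnitudes are not, and the
package never interprets them thermodynamically.

## What the synthetic generator emulates

`random_network(m, n_int, n_exch, n_planted_loops, seed)` produces
integer stoichiometries with entries in $-2..2$ (the coefficient range
typical of central metabolism), internal columns with at least two
nonzeros (so the single-nonzero exchange heuristic never misfires),
single-entry exchange columns, and planted directed cycles of length
2–3 on disjoint internal columns whose loop vectors are recorded and
exact-verified at generation time. Randomness comes from a module-owned
Lehmer generator, so instances are bit-reproducible and independent of
R's global RNG.

Planting guarantees loop *presence* only. Random columns can close
accidental cycles, so "no planted loop" never means "loop-free": the
property suites always certify loop-freeness post hoc with the
brute-force oracle. The generator does not attempt biologically
realistic topology, reversibility statistics, compartments or
gene–protein–reaction structure — a green property suite establishes
the algebraic claims on this instance class, not predictive validity on
genome-scale reconstructions.

Fuzz matrices for the dichotomy suites are dense $m \le 4$, $n \le 5$
integer matrices with entries in $-2..2$, crossed with *all* $3^n$ sign
patterns — small enough for exhaustive pattern coverage, large enough
to hit every rank/degeneracy case that class contains.

## Numerical and design choices

* **Degenerate inputs.** $v = 0$ contains no loop and always satisfies
  the loopless constraints (vacuous certificate $y = 0$); since
  downstream applications may want to exclude it, it is *flagged*
  (`trivial`) rather than silently accepted or rejected. Networks with
  no internal reactions are valid and trivially loop-free (loopless FBA
  collapses to plain FBA). All-zero stoichiometry columns are rejected
  at construction with the reaction named.
* **Determinism.** Echelon pivoting in fixed column order; Bland's rule
  for the simplex; smallest-integer normalization of every witness,
  basis vector and certificate; keyed vectors everywhere. Two runs on
  one input give identical objects.
* **Internal/exchange labels.** The loop law does not define how the
  partition is obtained. Explicit labels always win; the
  single-nonzero-column heuristic (`classify_reactions`) is a stated
  convention for unlabeled input, and SBML boundary species mark their
  reactions as exchange.
* **G components for exchange reactions** are not created: only
  $S_{int}$ is constrained, so they would be free variables with no
  effect. (Equivalent to leaving them unconstrained; chosen for
  economy.)
* **Certificate non-uniqueness.** Any valid $y$ is accepted and
  verified; the package makes no attempt to reproduce one particular
  published example vector, which is display-dependent anyway.

## Known limitations

* Exact arithmetic overflows (with a clean error, never silently)
  beyond numerators/denominators of $2^{52}$; fine for desk-scale
  models, not for genome-scale kernels.
* `solve_loopless_fba` enumeration is exponential in the number of
  internal reactions (capped at 16); `loop_circuits` is exponential in
  columns (capped at 12). These caps implement the package's scope,
  not a promise about larger models.
* SBML support is read-only and minimal: core stoichiometry, boundary
  flags, fbc or kinetic-law bounds. No writing, no objectives beyond a
  named reaction, no compartments semantics.
* Admissibility under the loopless constraints is decided at the sign
  pattern induced by the flux-sign tolerance; fluxes hovering at that
  threshold are classified, not agonized over.
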