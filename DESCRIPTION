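Package: looplaw
Title: Loop-Law Constraints and Gordan Certificates for Stoichiometric
    Metabolic Networks
Version: 0.1.0
Authors@R: person("looplaw", "developers", email = "looplaw@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting thermodynamically infeasible internal
    cycles (loops) in constraint-based metabolic models and for certifying
    their absence.  A flux distribution contains a loop when a nonzero
    sign-consistent vector lies in the null space of the internal
    stoichiometric matrix; by Gordan's theorem of the alternative, the
    only other possibility is a vector of metabolite potentials whose
    induced reaction energies oppose every active flux direction.  The
    package decides this dichotomy with exact rational arithmetic (an
    in-package exact simplex and exact null-space computations), builds
    the loopless flux balance analysis problem in both the null-space and
    the image-space (potential-based) formulation, machine-checks their
    equivalence, and ships synthetic network generators, TSV/SBML readers
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
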