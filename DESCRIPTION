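Package: gentrust
Title: Generous Trust in Repeated Trust Games with Incompetence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when forgiving ("generous") trust strategies are
    viable in repeated trust games where a trustee's failure can come from bad
    intent or from lack of competence. Provides exact expected-payoff
    computation for a finite-horizon modified trust game via absorbing Markov
    chains, Nash-equilibrium analysis (pure and mixed) with competence
    thresholds for Pareto efficiency, cooperation and equilibrium uniqueness,
    and an evolutionary agent-based simulation of a matching market in which
    donors differ in matching generosity and exit generosity and strategies
    spread by imitation dynamics with mutation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
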