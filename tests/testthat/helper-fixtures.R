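# Hand-built fixtures for unit tests.

# A population with explicit donor flags, recipient intents and (optionally)
# histories and partner links. Partner links are 1-based indices into the
# opposite role, 0 = unpaired.
make_pop <- function(match_gen, exit_gen, r_intent, r_history = NULL,
                     d_partner = NULL, r_partner = NULL) {
  nd <- length(match_gen)
  nr <- length(r_intent)
  structure(list(
    match_gen = as.integer(match_gen),
    exit_gen = as.integer(exit_gen),
    d_partner = if (is.null(d_partner)) integer(nd) else as.integer(d_partner),
    d_payoff = numeric(nd),
    r_intent = as.numeric(r_intent),
    r_history = if (is.null(r_history)) rep(1L, nr) else as.integer(r_history),
    r_partner = if (is.null(r_partner)) integer(nr) else as.integer(r_partner),
    r_payoff = numeric(nr)
  ), class = "trust_population")
}

# A payoff_matrix object with prescribed cell values (for condition /
# equilibrium arithmetic that does not depend on the chain).
make_matrix <- function(a1, a2, b1, b2, c1, c2, d1, d2, e1, e2, f1, f2) {
  md <- matrix(c(a1, c1, e1, b1, d1, f1), 3, 2,
               dimnames = list(c("H", "M", "L"), c("C", "D")))
  mr <- matrix(c(a2, c2, e2, b2, d2, f2), 3, 2,
               dimnames = list(c("H", "M", "L"), c("C", "D")))
  structure(list(donor = md, recipient = mr,
                 cells = list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1,
                              c2 = c2, d1 = d1, d2 = d2, e1 = e1, e2 = e2,
                              f1 = f1, f2 = f2),
                 cfg = game_config(a = 0.5), params = payoff_params()),
            class = "payoff_matrix")
}

# Mutual-and-exclusive pairing check
expect_pairing_integrity <- function(pop) {
  paired_d <- which(pop$d_partner > 0)
  paired_r <- which(pop$r_partner > 0)
  expect_equal(length(paired_d), length(paired_r))
  for (i in paired_d) {
    j <- pop$d_partner[i]
    expect_identical(pop$r_partner[j], i)
  }
  expect_false(any(duplicated(pop$d_partner[paired_d])))
  expect_false(any(duplicated(pop$r_partner[paired_r])))
}

tiny_cfg <- function(a, nd = 12, nr = 12, generations = 3, L = 10, ...) {
  sim_config(a = a, n_donors = nd, n_recipients = nr,
             generations = generations, L = L, ...)
}
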