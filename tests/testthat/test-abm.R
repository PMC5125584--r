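test_that("initial populations are uniform, unpaired and reproducible", {
  cfg <- tiny_cfg(a = 0.6, nd = 4, nr = 4)
  set.seed(1); pop <- init_population(cfg)
  expect_length(pop$match_gen, 4)
  expect_length(pop$r_intent, 4)
  expect_true(all(pop$d_partner == 0) && all(pop$r_partner == 0))
  expect_true(all(pop$d_payoff == 0) && all(pop$r_payoff == 0))
  expect_true(all(pop$r_history == 1L)) # everyone starts with a clean slate
  set.seed(99); p1 <- init_population(sim_config(a = 0.5))
  set.seed(99); p2 <- init_population(sim_config(a = 0.5))
  expect_identical(p1, p2)
  # uniform assignment: shares near 1/4 (policies) and 1/3 (intents)
  set.seed(2); big <- init_population(sim_config(a = 0.5, n_donors = 8000,
                                                 n_recipients = 9000))
  shares <- table(donor_policy(big)) / 8000
  expect_true(all(abs(shares - 0.25) < 0.02))
  expect_true(abs(mean(big$r_intent) - 0.5) < 0.02)
})

test_that("matching respects the donor's acceptance criterion", {
  # strict donor facing an all-D pool stays unpaired
  pop <- make_pop(match_gen = 0, exit_gen = 0, r_intent = c(1, 1),
                  r_history = c(0, 0))
  set.seed(1); out <- matching_step(pop)
  expect_equal(out$d_partner, 0L)
  # a matching-generous donor pairs with a D-history recipient
  pop$match_gen <- 1L
  set.seed(1); out <- matching_step(pop)
  expect_true(out$d_partner > 0)
  expect_pairing_integrity(out)
  # one donor, one clean recipient: exactly one pair forms
  pop <- make_pop(match_gen = 0, exit_gen = 0, r_intent = 1)
  set.seed(1); out <- matching_step(pop)
  expect_equal(out$d_partner, 1L)
  expect_equal(out$r_partner, 1L)
  # a chosen recipient leaves the pool: two strict donors, one clean recipient
  pop <- make_pop(match_gen = c(0, 0), exit_gen = c(0, 0),
                  r_intent = c(1, 1), r_history = c(1, 0))
  set.seed(1); out <- matching_step(pop)
  expect_equal(sum(out$d_partner > 0), 1)
  expect_equal(sum(out$r_partner > 0), 1)
  expect_true(out$r_partner[1] > 0) # only the C-history recipient is eligible
})

test_that("played rounds assign sub-game payoffs and isolation pay", {
  p <- payoff_params()
  # committed cooperator with certain success
  pop <- make_pop(1, 1, r_intent = 1, d_partner = 1, r_partner = 1)
  out <- play_round(pop, sim_config(a = 1, n_donors = 1, n_recipients = 1))
  expect_equal(out$d_payoff, p$R)
  expect_equal(out$r_payoff, p$R)
  expect_equal(out$r_history, 1L)
  # certain betrayal with certain success
  pop <- make_pop(1, 1, r_intent = 0, d_partner = 1, r_partner = 1)
  out <- play_round(pop, sim_config(a = 1, n_donors = 1, n_recipients = 1))
  expect_equal(out$d_payoff, 0)
  expect_equal(out$r_payoff, p$T)
  expect_equal(out$r_history, 0L)
  # certain failure: both get nothing, history D regardless of intent
  pop <- make_pop(1, 1, r_intent = 1, d_partner = 1, r_partner = 1)
  out <- play_round(pop, sim_config(a = 0, n_donors = 1, n_recipients = 1))
  expect_equal(out$d_payoff, 0)
  expect_equal(out$r_payoff, 0)
  expect_equal(out$r_history, 0L)
  # unpaired agents of either role collect P
  pop <- make_pop(c(1, 1), c(1, 1), r_intent = c(1, 0.5),
                  d_partner = c(1, 0), r_partner = c(1, 0))
  out <- play_round(pop, sim_config(a = 1, n_donors = 2, n_recipients = 2))
  expect_equal(out$d_payoff[2], p$P)
  expect_equal(out$r_payoff[2], p$P)
})

test_that("commitment applies exit strictness then exogenous dissolution", {
  base <- function(exit_gen, hist) {
    make_pop(1, exit_gen, r_intent = 1, r_history = hist,
             d_partner = 1, r_partner = 1)
  }
  # exit-generous donor keeps a D-history partner when d = 0
  out <- commitment_step(base(1, 0), sim_config(a = 0.5, d = 0,
                                                n_donors = 1, n_recipients = 1))
  expect_equal(out$d_partner, 1L)
  # exit-strict donor dissolves on D even when d = 0
  out <- commitment_step(base(0, 0), sim_config(a = 0.5, d = 0,
                                                n_donors = 1, n_recipients = 1))
  expect_equal(out$d_partner, 0L)
  expect_equal(out$r_partner, 0L)
  # d = 1 dissolves every surviving pair
  out <- commitment_step(base(1, 1), sim_config(a = 0.5, d = 1,
                                                n_donors = 1, n_recipients = 1))
  expect_equal(out$d_partner, 0L)
})

test_that("population and pairing invariants hold through noisy rounds", {
  cfg <- sim_config(a = 0.55, n_donors = 30, n_recipients = 25, L = 5,
                    generations = 2)
  set.seed(5)
  pop <- init_population(cfg)
  for (k in 1:20) {
    pop <- matching_step(pop)
    expect_pairing_integrity(pop)
    before_d <- pop$d_payoff; before_r <- pop$r_payoff
    pop <- play_round(pop, cfg)
    # each agent gains exactly one of {0, P, R, T} per round
    expect_true(all((pop$d_payoff - before_d) %in% c(0, 1, 4)))
    expect_true(all((pop$r_payoff - before_r) %in% c(0, 1, 4, 6)))
    pop <- commitment_step(pop, cfg)
    expect_pairing_integrity(pop)
    expect_length(pop$d_partner, 30)
    expect_length(pop$r_partner, 25)
  }
})

test_that("composing the step functions reproduces the generation engine", {
  cfg <- sim_config(a = 0.6, n_donors = 40, n_recipients = 40, L = 25,
                    generations = 1)
  set.seed(11); pop0 <- init_population(cfg)
  set.seed(12); gen <- run_generation(pop0, cfg)
  set.seed(12)
  pop <- pop0
  for (t in seq_len(cfg$L)) {
    pop <- matching_step(pop)
    pop <- play_round(pop, cfg)
    pop <- commitment_step(pop, cfg)
  }
  expect_identical(gen$pop, pop)
})

test_that("imitation copies strict improvements and mutation explores", {
  # a single uniform strategy with M = 0 is frozen forever
  cfg <- sim_config(a = 0.6, n_donors = 20, n_recipients = 20, M = 0,
                    generations = 1)
  pop <- make_pop(rep(1, 20), rep(0, 20), r_intent = rep(0.5, 20))
  pop$d_payoff <- runif(20) * 10
  pop$r_payoff <- runif(20) * 10
  set.seed(3); out <- evolve_population(pop, cfg)
  expect_equal(out$match_gen, rep(1L, 20))
  expect_equal(out$exit_gen, rep(0L, 20))
  expect_equal(out$r_intent, rep(0.5, 20))
  # evolution resets state for the next generation
  expect_true(all(out$d_payoff == 0) && all(out$r_payoff == 0))
  expect_true(all(out$d_partner == 0) && all(out$r_history == 1L))
  # equal payoffs (ties) never trigger copying
  pop <- make_pop(rep(c(0, 1), 10), rep(c(1, 0), 10), r_intent = rep(c(0, 1), 10))
  set.seed(4); out <- evolve_population(pop, cfg)
  expect_identical(out$match_gen, pop$match_gen)
  expect_identical(out$r_intent, pop$r_intent)
  # agents holding the maximal payoff never copy anyone
  pop <- make_pop(rep(c(0, 1), 10), rep(0, 20), r_intent = rep(c(0, 1), 10))
  pop$d_payoff <- rep(c(5, 1), 10)
  pop$r_payoff <- rep(c(5, 1), 10)
  set.seed(6); out <- evolve_population(pop, cfg)
  expect_true(all(out$match_gen[seq(1, 19, 2)] == 0L))
  expect_true(all(out$r_intent[seq(1, 19, 2)] == 0))
  # M = 1 redraws every strategy uniformly
  cfg$M <- 1
  pop <- make_pop(rep(0, 2000), rep(0, 2000), r_intent = rep(0, 2000))
  set.seed(8); out <- evolve_population(pop, cfg)
  expect_true(abs(mean(out$match_gen) - 0.5) < 0.05)
  expect_true(abs(mean(out$r_intent) - 0.5) < 0.05)
})

test_that("trials are deterministic under a seed and conserve the population", {
  cfg <- sim_config(a = 0.6, n_donors = 40, n_recipients = 40, L = 20,
                    generations = 5, seed = 21)
  r1 <- run_trial(cfg)
  r2 <- run_trial(cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 5)
  shares <- r1$share_ST + r1$share_MG + r1$share_EG + r1$share_SG
  expect_equal(shares, rep(1, 5))
  expect_true(all(r1$mean_intent >= 0 & r1$mean_intent <= 1))
})

test_that("degenerate parameters behave as designed", {
  # d = 1: no pair survives its round, so every round re-matches from scratch
  cfg <- sim_config(a = 1, n_donors = 10, n_recipients = 10, d = 1, L = 8,
                    generations = 1)
  pop <- make_pop(rep(1, 10), rep(1, 10), r_intent = rep(1, 10))
  set.seed(13); gen <- run_generation(pop, cfg)
  expect_true(all(gen$pop$d_partner == 0))
  expect_equal(gen$metrics$iso_recipients, rep(0, 8)) # everyone re-pairs first
  # M = 0 with one strategy everywhere: distribution frozen forever
  cfg <- sim_config(a = 0.6, n_donors = 15, n_recipients = 15, M = 0,
                    generations = 1, L = 10)
  pop <- make_pop(rep(0, 15), rep(1, 15), r_intent = rep(1, 15))
  set.seed(14)
  for (g in 1:4) {
    pop <- run_generation(pop, cfg)$pop
    pop <- evolve_population(pop, cfg)
    expect_equal(pop$match_gen, rep(0L, 15))
    expect_equal(pop$exit_gen, rep(1L, 15))
    expect_equal(pop$r_intent, rep(1, 15))
  }
})

test_that("near-noiseless competence keeps the strict and exit-generous donors", {
  res <- t(vapply(1:3, function(s) {
    rec <- run_trial(sim_config(a = 0.97, n_donors = 100, n_recipients = 100,
                                generations = 25, seed = s))
    unlist(rec[25, c("share_ST", "share_EG", "mean_intent")])
  }, numeric(3)))
  expect_true(all(res[, "share_ST"] + res[, "share_EG"] > 0.5))
  expect_true(mean(res[, "mean_intent"]) > 0.7)
})
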