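# Evolutionary agent-based simulation of socially embedded trust.
#
# A population of donors and recipients meets in a matching pool. Donors
# differ in two generosity dimensions: matching generosity (accept a pool
# recipient whose last observed outcome was D) and exit generosity (keep a
# partner after a D outcome), giving four policies — ST (strict in both),
# MG (matching-generous only), EG (exit-generous only), SG (generous in
# both). Recipients carry an intent x in {0, 0.5, 1}, the probability of
# honouring the trust. Every L rounds, strategies spread by pairwise
# imitation of more successful same-role peers with mutation rate M.

DONOR_POLICIES <- c("ST", "MG", "EG", "SG")
# policy -> (matching_generous, exit_generous)
POLICY_FLAGS <- matrix(c(0L, 0L, 1L, 0L, 0L, 1L, 1L, 1L), ncol = 2, byrow = TRUE,
                       dimnames = list(DONOR_POLICIES, c("match", "exit")))
RECIPIENT_INTENTS <- c(0, 0.5, 1)

#' Configuration of the agent-based simulation
#'
#' Defaults are the benchmark: 250 donors and 250 recipients, exogenous
#' dissolution `d = 0.1`, `L = 100` rounds per generation, mutation rate
#' `M = 0.025`, stage payoffs `P = 1, R = 4, T = 6`. Competence `a` is
#' shared by all recipients and never evolves (a natural endowment).
#'
#' @param a Common competence in `[0, 1]`.
#' @param n_donors,n_recipients Population sizes.
#' @param d Exogenous dissolution probability per round.
#' @param L Rounds per generation.
#' @param M Mutation rate per agent per generation.
#' @param generations Number of generations per trial.
#' @param params A [payoff_params()].
#' @param seed Optional RNG seed for [run_trial()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(a, n_donors = 250, n_recipients = 250, d = 0.1,
                       L = 100, M = 0.025, generations = 100,
                       params = payoff_params(), seed = NULL) {
  stopifnot(is.numeric(a), length(a) == 1, a >= 0, a <= 1,
            is.numeric(d), d >= 0, d <= 1,
            is.numeric(M), M >= 0, M <= 1,
            inherits(params, "payoff_params"))
  n_donors <- as.integer(n_donors); n_recipients <- as.integer(n_recipients)
  L <- as.integer(L); generations <- as.integer(generations)
  stopifnot(n_donors >= 1, n_recipients >= 1, L >= 1, generations >= 1)
  structure(list(a = a, n_donors = n_donors, n_recipients = n_recipients,
                 d = d, L = L, M = M, generations = generations,
                 params = params, seed = seed),
            class = "sim_config")
}

#' Initialize a population
#'
#' Donors get uniformly random (matching, exit) generosity flags and
#' recipients a uniformly random intent from {0, 0.5, 1}. Everybody starts
#' unpaired with zero payoff; histories start at `C` so that strict
#' matchers can pair in round one.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `trust_population`: a list of parallel
#'   vectors (`match_gen`, `exit_gen`, `d_partner`, `d_payoff` for donors;
#'   `r_intent`, `r_history`, `r_partner`, `r_payoff` for recipients).
#'   Partner entries are indices into the opposite role, 0 when unpaired;
#'   histories are 1 for `C` and 0 for `D`.
#' @export
init_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  nd <- cfg$n_donors; nr <- cfg$n_recipients
  pol <- sample.int(4L, nd, replace = TRUE)
  structure(list(
    match_gen = POLICY_FLAGS[pol, "match"],
    exit_gen = POLICY_FLAGS[pol, "exit"],
    d_partner = integer(nd),
    d_payoff = numeric(nd),
    r_intent = sample(RECIPIENT_INTENTS, nr, replace = TRUE),
    r_history = rep(1L, nr),
    r_partner = integer(nr),
    r_payoff = numeric(nr)
  ), class = "trust_population")
}

#' Donor policy labels of a population
#'
#' @param pop A `trust_population`.
#' @return Character vector over `ST`, `MG`, `EG`, `SG`.
#' @export
donor_policy <- function(pop) {
  stopifnot(inherits(pop, "trust_population"))
  DONOR_POLICIES[1L + pop$match_gen + 2L * pop$exit_gen]
}

#' One matching step
#'
#' Unpaired donors, visited in a fresh random order, each pick one
#' recipient uniformly at random among the currently pooled recipients
#' whose history they accept (strict matchers: history `C` only;
#' matching-generous: any). A chosen recipient leaves the pool
#' immediately; a donor with no acceptable recipient stays unpaired.
#'
#' @param pop A `trust_population`.
#' @return The updated population.
#' @export
matching_step <- function(pop) {
  stopifnot(inherits(pop, "trust_population"))
  upd <- abm_match_cpp(pop$match_gen, pop$d_partner, pop$r_history, pop$r_partner)
  pop$d_partner <- upd$d_partner
  pop$r_partner <- upd$r_partner
  pop
}

#' One played round
#'
#' Each pair plays the modified trust sub-game: the recipient honours the
#' trust with probability `x` (its intent) and succeeds with probability
#' `a`; payoffs follow [play_subgame()] and the recipient's history is set
#' by the observable outcome. Every unpaired agent of either role collects
#' the isolation payoff `P`.
#'
#' @param pop A `trust_population`.
#' @param cfg A [sim_config()].
#' @return The updated population.
#' @export
play_round <- function(pop, cfg) {
  stopifnot(inherits(pop, "trust_population"), inherits(cfg, "sim_config"))
  upd <- abm_play_cpp(pop$d_partner, pop$r_partner, pop$r_intent,
                      pop$r_history, pop$d_payoff, pop$r_payoff,
                      cfg$a, cfg$params$P, cfg$params$R, cfg$params$T)
  pop$r_history <- upd$r_history
  pop$d_payoff <- upd$d_payoff
  pop$r_payoff <- upd$r_payoff
  pop
}

#' One commitment (exit) step
#'
#' An exit-strict donor dissolves the pair when the partner's observed
#' history is `D`; every pair surviving that check dissolves exogenously
#' with probability `d`. Dissolved members return to the pool (the donor
#' re-selects next round, the recipient waits to be chosen).
#'
#' @param pop A `trust_population`.
#' @param cfg A [sim_config()].
#' @return The updated population.
#' @export
commitment_step <- function(pop, cfg) {
  stopifnot(inherits(pop, "trust_population"), inherits(cfg, "sim_config"))
  upd <- abm_commit_cpp(pop$exit_gen, pop$d_partner, pop$r_history,
                        pop$r_partner, cfg$d)
  pop$d_partner <- upd$d_partner
  pop$r_partner <- upd$r_partner
  pop
}

#' Run one generation of L rounds
#'
#' Executes `cfg$L` rounds of matching, play and commitment in the
#' compiled engine and records, after each matching step, the number of
#' pooled recipients and the number of pooled recipients with good intent
#' but a bad history.
#'
#' @param pop A `trust_population`.
#' @param cfg A [sim_config()].
#' @param good_x_min Smallest intent counted as "good intention" in the
#'   isolation metric (default 1: only fully cooperative recipients; set
#'   0.5 to include half-hearted ones).
#' @return A list with the updated `pop` and `metrics`, a data frame of
#'   per-round pool counts (`round`, `iso_recipients`, `iso_good_bad`).
#' @export
run_generation <- function(pop, cfg, good_x_min = 1) {
  stopifnot(inherits(pop, "trust_population"), inherits(cfg, "sim_config"))
  upd <- abm_generation_cpp(pop$match_gen, pop$exit_gen, pop$d_partner,
                            pop$d_payoff, pop$r_intent, pop$r_history,
                            pop$r_partner, pop$r_payoff,
                            cfg$a, cfg$d, cfg$params$P, cfg$params$R,
                            cfg$params$T, cfg$L, good_x_min)
  pop$d_partner <- upd$d_partner
  pop$d_payoff <- upd$d_payoff
  pop$r_history <- upd$r_history
  pop$r_partner <- upd$r_partner
  pop$r_payoff <- upd$r_payoff
  list(pop = pop,
       metrics = data.frame(round = seq_len(cfg$L),
                            iso_recipients = upd$iso_recipients,
                            iso_good_bad = upd$iso_good_bad))
}

#' Imitation dynamics with mutation
#'
#' Role-wise synchronous update: each agent samples one uniformly random
#' same-role peer and adopts the peer's full strategy exactly when the
#' peer's cumulative generation payoff is strictly higher (ties keep the
#' own strategy); afterwards, with probability `M`, the agent's strategy is
#' replaced by a uniformly random strategy from its role's space.
#' Competence never changes. Payoffs, pairings and histories are reset for
#' the next generation (histories back to `C`).
#'
#' @param pop A `trust_population`.
#' @param cfg A [sim_config()].
#' @return The evolved, reset population.
#' @export
evolve_population <- function(pop, cfg) {
  stopifnot(inherits(pop, "trust_population"), inherits(cfg, "sim_config"))
  nd <- length(pop$match_gen); nr <- length(pop$r_intent)

  peer <- sample.int(nd, nd, replace = TRUE)
  copy <- pop$d_payoff[peer] > pop$d_payoff
  match_gen <- ifelse(copy, pop$match_gen[peer], pop$match_gen)
  exit_gen <- ifelse(copy, pop$exit_gen[peer], pop$exit_gen)
  mut <- stats::runif(nd) < cfg$M
  if (any(mut)) {
    pol <- sample.int(4L, sum(mut), replace = TRUE)
    match_gen[mut] <- POLICY_FLAGS[pol, "match"]
    exit_gen[mut] <- POLICY_FLAGS[pol, "exit"]
  }

  rpeer <- sample.int(nr, nr, replace = TRUE)
  rcopy <- pop$r_payoff[rpeer] > pop$r_payoff
  r_intent <- ifelse(rcopy, pop$r_intent[rpeer], pop$r_intent)
  rmut <- stats::runif(nr) < cfg$M
  if (any(rmut)) {
    r_intent[rmut] <- sample(RECIPIENT_INTENTS, sum(rmut), replace = TRUE)
  }

  pop$match_gen <- as.integer(match_gen)
  pop$exit_gen <- as.integer(exit_gen)
  pop$r_intent <- as.numeric(r_intent)
  pop$d_partner <- integer(nd)
  pop$r_partner <- integer(nr)
  pop$d_payoff <- numeric(nd)
  pop$r_payoff <- numeric(nr)
  pop$r_history <- rep(1L, nr)
  pop
}

#' Run one simulation trial
#'
#' Initializes a population and iterates `cfg$generations` generations of
#' `cfg$L` rounds each, evolving strategies at every generation boundary.
#' Fully reproducible: `cfg$seed` (when non-`NULL`) seeds R's RNG at the
#' start of the trial.
#'
#' @param cfg A [sim_config()].
#' @param trial Trial identifier stored in the output (default 1).
#' @param good_x_min See [run_generation()].
#' @return A data frame with one row per generation: `trial`, `generation`,
#'   donor strategy shares `share_ST`, `share_MG`, `share_EG`, `share_SG`,
#'   `mean_intent`, and the generation means of the per-round pool counts
#'   `n_isolated_recipients` and `n_isolated_good_intent_bad_history`.
#'   Shares and intent describe the strategy distribution that played the
#'   generation (recorded before the evolution step).
#' @export
run_trial <- function(cfg, trial = 1L, good_x_min = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pop <- init_population(cfg)
  rows <- vector("list", cfg$generations)
  for (g in seq_len(cfg$generations)) {
    gen <- run_generation(pop, cfg, good_x_min = good_x_min)
    pop <- gen$pop
    pol <- donor_policy(pop)
    rows[[g]] <- data.frame(
      trial = trial, generation = g,
      share_ST = mean(pol == "ST"), share_MG = mean(pol == "MG"),
      share_EG = mean(pol == "EG"), share_SG = mean(pol == "SG"),
      mean_intent = mean(pop$r_intent),
      n_isolated_recipients = mean(gen$metrics$iso_recipients),
      n_isolated_good_intent_bad_history = mean(gen$metrics$iso_good_bad))
    pop <- evolve_population(pop, cfg)
  }
  do.call(rbind, rows)
}
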