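# Exact expected total payoffs of the finite-horizon repeated game.
#
# Each donor strategy x recipient strategy pair induces a small absorbing
# Markov chain over relationship states; the expected total payoff of both
# parties is obtained by forward propagation of the state distribution with
# per-round expected-reward accumulation, which is exact for the finite
# horizon (no truncation of a fundamental-matrix series).

DONOR_STRATEGIES <- c("H", "M", "L")
RECIPIENT_STRATEGIES <- c("C", "D")

CHAIN_STATES <- c("IN", "RR", "RF", "FF", "BROKEN")

check_donor <- function(donor) {
  if (!(is.character(donor) && length(donor) == 1 && donor %in% DONOR_STRATEGIES)) {
    stop("donor strategy must be one of ", paste(DONOR_STRATEGIES, collapse = ", "))
  }
  donor
}

check_recipient <- function(recipient) {
  if (!(is.character(recipient) && length(recipient) == 1 &&
        recipient %in% RECIPIENT_STRATEGIES)) {
    stop("recipient strategy must be one of ",
         paste(RECIPIENT_STRATEGIES, collapse = ", "))
  }
  recipient
}

#' Markov chain of a strategy pair
#'
#' Builds the per-round transition matrix and expected one-round rewards for
#' a donor strategy (`H` never exits, `M` exits after two consecutive `D`
#' outcomes, `L` exits after one) against a pure recipient strategy (`C`
#' always intends to cooperate, `D` never does). States:
#' `IN` the initial state; `RR` good standing (last outcome was `C`);
#' `RF` one unforgiven `D` outcome (reachable only under `M`); `FF`
#' voluntary exit; `BROKEN` exogenous dissolution. `FF` and `BROKEN` are
#' absorbing and pay the isolation payoff `P` to both parties each round.
#'
#' Round ordering within a state transition: the sub-game is played first
#' (success with probability `a`), the donor then applies its exit rule to
#' the observed outcome, and a surviving pair finally dissolves exogenously
#' with probability `d`.
#'
#' @param donor `"H"`, `"M"` or `"L"`.
#' @param recipient `"C"` or `"D"`.
#' @param cfg A [game_config()].
#' @param params A [payoff_params()].
#' @return A list of class `chain_spec` with `states`, `transition` (5x5
#'   row-stochastic matrix) and `rewards` (5x2 matrix of expected one-round
#'   donor/recipient rewards per state).
#' @export
chain_spec <- function(donor, recipient, cfg, params = payoff_params()) {
  check_donor(donor); check_recipient(recipient)
  stopifnot(inherits(cfg, "game_config"), inherits(params, "payoff_params"))
  a <- cfg$a; d <- cfg$d
  # probability the observed outcome is C (cooperate AND succeed)
  pc <- if (recipient == "C") a else 0
  # expected one-round rewards while the pair is intact
  rew <- if (recipient == "C") c(a * params$R, a * params$R) else c(0, a * params$T)

  tm <- matrix(0, 5, 5, dimnames = list(CHAIN_STATES, CHAIN_STATES))
  intact_from <- function(state) {
    if (donor == "H") {
      tm[state, "RR"] <<- 1 - d
      tm[state, "BROKEN"] <<- d
    } else if (donor == "L") {
      tm[state, "RR"] <<- pc * (1 - d)
      tm[state, "BROKEN"] <<- pc * d
      tm[state, "FF"] <<- 1 - pc
    } else { # M: forgive a first D, exit on a D observed from RF
      tm[state, "RR"] <<- pc * (1 - d)
      tm[state, "RF"] <<- (1 - pc) * (1 - d)
      tm[state, "BROKEN"] <<- d
    }
  }
  intact_from("IN")
  intact_from("RR")
  if (donor == "M") {
    # from RF a success resets the forgiveness counter, a failure means exit
    tm["RF", "RR"] <- pc * (1 - d)
    tm["RF", "BROKEN"] <- pc * d
    tm["RF", "FF"] <- 1 - pc
  } else {
    tm["RF", "FF"] <- 1 # unreachable under H and L
  }
  tm["FF", "FF"] <- 1
  tm["BROKEN", "BROKEN"] <- 1

  rewards <- rbind(IN = rew, RR = rew, RF = rew,
                   FF = c(params$P, params$P), BROKEN = c(params$P, params$P))
  colnames(rewards) <- c("donor", "recipient")
  structure(list(states = CHAIN_STATES, transition = tm, rewards = rewards,
                 donor = donor, recipient = recipient),
            class = "chain_spec")
}

#' Exact expected total payoffs of the repeated game
#'
#' Propagates the state distribution of the strategy pair's chain forward
#' over `cfg$n_rounds` rounds (round 1 is always played: every donor
#' strategy trusts an untested partner), accumulating each round's expected
#' rewards. After any break, voluntary or exogenous, both parties collect
#' the isolation payoff `P` per remaining round and never re-match.
#'
#' @inheritParams chain_spec
#' @return Named numeric vector `c(donor =, recipient =)` of expected totals.
#' @examples
#' cfg <- game_config(a = 1, d = 0)
#' expected_total_payoffs("H", "C", cfg)   # 100 rounds of R: (400, 400)
#' @export
expected_total_payoffs <- function(donor, recipient, cfg, params = payoff_params()) {
  spec <- chain_spec(donor, recipient, cfg, params)
  v <- c(1, 0, 0, 0, 0)
  tot <- c(donor = 0, recipient = 0)
  for (k in seq_len(cfg$n_rounds)) {
    tot <- tot + as.vector(v %*% spec$rewards)
    v <- as.vector(v %*% spec$transition)
  }
  tot
}

#' Entire-game payoff matrix
#'
#' Assembles the six expected-total-payoff pairs for donor rows `H`, `M`,
#' `L` against recipient columns `C`, `D`. Entries are named after the
#' conventional cell labels: `(a1, a2)` for `(H, C)`, `(b1, b2)` for
#' `(H, D)`, `(c1, c2)` for `(M, C)`, `(d1, d2)` for `(M, D)`, `(e1, e2)`
#' for `(L, C)`, `(f1, f2)` for `(L, D)`; index 1 is the donor, 2 the
#' recipient.
#'
#' @inheritParams chain_spec
#' @return An object of class `payoff_matrix`: a list with `donor` and
#'   `recipient` 3x2 matrices (rows H/M/L, columns C/D), the flat named
#'   entries `a1 ... f2`, and the generating `cfg` and `params`.
#' @export
payoff_matrix <- function(cfg, params = payoff_params()) {
  md <- matrix(0, 3, 2, dimnames = list(DONOR_STRATEGIES, RECIPIENT_STRATEGIES))
  mr <- md
  for (row in DONOR_STRATEGIES) {
    for (col in RECIPIENT_STRATEGIES) {
      tot <- expected_total_payoffs(row, col, cfg, params)
      md[row, col] <- tot[["donor"]]
      mr[row, col] <- tot[["recipient"]]
    }
  }
  cells <- c(a1 = md["H", "C"], a2 = mr["H", "C"],
             b1 = md["H", "D"], b2 = mr["H", "D"],
             c1 = md["M", "C"], c2 = mr["M", "C"],
             d1 = md["M", "D"], d2 = mr["M", "D"],
             e1 = md["L", "C"], e2 = mr["L", "C"],
             f1 = md["L", "D"], f2 = mr["L", "D"])
  structure(list(donor = md, recipient = mr, cells = as.list(cells),
                 cfg = cfg, params = params),
            class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("Entire-game expected payoffs (donor, recipient), n =",
      x$cfg$n_rounds, "rounds, a =", x$cfg$a, ", d =", x$cfg$d, "\n")
  tab <- matrix(sprintf("(%.4g, %.4g)", x$donor, x$recipient), 3, 2,
                dimnames = dimnames(x$donor))
  print(tab, quote = FALSE)
  invisible(x)
}

#' Tidy the payoff matrix into a table
#'
#' @param m A [payoff_matrix()].
#' @return A data frame with columns `donor`, `recipient`, `donor_payoff`,
#'   `recipient_payoff`, one row per strategy pair.
#' @export
payoff_matrix_table <- function(m) {
  stopifnot(inherits(m, "payoff_matrix"))
  grid <- expand.grid(donor = DONOR_STRATEGIES, recipient = RECIPIENT_STRATEGIES,
                      stringsAsFactors = FALSE)
  grid$donor_payoff <- m$donor[cbind(grid$donor, grid$recipient)]
  grid$recipient_payoff <- m$recipient[cbind(grid$donor, grid$recipient)]
  grid
}

#' Monte-Carlo oracle for the repeated game
#'
#' Simulates the repeated game with explicit Bernoulli draws for success and
#' exogenous dissolution (no chain algebra), across `n_reps` independent
#' replicates. Serves as an independent check of
#' [expected_total_payoffs()].
#'
#' @inheritParams chain_spec
#' @param n_reps Number of replicates.
#' @param seed Optional RNG seed set before drawing.
#' @return A list with `mean` and `se` (each `c(donor =, recipient =)`)
#'   and `n_reps`.
#' @export
simulate_repeated_game <- function(donor, recipient, cfg,
                                   params = payoff_params(),
                                   n_reps = 1000, seed = NULL) {
  check_donor(donor); check_recipient(recipient)
  stopifnot(inherits(cfg, "game_config"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- cfg$a; d <- cfg$d
  coop <- recipient == "C"
  tot_d <- numeric(n_reps)
  tot_r <- numeric(n_reps)
  # per-replicate relationship state: 0 intact/fresh, 1 one unforgiven D, 2 broken
  state <- integer(n_reps)
  for (k in seq_len(cfg$n_rounds)) {
    alive <- state < 2L
    n_alive <- sum(alive)
    tot_d[!alive] <- tot_d[!alive] + params$P
    tot_r[!alive] <- tot_r[!alive] + params$P
    if (n_alive == 0L) next
    succ <- stats::runif(n_alive) < a
    if (coop) {
      tot_d[alive] <- tot_d[alive] + ifelse(succ, params$R, 0)
      tot_r[alive] <- tot_r[alive] + ifelse(succ, params$R, 0)
      outcome_D <- !succ
    } else {
      tot_r[alive] <- tot_r[alive] + ifelse(succ, params$T, 0)
      outcome_D <- rep(TRUE, n_alive)
    }
    st <- state[alive]
    exit <- switch(donor,
                   H = rep(FALSE, n_alive),
                   L = outcome_D,
                   M = outcome_D & st == 1L)
    # M's forgiveness counter: set after one D, reset on any success;
    # meaningless (kept at 0) for H and L
    st <- if (donor == "M") ifelse(outcome_D, 1L, 0L) else rep(0L, n_alive)
    st[exit] <- 2L
    # exogenous dissolution only for pairs that survived the voluntary check
    surv <- st < 2L
    if (any(surv)) {
      diss <- stats::runif(sum(surv)) < d
      st[surv][diss] <- 2L
    }
    state[alive] <- st
  }
  mean_ <- c(donor = mean(tot_d), recipient = mean(tot_r))
  se_ <- c(donor = stats::sd(tot_d), recipient = stats::sd(tot_r)) / sqrt(n_reps)
  list(mean = mean_, se = se_, n_reps = n_reps)
}
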