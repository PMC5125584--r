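# Single-round mechanics of the modified trust game.
#
# One sub-game round: a donor decides whether to entrust a resource to a
# recipient; the recipient decides whether to honour the trust; "nature"
# then decides whether the recipient's undertaking succeeds (probability a,
# the recipient's competence). The donor observes only the outcome, so an
# honest failure and an intentional betrayal are indistinguishable.

#' Stage payoffs of the modified trust game
#'
#' Bundles the three stage payoffs: the isolation payoff `P` both parties
#' collect when no trust is extended (or after a relationship has broken),
#' the mutual-cooperation payoff `R`, and the temptation payoff `T` a
#' defecting recipient keeps for itself. Valid payoffs satisfy
#' `T > R > P > 0` and `2R > T`, so mutual cooperation beats alternating
#' exploitation but defection still tempts the recipient.
#'
#' @param P Isolation payoff (default 1).
#' @param R Cooperation payoff (default 4).
#' @param T Temptation payoff (default 6).
#' @return An object of class `payoff_params`.
#' @examples
#' payoff_params()          # benchmark P = 1, R = 4, T = 6
#' @export
payoff_params <- function(P = 1, R = 4, T = 6) {
  stopifnot(is.numeric(P), is.numeric(R), is.numeric(T),
            length(P) == 1, length(R) == 1, length(T) == 1)
  if (!(T > R && R > P && P > 0)) {
    stop("payoffs must satisfy T > R > P > 0 (got P=", P, ", R=", R, ", T=", T, ")")
  }
  if (!(2 * R > T)) {
    stop("payoffs must satisfy 2R > T (got R=", R, ", T=", T, ")")
  }
  structure(list(P = P, R = R, T = T), class = "payoff_params")
}

#' Configuration of the repeated game
#'
#' @param a Competence: probability in `[0, 1]` that the recipient's
#'   undertaking succeeds, independent of intent.
#' @param d Exogenous dissolution probability in `[0, 1]`: each round an
#'   intact relationship breaks for outside reasons with this probability.
#' @param n_rounds Horizon of the repeated game (default 100).
#' @return An object of class `game_config`.
#' @export
game_config <- function(a, d = 0.1, n_rounds = 100) {
  stopifnot(is.numeric(a), length(a) == 1, is.numeric(d), length(d) == 1)
  if (a < 0 || a > 1) stop("competence a must lie in [0, 1], got ", a)
  if (d < 0 || d > 1) stop("dissolution probability d must lie in [0, 1], got ", d)
  n_rounds <- as.integer(n_rounds)
  if (is.na(n_rounds) || n_rounds < 1) stop("n_rounds must be a positive integer")
  structure(list(a = a, d = d, n_rounds = n_rounds), class = "game_config")
}

#' Play one realized sub-game round
#'
#' Resolves the game tree of a single round. If the donor withholds trust the
#' round ends at the isolation payoffs `(P, P)`. If trust is extended, the
#' recipient's intent and the success draw determine the outcome: honoured
#' trust that succeeds pays `(R, R)` and records history `C`; a successful
#' betrayal pays `(0, T)`; any failure pays `(0, 0)`. Every outcome other
#' than honoured-and-successful is recorded as history `D` — the donor cannot
#' tell malice from incompetence.
#'
#' @param trusted Did the donor entrust its resource?
#' @param cooperated Did the recipient intend to honour the trust? Ignored
#'   when `trusted` is `FALSE`.
#' @param succeeded Did the undertaking succeed? Ignored when `trusted` is
#'   `FALSE`.
#' @param params A [payoff_params()] object.
#' @return A list with `donor_payoff`, `recipient_payoff` and `history`
#'   (`"C"` or `"D"`; `NA` when no trust was extended, since the recipient
#'   produced no observable outcome).
#' @export
play_subgame <- function(trusted, cooperated = NA, succeeded = NA,
                         params = payoff_params()) {
  stopifnot(inherits(params, "payoff_params"), is.logical(trusted))
  if (!trusted) {
    return(list(donor_payoff = params$P, recipient_payoff = params$P,
                history = NA_character_))
  }
  stopifnot(is.logical(cooperated), is.logical(succeeded))
  if (!succeeded) {
    list(donor_payoff = 0, recipient_payoff = 0, history = "D")
  } else if (cooperated) {
    list(donor_payoff = params$R, recipient_payoff = params$R, history = "C")
  } else {
    list(donor_payoff = 0, recipient_payoff = params$T, history = "D")
  }
}

#' Expected sub-game payoffs over the success draw
#'
#' Marginalises [play_subgame()] over the Bernoulli(`a`) success draw,
#' giving the one-round payoff matrix entries: `(aR, aR)` for trusted
#' cooperation, `(0, aT)` for trusted defection, `(P, P)` when trust is
#' withheld.
#'
#' @param donor_trusts,recipient_cooperates Logical flags.
#' @param a Competence in `[0, 1]`.
#' @param params A [payoff_params()] object.
#' @return Named numeric vector `c(donor =, recipient =)`.
#' @export
expected_subgame_payoffs <- function(donor_trusts, recipient_cooperates, a,
                                     params = payoff_params()) {
  stopifnot(is.numeric(a), length(a) == 1, a >= 0, a <= 1,
            inherits(params, "payoff_params"))
  if (!donor_trusts) {
    c(donor = params$P, recipient = params$P)
  } else if (recipient_cooperates) {
    c(donor = a * params$R, recipient = a * params$R)
  } else {
    c(donor = 0, recipient = a * params$T)
  }
}

#' Observable history of a round
#'
#' The donor only sees the returned share, so the recorded history is `C`
#' exactly when the recipient both intended to cooperate and succeeded,
#' and `D` in every other case (betrayal or honest failure alike).
#'
#' @param cooperated,succeeded Logical flags.
#' @return `"C"` or `"D"`.
#' @export
update_history <- function(cooperated, succeeded) {
  if (isTRUE(cooperated) && isTRUE(succeeded)) "C" else "D"
}
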