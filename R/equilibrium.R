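# Nash-equilibrium analysis of the entire-game payoff matrix.
#
# The 3x2 bimatrix (donor rows H/M/L, recipient columns C/D) admits a
# mixed equilibrium in which the donor mixes H and M and the recipient
# mixes C and D whenever three conditions on the payoff differences hold.
# Competence thresholds for Pareto efficiency of (H, C), for cooperation,
# and for uniqueness of the mixed equilibrium are located by root-finding
# on the matrix entries as functions of competence a.

#' Mixed-equilibrium conditions
#'
#' Evaluates the three conditions for a mixed Nash equilibrium in which the
#' donor mixes `H` and `M` while the recipient mixes `C` and `D`:
#' \describe{
#'   \item{C1}{`(d1 - b1) / (a1 - c1 + d1 - b1)` lies in `(0, 1)` — the
#'     recipient's cooperation probability that leaves the donor indifferent
#'     between `H` and `M` is a proper probability.}
#'   \item{C2}{`((d1 - b1)(a1 - e1) + (a1 - c1)(b1 - f1)) /
#'     (a1 - c1 + d1 - b1) > 0` — at that mixture the donor strictly prefers
#'     the `H`/`M` mix to deviating to `L`.}
#'   \item{C3}{`(c2 - d2) / ((c2 - d2) + (b2 - a2))` lies in `(0, 1)` — the
#'     donor's `H` probability that leaves the recipient indifferent between
#'     `C` and `D` is a proper probability.}
#' }
#'
#' @param m A [payoff_matrix()].
#' @return A list with the raw `value` and logical `holds` for each of
#'   `C1`, `C2`, `C3`, plus `degenerate` flags where a denominator vanished
#'   (the value is then `NA` rather than a division by zero).
#' @export
evaluate_conditions <- function(m) {
  stopifnot(inherits(m, "payoff_matrix"))
  cl <- m$cells
  den13 <- cl$a1 - cl$c1 + cl$d1 - cl$b1
  den3 <- (cl$c2 - cl$d2) + (cl$b2 - cl$a2)
  c1_val <- if (den13 == 0) NA_real_ else (cl$d1 - cl$b1) / den13
  c2_val <- if (den13 == 0) NA_real_ else
    ((cl$d1 - cl$b1) * (cl$a1 - cl$e1) + (cl$a1 - cl$c1) * (cl$b1 - cl$f1)) / den13
  c3_val <- if (den3 == 0) NA_real_ else (cl$c2 - cl$d2) / den3
  list(
    C1 = list(value = c1_val, holds = isTRUE(c1_val > 0 && c1_val < 1),
              degenerate = den13 == 0),
    C2 = list(value = c2_val, holds = isTRUE(c2_val > 0),
              degenerate = den13 == 0),
    C3 = list(value = c3_val, holds = isTRUE(c3_val > 0 && c3_val < 1),
              degenerate = den3 == 0)
  )
}

#' Mixed Nash equilibrium of the entire game
#'
#' When conditions C1-C3 all hold, returns the mixing probabilities:
#' `q_C`, the recipient's probability of `C` that makes the donor
#' indifferent between `H` and `M`, and `p_H`, the donor's probability of
#' `H` (with `1 - p_H` on `M`, none on `L`) that makes the recipient
#' indifferent between `C` and `D`.
#'
#' @param m A [payoff_matrix()].
#' @return A list `list(p_H =, q_C =)`, or `NULL` when no such equilibrium
#'   exists.
#' @export
mixed_equilibrium <- function(m) {
  cond <- evaluate_conditions(m)
  if (!(cond$C1$holds && cond$C2$holds && cond$C3$holds)) return(NULL)
  list(p_H = cond$C3$value, q_C = cond$C1$value)
}

#' Pure Nash equilibria of the entire game
#'
#' Exhaustively checks every cell of the 3x2 bimatrix for mutual best
#' response. With `strict = FALSE` (default) a tie counts as a best
#' response (weak Nash equilibrium); with `strict = TRUE` each player's
#' action must be a unique maximiser.
#'
#' @param m A [payoff_matrix()].
#' @param strict Require strict best responses?
#' @return A data frame with columns `donor` and `recipient`, one row per
#'   pure equilibrium (zero rows if none).
#' @export
pure_equilibria <- function(m, strict = FALSE) {
  stopifnot(inherits(m, "payoff_matrix"))
  res <- list()
  for (row in rownames(m$donor)) {
    for (col in colnames(m$donor)) {
      dbest <- if (strict) {
        all(m$donor[row, col] > m$donor[setdiff(rownames(m$donor), row), col])
      } else {
        m$donor[row, col] >= max(m$donor[, col])
      }
      rbest <- if (strict) {
        all(m$recipient[row, col] > m$recipient[row, setdiff(colnames(m$donor), col)])
      } else {
        m$recipient[row, col] >= max(m$recipient[row, ])
      }
      if (dbest && rbest) res[[length(res) + 1L]] <- c(row, col)
    }
  }
  if (length(res) == 0) {
    data.frame(donor = character(), recipient = character())
  } else {
    do.call(rbind.data.frame,
            lapply(res, function(x) data.frame(donor = x[1], recipient = x[2])))
  }
}

#' Pareto efficiency of mutual high-generosity cooperation
#'
#' Is the `(H, C)` outcome Pareto efficient, i.e. is there no other cell
#' that makes one player strictly better off without harming the other?
#' With these payoffs this holds exactly when the per-round cooperation
#' surplus is strictly positive, `aR > P`: at `aR = P` the whole cooperate
#' column collapses onto the isolation stream, cooperation yields no strict
#' improvement over isolation, and the outcome is not reported as
#' efficient.
#'
#' @param m A [payoff_matrix()].
#' @return `TRUE` or `FALSE`.
#' @export
pareto_hc <- function(m) {
  stopifnot(inherits(m, "payoff_matrix"))
  hc <- c(m$donor["H", "C"], m$recipient["H", "C"])
  # strict-surplus convention at the boundary aR = P
  if (hc[1] <= m$cfg$n_rounds * m$params$P) return(FALSE)
  for (row in rownames(m$donor)) {
    for (col in colnames(m$donor)) {
      if (row == "H" && col == "C") next
      other <- c(m$donor[row, col], m$recipient[row, col])
      if (all(other >= hc) && any(other > hc)) return(FALSE)
    }
  }
  TRUE
}

threshold_objective <- function(criterion, a, d, n_rounds, params) {
  m <- payoff_matrix(game_config(a = a, d = d, n_rounds = n_rounds), params)
  cl <- m$cells
  switch(criterion,
    # C2 numerator changes sign where (H,C) gains/loses Pareto efficiency
    pareto = (cl$d1 - cl$b1) * (cl$a1 - cl$e1) + (cl$a1 - cl$c1) * (cl$b1 - cl$f1),
    # recipient indifferent between C and D against M
    cooperation = cl$c2 - cl$d2,
    # recipient indifferent between C and D against L: above the root,
    # (L, D) stops being a pure equilibrium
    uniqueness = cl$e2 - cl$f2,
    stop("unknown criterion '", criterion, "'")
  )
}

#' Competence thresholds of the repeated game
#'
#' Locates the competence value at which one of three regime boundaries
#' occurs, by a grid pre-scan for a single sign change followed by
#' bisection (via [stats::uniroot()]) to the requested tolerance:
#' \describe{
#'   \item{`"pareto"`}{`(H, C)` becomes Pareto efficient and condition C2
#'     turns positive; analytically the root of `aR - P`.}
#'   \item{`"cooperation"`}{the recipient's best response to `M` flips from
#'     `D` to `C` (`c2 = d2`) — the cooperation threshold.}
#'   \item{`"uniqueness"`}{`(L, D)` ceases to be a pure Nash equilibrium
#'     (`e2 = f2`), leaving the mixed equilibrium as the only one.}
#' }
#'
#' @param criterion One of `"pareto"`, `"cooperation"`, `"uniqueness"`.
#' @param d Exogenous dissolution probability.
#' @param n_rounds Horizon.
#' @param params A [payoff_params()].
#' @param tol Bracket tolerance for the bisection (default `1e-6`).
#' @param digits Decimal places for the reported threshold; `NULL` for the
#'   full-precision root.
#' @return The competence threshold (scalar).
#' @examples
#' \donttest{
#' find_threshold("pareto")       # 0.25 with the benchmark payoffs
#' }
#' @export
find_threshold <- function(criterion = c("pareto", "cooperation", "uniqueness"),
                           d = 0.1, n_rounds = 100, params = payoff_params(),
                           tol = 1e-6, digits = 2) {
  criterion <- match.arg(criterion)
  f <- function(a) threshold_objective(criterion, a, d, n_rounds, params)
  grid <- seq(0.01, 1, by = 0.01)
  vals <- vapply(grid, f, numeric(1))
  # locate sign changes between consecutive non-zero values; an exact zero
  # at a grid point counts as a root only if flanked by opposite signs
  # (zeros with same-sign neighbours, e.g. the degenerate boundary a = 1
  # where all cooperate-column totals coincide, are not crossings)
  nz <- which(vals != 0)
  s <- sign(vals[nz])
  flips <- which(s[-1] != s[-length(s)])
  if (length(flips) == 0) {
    stop("criterion '", criterion, "' has no sign change on (0, 1]")
  }
  if (length(flips) > 1) {
    stop("criterion '", criterion, "' changes sign more than once on (0, 1]")
  }
  lo <- nz[flips]; hi <- nz[flips + 1]
  root <- if (hi == lo + 2L && vals[lo + 1L] == 0) {
    grid[lo + 1L] # the grid point itself is the root
  } else {
    stats::uniroot(f, lower = grid[lo], upper = grid[hi], tol = tol)$root
  }
  if (is.null(digits)) root else round(root, digits)
}

#' Classify the equilibrium regime at a competence level
#'
#' Computes the payoff matrix at competence `a` and labels the regime from
#' the computed equilibria and Pareto check (never from hard-coded
#' cut-offs): whether `(L, D)` is the only equilibrium and `(H, C)` is
#' Pareto-inefficient; the same with `(H, C)` Pareto efficient; coexistence
#' of `(L, D)` with the mixed equilibrium; or the mixed equilibrium alone.
#'
#' @param a Competence in `[0, 1]`.
#' @param d Exogenous dissolution probability.
#' @param n_rounds Horizon.
#' @param params A [payoff_params()].
#' @return One of `"only-LD-not-pareto"`, `"only-LD-pareto"`,
#'   `"LD-and-mixed"`, `"mixed-only"` (or `"other"` for parameter corners
#'   outside the four canonical regimes).
#' @export
classify_regime <- function(a, d = 0.1, n_rounds = 100, params = payoff_params()) {
  m <- payoff_matrix(game_config(a = a, d = d, n_rounds = n_rounds), params)
  pure <- pure_equilibria(m)
  mixed <- mixed_equilibrium(m)
  pareto <- pareto_hc(m)
  only_ld <- nrow(pure) == 1 && pure$donor == "L" && pure$recipient == "D"
  if (only_ld && is.null(mixed)) {
    if (pareto) "only-LD-pareto" else "only-LD-not-pareto"
  } else if (only_ld && !is.null(mixed)) {
    "LD-and-mixed"
  } else if (nrow(pure) == 0 && !is.null(mixed)) {
    "mixed-only"
  } else {
    "other"
  }
}

#' Full equilibrium report for one parameter setting
#'
#' Convenience wrapper assembling the payoff matrix, the condition values,
#' pure and mixed equilibria, the Pareto flag, the three competence
#' thresholds and the regime label into one object.
#'
#' @param a Competence in `[0, 1]`.
#' @param d Exogenous dissolution probability.
#' @param n_rounds Horizon.
#' @param params A [payoff_params()].
#' @return A list of class `equilibrium_report`.
#' @export
analyze_game <- function(a, d = 0.1, n_rounds = 100, params = payoff_params()) {
  m <- payoff_matrix(game_config(a = a, d = d, n_rounds = n_rounds), params)
  structure(list(
    a = a, d = d, n_rounds = n_rounds, params = params,
    matrix = m,
    conditions = evaluate_conditions(m),
    pure_equilibria = pure_equilibria(m),
    mixed = mixed_equilibrium(m),
    pareto_HC = pareto_hc(m),
    thresholds = c(
      pareto = find_threshold("pareto", d = d, n_rounds = n_rounds, params = params),
      cooperation = find_threshold("cooperation", d = d, n_rounds = n_rounds,
                                   params = params),
      uniqueness = find_threshold("uniqueness", d = d, n_rounds = n_rounds,
                                  params = params)
    ),
    regime = classify_regime(a, d = d, n_rounds = n_rounds, params = params)
  ), class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("Modified trust game, a =", x$a, ", d =", x$d, ", n =", x$n_rounds, "\n\n")
  print(x$matrix)
  cat("\nConditions: C1 =", signif(x$conditions$C1$value, 4),
      "(", x$conditions$C1$holds, "), C2 =", signif(x$conditions$C2$value, 4),
      "(", x$conditions$C2$holds, "), C3 =", signif(x$conditions$C3$value, 4),
      "(", x$conditions$C3$holds, ")\n")
  if (nrow(x$pure_equilibria) > 0) {
    cat("Pure equilibria:",
        paste0("(", x$pure_equilibria$donor, ",", x$pure_equilibria$recipient, ")",
               collapse = " "), "\n")
  } else cat("Pure equilibria: none\n")
  if (!is.null(x$mixed)) {
    cat(sprintf("Mixed equilibrium: p_H = %.4f, q_C = %.4f\n",
                x$mixed$p_H, x$mixed$q_C))
  } else cat("Mixed equilibrium: none\n")
  cat("(H,C) Pareto efficient:", x$pareto_HC, "\n")
  cat(sprintf("Thresholds: pareto %.2f, cooperation %.2f, uniqueness %.2f\n",
              x$thresholds["pareto"], x$thresholds["cooperation"],
              x$thresholds["uniqueness"]))
  cat("Regime:", x$regime, "\n")
  invisible(x)
}
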