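# Competence sweeps and trial aggregation.
#
# The headline question is where, on a competence grid, the evolved
# population sustains cooperation. A trial's "final state" is summarised by
# the mean over its last k generations (default 10), which damps the
# mutation-driven fluctuations of the imitation dynamics.

#' Snapshot metrics of a population
#'
#' Computes the donor strategy shares, the mean recipient intent, and the
#' isolation counts of a population snapshot (meaningful when taken right
#' after a matching step): the number of pooled recipients and the number
#' of pooled recipients with good intention but a bad history.
#'
#' @param pop A `trust_population`.
#' @param good_intent `"strict"` counts only intent `x = 1` as good
#'   intention; `"half"` counts `x >= 0.5`.
#' @return One-row data frame with `share_ST`, `share_MG`, `share_EG`,
#'   `share_SG`, `mean_intent`, `n_isolated_recipients`,
#'   `n_isolated_good_intent_bad_history`.
#' @export
generation_metrics <- function(pop, good_intent = c("strict", "half")) {
  stopifnot(inherits(pop, "trust_population"))
  good_intent <- match.arg(good_intent)
  x_min <- if (good_intent == "strict") 1 else 0.5
  pol <- donor_policy(pop)
  pooled <- pop$r_partner == 0L
  data.frame(
    share_ST = mean(pol == "ST"), share_MG = mean(pol == "MG"),
    share_EG = mean(pol == "EG"), share_SG = mean(pol == "SG"),
    mean_intent = mean(pop$r_intent),
    n_isolated_recipients = sum(pooled),
    n_isolated_good_intent_bad_history =
      sum(pooled & pop$r_intent >= x_min & pop$r_history == 0L))
}

#' Sweep the simulation over a competence grid
#'
#' Runs [run_trial()] for every combination of a competence value and a
#' trial seed, and aggregates final-state statistics. Per-trial seeds are
#' spawned from `master_seed` (seed `master_seed * 1000 + t` for trial
#' `t`) unless an explicit `seeds` vector is given.
#'
#' @param a_grid Competence values in `[0, 1]`.
#' @param cfg A [sim_config()] template; its `a` and `seed` are overridden
#'   per run.
#' @param trials Trials per grid value.
#' @param master_seed Master seed spawning per-trial substreams.
#' @param seeds Optional explicit per-trial seeds (length `trials`).
#' @param last_k Number of final generations averaged into a trial's final
#'   state (capped at the number of generations).
#' @return An object of class `sweep_summary`: list with `finals` (one row
#'   per `a` x trial: final intent and shares), `summary` (per `a`: mean
#'   and SD across trials), `records` (all generation records, with `a`
#'   column), and the sweep settings.
#' @export
competence_sweep <- function(a_grid, cfg, trials = 10, master_seed = 1,
                             seeds = NULL, last_k = 10) {
  stopifnot(inherits(cfg, "sim_config"), all(a_grid >= 0 & a_grid <= 1),
            trials >= 1)
  if (is.null(seeds)) seeds <- master_seed * 1000 + seq_len(trials)
  stopifnot(length(seeds) == trials)
  last_k <- min(last_k, cfg$generations)

  records <- list()
  finals <- list()
  for (a in a_grid) {
    for (t in seq_len(trials)) {
      cfg_t <- cfg
      cfg_t$a <- a
      cfg_t$seed <- seeds[t]
      rec <- run_trial(cfg_t, trial = t)
      rec$a <- a
      records[[length(records) + 1L]] <- rec
      tail_rec <- rec[rec$generation > cfg$generations - last_k, ]
      finals[[length(finals) + 1L]] <- data.frame(
        a = a, trial = t, seed = seeds[t],
        final_intent = mean(tail_rec$mean_intent),
        final_share_ST = mean(tail_rec$share_ST),
        final_share_MG = mean(tail_rec$share_MG),
        final_share_EG = mean(tail_rec$share_EG),
        final_share_SG = mean(tail_rec$share_SG))
    }
  }
  finals <- do.call(rbind, finals)
  agg <- function(col) {
    m <- tapply(finals[[col]], finals$a, mean)
    s <- tapply(finals[[col]], finals$a, stats::sd)
    list(mean = as.numeric(m), sd = as.numeric(s))
  }
  cols <- c("final_intent", "final_share_ST", "final_share_MG",
            "final_share_EG", "final_share_SG")
  summary <- data.frame(a = sort(unique(finals$a)))
  for (col in cols) {
    ag <- agg(col)
    summary[[paste0(sub("final_", "", col), "_mean")]] <- ag$mean
    summary[[paste0(sub("final_", "", col), "_sd")]] <- ag$sd
  }
  structure(list(finals = finals, summary = summary,
                 records = do.call(rbind, records),
                 a_grid = sort(unique(a_grid)), trials = trials,
                 seeds = seeds, last_k = last_k, cfg = cfg),
            class = "sweep_summary")
}

#' Estimate the simulated cooperation threshold
#'
#' Applies the sustained-cooperation rule to a sweep: a grid value
#' sustains cooperation when the final intent (mean over the last `last_k`
#' generations) exceeds `intent_cutoff` in a strict majority of trials.
#' Returns the smallest sustaining grid value and the bracketing interval
#' formed with the largest non-sustaining value below it.
#'
#' @param sweep A `sweep_summary` from [competence_sweep()].
#' @param intent_cutoff Intent level counted as cooperation (default 0.5).
#' @return A list with `threshold` (smallest sustaining `a`, `NA` when the
#'   criterion is never met), `bracket` (`c(low, high)`; `low` is `-Inf`
#'   when even the smallest grid value sustains, `high` is `Inf` when none
#'   does), and `sustain`, the per-`a` majority table.
#' @export
estimate_sim_threshold <- function(sweep, intent_cutoff = 0.5) {
  stopifnot(inherits(sweep, "sweep_summary"))
  fin <- sweep$finals
  grid <- sort(unique(fin$a))
  n_sust <- vapply(grid, function(a) {
    sum(fin$final_intent[fin$a == a] > intent_cutoff)
  }, numeric(1))
  n_tr <- vapply(grid, function(a) sum(fin$a == a), numeric(1))
  sustain <- data.frame(a = grid, n_sustaining = n_sust, n_trials = n_tr,
                        majority = n_sust > n_tr / 2)
  idx <- which(sustain$majority)
  if (length(idx) == 0) {
    return(list(threshold = NA_real_, bracket = c(max(grid), Inf),
                sustain = sustain))
  }
  first <- min(idx)
  low <- if (first == 1) -Inf else grid[first - 1]
  list(threshold = grid[first], bracket = c(low, grid[first]),
       sustain = sustain)
}
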