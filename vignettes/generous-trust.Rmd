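---
title: "Generous trust: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generous trust: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Trust has two faces. The familiar one is vigilance: drop a partner the
moment they let you down. The other, often overlooked, is forgiveness:
when a failure may reflect bad luck or limited ability rather than bad
intent, keeping the relationship alive can be the better strategy. This
package studies when such *generous* trust is viable, using two linked
models of a modified trust game in which a trustee's success is
probabilistic, so a trustor can never tell betrayal from honest failure.

# The modified trust game

Each round, a donor decides whether to entrust a resource to a recipient.
Declining ends the round at the isolation payoffs $(P, P)$. If trust is
extended, the recipient decides whether to honour it, and "nature" decides
whether the undertaking succeeds, with probability $a$ — the recipient's
*competence*. Honoured trust that succeeds pays $(R, R)$; a successful
betrayal pays $(0, T)$ to the recipient alone; any failure pays $(0, 0)$.
Payoffs satisfy $T > R > P > 0$ and $2R > T$ (defaults $P = 1$, $R = 4$,
$T = 6$), so mutual cooperation is jointly efficient but defection tempts.

The donor observes only the returned share. The recorded *history* of a
round is therefore `C` exactly when the recipient both intended to
cooperate and succeeded, and `D` otherwise — malice and incompetence are
observationally identical. This information asymmetry is the engine of
everything that follows.

# Model 1: the repeated dyadic game

The entire game repeats the sub-game for $n = 100$ rounds without
discounting. Donors are one of three types: `H` never exits, `M` forgives
a single `D` outcome but exits on two consecutive ones, `L` exits after
any `D`. Recipients play pure `C` or `D`. An intact pair additionally
dissolves for exogenous reasons with probability $d = 0.1$ per round;
after any break, both parties collect $P$ per remaining round and never
re-match.

Each of the six strategy pairs induces a small absorbing Markov chain over
relationship states (`IN`, `RR` good standing, `RF` one unforgiven
failure, `FF` voluntary exit, `BROKEN` exogenous dissolution).
`expected_total_payoffs()` propagates the state distribution forward one
round at a time, accumulating expected rewards — exact for the finite
horizon, with no fundamental-matrix truncation. Within each round the
order is: play the sub-game, apply the donor's exit rule to the observed
outcome, then draw exogenous dissolution. Round one is always played, and
`M`'s forgiveness counter resets on any success. `simulate_repeated_game()`
is an independent Monte-Carlo oracle over explicit Bernoulli draws
(vectorized across replicates); the test suite holds the two routes to
within three standard errors at $10^5$ replicates.

## Equilibrium structure

On the resulting $3 \times 2$ bimatrix (cells $(a_1,a_2) \ldots
(f_1,f_2)$), `evaluate_conditions()` computes the three conditions under
which the donor mixes `H` and `M` against a recipient mixing `C` and `D`:
$q_C = (d_1-b_1)/(a_1-c_1+d_1-b_1)$ must be a proper probability (C1),
the `H`/`M` mix must beat deviating to `L` at that $q_C$ (C2), and
$p_H = (c_2-d_2)/((c_2-d_2)+(b_2-a_2))$ must be a proper probability
(C3). `find_threshold()` locates three regime boundaries by a grid
pre-scan (step 0.01, requiring a single sign change) followed by
bisection to $10^{-6}$:

* **Pareto** — where C2 turns positive and $(H, C)$ becomes Pareto
  efficient; analytically the root of $aR - P$, i.e. 0.25 at the
  defaults. At the exact boundary the whole cooperate column collapses
  onto the isolation stream, so we use the strict-surplus convention and
  report the boundary itself as not efficient.
* **Cooperation** — where the recipient's best response to `M` flips from
  `D` to `C` ($c_2 = d_2$); 0.47 at two decimals.
* **Uniqueness** — where $(L, D)$ stops being a pure equilibrium
  ($e_2 = f_2$), leaving the mixed equilibrium alone; 0.54 at two
  decimals. Given `D`, `L` is always the donor's best response
  ($f_1 \ge d_1 \ge b_1$), so only the recipient's side binds.

`classify_regime()` labels the four regimes from the computed equilibria,
never from stored cut-offs, so the labels and the bisection roots agree by
construction. Thresholds are reported at two decimals (matching the
precision the quantities are usually quoted at); full precision is
available with `digits = NULL`.

Two numerical notes. First, the mixed equilibrium degenerates at $a = 1$
exactly (with no failures, `H` and `M` are indistinguishable against `C`
and the indifference denominators vanish); degenerate denominators are
flagged, not divided, and monotonicity statements are made on the open
interior. Second, $p_H$ rises strictly with competence throughout, but
$q_C$ is U-shaped: it falls from 0.556 at $a = 0.55$ to a minimum of
0.5399 near $a = 0.63$ before rising towards 1. The common qualitative
summary "both mixing weights rise with competence" is accurate for $p_H$
everywhere and for $q_C$ only above roughly 0.65; the tests assert the
computed shape.

# Model 2: the evolutionary matching market

The agent-based model embeds the same sub-game in a population of 250
donors and 250 recipients. Donors carry two generosity flags — *matching*
(accept a pool recipient whose last observed outcome was `D`) and *exit*
(keep a partner after a `D`) — giving four policies: `ST` strict in both,
`MG` matching-generous, `EG` exit-generous, `SG` generous in both.
Recipients carry an intent $x \in \{0, 0.5, 1\}$, their per-round
probability of honouring trust. All recipients share one competence $a$,
a fixed endowment that never evolves.

Each of the $L = 100$ rounds per generation proceeds: **matching**
(unpaired donors, in a fresh random order, each pick one uniformly random
pooled recipient their criterion accepts; chosen recipients leave the pool
immediately), **play** (pairs play the sub-game; every unpaired agent of
either role collects $P$), **commitment** (exit-strict donors dissolve on
an observed `D`; survivors dissolve exogenously with probability
$d = 0.1$). At each generation boundary, strategies update role-wise by
imitation: every agent samples one uniformly random same-role peer and
copies the peer's full strategy exactly when the peer's cumulative
generation payoff is strictly higher (ties keep the own strategy), then
mutates to a uniformly random strategy of its role's space with
probability $M = 0.025$; payoffs, pairings and histories then reset
(histories to `C`, so strict matchers can pair in round one).

The round loop is implemented in C++ for speed; the exported step
functions (`matching_step()`, `play_round()`, `commitment_step()`) call
the same compiled routines as the generation driver, and a test asserts
that composing the steps reproduces `run_generation()` draw for draw
under one seed. All randomness flows through R's RNG, so a trial is fully
determined by its seed.

## Design choices on under-determined mechanics

Several mechanics of this kind of model are conventionally left implicit;
the package fixes them once, as follows, and treats them as part of the
model definition rather than tunable knobs.

* *Isolation payoff.* Unpaired agents of both roles earn $P$ per round,
  mirroring the dyadic model, where both parties of a broken pair collect
  $P$. We probed the two natural alternatives and both break the model's
  characteristic regime structure: paying isolated recipients nothing
  makes cooperation sustainable at every competence level from 0.50 up
  (no threshold, and strict donors never dominate anywhere), while paying
  both roles nothing collapses cooperation at every level. Only the
  symmetric $P$ reproduces strictness dominating at low competence and
  generosity at high competence with a transition in between.
* *Matching mechanics.* Random donor visiting order, uniform choice among
  acceptable pooled recipients, immediate removal — the simplest scheme
  consistent with donors choosing from a pool, re-randomized each round
  so no donor holds a positional privilege.
* *Generation reset.* Pairings, payoffs and histories reset at each
  evolution step; the model's within-generation isolation dynamics start
  from a full pool each generation.
* *Imitation.* Pairwise random-peer imitation with strict-improvement
  copying and a synchronous update is the weakest standard
  payoff-monotone dynamic; it makes no assumption about global knowledge
  of the strategy distribution.
* *Seeding.* One master seed spawns per-trial seeds
  (`master_seed * 1000 + trial`) unless explicit seeds are given, so
  sweeps are reproducible trial by trial.

## What the simulation shows — and what it does not

`competence_sweep()` runs trials across a competence grid and summarises
each trial's final state by the mean over its last ten generations, which
damps mutation-driven fluctuation. `estimate_sim_threshold()` applies the
sustained-cooperation rule: a grid value sustains cooperation when final
mean intent exceeds 0.5 in a strict majority of trials; the smallest
sustaining value and its bracketing interval are reported, and a
never-satisfied criterion is reported as an explicit boundary, never
guessed.

At desk scale (grid step 0.05, ten trials of forty generations — phase
structure in this model completes within roughly the first fifteen
generations, and within-generation processes converge around round fifty,
so forty generations of a hundred rounds leave a wide stationary tail)
the package reproduces the qualitative regime structure: strict trust
(`ST`) dominates the donor population at $a \le 0.55$ with low recipient
intent; from $a \ge 0.60$ the generous strategies led by `EG` take over,
`SG` stays marginal (unconditional generosity cannot stand alone), and
the sustained-cooperation threshold brackets into $[0.55, 0.60]$. Near
$a = 0.97$, where failures are rare and hence informative, strict and
exit-generous donors jointly retain the population and intent is close
to 1.

One quantitative feature deserves honesty: in the generous regime around
$a = 0.65$, mean recipient intent in this implementation plateaus at
roughly 0.45–0.48 rather than clearly above one half. With exit-generous
donors never punishing and matching-generous donors re-hiring any pooled
recipient within about a round and a half, a half-hearted recipient
($x = 0.5$) earns within a few percent of a full cooperator
($a(R+T)/2 = 3.25$ per paired round against $aR = 2.6$, offset only by
slightly longer pool waits), so recipient selection is nearly neutral
between $x = 1$ and $x = 0.5$ and mutation keeps the population near the
mixed mean. The regime *transition* is unaffected — it is sharp and sits
between 0.55 and 0.60 — but point claims about the intent level at a
single competence value in this plateau are fragile under this model
definition, and we flag them as such rather than adjusting the mechanics
to move them.

The generator emulates the model's own study conditions, not field data:
payoffs are stylised, competence is homogeneous and static, memory is one
round, and there is no network structure, reputation flow or role
switching. Passing tests therefore certify the internal logic and the
reproducibility of the model's regimes, not predictions about any
empirical trust relationship.

# Using the package

```{r example}
library(gentrust)

# equilibrium analysis of the repeated game at one competence level
analyze_game(a = 0.6)

# one evolutionary trial
rec <- run_trial(sim_config(a = 0.65, generations = 40, seed = 1))
tail(rec, 3)

# competence sweep with threshold estimate
sw <- competence_sweep(seq(0.5, 0.65, by = 0.05),
                       sim_config(a = 0.5, generations = 40),
                       trials = 10, seeds = 1:10)
estimate_sim_threshold(sw)$sustain
```

A thin command-line wrapper with `analyze`, `simulate` and `sweep`
subcommands is installed under `inst/scripts/gentrust`; it accepts a flat
`key = value` configuration file and `--key value` flags (flags win), and
writes tidy CSV output plus a JSON manifest with the full configuration
and seeds.
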