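# gentrust

Trust involves more than vigilance: when a partner's failure can come from
bad luck or limited ability rather than bad intent, *forgiving* the failure
can be the better strategy. `gentrust` implements two linked models for
studying when such generous trust is viable, aimed at researchers in
behavioural game theory and computational social science.

**Model 1 — repeated dyadic game.** A donor repeatedly decides whether to
entrust a resource to a recipient whose undertaking succeeds with
probability *a* (competence). Honoured, successful trust pays (R, R); a
successful betrayal pays (0, T); failure pays (0, 0); withheld trust pays
(P, P), with T > R > P > 0 and 2R > T (defaults P = 1, R = 4, T = 6). The
donor sees only outcomes, so betrayal and honest failure are recorded
identically as history `D`. Donor types differ in forgiveness — `H` never
exits, `M` exits after two consecutive `D` outcomes, `L` after one — and
an intact pair also dissolves exogenously with probability d = 0.1 per
round. The package computes exact expected totals of the 100-round game
for all six strategy pairs by forward propagation of each pair's absorbing
Markov chain, evaluates the conditions for the mixed Nash equilibrium in
which the donor mixes `H` and `M` while the recipient mixes `C` and `D`,
and locates three competence thresholds by bisection: Pareto efficiency
of (H, C) at a = P/R, the cooperation threshold where the recipient's
best response to `M` flips, and the point where (L, D) stops being a pure
equilibrium.

**Model 2 — evolutionary matching market.** 250 donors and 250 recipients
meet in a matching pool. Donors are generous (or not) in two separate
senses — *matching* generosity (accept a partner with a bad last-round
history) and *exit* generosity (keep a partner after a bad outcome) —
giving four policies ST, MG, EG, SG; recipients carry an intent
x ∈ {0, 0.5, 1}, their probability of honouring trust. Rounds of
matching, play and commitment repeat L = 100 times per generation, after
which strategies spread by payoff-based imitation with mutation rate
M = 0.025. The round engine is compiled (Rcpp); a 40-generation trial of
500 agents runs in well under a second.

## Worked example

```r
library(gentrust)
analyze_game(a = 0.6)
```

```
Modified trust game, a = 0.6 , d = 0.1 , n = 100

Entire-game expected payoffs (donor, recipient), n = 100 rounds, a = 0.6 , d = 0.1
  C              D
H (114, 114)     (90, 126)
M (107.2, 107.2) (98.1, 104.9)
L (103, 103)     (99, 102.6)

Conditions: C1 = 0.5425 ( TRUE ), C2 = 1.826 ( TRUE ), C3 = 0.1566 ( TRUE )
Pure equilibria: none
Mixed equilibrium: p_H = 0.1566, q_C = 0.5425
(H,C) Pareto efficient: TRUE
Thresholds: pareto 0.25, cooperation 0.47, uniqueness 0.54
Regime: mixed-only
```

At competence 0.6, no pure equilibrium survives: the only equilibrium has
the donor playing the fully forgiving strategy `H` 15.7% of the time
(otherwise the moderately punishing `M`) and the recipient cooperating
54.3% of the time. Generosity is viable, but only mixed with moderate
punishment. The three thresholds partition competence into four regimes:
below 0.25 cooperation has no surplus; up to 0.47 distrust (L, D) is the
only equilibrium even though (H, C) would be efficient; between 0.47 and
0.54 the mixed equilibrium appears alongside (L, D); above 0.54 it is
unique.

An evolutionary trial at competence 0.65:

```r
rec <- run_trial(sim_config(a = 0.65, generations = 40, seed = 1))
round(tail(rec, 3), 3)
```

```
   trial generation share_ST share_MG share_EG share_SG mean_intent
38     1         38    0.000    0.436    0.544    0.020       0.460
39     1         39    0.012    0.448    0.516    0.024       0.476
40     1         40    0.012    0.472    0.500    0.016       0.472
   n_isolated_recipients n_isolated_good_intent_bad_history
38                 77.53                               0.83
39                 68.88                               0.99
40                 74.91                               1.46
```

Strict trust has vanished (share 1.2%) and the two generous strategies
split the donor population, led by exit generosity — forgiving partners
in ongoing relationships — with matching generosity re-hiring the
recipients others discard. At competence 0.55 the same simulation is
dominated by strict trust instead; the transition between the two regimes
is what `competence_sweep()` and `estimate_sim_threshold()` locate.

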