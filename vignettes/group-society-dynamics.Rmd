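---
title: "Modelling cooperation, power, and inequality in group-structured societies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cooperation, power, and inequality in group-structured societies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupsoc)
```

## The model

`groupsoc` simulates a society of `G` groups with sizes `n_j` and political
powers `f_j` (`0 <= f_j <= 1`, `sum(f_j) = 1`). Each discrete time step has
four phases.

**Within-group public goods game.** Each individual holds an endowment
`pi0` and chooses whether to contribute (`x_ij = 1`, cost `c`, with
`0 < c <= pi0`) to the group effort `X_j = sum_i x_ij`. The group produces

    P_j = B1 * X_j / (X_j + X0),

a saturating production function with maximum benefit `B1` and half-effort
`X0` (`P(X0) = B1/2`). Diminishing marginal returns allow stable mixtures of
contributors and free riders, unlike a linear public goods game.

**Between-group club goods game.** Each group chooses whether to invest its
production in a coalition (`theta_j = 1`, the "elites") or keep it
(`theta_j = 0`, "counter-elites"). Groups with `X_j = 0` can never be
coalition members — this *elite rule* is enforced as a state invariant and
inside every hypothetical payoff evaluation. The coalition's combined
contribution `Z = sum of P_j over cooperators` yields the club good
`Q = B2 * Z / (Z + Z0)`, which only members share: member `j` receives the
share `v_j = f_j / sum(f_k over members)`, its relative power within the
coalition. Group payoffs are

    Pi_j = n_j*pi0 - c*X_j + P_j      (defector)
    Pi_j = n_j*pi0 - c*X_j + v_j*Q    (cooperator)

and each individual receives a `1/n_j^alpha` share of its group's resource
term. The rivalrousness exponent `alpha` interpolates between pure public
goods (`alpha = 0`, no per-capita division) and fully rival goods
(`alpha = 1`).

**Political contest.** Groups convert payoffs into effective political
effort `y_j = Pi_j * (1 - epsilon + epsilon*f_j)` and next-step power
follows the Tullock contest success function `f'_j = y_j / sum(y)` (uniform
`1/G` if all efforts vanish). The incumbency parameter `epsilon` measures
how strongly current power amplifies effort: `epsilon = 0` corresponds to
strong checks-and-balances (only resources matter), `epsilon = 1` lets
resources and power combine multiplicatively.

**Strategy revision.** Individuals and groups are myopic quantal
responders. Each individual revises with probability `mu1`, each group with
probability `mu2`; a reviser compares the payoffs of its two actions
against the *pre-revision* state — everything else held fixed, with the
club good recomputed for its own hypothetical change — and chooses action 1
with logit probability `1/(1 + exp(-lam*delta))`. At `lam = Inf` (the
default and the case studied throughout) this is exact best response with a
fair coin at ties. Individuals decide first (synchronously), then groups
(synchronously), then power updates. Because all hypotheticals are
evaluated against the pre-revision state, the outcome distribution does not
depend on agent evaluation order.

Two modelling points deserve emphasis, since the verbal description leaves
them open:

* *The elite rule inside hypotheticals.* A sole contributor weighing
  defection anticipates that its departure zeroes the group effort and —
  by the elite rule — expels the group from the coalition; its hypothetical
  payoff is then just `pi0`. Symmetrically, a group whose cooperation would
  make it the only coalition member evaluates `v_j = 1`.
* *No foresight about power.* The hypothetical holds powers `f` fixed:
  agents do not anticipate that today's payoff changes tomorrow's power.
  Planning two steps ahead is deliberately outside the revision protocol.

## Default protocol and parameters

The simulation protocol defaults are: `T = 4000`
steps, statistics averaged over the last 1000 steps, `mu1 = mu2 = 0.25`,
`lam = Inf`, 100–200 runs per parameter point. Initial powers follow a
broken-stick partition of the unit interval when group sizes are equal and
are uniform `1/G` otherwise; each individual and group starts cooperating
independently with probability 0.5. Broken-stick powers are assigned in
segment-position order (unsorted); group labels are exchangeable, so
summaries are unaffected.

Useful derived ratios: `R1 = B1/(c*X0)` and `R2 = B2/Z0` are the
benefit-to-cost ratios of the two games, `omega = c*X0/Z0` the cost ratio
between levels, and the normalized per-individual benefits are
`b1 = B1/n^alpha`, `b2 = B2/sum(n_j^alpha)`. Experimental presets
(`preset_params()`) accept either the raw or the normalized form.

## Summary statistics and classification

`summarize_window()` reports the coalition size `C`, the Gini index `I` of
power among cooperating groups (half the relative mean absolute
difference), and the dispersion `sigma` of cooperating-group efforts. Two
conventions are the package's own choices, as the quantities are otherwise
underdetermined:

* `sigma` uses the *population* standard deviation (divide by `C`): the
  cooperating groups are the entire population of interest, not a sample.
* Steps with an empty coalition contribute no value to the `I` and `sigma`
  averages (inequality among cooperators is undefined there); they are
  excluded rather than imputed as zero.

A run is classified `equilibrium` when, over the averaging window, every
contribution and status is constant and every power stays within `f_tol`
(default `1e-6`) of its window mean; any flip or drift makes it
`non-equilibrium`. The threshold exploits the geometric convergence of the
power map once strategies freeze. At equilibrium the cooperating groups'
powers are clustered with gap tolerance `power_tol` (default `1e-3`, well
below the order-of-magnitude separation seen between power classes):
one class is an `equal` elite, two classes are `dominant-subordinate`.
More than two classes is impossible at a true equilibrium of this model,
so the classifier treats it as an upstream misclassification: it errors
when called directly, and `summarize_window()` records `NA` (this occurs
legitimately for frozen-strategy states, which need not be best-response
equilibria).

## Analytic approximations

The `analytics` functions treat contributions as continuous, an
approximation whose adequacy is itself checked by simulation in the test
suite (stationary efforts match within one contributor across a grid of
`R1`, `n`, `alpha`).

* Isolated group: positive effort requires `b1 > c*(1 + X0)`; the
  stationary effort is `X* = min(n, X0*(sqrt(R1/n^alpha) - 1))` when
  `R1 > n^alpha`, else 0.
* No-cooperation equilibrium (`C = 0`): exists iff
  `R2 < 1 + omega*R1*(1 - sqrt(n^alpha/R1))`, stable in power for
  `epsilon < 1`.
* Symmetric coalition of `C` groups: each cooperating group's effort is
  `X_c* = X0/(omega*C*R1 + 1) * (sqrt(R1*R2/(C*n^alpha)) - 1)`, positive
  iff `R1*R2 > C*n^alpha`; members stay iff `R1` is below a threshold
  increasing in `R2` (`no_defection_condition()`).
* Full coalition (`C = G`): power-stable iff
  `epsilon < eps_max = A_c*/(A_c* + Q_G/G^2)`, where `A_c* = n*pi0 - c*X_c*`
  and `Q_G` is the club good at the symmetric equilibrium. `Q_G` and
  `A_c*` are computed by composing `X_c*` through the two production
  functions — the only self-consistent reading of the bound.

For partial coalitions (`0 < C < G`) the epsilon bounds are defined only
implicitly; the package does not attempt the algebra. Instead
`power_stability_probe()` freezes strategies at the symmetric candidate,
perturbs one cooperator's power by `delta` (default `1e-3`), iterates the
payoff-to-power map `H = 200` times, and declares stability when the
deviation has contracted below `delta/10`; `eps_max_numeric()` wraps this
in a bisection on `epsilon` with tolerance `1e-3`. The probe is
conservative near the boundary (decay is slow there), so its estimate sits
slightly inside the analytic `eps_max` where the latter applies; candidates
are evaluated at the *rounded* (integer) contributor count, which also
shifts the numeric boundary slightly relative to the continuous formula.

## What the generator emulates, and what it does not

Synthetic societies produced by `init_state()` and the fixture catalogue
reproduce the canonical protocol conditions exactly: equal-size societies with
broken-stick power, unequal-size societies (5, 10, 15, 20) with uniform
power, Bernoulli(0.5) initial cooperation. They do not emulate features of
real societies that the model itself abstracts away — reputation and
punishment, imitation or foresighted updating, network structure, coalition
formation costs, endogenous group sizes, or non-material motives. Passing
tests therefore validate the implementation of *this* model, not the
model's fit to any empirical society.

## Numerical choices

* Powers must sum to 1 within `1e-12` after every update; violations are
  errors, never silently renormalized (the Tullock update guarantees
  normalization up to rounding).
* A coalition whose total power is exactly zero divides the club good
  equally — the symmetric limit of the share rule, avoiding 0/0 at
  degenerate, transient states.
* Group payoffs are asserted nonnegative before the contest; the parameter
  bound `c <= pi0` guarantees this, so a violation indicates an invalid
  state rather than a modelling regime.
* Per-agent random draws consume the RNG in a fixed canonical order (all
  selection draws, then all action draws, in flat group order), making
  every trajectory a pure function of `(params, T, seed)`. Ensemble runs
  draw per-run child seeds from the master seed.
* `lam = Inf` is an explicit sentinel handled before the logistic formula,
  with ties broken by a fair coin (the logit limit).

## Problem sizes in the tests

The test and acceptance workloads run the full protocol at reduced scale —
`T` of 500–1200 with windows of 250–400, 5–20 runs per point, and ensemble
grids of at most 6 × 10 runs — sizes chosen so the qualitative results
(coalition collapse with rising `epsilon`, non-equilibrium dynamics at
small `epsilon` with large `b2`, the group-size paradox under rivalry, and
stationarity of analytically predicted equilibria) are already stable.
`run_sweep()` accepts the full-scale protocol (`T = 4000`, 100–200 runs)
unchanged.

## A worked example

```{r example, eval = FALSE}
p <- preset_params("equal-groups", epsilon = 0.1)   # 8 groups of 10, b1 = 20, b2 = 10
sm <- run_ensemble(p, T = 1000, n_runs = 10, base_seed = 1, window = 250)
df <- summaries_to_df(sm)
colMeans(df[, c("mean_C", "gini_I", "sd_sigma")])
```

Increasing `epsilon` and re-running shrinks `mean_C` towards one group —
weakening checks-and-balances hollows out the cooperative coalition while
inequality among the remaining members rises and then falls as the
coalition collapses.

## Known limitations

* The equilibrium/non-equilibrium classifier is a reconstruction: strategy
  constancy plus bounded power drift. Runs that freeze only in the last few
  window steps are conservatively labelled non-equilibrium.
* The epsilon bounds for partial coalitions are numerical estimates from
  the stability probe, not closed forms.
* The contest exponent is fixed at 1 (shares proportional to effort);
  general Tullock exponents and inter-society conflict are out of scope.
* Group sizes, `c` and `pi0` are homogeneous within a society and constant
  in time.
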