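---
title: "Methods: simulating and analysing veil-of-ignorance redistribution games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing veil-of-ignorance redistribution games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voigame)
```

`voigame` implements, end to end, the computational core of a
veil-of-ignorance (VoI) redistribution experiment: the game and payoff
engine, a synthetic cohort generator, the accordance/non-accordance
affective classification, the baseline-invariant interaction decomposition
(τ, ψ, π), and the behavioural statistics including a participant-level
cluster bootstrap. This vignette records the models, the defaults, and the
design decisions that were genuinely open.

## The game and its payoff scheme

A society has three income classes with pre-tax incomes `h > m > l > 0`
(abstract money points; defaults 2100/1300/700). Redistribution transfers
income from the high to the low class, and a fraction `cost_rate` (default
0.25) of the transferred amount is lost in transit. The `equality` rule
transfers `T = h − m`; the `intermediate` rule transfers
`intermediate_fraction · T` (default one half); `inequality` transfers
nothing and is cost-free. The middle class is never party to a transfer, so
its payoff is identical under every rule.

Absolute equality is attainable only if the post-transfer incomes line up:

```
m − l = (1 − cost_rate) · (h − m)
```

`payoff_scheme()` rejects parameter sets violating this constraint (to
within a relative tolerance of `1e-8`, so user-supplied rounded values are
not spuriously rejected). The default (2100, 1300, 700) at cost 0.25 was
chosen as the round-number solution of the constraint; the incomes actually
deployed in such experiments are typically not published, so these values
are a configuration default, not an estimate.

Society-level decisions are by strict majority in voting mode; split votes
(all three players voting differently) are resolved by a uniform draw *among
the cast votes*. Randomising among the tied alternatives, rather than among
all three rules, is the natural reading of resolving a split vote at random;
with three distinct votes the two coincide anyway. In dictatorship mode the
round's dictator decides alone.

## Agent policies

The true decision process of participants is unknown; the generator adopts a
softmax-utility family chosen because it spans the two motivators debated
for equality choices — consideration of others and prospective calculation
for oneself:

```
u(rule) = w_self · own(rule) + w_total · total(rule) − w_fair · spread(rule)
P(rule) ∝ exp(u(rule) / temperature)
```

Informed agents take `own` to be their class payoff. Behind the veil,
`risk = "expected_value"` agents use the mean payoff over the three classes
(risk-neutral prospective calculation), `risk = "maximin"` agents the
minimum class payoff (maximise the worst foreseen outcome). In the
degenerate limit `temperature → 0` these become analytic: a maximin agent
behind the veil chooses equality (worst-off payoffs 700/1000/1300 across
the default rules) and an expected-value agent chooses inequality
(per-capita endowments 4100/3 > 4000/3 > 3900/3), which the tests assert.

**Calibration of the defaults.** The default mixture — 90% expected-value /
10% maximin agents, `w_self = 1`, `w_total = w_fair = 0`, `temperature =
240` points — was set once, analytically, against three requirements:

* the aggregate non-equality share behind the veil sits near the
  empirically typical ~72% (the analytic mixture value is ≈67%, inside the
  ±10-percentage-point sanity band the tests check);
* informed high-class agents choose the selfish inequality rule in roughly
  80% of trials (analytic ≈82%);
* every cell of the 4 × 3 (condition × rule) factorial table is populated
  with near-certainty at the default design size, which the interaction
  decomposition requires — this caps how deterministic (cold) the policy
  may be, since the rarest cell (high class choosing equality) has
  probability ≈3% per trial.

A single temperature cannot match all published choice shares
simultaneously: with these payoff gaps the low-income class comes out less
selfish (≈69% choosing equality) than typically reported (~90%). We accept
this, prioritising the VoI share and cell coverage; the figure is a
calibration, not an inference about real participants.

## The synthetic cohort

`generate_cohort()` simulates 33 participants by default, each playing four
sessions (VoI/Informed × Voting/Dictatorship), with 18 redistribution
rounds and 3 randomly inserted lottery rounds per session. The number of
rounds per session is not constrained by published designs beyond the
requirement that each participant experience every (class, societal
outcome) pair; 18 rounds (a structured block of all nine pairs plus nine
random rounds) doubles the trial counts so that rare cells of the factorial
table are reliably non-empty at desk scale.

Societal outcomes in voting sessions are *scripted* to traverse the 3 × 3
grid, mirroring a deception design in which partners are simulated and the
experimenter controls outcomes; `society_decision()` is therefore exercised
in dictatorship sessions (where the participant dictates a third of the
rounds and a simulated partner the rest) and tested separately. Partner
agents are drawn from the same policy mixture. Lottery rounds use the same
choice screen (the agent picks a payoff set under its veil policy, then a
class-payoff is drawn uniformly); partners draw their own lotteries so that
accumulated totals remain comparable across the three players.

Incomes accumulate per session for the participant and both partners; the
participant's total equals the sum of their per-round payoffs, an invariant
the tests check. Relative income is the participant's total divided by the
*sum* of both partners' totals ("partners' total" is ambiguous between sum
and mean; the two differ by a factor of two, leaving every correlation
unchanged, and the denominator is switchable). Its fair-share value is
therefore 1/2.

### Affect generator

Per participant–partner–session pair: rating I is drawn from a normal
distribution (mean 46, sd 12 thermometer degrees) clipped to [0, 100] —
clipping rather than proper truncation, which at these defaults affects
well under 1% of draws. A latent session-level attitude is accordance with
probability `p_accordance = 0.38`; each partner-level attitude copies it
with probability `attitude_concordance = 0.9`, so contradictory sessions
arise at a controllable rate. The change after playing is `±12 ± 6` degrees
(sign `+` for accordance), and the change after income disclosure reverses
sign: `∓15 ± 6` degrees plus a relative-income term
`income_slope · (rel − 1/2)` with `income_slope = −100` degrees per unit of
relative income. With probability `zero_change_prob = 24/78` the disclosure
change is exactly zero (emulating the observed share of unchanged raters).
Since relative income varies with a standard deviation near 0.035 at the
default design, the slope produces a disclosure-change/relative-income
correlation around −0.2, the qualitative structure the analyses probe.

### Neural outcome generator

One continuous outcome per non-lottery trial, standing in for a
region-of-interest percent signal change from which the lottery baseline
has already been subtracted (the pipeline never models raw BOLD):

```
y = mu + a·1[equality-or-selfless] + b·1[VoI]
      + c·1[equality ∧ VoI or selfless ∧ Informed]
      + d·1[accordance session] + s·(rel − 1/2)·1[equality ∧ VoI]
      + u_participant + ε
```

with `u ~ N(0, ranef_sd²)`, `ε ~ N(0, noise_sd²)`. The `c` coefficient is
the designed condition-by-decision interaction (defaults: `mu = 0.1`,
`a = 0.15`, `b = −0.1`, `c = 0.4`, `d = 0.25`, `s = −5`, `ranef_sd = 0.2`,
`noise_sd = 0.8`). The income term is centred at the fair share 1/2: an
uncentred term of useful magnitude would shift the (VoI, equality) cell
mean by `s/2` and could flip the sign of the generated interaction, whereas
centring contributes the intended negative outcome–relative-income slope on
equality-behind-the-veil trials without moving the cell means. Correlations
are unaffected by the centring.

### Decision categories

In the informed conditions a choice is *selfless* when it runs against
class interest: intermediate or equality for the high class; inequality or
intermediate for the low class (for the low class, equality — which pays it
the most — is the selfish choice). Middle-class decisions are neutral,
since the middle payoff is rule-invariant. Behind the veil the dichotomy is
equality vs non-equality. `decision_category()` encodes these groupings.

## Affect metrics and the exclusion screen

A *case* is a participant–partner–session triple; the attitude analysis is
restricted to cases where the participant out-earned that partner, because
only there is a drop in affection unexpected from material vantage. Cases
are classified by the sign of the disclosure change (`III − II`): decrease
→ accordance, increase → non-accordance, exactly zero → excluded. After the
zero-change exclusion, sessions whose two pair-cases carry opposite labels
are contradictory and lose both cases. Whether a "contradictory case"
counts sessions or pair-cases is ambiguous in common usage, so
`apply_exclusions()` reports both (`n_contradictory_sessions`,
`n_contradictory_cases`) along with every other stage count. Ties in income
are out of scope rather than assigned to a side. Lower-income cases are
labelled `out_of_scope`: the attitude construct is defined only on the
higher-income side, though the case table retains them for completeness.

## The interaction decomposition

Interaction effects estimated against an arbitrary baseline condition
change with the choice of baseline. The decomposition implemented here
removes that dependence: for a target cell (c₁, r₁) and baseline cell
(c₀, r₀),

* `τ = Ȳ(c₁,r₁) − Ȳ(c₀,r₀)` — the combined effect,
* `ψ(c₁;c₀) = Σ_r {Ȳ(c₁,r) − Ȳ(c₀,r)} · P(r)` over the three rules,
* `ψ(r₁;r₀) = Σ_c {Ȳ(c,r₁) − Ȳ(c,r₀)} · P(c)` over the high, low and VoI
  conditions,
* `π = τ − ψ(c₁;c₀) − ψ(r₁;r₀)`.

The weights P are observed choice/condition frequencies, computed from
pooled trial counts over the whole dataset and normalised over exactly the
category set entering each ψ. The middle condition is excluded from the
rule-effect sum and its weights: middle-class decisions are neutral, so a
marginal rule effect averaged over it would dilute the contrast. π is
computed literally as the difference, so the identity is machine-exact; the
test suite verifies equivalence with an independent term-by-term
transcription on a thousand random tables, the additivity null (π = 0 for
any table of the form `f(condition) + g(rule)`), and shift invariance.

`cell_means()` aggregates per-trial by default and offers a
participant-first option (mean of participant means) matching second-level
analyses that average within subjects first; cell counts remain trial
counts in either mode because the ψ weights are observed choice
frequencies. A contrast touching an empty cell raises a typed error naming
the missing cell rather than returning a silent `NaN`.

## Inference

Choice summaries follow the two standard panels: per-participant trial
proportions (mean ± s.e.m. across participants) and the proportion of
participants who ever chose a rule set, with a binomial dispersion
`sqrt(p(1−p)/n)` — the across-session dispersion some reports print is not
recoverable from a single binary indicator per participant, so the binomial
form is used and documented. Group comparisons default to Welch's t
(pooled-variance optional); the 2 × 2 association test is Pearson's
chi-squared without continuity correction (Yates optional). No
multiple-testing correction is applied, mirroring standard practice for
these few planned behavioural contrasts.

`cluster_bootstrap()` addresses the non-independence of rows from the same
participant by resampling whole participants with replacement and
recomputing the statistic per replicate (default B = 2000), reporting the
percentile interval and whether it excludes the null value. Replicates on
which the statistic fails (e.g. an empty cell after resampling) are
recorded and redrawn, up to a retry cap, so degenerate resamples cannot
silently bias the replicate set. The suite verifies nominal coverage (95% ±
3 points over 500 simulated 33-cluster datasets) and that no replicate ever
splits a participant.

## Problem sizes and determinism

Every randomised component is seeded: `generate_cohort()` is byte-identical
given its seed and restores the global RNG state, and `cluster_bootstrap()`
takes an optional local seed. The shipped checks run at the design's native
scale — 33 participants, 4 sessions, 21 rounds each (≈1,200 veil trials,
≈2,400 neural trials) — with 20-seed replications for the recovery
properties and 500 simulated datasets for bootstrap coverage.

## What passing tests do and do not show

The generator reproduces the *structure* the analyses assume: factorial
decision records with full cell coverage, attitude-linked thermometer
trajectories with a zero-change atom and an income-linked disclosure
change, and trial-level outcomes with a designed interaction. It does not
model reaction times, learning or strategic voting across rounds (repeated
rounds are exchangeable by design), rater drift, or raw BOLD; partner
behaviour comes from the same policy family as participants. Passing
recovery tests therefore show that the estimators recover what this
generative family encodes — not that real participants follow softmax
utilities, nor that published coefficients are reproduced. Where published
quantities derive from unreleased participant or imaging data, the package
emulates their sign and rough magnitude only, and its tests are written
against properties (identities, nulls, monotone recovery, coverage), not
against those numbers.
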