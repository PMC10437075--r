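---
title: "Models and measures in seqstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measures in seqstrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqstrat)
```

`seqstrat` simulates prediction-task experiments on first-order Markov
symbol streams and computes the behavioural measures used to characterise
what was learned and which decision strategy produced the responses. This
vignette is the package's account of those models: the assumptions they
make, the parameters that matter, the numerical choices, and what the
synthetic data can and cannot tell you.

## The generative design

Sequences are produced by a four-state Markov chain of order 1: the symbol
at position *i* depends only on the symbol at position *i − 1* (the
*context*), via a 4×4 conditional matrix in which every context allows
exactly two targets, one with probability `p_high` and one with
`1 − p_high`. The default topology is cyclic — A → (B, C), B → (C, D),
C → (D, A), D → (A, B) — which satisfies the two-target row constraint and
is doubly stochastic, so its stationary context distribution is exactly
uniform. That property is load-bearing: with uniform context weights the
random-guess Performance Index baseline evaluates in closed form to 0.45
for `p_high = 0.8` and 0.50 for `p_high = 0.6`, the reference values the
rest of the analysis normalizes against. Any other matrix satisfying the
row constraint can be supplied explicitly (`markov_model(transitions = )`),
and `stationary_distribution()` then solves for its context weights,
refusing reducible chains by name.

Two design choices here were genuinely open. The exact matrix beyond the
A → (B, C) example is not determined by the two-target constraint alone;
the cyclic default is one consistent choice, selected because it reproduces
the closed-form baselines above. And the first symbol of each trial is drawn
from the stationary distribution, which keeps the empirical context
frequencies consistent with the weights used to aggregate the measures;
trial length is uniform on 9–13 symbols.

Trials come in two kinds: *structured* (chain-generated, with a hidden
target sampled from the final context's row — never displayed, but used for
trial feedback) and *random* (i.i.d. uniform symbols and target), the
control condition of the test sessions. Inter-stimulus intervals are
bookkeeping only: fixed 400 ms, or jittered uniformly over the 20 ms grid
from 100 to 700 ms (31 values, mean 400 ms) for the temporal-uncertainty
design.

## Synthetic participants

Since no human data ship with the package, the unit of analysis is the
synthetic agent. Fixed policies cover the strategy continuum exactly:

- `random`: uniform 0.25 over the four symbols;
- `matching`: respond with the context's true contingency probabilities;
- `maximizing`: point mass on the most likely target (ties are an error
  unless a lexicographic tie-break is configured; ties only arise at
  `p_high = 0.5`, which the model constructor already forbids);
- `interpolated`: a one-parameter family over the whole strategy axis,
  λ ∈ [−1, 1]: nonnegative λ mixes matching with the argmax point mass
  (`(1 − λ) · matching + λ · maximizing`), negative λ mixes matching with
  the uniform distribution, reaching pure random guessing at λ = −1. The
  mass on the frequent target is strictly increasing in λ across the whole
  axis, and on [0, 1] the expected hit rate is affine (0.68 to 0.80 on the
  80/20 design);
- `learning`: a pseudo-count (Dirichlet-style) belief over the 4×4
  transition counts, updated by exposure (every consecutive pair in the
  stream adds `learn_rate` to its cell) and read out through a matching or
  maximizing rule.

Lapses are modelled with probability `p_null` per trial (default 0 for
fixed-policy agents; 0.009 in the recovery cohort, the rate typical of a
2 s response deadline). A lapse is *registered*, not dropped: its response
vector is uniform 0.25, and it enters the conditional estimates with that
fractional weight. This registration rule is applied verbatim because the
downstream measures consume response *distributions*, not accuracy counts.

Feedback enters the learning agent as a bonus update: a "correct" trial
outcome adds `feedback_sensitivity × learn_rate` to the (context, chosen)
cell. Under uncorrelated feedback the same bonus lands on a random cell,
which corrupts the belief — the mechanism by which the simulator reproduces
the qualitative direction that random feedback impairs learning while
trial-by-trial feedback sharpens it. This update rule is an explicit
stand-in: the experimental literature this package serves does not commit
to a mechanistic participant model, so no quantitative feedback effect
should be read off these agents — only signs and orderings.

## The measures

**Performance Index.** Per context, the minimum overlap
`PI(c) = Σ_t min(P_resp(t|c), P_pres(t|c))`; overall, the context-weighted
mean. It is symmetric, bounded in [0, 1], and equal to 1 exactly when the
distributions coincide on the weighted support. `P_pres` defaults to the
generative rows rather than the per-block empirical tally: only the
model-based choice makes the random-guess baseline the exact constants
0.45/0.50, which is what the normalization `PI − PI_rand` assumes. An
empirical-`P_pres` mode is available (pass a `conditional_table` estimated
from presented targets) for sensitivity analyses. Context weights default
to the stationary distribution; blocks that happen to miss a context have
their weights renormalized over the supported contexts. The learner
criterion is inclusive: post-training normalized PI ≥ 0.10.

**Strategy choice and index.** Response tables are compared to two
reference models by Kullback–Leibler divergence with the reference outside:
`KL(M ‖ R) = Σ_c M(c) Σ_t M(t|c) log(M(t|c)/R(t|c))`, natural log. The
response table is smoothed additively, `(r + ε)/(1 + 4ε)` with ε = 10⁻³ by
default, because maximizing responders produce exact zeros; reference zeros
vanish by the 0·log 0 convention and are not smoothed. The per-block
strategy choice is `ΔKL = KL(matching ‖ R) − KL(maximization ‖ R)`. The
verbal convention and the ΔKL argument order in the source literature
conflict; this sign was fixed because it reproduces every qualitative
anchor at once — an exact matcher scores `−ln(1/p_high)` (≈ −0.223 at 0.8),
a uniform responder lower (≈ −0.500), a maximizer positive. The strategy
index integrates the strategy curve over training blocks (unit-spaced
rectangle sum; a trapezoid option differs only in the endpoints) and
subtracts the integral of the exact-matching reference curve, computed
analytically from the generative rows passed through the same smoothing —
so an agent whose estimated table equals the generative rows scores exactly
0 at any ε. The analytic reference was chosen over a simulated one for
determinism.

A property worth knowing before interpreting small samples: the plug-in KL
is biased upward in finite blocks, and the bias is larger for
`KL(matching ‖ R̂)` than for the single-term maximization divergence, so
matching agents estimated from 60-trial blocks show a small positive index
offset. At 500 trials per block the offset is negligible relative to seed
noise; the package's recovery checks therefore test *sign* at large blocks
and *ordering across λ* at the experimental block size, where the offset is
common to all agents and cannot reorder them. Orderings are insensitive to
ε across [10⁻⁴, 10⁻²].

## The protocol

`run_experiment()` executes the session plan: a pre-training test session
(structured, random, structured blocks of 40 trials, no feedback), 23
training blocks of 60 structured trials under the group's feedback regime,
a mirrored post-training session, and optionally a retest session. The six
group presets vary one factor each against the Group-1 baseline (80/20,
fixed ISI, block feedback): 60/40 contingencies (2), jittered ISI (3),
trial feedback (4), no feedback (5), uncorrelated feedback (6). Uncorrelated
feedback is Bernoulli(0.5) by default and configurable, since only
"uncorrelated" is specified by the design. Training days are block indices
only; no forgetting process is modelled between them. Block feedback — the
PI score a participant would see at the end of a training block — is
attached to the log as an attribute and given displayed-value semantics
only: fixed-policy agents cannot react to it, and the learning agent's
update rule deliberately takes no input from it, mirroring the fact that
the design it emulates found no behavioural difference between block and no
feedback.

The log is a plain CSV with a fixed 15-column schema (response vectors to
12 significant digits); reading validates the header order and the row sums
and the round trip is lossless. Reruns from a logged seed are
bit-identical.

## The staircase

Cognitive covariates come from a simulated two-down one-up staircase:
difficulty (number of dots in a memory display) starts at 2, rises by one
after two consecutive correct responses, falls by one after any error
(floor 2), with 10 reversals per run and thresholds taken as the mean of
the last two-thirds of reversal levels (⌈2k/3⌉), averaged over 3 runs. The
rule's equilibrium sits where P(correct)² = 0.5, i.e. accuracy ≈ 70.7%, and
long simulated runs of the implementation settle at that accuracy to within
a percentage point.

Short runs are another matter, and the choice of simulated observer
reflects it. Trial-wise accuracy in a 10-reversal run includes the approach
from the easy 2-dot start and, for observers whose equilibrium is near the
floor, truncation of the easy-side excursions; both push measured accuracy
a point or two above the asymptote, a generic property of short staircases.
The default observer is therefore a steep, capacity-style logistic —
guess rate 0.5 (same/different judgement), midpoint 5 dots, width 0.6 —
realistic for a colour-change memory task (near-ceiling at 2–4 items, sharp
collapse beyond capacity) and quick to reach its stationary regime, so that
the accuracy measured after a 3-reversal burn-in reflects the rule rather
than the approach. With a shallower psychometric the same measurement reads
1–3 points higher; that is a property of the measurement window, not of the
rule. The attention covariate has no specified mechanics in the source
design (commercial double-staircase software), so it is drawn from a
log-normal threshold family and labelled synthetic.

## Cohort analysis and recovery

`recovery_experiment()` is the validation harness: agents on a λ grid
spanning the full strategy axis (−1 = random, 0 = matching,
1 = maximizing) run through the full protocol, and the cohort table links
true λ to estimated strategy index, post-training normalized PI and
improvement. Two summaries matter: the mean index must be strictly
increasing in λ, and the correlation between strategy index and
post-training normalized PI must be positive. The second deserves a note,
because it is easy to misread: among agents at or beyond matching, *more*
maximization *lowers* the minimum-overlap PI (a pure maximizer's PI caps at
`p_high`, while a matcher's tends to 1), so a cohort confined to the
matching→maximization segment shows a negative association. The positive
association characteristic of learning cohorts comes from the
random→structured side of the axis — under-learned, random-leaning
responders have both low normalized PI and negative strategy index — which
is why the default grid spans both sides. The association's human-cohort
magnitude is not a target of this package, as it depends on data that were
never deposited. Correlations use the product-moment coefficient with a
Fisher-z 95% interval; incremental variance explained is computed as the
R² gain of adding a regressor to a group-indicator design, both verified
against from-definition oracles in the test suite. Group membership enters
as indicator columns with an intercept.

## Problem sizes and limitations

The test suite runs its stochastic checks at sizes chosen to keep the whole
suite in a few minutes on one core: sign recovery at 12 seeds × 23 × 500
trials, λ-ordering at 20 seeds × 23 × 60 trials, belief-update comparisons
at 10 seeds × 2000 trials, staircase convergence at 200 seeds, Monte-Carlo
frequency checks at 10³–10⁵ draws with 3-standard-error bounds.

What passing these tests shows is that the measures do what they claim on
data whose generating process is known exactly. What they cannot show is
anything about human data: the agents have stationary policies (except the
pseudo-count learner, itself a stand-in), no reaction times, no
working-memory limits on context encoding, no day boundaries or forgetting,
and the feedback mechanism is an assumption. Higher-order (level-2+)
models, trial-level strategy estimation, robust (skipped) correlations and
Bayes-factor inference are out of scope.
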