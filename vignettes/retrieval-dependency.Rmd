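---
title: "Retrieval dependency and models of forgetting for three-element events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval dependency and models of forgetting for three-element events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopdep)
```

## The scientific question

When a multi-element episodic event — a place, a person and an object bound
together — is forgotten, does it fragment association by association, or is
the whole representation lost at once? `loopdep` implements the behavioral
machinery for answering this with cued-recognition data on
location–person–object *triplets*: closed-loops (all three pairwise
associations encoded) and open-loops (two associations sharing a common
element; the third is never studied).

The observable is *retrieval dependency*. If a closed-loop is stored and
retrieved holistically, then retrieving one of its associations predicts
retrieving the others; if associations are independent memory traces, it
does not.

## The dependency statistic

For each participant, session and loop type, responses form a 6 × N matrix:
six ordered cue→target directions (L→P, L→O, P→L, P→O, O→L, O→P) by N
events, entries correct/incorrect, with open-loop events administering only
the four directions involving their common element. Six 2×2 contingency
tables cross-classify pairs of directions sharing a common element: for each
category X, one table for the two retrievals *cued by* X and one for the two
retrievals *of* X. Closed-loops feed all six tables; open-loops exactly the
two matching their common element.

For a table with counts $n_{11}, n_{10}, n_{01}, n_{00}$ over $N$ events,
the proportion of joint retrieval is the leading-diagonal share
$(n_{11}+n_{00})/N$. The independence model predicts, from the participant's
marginal accuracies $P_1, P_2$ of the two directions,

$$P_{\text{joint}}^{\text{ind}} = P_1 P_2 + (1-P_1)(1-P_2),$$

and **dependency** is the data-minus-model difference, averaged over the
non-empty tables. Because the joint proportion scales with accuracy (it is
minimized at marginals of .5 — note $P_1=P_2=p$ gives $1-2p(1-p)$), only
this difference is interpretable, never the raw joint proportion.

Three deliberate choices, where the construction was genuinely open:

* **Participant-level marginals.** Marginals are estimated per direction
  across events, not per event: event-level retrieval probabilities are not
  observable from one binary outcome each. Under this reading the
  independence model's cell sums reduce to $N P_1 P_2$ etc.
* **Marginals per table, over that table's contributing events.** This keeps
  data and model on identical event sets, which matters for open-loops
  (each table sees a different third of them) and for matrices with
  non-administered directions.
* **Empty tables are dropped from the six-table average** rather than
  imputed — their joint proportion is 0/0.

Missing responses are recoded as incorrect at load time (`read_trials()`
logs the count); dependency is computed on complete matrices downstream.

## The independent-forgetting model

The independence model above conditions on accuracy at one session; it says
nothing about *forgetting*. The second model asks: given a participant's
immediate-test (T1) closed-loop matrix and their observed delayed-test (T2)
accuracy, what dependency would remain at T2 if associations were forgotten
independently of one another?

`simulate_t2_matrix()` flips $k$ correct cells to incorrect, drawn uniformly
without replacement, with $k = \mathrm{round}((\mathrm{acc}_{T1} -
\mathrm{acc}_{T2}) \times 6N)$ clamped to the number of correct cells.
Incorrect cells are never restored: the model removes memories only, and a
target above T1 accuracy yields zero flips with a warning.
`forgetting_model_dependency()` repeats this (100 simulations per
participant by default) and recomputes dependency on every simulated matrix
— with the independence model rebuilt from the *simulated* marginals, since
dependency is defined relative to the same matrix's own margins.

Numerical choices:

* **Exact-count flips by default.** Equating mean accuracy is stated as an
  equality, and the exchangeable uniform draw gives every correct cell the
  same flip probability. A per-cell Bernoulli scheme
  (`method = "bernoulli"`, flip probability
  $(\mathrm{acc}_{T1}-\mathrm{acc}_{T2})/\mathrm{acc}_{T1}$) is provided for
  sensitivity analysis; it matches the target only in expectation.
* **Deterministic rounding** of the flip count; the achieved accuracy of
  every simulated matrix is within $1/(6N)$ of the target.
* Open-loop matrices are rejected: the model is defined for closed-loops,
  the condition that shows dependency in the first place.
* No recovery (incorrect at T1, correct at T2) is modeled; this is a
  faithful limitation of the conversion rule, not an oversight.

The diagnostic contrast is: observed dependency stable from T1 to T2
*versus* simulated dependency substantially below both — evidence that real
forgetting is not association-independent.

## The synthetic cohort generator

The paper-shaped analyses need data with known ground truth, so the
generator makes the competing hypotheses explicit as parameters
(`gen_params()`):

| parameter | meaning | default |
|---|---|---|
| `p_store` | probability a trace is stored at encoding | .72 |
| `lapse` | incorrect response despite a stored trace | .03 |
| `p_guess` | correct response without a trace | 1/6 |
| `survival_T2` | stored trace survives to the delayed session | .50 |
| `encoding_mode` | `holistic` or `independent_associations` | holistic |
| `forgetting_mode` | `all_or_none` or `association_independent` | all_or_none |
| `tested_boost` | survival multiplier for triplets tested at T1 | 1 |

Defaults were chosen once to emulate the closed-loop accuracy levels of the
one-week designs: the closed form
$p_{\text{store}}(1-\text{lapse}) + (1-p_{\text{store}})\,p_{\text{guess}}$
gives ≈ .75 at T1, and with survival .5, ≈ .46 at T2 — the neighborhood of
the published group means. `p_guess = 1/6` is the six-alternative
forced-choice floor. These values are constructs that make the analysis
testable; they are not estimates of any real participant.

Semantics of the regimes:

* **Holistic encoding** draws one storage Bernoulli per closed-loop event,
  shared by its three pairs. Open-loops always store per pair, in either
  mode — they are, by hypothesis, not bound into a single engram, which is
  what reproduces their null dependency.
* **All-or-none forgetting** draws one survival Bernoulli per *holistically
  stored* event. Where pairs were stored independently there is no unitary
  engram to lose, so survival is drawn per pair; an event-level survival
  draw over independently stored pairs would itself manufacture delayed
  dependency and corrupt the independence null.
* Both retrieval directions of a pair share one trace; lapses and guesses
  are independent across trials. Foil identity is not modeled — outcomes
  are binary.

What the generator deliberately does **not** emulate: reaction times,
participant-level parameter heterogeneity (one parameter set per cohort),
response-option confusion structure, testing effects (unless
`tested_boost` is raised), sleep physiology, and any integration of
open-loops over time. Passing tests therefore show that the *analysis*
behaves correctly under known generative truth, not that real forgetting
follows these regimes — that inference belongs to the dissociation logic
above applied to real data.

## Trial schedules

`generate_triplets()`, `build_encoding_schedule()` and
`build_test_schedule()` reproduce the four designs' combinatorics: 60
triplets per participant; encoding one pair per trial with one pair from
each triplet per block and pair order rotated across blocks (three quoted
rotation orders; for open-loops the rotation is forced by the common
element, for closed-loops it is assigned round-robin after shuffling, the
rule being otherwise unconstrained); within-subject designs use encoding
blocks of 30/60/60 with closed-loops only in block 1. Tests probe every
encoded association in both directions exactly once per session, six
directions one-per-block for closed-loops, four blocks (of six where the
designs intermix) for open-loops, with the delayed inference test appended
for the first design's open-loop cohort. Timing (6 s study, 500 ms
fixation/blank, 20 s breaks every 30 trials — 25 at the fourth design's
immediate test) is carried as metadata only; there is no presentation
engine. Element labels are synthetic (`location_01`, …): the real word
lists are stimuli, not computation.

Every schedule is driven by one explicit seed through R's default RNG;
cohort members derive per-participant seeds from the master seed, so any
participant is reproducible in isolation.

## The inferential layer

Dependency scores feed standard one-sample *t* tests (`one_sample_t()`),
Cohen's *d* with the pooled standard deviation across conditions regardless
of design (`cohens_d_pooled()`), and JZS Bayes factors
(`jzs_bayes_factor()`): a Cauchy prior with scale .707 centered at zero on
the standardized effect, with one-sided hypotheses implemented by *prior
truncation* (renormalized half-Cauchy), not by posterior-odds correction.
The *exceedance probability* reported alongside a Bayes factor is read as
the posterior probability of the favored hypothesis at equal prior odds,
$\mathrm{BF}/(1+\mathrm{BF})$ — this reading reproduces the published
pairing of Bayes factors with exceedance values (e.g. a BF of 5.41 pairs
with .84).

Two numerical points deserve note:

* The marginal likelihood integrates the noncentral-*t* density of the
  observed statistic over the (truncated) prior. R's `dt(ncp = )` loses
  accuracy far into its tails — exactly where a one-sided prior opposing a
  large observed effect places all its mass — so the package evaluates the
  noncentral-*t* log-density through the scale-mixture representation with
  64-node Gauss–Hermite quadrature after an exact Laplace match; the
  transformed integrand is strictly log-concave and the rule is accurate to
  near machine precision. Adaptive quadrature over the prior is guided by
  explicit split points at the likelihood peak and in a geometric boundary
  layer at truncation edges; a dense-grid Riemann evaluator over the prior
  cdf scale exists solely as an independent numerical cross-check.
* `required_sample_size()` computes exact noncentral-*t* power and returns
  the smallest n reaching the requested level, with a floor of n = 2 (a
  *t* test needs two observations). The a-priori design question — d = .62,
  α = .05, power = .85, two-tailed one-sample, the paired data-versus-model
  contrast — returns 26, which validates interpreting that power analysis
  as a two-tailed one-sample test.

## A worked run

```{r, eval = FALSE}
params <- gen_params(n_participants = 26, seed = 1)
cohort <- simulate_cohort(params, experiment_config(2, "closed"))
fit <- retdep(cohort)
summary(fit)                       # joint retrieval, data vs model, by cell
sim <- simulate(fit, nsim = 100, seed = 2)   # independent-forgetting model
one_sample_t(sim$simulated_T2 - sim$dependency_T1)
jzs_bayes_factor(sim$dependency_T2 - sim$dependency_T1,
                 direction = "decrease")
```

`run_pipeline()` chains the same stages from a flat configuration (list or
YAML), writes the trial-level CSV, the per-participant results, the group
summary tables and a manifest with seeds and parameter values, so every
emitted number is recomputable from the emitted trial file alone.

## Problem sizes and test design

The test suite exercises cohorts of 26 participants (the designed sample
size) for the headline dissociation, 100–200 participants where a
population null must be bounded (independence gives mean dependency zero to
within two standard errors at accuracies around .3, .5 and .8), 100
forgetting simulations per participant as in the standard analysis, and
10^5 resamples for the brute-force check of the independence model. The
analytic oracle for the holistic regime enumerates the latent states of an
event (stored-and-survived versus traceless) and includes the finite-N
covariance term that plug-in marginals introduce, so the simulated cohort
is compared against an exact expectation rather than a second simulation.

## Known limitations

* One parameter set per cohort; between-participant heterogeneity is future
  work.
* The forgetting model only deletes; designs where delayed accuracy exceeds
  immediate accuracy (strong testing effects) fall outside its domain and
  produce a warning with zero flips.
* Second-level data deposited by other groups arrive in unknown layouts;
  `read_second_level()` therefore requires an explicit column mapping
  rather than guessing.
* Yule's Q / odds-ratio dependency variants and trial-level generalized
  linear models are out of scope, as are the omnibus mixed ANOVAs — the
  package's inferential surface for group contrasts is t tests and Bayes
  factors.
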