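---
title: "Latent rule states and representational warping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent rule states and representational warping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rulewarp)
```

rulewarp implements a complete analysis chain for rule-based decision-making
in the cognitive set-shifting task (CSST): behavioral segmentation into
latent rule states, an ideal-observer account of the remaining choices, and
a battery of single-neuron and population analyses that measure how rule
adherence reshapes choice coding. This vignette explains each model, the
parameters that matter, the numerical choices, and what the synthetic-data
generator can and cannot establish.

## The task

On every trial three options appear, pairing the three colors (cyan,
magenta, yellow) with the three shapes (circle, star, triangle) in a
uniformly random bijection, with randomized positions and presentation
orders. One of the six features is the block's hidden *correct feature*;
any choice matching it (by color or by shape) is rewarded. Because each
feature matches exactly one option, a uniformly random chooser is rewarded
with probability exactly 1/3. A block ends after a criterion number of
correct choices (`block_schedule()`, default 15 — the value used on almost
all sessions; 10/20/30 are accepted). The next correct feature is drawn
uniformly from the five others: the task description says the feature
"changed", which we read as excluding repeats; a `rule_draw_policy =
"uniform"` switch restores unconstrained draws for sensitivity checks.

## The rule-state hidden Markov model

Choices are emissions from a seven-state chain: six rule states (one per
feature) and a max-entropy *residual* state.

* **Emissions are fixed, not learned.** A rule state emits the option
  matching its feature with probability 1 (exactly one option matches), and
  the residual state emits each of the `N = 3` options with probability
  `1/N`. The residual state is a modeling device — the maximum-entropy
  catch-all for everything a single-feature rule cannot explain — not a
  claim that those choices are random.
* **Transitions are tied and structurally constrained.** Direct transitions
  between different rules are fixed at zero (after a block change the
  subject must pass through exploration to find the new rule), rules exit
  only to the residual state, and the chain starts in the residual state.
  The residual exit mass is split uniformly over the six rules; this is the
  only reading consistent with the model having exactly **two free
  parameters**, `a_rr` (rule self-transition) and `a_oo` (residual
  self-transition).

Fitting is per session by Baum–Welch. The M-step pools expected transition
counts across the six tied rule states, so structural zeros are preserved
exactly at every iteration. Numerical choices, none of which the original
protocol pins down: convergence when the log-likelihood increment falls
below `1e-6` (500 iterations cap); restart initializations uniform on
(0.5, 0.999) for both parameters; zero-probability emissions carried in log
space as a `-1e30` sentinel (never exponentiated); Viterbi ties broken
toward the lowest state index (residual first, then features in canonical
order). The reference protocol's 100 restarts are supported; the
two-parameter likelihood surface is benign enough that a handful behave
identically, and the test suite runs with 2–10.

The forward–backward and Viterbi recursions are implemented in C++ with
per-step scaling, so 10,000-trial sessions run without underflow and
parameter-recovery suites over many seeds stay fast. Both recursions are
verified against exhaustive path enumeration (every state path kept
separate) on sessions short enough to enumerate.

**What recovery tests can show.** With the generating agent making
max-entropy residual choices — the agent matched to the model's emission
assumption — EM recovers (`a_rr`, `a_oo`) essentially unbiased. The
information about `a_oo` is limited by the residual occupancy: at
(0.95, 0.60) roughly 11% of trials are residual, so a 5,000-trial session
carries a sampling floor near 0.02 for `a_oo` even if the states were
observed. The default synthetic agent instead makes structured
hypothesis-testing residual choices (as real subjects do); this deliberate
misspecification biases `a_oo` upward by a few hundredths and is the
realistic regime for the downstream analyses.

## The ideal-observer belief model

Residual choices are evaluated against a one-trial-history Bayesian
observer. A belief over the six features starts uniform (1/6). A rewarded
choice has likelihood 1/2 on each of its two features and 0 elsewhere; an
unrewarded choice has 0 on its features and 1/4 on the other four.
Posterior = prior x likelihood, renormalized; exact zeros are replaced by
`|N(0, 1e-4)|` noise before renormalization so entropies stay computable
(tests that need exact values set the noise to zero and rely on the
`0 log 0 = 0` convention). Entropies are base-2 throughout.

For a candidate choice `c`, the reward probability is the belief mass on
its two features, and the expected information gain is the prior entropy
minus the reward-probability-weighted average of the two outcome-branch
posterior entropies. After an omission, the *novel* option — differing from
the previous choice in both dimensions — maximizes both quantities; after a
reward, single-dimension changes carry the information maximum. The
`residual_prior_mixture()` helper reproduces the reward-marginalized
profile using the observed probability (0.52 by default) that the trial
before a residual choice was rewarded. Longer-horizon (exponential-decay)
history models are out of scope.

## The synthetic-data generator

`simulate_behavior()` inverts the HMM: a latent chain with the same
structural constraints emits choices by state. Rule states choose the
matching option (a `lapse` probability, default 0, allows violations).
Residual choices follow a policy over choice-relation classes (0, 1, or 2
feature dimensions changed from the last choice) conditioned on the last
outcome, realized by a uniform draw among qualifying options. Defaults:
after an omission the novel option is taken with probability 0.95 (the
observed rate of that optimal choice); after a reward, mass 0.25/0.65/0.10
on classes 0/1/2 — a win-stay-in-one-dimension profile that matches the
qualitative shape of the observed post-reward choice distribution. Setting
`residual_policy = NULL` yields the max-entropy agent used for parameter
recovery. Agent dynamics default to `a_rr = 0.95`, `a_oo = 0.6`, which
produce rule runs of ~20 trials and residual runs of ~2.5 trials at a
15-correct criterion — session statistics in the range of trained subjects.

`simulate_neurons()` draws Poisson counts over a 3,350 ms analysis epoch
(and optionally three 400 ms presentation epochs, evaluated on each
presented option's features) from a log-linear rate model per neuron:
baseline (uniform 2–10 spikes/s) plus coefficients for rule identity (6),
chosen color (3), chosen shape (3), and the 9-level identity interaction.
State-dependent structure:

* `state_gain` (default 0.9) multiplies the rate on rule-based trials —
  the firing-rate reduction under rule adherence.
* `relevant_gain` (1.8) and `irrelevant_gain` (0.3) scale the
  chosen-feature coefficients whose domain is relevant/irrelevant to the
  active rule — expansion of rule-relevant coding and compression of
  rule-irrelevant coding.
* `residual_feature_gain` (0) and `rule_identity_gain` (0) shift the *form*
  of coding with state: residual trials carry conjunction (identity)
  coding, rule trials carry additive category coding. This mirrors the
  identity-to-category shift the analyses are designed to detect and is the
  only configuration under which shared-feature similarity appears *only*
  under rule-based conditions; with additive coding active in both states,
  shared-feature pairs are closer in both, which is a geometric necessity
  rather than a bug.
* `rule_choice_alignment` (0.5) correlates each rule's coefficients with
  the matching feature's choice coefficients, so rule and choice coding
  dimensions are neither identical nor orthogonal — the mixed-coding regime
  the subspace analyses presume. At 0 they are orthogonal on average.

`no_warping_tuning()` is the state-blind null generator (all gains 1, no
rule coding): every state-dependent signature must calibrate to null on it.

**What passing tests do and do not show.** The generator produces
independent Poisson counts given the trial conditions: no noise
correlations (unrecoverable in pseudopopulations anyway), no slow drifts,
no temporal autocorrelation in rates, no overdispersion (off by default),
and the state labels driving the neural generator are the *true* ones. Real
data add all of these, plus the temporal confounds discussed with the
rule-domain analyses (choices sharing a rule domain and feature cluster in
time). Passing the recovery suites shows the estimators and the pipeline
plumbing are correct, not that the brain works this way.

## Single-neuron statistics

Rates are z-scored within neurons for all analyses except direct rate
comparisons, which are centered only. Multiple comparisons across reported
contrasts use Benjamini–Hochberg at 0.05 (`bh_fdr()` wraps the standard
step-up rule); proportions of tuned neurons are tested against the 5%
false-positive rate with one-sided binomial tests.

* **Rate contrasts** use a two-sided label-shuffling permutation test,
  1,000 shuffles by default (the count is our choice; the test is named but
  not parameterized in the reference protocol), with an add-one Monte Carlo
  estimator and an exact enumeration option for small samples.
* **Gini sparsity** implements
  `1 - 2 * sum_k (x_k/||x||_1) (N - k + 1/2)/N` over the ascending sort.
  On a perfectly uniform vector this form evaluates to 0 (one minus twice
  the area under the Lorenz curve), although the accompanying prose
  tradition describes uniform input as 0.5; group comparisons are unaffected
  by the convention, and we implement the formula as printed. All-zero
  pseudotrial vectors are undefined under the formula and rejected; callers
  should skip and count them.
* **Mutual information** between quantile-binned counts (2 bins, so the
  minimum cell count for the rule/residual contrast is 2 types x 9
  identities x 2 bins = 36) and choice identity, plug-in estimator.
  Rule-based trials are downsampled to the residual count to equate
  limited-sampling bias, and a label-shuffle floor is reported alongside
  (never subtracted). Binning ties are broken by randomized ranks under the
  caller's seed so sparse neurons split as evenly as possible. Bits per
  spike divides MI by the mean count within the choice type — the reference
  analysis reports "information per spike" without defining the
  denominator, so this is our documented choice.
* **Identity–category index** is the ratio of the overall ANOVA F of the
  9-level identity model to that of the additive color + shape model,
  per neuron per choice type; paired across choice types at the group
  level.
* **Relevance-tuning GLM** ranks each neuron's features
  best/intermediate/worst per domain from all trials (ties broken by
  canonical feature order), averages z-scored presentation-epoch responses
  within conditions, and fits `fr = b0 + b1 S + b2 R + b3 (S x R)`; `b3`
  is the tuning-sharpening term. Best-minus-worst tuning depths are
  contrasted between relevance classes with paired t-tests.

## Pseudopopulations, RSA, and choice subspaces

`build_pseudotrials()` resamples z-scored rates with replacement,
independently across neurons, 20 pseudotrials per condition, under three
condition schemes (rules pooled; rule domain; specific rule). Neurons below
2 spikes/s (full epoch, all trials — the window is our documented choice)
are excluded; 1–4 missing conditions are imputed at the neuron's global
mean normalized rate (read as "fewer than 5", regardless of scheme size);
5 or more missing conditions exclude the neuron. A condition missing for
more than half the retained neurons is a hard error naming the condition —
the fixture is too small. Split-half construction partitions each neuron's
trials within conditions into two equal subsets (singleton conditions fall
back to imputation in the empty half) so cross-matrix distances are
cross-validated; `bootstrap_pseudopopulations()` re-seeds entire rebuilds
and reports percentile intervals and sign-crossing p-values.

RSA takes arithmetic condition centroids — the protocol's phrase "geometric
mean representation" cannot be computed on signed z-scored values, so the
arithmetic centroid is the implementation and a geometric option exists for
positive inputs — then Euclidean distances, z-scored over the unique
off-diagonal entries (the self-distance diagonal is excluded from
everything). Planned contrasts compare between- versus within-type
distances (two-sample t), total spread by type (paired over matched
identity pairs), and shared- versus unshared-feature distances within type.
The structure ANOVAs model the upper triangle with within/between, the
nested type, and feature-sharing predictors plus interactions; in the
rule-domain scheme the nine pairs matching both features but differing in
domain are omitted (they make the design rank-deficient), leaving the
144-pair, 135-residual-df design.

A note on direction: compressing the rule-irrelevant domain makes choices
that differ *only* in the irrelevant feature — i.e., pairs sharing the
rule-relevant feature — more similar. That geometrically forced direction
(shared-relevant pairs closer within each rule domain) is what the package
computes and what its generator recovers.

Choice subspaces are six one-vs-rest ridge logistic classifiers (glmnet)
over the per-rule pseudotrial matrix, whose rows span color rules, shape
rules, and residual states so the choice axes marginalize over goals.
Stratified 20-fold cross-validation scores 25 penalties — zero plus 24
log-spaced values on `[1e-4, 1e4]` (a literal log-spacing cannot include
zero) — and the smallest penalty attaining maximal mean accuracy is refit
on all rows; a per-classifier penalty is available by flag. Projections
(`x . beta + intercept`, the log odds) are tagged by chosen feature and
rule relevance; the projection ANOVA tests the residual/rule main effect
and the nested relevance effect. Rule axes are fit by the same protocol on
rule-based rows only (the protocol implies but does not state this
restriction; a flag exposes it), and angles between coefficient vectors
exclude intercepts. Because pseudotrial rows are resamples of the same
trials, calibration-grade significance tests aggregate projections to
condition-level means; the row-level ANOVA mirrors the reference analysis
and is reported alongside.

## Pipeline and problem sizes

`run_pipeline()` chains the stages under one root seed (each stage draws
from a fixed offset), echoes the configuration, and writes every table as
TSV. The packaged test and acceptance runs use desk-scale problems chosen
to keep the full suite comfortably reproducible on a laptop: 12-block
(~500–800 trial) sessions, 60-neuron populations across three region tags,
20 pseudotrials per condition, 10-fold classifier CV, 100,000 trials for
the random-policy reward rate, 20 seeds at 5,000 trials for parameter
recovery, and 500 state-blind neurons for type-I calibration of the
permutation and ANOVA suites.

## Known limitations

Pseudopopulations cannot recover trial-to-trial noise correlations. The
belief model's one-trial history is a simplification of decaying multi-trial
influence. The per-module command-line tools of a deployment setting are
not shipped; the exported functions plus `run_pipeline()` are the
interface. The generator's state-dependent gains are constructs for
recovery testing, not claims about cortical mechanism; and figure-level
cosmetic reproduction is out of scope.
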