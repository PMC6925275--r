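---
title: "Arbitrating between Pavlovian and instrumental control: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arbitrating between Pavlovian and instrumental control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavarb)
```

## The model

`pavarb` implements a Bayesian model-averaging account of how agents weigh
Pavlovian against instrumental control. Two Bernoulli reward predictors run
in parallel. The Pavlovian predictor conditions only on the stimulus and
maintains a posterior mean reward rate $\hat\theta_s$; the instrumental
predictor conditions on stimulus and action and maintains
$\hat\theta_{sa}$. Both are Beta–Bernoulli learners summarized by their
posterior means, updated with a decaying learning rate:

$$\eta \leftarrow \eta + 1, \qquad
  \hat\theta \leftarrow \hat\theta + \frac{r - \hat\theta}{\eta},$$

with the counter initialized at the prior confidence $\eta_0$ and the mean
at the prior mean $\theta_0$. This update has an exact closed form — after
$n$ observations $\hat\theta_n = (\eta_0\theta_0 + \sum_i r_i)/(\eta_0 + n)$
— which the test suite uses as an oracle at tolerance $10^{-12}$.

Which predictor should drive behavior depends on whether the environment is
controllable. The arbitrator tracks the log posterior odds $L$ of the
uncontrollable hypothesis, accumulating on each trial the log ratio of the
two predictors' one-step predictive probabilities for the observed reward:

$$\Delta L = r \log\frac{\hat\theta_s}{\hat\theta_{sa}}
  + (1 - r)\log\frac{1 - \hat\theta_s}{1 - \hat\theta_{sa}}.$$

This is a prequential decomposition of the marginal likelihood ratio: the
product of one-step predictions equals each model's evidence, so $L$ is the
running log Bayes factor plus the prior log-odds $L_0$. Because the
instrumental predictor spreads its probability mass over more contingencies,
it is penalized when its extra flexibility goes unused — the Bayesian
Occam's razor that makes low-controllability environments favor the
Pavlovian predictor even though, asymptotically, the instrumental predictor
can always mimic the Pavlovian one.

The Pavlovian weight $w = \sigma(L)$ mixes the controllers' action values,
with the Pavlovian value of No-Go pinned at zero (reward expectation
invigorates action):

$$V(s, \mathrm{go}) = w\,\hat\theta_s + (1-w)\,\hat\theta_{s,\mathrm{go}},
  \qquad V(s, \mathrm{nogo}) = (1-w)\,\hat\theta_{s,\mathrm{nogo}},$$

and choices are softmax in $V$ with inverse temperature $\beta$. The
*adaptive* model updates $w$ endogenously as above; the *fixed* comparison
model holds $w$ constant as a free parameter. Both share $\beta$ and one
$(\theta_0, \eta_0)$ pair per internal learner — five free parameters for
the adaptive model, six for the fixed one.

## Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| $\beta$ | softmax inverse temperature (unitless) | 3 | moderate determinism; the generating value used throughout the synthetic cohorts |
| $\theta_0$ | prior mean reward rate | 0.5 | uninformative midpoint of the task's reward rates |
| $\eta_0$ | prior confidence (pseudo-observations) | 2 | weak prior: beliefs move substantially within the first few trials |
| $L_0$ | initial log-odds of uncontrollability | 0.5 | held fixed, not fitted; gives initial weight $\sigma(0.5) \approx 0.62$, a mild initial Pavlovian tilt |
| $w$ (fixed model) | constant Pavlovian weight | fitted | in $[0,1]$ |

$L_0 = 0.5$ is interpreted on the log-odds scale, the scale on which $L$ is
defined and updated. The value is exposed in `model_spec()` so the
alternative reading ($P(\text{uncontrollable}) = 0.5$, i.e. $L_0 = 0$) is a
one-argument change.

A note on the prior parametrization: a
$\mathrm{Beta}(\theta_0\eta_0/2, (1-\theta_0)\eta_0/2)$ prior carries
pseudo-count mass $\eta_0/2$, while the counter update above carries
$\eta_0$. The two conventions disagree by a factor of two; we implement the
incremental counter rule literally, because it is the operative recursion
and has the exact closed form used by the oracle tests.

## The task and the synthetic cohorts

The simulated task mirrors a reward-only Go/No-Go paradigm with a
controllability manipulation. Each 120-trial session interleaves three
stimuli, 40 trials each, in seeded uniform shuffles: Go-to-Win (Go rewarded
75% of the time), No-Go-to-Win (No-Go rewarded 75%), and a Decoy. In the
Low Control condition the Decoy pays 50% for either action — the optimal
action is undefined, and outcomes carry no information about control. In
the High Control condition the Decoy pays 80% for Go. Experiment-1 sessions
are between-subjects (one condition); Experiment-2 sessions concatenate two
120-trial blocks, one per condition, order randomized per participant.

Two contingencies are not pinned down by the task description and are set
by design, exposed in `default_contingencies()`: the complementary action
on each win stimulus pays 25% (the standard complement for this task
family), and the High Control Decoy pays 20% for No-Go (complement of 80%).
The Low Control Decoy pays 50% for No-Go — equality of the two action rates
*is* the operational meaning of uncontrollability.

Learner state (means, counters and $L$) resets at Experiment-2 block
boundaries: each block introduces new stimuli, and the weight trajectories
of the two conditions are treated as separate inferences about two
different environments. Whether $L$ should instead carry over between
blocks is a genuinely open choice; resetting is the conservative one, since
carry-over would leak one condition's controllability evidence into the
other.

Synthetic agents are simulated from the models themselves at known
parameters ($\beta = 3$, $\theta_0 = 0.5$, $\eta_0 = 2$ unless stated), so
every downstream analysis has a ground truth. What the generator does *not*
emulate: reaction times, attention and motivation lapses, learning-rate
asymmetries between rewarded Go and No-Go trials, and any within-cohort
heterogeneity in parameters. A green test on these cohorts therefore
establishes internal consistency of the pipeline — the method recovers what
the model put in — not that the model describes human learners.

## Fitting

Per-participant maximum likelihood with unconstrained reparametrization
($\log$ for $\beta$ and $\eta_0$, logistic for $\theta_0$ and $w$), BFGS,
and 10 seeded random restarts by default; guard rails clip
$\beta \in (0, 50]$, $\eta_0 \in (0.1, 100]$, $\theta_0 \in [0.01, 0.99]$.
The session likelihood is computed in C (with a pure-R reference walk kept
under test at $10^{-12}$ agreement). Restart seeds derive from the settings
seed and the participant id, so cohort results are independent of
participant order and refits are bit-identical.

Group-level comparison uses random-effects Bayesian model selection:
per-participant log evidences (BIC approximation by default,
$\mathrm{loglik} - \tfrac{k}{2}\log T$; AIC selectable) enter a variational
Dirichlet–multinomial model of population model frequencies with uniform
prior $\alpha_0 = 1$. Exceedance probabilities are analytic for two models
(regularized incomplete beta); the Bayes omnibus risk compares the fitted
model's variational free energy against the closed-form evidence of the
equal-frequency null; the protected exceedance probability is
$\mathrm{PXP}_k = \mathrm{EP}_k(1 - \mathrm{BOR}) + \mathrm{BOR}/K$, an
identity the tests assert exactly.

## Behavioral measures

*Go bias* is accuracy on Go-to-Win minus accuracy on No-Go-to-Win trials;
zero under purely instrumental control. *Accuracy* always means agreement
with the optimal action and is computed only over trials whose optimal
action is defined, which excludes the Low Control decoy everywhere accuracy
appears — including the exclusion rules (overall incorrect $\ge 50\%$, or
$< 30\%$ accuracy on any single stimulus).

The *weight-quantile* analysis bins each participant's trials by that
participant's own per-trial $w$, using rank-based equal-count bins (5 by
default; the bin count is a display choice, not a model quantity).
Rank-binning handles ties and constant weights gracefully — with a constant
$w$ the bins are balanced and exchangeable — and at one bin the analysis
reduces exactly to the overall Go bias, a consistency the tests assert.

The *timecourse* analysis needs a trial-level Go bias. We pair the $k$-th
Go-to-Win presentation with the $k$-th No-Go-to-Win presentation within a
block ($k = 1..40$), the only pairing that makes "Go bias as a function of
trial" well defined per participant, and regress the per-participant series
on $\log k$; the group-level t-test on those slopes tests the predicted
decline. A 5-trial centered moving average is applied for display only.

The *bias–variance decomposition* of choice behavior scores each
participant by $\mathrm{bias} = \frac{1}{T}\sum_t \mathbb{I}[a_t =
\mathrm{Go}] - \mathbb{I}[a^*_t = \mathrm{Go}]$ over defined-optimal trials
and $\mathrm{variance} = \frac{1}{T}\sum_t (\mathbb{I}[a_t = \mathrm{Go}] -
\bar a)^2$ over all trials, which equals $\bar p(1 - \bar p)$ for Go rate
$\bar p$ (asserted against the direct sum). `bias_variance()` exposes
`include_decoy` for the variance because the choice is consequential; see
below.

## Numerical choices

- $\Delta L$ uses the predictive means *before* the trial's mean update:
  the prequential reading of the evidence ratio. Updating means first would
  double-count the trial.
- Counter order is increment-then-divide, giving the exact running-average
  closed form.
- Only the chosen $(s, a)$ instrumental entry updates per trial; the
  Pavlovian entry for $s$ updates on every trial of $s$.
- Predictive means are clipped to $[10^{-6}, 1 - 10^{-6}]$ before the logs
  in $\Delta L$; unreachable under valid priors but protects degenerate
  configurations.
- Choice log-probabilities are floored at $10^{-300}$ so a deterministic
  policy's likelihood is representable.
- Degenerate group comparisons (zero spread, zero difference) report
  $t = 0$, $p = 1$ rather than erroring, so mirrored synthetic cohorts are
  handled.
- Welch correction for between-subjects t-tests; Cohen's d with pooled SD
  (between) or the SD of paired differences (within).
- One global seed fans out to every stage through a label-hashed substream
  scheme (`derive_seed()`), so adding a pipeline stage never perturbs the
  streams of existing stages.

## Known limitations

**The all-trials variance reverses the predicted condition difference in
the synthetic world.** The arbitration account predicts low controllability
should yield high bias and *low* variance. On synthetic adaptive agents the
bias direction replicates robustly, but the variance computed over all
trials is reliably *higher* under Low Control, at every $\beta$ we probed:
the High Control decoy acquires a dominant Go response (rate $\approx$ its
80% contingency and above), which lowers its Bernoulli variance, while the
Low Control decoy's Go rate hovers near 0.5, the variance maximum.
Restricted to the two win stimuli (`include_decoy = FALSE`) the predicted
direction reappears. The acceptance suite asserts the prediction under the
literal all-trials definition and that expectation fails by design — it is
a property of the model on this task, not an implementation defect.

**$w$ is weakly identified in the fixed model.** With the prior parameters
free, a profile likelihood over $w$ is flat within $\sim$1 nat for many
sessions, and its maximum can sit far from the generating value: the
$(\theta_0, \eta_0)$ pairs absorb much of what $w$ encodes. Fits are
optimizer-adequate (fitted likelihood $\ge$ the generating-parameter
likelihood essentially always), yet only $\sim$75–80% of sessions generated
at $w = 0.9$ recover $w > 0.5$. Cohort-level orderings are preserved
(cohorts generated at high $w$ recover higher mean $\hat w$ than cohorts at
low $w$), so between-condition inferences survive; per-participant $\hat w$
should be interpreted with caution.

**Model discriminability is asymmetric under BIC.** Adaptive-generated
cohorts are attributed to the adaptive model with PXP $\approx 1$. The
converse does not hold: on fixed-generated cohorts the fixed model's raw
likelihood advantage over the adaptive fit is typically under 2 nats and
often negative (the adaptive model with free priors can mimic a
near-constant weight), while its sixth parameter costs
$\tfrac{1}{2}\log 240 \approx 2.74$ nats of BIC — so PXP often favors the
adaptive model even on fixed-generated data. A population-level PXP favoring
the adaptive model is therefore strong evidence against the fixed model,
but the 2×2 model-recovery confusion matrix is not symmetric and should not
be presented as such.

**Scope.** Reward valence only: no punishment trials, no Pavlovian
suppression ($V_P < 0$), no Pavlovian-instrumental transfer, no
instrumental learning-rate asymmetries. Evidence approximations are
MLE-based (BIC/AIC); no hierarchical fitting or MCMC posteriors.
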