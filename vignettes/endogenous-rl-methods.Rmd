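---
title: "Modeling learning from imagined rewards: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling learning from imagined rewards: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`imaginerl` analyzes a two-armed bandit task in which the "reward" is the
experienced pleasantness of an internally simulated episode rather than an
external payoff. On each trial a participant chooses between a high-reward
(HR) and a low-reward (LR) person — persons whose imagined scenarios are
pleasant with probability 0.8 versus 0.3 — then imagines an episode with the
chosen person for 8 s and rates its pleasantness on a continuous scale with a
neutral midpoint. The package provides the full model-based analysis of such
data: a five-model reinforcement-learning (RL) model space, maximum-likelihood
fitting with BIC-based and random-effects Bayesian model selection, parameter
and model recovery, the behavioral statistics, representational-similarity
(RSA) model matrices, and trial-wise regressor export for model-based fMRI —
all runnable end to end on synthetic cohorts.

```{r, eval = FALSE}
library(imaginerl)
```

## The model space

All models are choice models over the two offered persons; they differ in the
latent quantity that drives choice.

**Rescorla-Wagner (RW).** The expected value $Q^k$ of the chosen person $k$ is
updated by the prediction error (PE)

$$Q^k_{t+1} = Q^k_t + \alpha\,\delta_t, \qquad \delta_t = r_t - Q^k_t,$$

with learning rate $\alpha \in [0,1]$. Choice probabilities come from a
softmax over the two offered persons' values with inverse temperature
$\beta \ge 0$:

$$p^k_t = \frac{\exp(\beta Q^k_t)}{\sum_i \exp(\beta Q^i_t)}.$$

Values are initialized at 0.5 for every person: the to-be-imagined persons
are selected to be approximately neutrally liked before the task, so the
prior expectation sits at the scale midpoint. The reward $r_t$ is the
binarized pleasantness rating: ratings above the neutral midpoint count as
reward 1, the midpoint itself and everything below as 0 (the
neutral-to-unpleasant scenario class is the non-rewarding class; whether the
exact midpoint should count as reward is not determined by the task
description, and mapping it to 0 is the choice consistent with that reading).

**Choice kernel (CK).** A reward-blind perseveration account: a kernel
$CK^k$ tracks how often each person was recently chosen
($CK^k \leftarrow CK^k + \alpha_c(\mathbb{1}[k\ \text{chosen}] - CK^k)$ for
every person $k$), and choices follow a softmax on $\beta_c\,CK$.

**RW-CK.** Both quantities combined additively inside a single softmax,
$\beta Q + \beta_c CK$ (4 free parameters).

**Noisy win-stay-lose-shift (WSLS).** After a rewarded trial the previous
choice is repeated with probability $1-\varepsilon/2$; after a non-rewarded
trial it is avoided with the same probability. Stay/shift is defined on
person identity; with no usable history (first trial, after a missed trial,
or when the previously chosen person is not on offer — possible because each
condition contributes two persons) both options get 0.5.

**Null.** A fixed bias $b$: the HR person is chosen with constant
probability $b$, history-free.

The free-parameter counts are RW = 2, CK = 2, RW-CK = 4, WSLS = 1, Null = 1.
These models follow the standard formulations of the model-fitting framework
this analysis style descends from; the parameter counts are additionally
pinned down by the BIC identity $\mathrm{BIC} = \ln(n)\,\mathrm{df} +
2\,\mathrm{NegLL}$ applied to the published group means at $n = 96$ (the
`test-fitting.R` identities).

**Missed trials** contribute no likelihood term, trigger no value or kernel
update, reset the WSLS history, and are excluded from $n$ in the BIC.

### Numerical choices

- The pairwise softmax is evaluated in its logistic form
  $1/(1+e^{-\beta\Delta Q})$; with values in $[0,1]$ and $\beta \le 20$ the
  exponent is bounded, so no overflow is possible. The general
  `softmax_pair()` additionally uses max-subtraction.
- Probabilities are floored at $10^{-12}$ before taking logs so that
  deterministic parameter corners (e.g. WSLS with $\varepsilon = 0$) yield
  large finite penalties instead of infinities.
- The WSLS and Null likelihoods depend on the data only through a handful of
  counts (stay-after-win/shift-after-loss consistency counts; HR-choice
  counts), which are precomputed once per session; the sequential RW/CK/RW-CK
  passes are tight loops over precomputed index vectors.

The likelihoods are validated against a brute-force oracle: for 4-trial
sessions with a deterministic choice-to-reward mapping, the probabilities a
model assigns to all $2^4$ choice sequences must sum to 1 (to $10^{-10}$),
which exercises every branch of the sequential state machinery.

## Fitting and model selection

`fit_subject()` minimizes the negative log-likelihood by bounded L-BFGS-B
from `n_starts` Latin-hypercube initial points (default 10; ties between
starts broken by the lowest start index; all randomness seeded). Bounds are
$[0,1]$ for learning rates, lapse and bias, and $[0,20]$ for inverse
temperatures — with $[0,1]$-valued $Q$, the softmax is effectively
deterministic well below 20. `bic()` uses the subject's number of non-missed
trials as $n$. Failed starts are never silent: a subject whose every start
fails is returned as a flagged non-converged row.

`count_favoring()` gives the fixed-effects count of subjects whose minimal
BIC selects each model (ties to the first model in canonical order);
`delta_bic()` computes $\mathrm{BIC}_{\mathrm{ref}} - \mathrm{BIC}_m$ per
subject. `bms()` implements random-effects Bayesian model selection: model
identity is treated as a random effect with a Dirichlet population prior
(mass 1 per model), subject-wise model responsibilities and Dirichlet counts
are iterated to a $10^{-6}$ fixed point, and exceedance probabilities — the
posterior probability that a model is the most frequent in the population —
are estimated from $10^6$ Monte-Carlo Dirichlet draws (stable to about
$\pm 0.005$ across seeds; a closed form exists only for two models).
Log model evidence is approximated as $-\mathrm{BIC}/2$, the standard
Laplace-style surrogate, since per-subject BICs are what the fitting stage
produces.

## Recovery studies

`parameter_recovery()` draws generating parameters, simulates a session,
refits, and reports true-versus-recovered correlations;
`model_recovery()` crosses generating and fitting models into a
row-normalized confusion matrix with best-fit defined by minimal BIC. Default
simulation ranges keep agents away from the fitting bounds
($\alpha$-type parameters on $[0.1, 0.9]$, inverse temperatures on
$[1, 10]$), where recovery is ill-posed. Recovery fits default to 5
Latin-hypercube starts (the fitting default is 10): across thousands of
simulated fits on these 1- to 4-parameter bounded problems, 5 starts
reproduce the denser-start optimum to well below the $10^{-6}$ optimizer
tolerance, and the study sizes (100 simulations per parameter-recovery
condition, 50 per generating model) keep the full recovery suite at desk
scale. At the task's design size (96 trials), $\alpha$ recovers with
$r \approx 0.8$ and recovery sharpens as the generating $\beta$ grows —
more deterministic choices are more informative about the learning rate.

## Behavioral statistics

- `prob_hr()`: the acquired preference, the fraction of valid trials on
  which the HR person was chosen.
- `wilcoxon_signed_rank()`: one-tailed signed-rank test with the normal
  approximation (continuity and tie corrected) and the effect size
  $r = z/\sqrt{n}$. The approximation, not exact enumeration, is used
  deliberately: at $n = 49$ with all values above the null point it yields
  $W = 1225$ and $r = 0.87$, matching the published worked example, which
  indicates the original analysis used the approximation.
- `liking_change()`: per-condition mean post-minus-pre liking, corrected by
  the baseline condition's change (removing generic test-retest shifts),
  plus the HR-vs-LR contrast.
- `skipped_spearman()`: robust correlation that removes bivariate outliers
  before correlating. Outliers are flagged by the projection method —
  center at the coordinate-wise median, project all points onto the
  direction of each data point, and flag points falling outside the box
  rule (ideal-fourths quartiles $\pm$ 1.5 IQR) along any direction — then
  Spearman's $\rho$ is computed on the retained pairs with a seeded
  percentile-bootstrap CI (1000 resamples). Robust-correlation toolboxes
  differ in the outlier rule (projection versus minimum-covariance-
  determinant distances) and CI flavor; the projection/box-rule/percentile
  combination implemented here is the common default family, and the rule
  is isolated in one function so a different rule can be swapped in.

## The RSA model matrix

`build_model_rsm()` encodes the hypothesis that a brain region re-instates a
person-specific activity pattern whenever the same person is imagined: over
16 patterns (4 persons × 4 runs), same-person different-run pairs are coded
+1 and different-person different-run pairs from the same reward condition
−1. Same-run pairs and cross-condition pairs are excluded by the inclusion
mask: the hypothesis is about replication *across* runs, and restricting
different-person pairs to the same condition prevents condition (value)
differences from masquerading as person coding. This yields exactly 24
positive and 24 negative included lower-triangle cells of 120.

`neural_rsm()` computes Kendall-$\tau$ pattern similarities;
`rsm_agreement()` scores model-data agreement with Kendall $\tau$-a, the
variant recommended for tied model matrices: $\tau$-a counts tied pairs as
neither concordant nor discordant, so agreement with a two-level model
matrix has a ceiling of $(C_\max - 0)/N = 0.511$ rather than 1. Group
inference (is the mean agreement positive?) is unaffected by the ceiling.

## The synthetic-data generator

`generate_session()` emulates the study conditions: 96 trials in 4 blocks;
one HR and one LR person offered per trial (each of the four pairs equally
often per block, screen side counterbalanced; the real pairing schedule is
not specified beyond "an HR and an LR person", so balance is imposed);
agent choices from any of the five models; scenario valence Bernoulli(0.8)
for chosen HR persons and Bernoulli(0.3) for LR; pleasantness drawn from
truncated normals on $[-1,1]$ (pleasant: mean $+0.5$, SD $0.25$;
neutral-to-unpleasant: mean $-0.25$, SD $0.25$ — qualitatively matching a
class that ranges from unpleasant to neutral); rewards by binarization;
optional missed trials; onsets following the trial timing (simulation 8 s,
starting 8 s after trial onset; jittered 2–5 s ITI).

`generate_cohort()` simulates 49 subjects by default, with RW agents drawn
from $\alpha \sim U(0.1, 0.9)$, $\beta \sim U(1, 10)$ — the same ranges the
recovery studies use. Post-task liking for HR persons is planted as
`liking_effect` $\times\,(p(\mathrm{HR}) - 0.5)$ plus rating noise; LR and
baseline persons get noise only. Defaults `liking_effect = 0.3` and
`liking_noise_sd = 0.04` (on the $[0,1]$ liking scale) put the planted
signal and the rating noise at comparable magnitude, giving a clearly
detectable but not degenerate preference–liking correlation at $n = 49$.
`generate_patterns()` produces person-consistent activity patterns (a fixed
person signal plus independent run noise) as the RSA fixture.

What the generator does *not* emulate: real pleasantness-rating
distributions (the defaults are stand-ins, not calibrated to empirical
histograms), within-subject nonstationarity (fatigue, scenario repetition),
heterogeneity of the generating model across subjects, any BOLD/HRF/scanner
properties, and item effects of the specific scenarios. Passing tests
therefore show that the pipeline is correct and well-calibrated on data
satisfying its own assumptions — they do not certify the behavioral claims
on real data.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the studies at desk scale,
chosen for statistical stability per check: 100 simulations per
parameter-recovery condition, 50 per generating model in model recovery,
20 synthetic subjects for planted-RSA recovery, 100 replicates for
null-calibration and for the cohort-correlation replication rate, $10^6$
Monte-Carlo draws for exceedance probabilities. Every stochastic component
takes an explicit seed, and cohort-, fit- and bootstrap-level seeds are
derived deterministically from it, so all outputs are exactly reproducible
from `(spec, seed)`.

## Known limitations

- Log model evidence is the BIC surrogate; a package fitting hierarchical
  models would use proper marginal likelihoods.
- The exceedance computation does not include the Bayes-omnibus-risk
  correction (protected exceedance probabilities).
- The WSLS fallback for "previous choice not on offer" (uniform choice) is
  one of several defensible conventions; it matters only for designs with
  more than one person per condition, and alternatives would change the
  likelihood only on those trials.
- $\tau$-a agreement values are not comparable across model matrices with
  different tie structure (see the ceiling above); compare signs and
  within-design magnitudes only.
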