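---
title: "Measuring dynamic adaptive learning under change points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dynamic adaptive learning under change points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrate)
```

## The problem

A learner in a volatile environment must estimate a hidden quantity from
noisy observations while the quantity itself occasionally jumps at hidden
*change points*. Each new observation should move the estimate by an amount
that depends on whether the observation looks like ordinary noise or like
evidence of a change. The per-observation *apparent learning rate*

$$\alpha_t = \frac{v_t - v_{t-1}}{x_t - v_{t-1}}$$

— the ratio of the estimate update to the prediction error — is a
model-free window onto this process: a delta-rule learner has constant
$\alpha$, whereas an adaptive learner raises $\alpha$ after a suspected
change and lowers it as the estimate stabilizes.

`adaptrate` implements the full simulation-to-analysis chain for two
classic task families:

* **Magnitude learning** — observations are Gaussian around a hidden mean
  (SD 10/300 in normalized slider units) that jumps with hazard 1/10,
  with a 3-observation refractory period after each jump.
* **Probability learning** — observations are Bernoulli draws (0/1) whose
  hidden parameter, uniform on [0.1, 0.9], jumps with hazard 1/20 after a
  6-observation refractory period, each jump changing the odds
  $p/(1-p)$ at least fourfold.

Sessions are 75 observations long; reports start at the slider midpoint
($v_0 = 0.5$). These generative settings are the package defaults and are
the conditions under which all shipped analyses and tests run.

## The normative observers

Both observers know the true generative process and compute (or
approximate) the posterior over the hidden quantity by Bayesian filtering:
a *predict* step mixes the previous posterior with the change
distribution, weighted by the hazard $H$, and an *update* step multiplies
by the likelihood of the new observation and renormalizes. Two summary
quantities of this computation are the package's central objects:

* **prior uncertainty** $u_t$ — the SD of the belief distribution before
  seeing $x_t$;
* **change-point probability** $\Omega_t$ — the posterior probability that
  the hidden quantity changed at the last observation,
  $\Omega_t = p(x_t \mid \text{change})\,H \,/\, p(x_t \mid x_{1:t-1})$.

### Probability task: grid filter

`run_probability_filter()` tracks the full posterior on a grid. The grid
uses 301 midpoints of equal cells on [0.1, 0.9] with midpoint-rule masses;
doubling the grid changes estimates by less than $10^{-4}$ (tested), far
below behavioral effect sizes, and `grid_size` is configurable. The filter
assumes a constant hazard with uniform resampling, deliberately ignoring
the generative refractory period and odds constraint — the small model
mismatch this induces is the conventional choice for this task family.

Two conventions exist for "prior uncertainty": the SD of the previous
posterior, and the SD of the change-point-predicted prior that is actually
multiplied with the likelihood. Both are returned (`u_prev` and `u`); `u`
is the default regressor because it is the distribution the update really
uses. With $H = 0$ the two coincide (tested).

### Magnitude task: reduced two-moment model

`run_magnitude_model()` iterates the standard reduced (two-moment)
approximation of the Gaussian change-point posterior: the estimate $b_t$
and relative uncertainty $\tau_t$ evolve through
$\sigma_t^2 = N^2 + \tau_t N^2/(1-\tau_t)$,
$\Omega_t = \mathcal{U}(x_t)H / (\mathcal{U}(x_t)H + \mathcal{N}(x_t; b_t,
\sigma_t^2)(1-H))$, learning rate
$\eta_t = \tau_t + (1-\tau_t)\Omega_t$, and the printed $\tau$ recursion;
$u_t = \sqrt{\tau_t}\,\sigma_t$. The change likelihood
$\mathcal{U}(x_t)$ is density 1 on [0, 1] (normalized units). Because
$v_t - v_{t-1} = \eta_t (x_t - v_{t-1})$ exactly, the measured learning
rate on the model's own estimates reproduces $\eta_t$ to machine precision
wherever the prediction error is nonzero — a self-consistency the test
suite asserts.

Initialization is not prescribed by the task: we use $b_0 = 0.5$ (the
slider midpoint) and $\tau_0 = 0.5$ (moderate initial uncertainty), both
configurable. $\tau$ is clamped to $[10^{-6}, 1-10^{-6}]$ to keep
$\sigma_t^2$ finite. $\Omega_1$ is computed with the initial prior
standing in for a previous posterior; it is an initialization artifact,
and every shipped analysis excludes $t = 1$.

## Synthetic cohorts

`simulate_agent()` / `simulate_cohort()` produce report traces that stand
in for subjects: the normative observer itself, the normative observer
plus clipped Gaussian *report* noise, a fixed-$\alpha$ delta rule, and two
*learning-noise* controls — a delta rule whose every update is corrupted
by Gaussian noise, either of constant SD or of SD proportional to the
absolute prediction error. The learning-noise agents are built on a
non-adaptive base learner on purpose: they reproduce the autocorrelated
report variability of real subjects while making, by construction, no true
learning-rate adjustment, so any change-point-aligned structure they show
would be a measurement artifact. Their default noise SD (0.05 normalized
units) is of the same order as typical report noise; it is a free
parameter, not an estimate. Reports are clipped (not reflected) at the
slider bounds, matching the physical device.

Cohorts assign each agent a without-replacement sample of sequences
(reference design: 96 agents; 10 magnitude or 15 probability sessions from
sets of 100 or 150 sequences), so sequences are shared across agents — the
overlap that makes the group-level decomposition possible.

What the generator does **not** emulate: motor dynamics of continuous
slider motion within the inter-observation interval, lapses and attention
fluctuations, individual differences in assumed hazard, and conservatism
biases. Passing tests on these cohorts therefore validate the analysis
machinery and the normative predictions, not any claim about human data.

## Analyses

**Change-point-aligned dynamics.** Learning rates are measured per
observation, aligned to change points and averaged within subject, then
across subjects. Offset $+k$ is the $k$-th observation after the change
(the first observation drawn from the new regime is $+1$); offset $-k$ is
the $k$-th before it; there is no offset 0. The default window is $-2$ to
$+8$ and the baseline is the mean over offsets $-2$ and $-1$. Change
points without two clean pre-change observations (session starts, excluded
entries) are dropped. Magnitude-task learning rates outside $[-0.6, 1.3]$
— ratio blow-ups near zero prediction error — are excluded, as is
standard for this task.

**Cluster-based permutation test.** Per-subject difference curves (offset
minus own baseline) are t-tested per offset (two-tailed); contiguous
offsets with $p < 0.05$ form clusters scored by summed $|t|$; family-wise
error over offsets is controlled by the permutation distribution of the
maximal cluster score under random sign flips of subjects' difference
curves (10,000 by default). For cohorts where $2^n$ does not exceed the
permutation budget the test enumerates all sign flips and is exact — the
suite checks this against an independent enumeration oracle up to
$n = 10$. Degenerate inputs are resolved conservatively: offsets whose
mean and SD are zero give $p = 1$, and means or SDs below $10^{-12}$
(floating-point residue of the $\alpha$ ratio for identically flat
cohorts) are treated as exact zeros.

**Two-determinant regression.** Per subject, $\alpha_t$ is regressed on
$\Omega_t$ and $u_t$, all three z-scored within subject across their
pooled observations of a task. Pooling across a subject's sessions (rather
than per session) maximizes the per-subject sample; $t = 1$ and excluded
observations are dropped, and an intercept is included (immaterial after
z-scoring, harmless in finite samples). Group-level inference uses
one-sample and paired t-tests. The normative prediction — the
$\Omega$ weight dominates for magnitudes, the $u$ weight for
probabilities — is reproduced by normative cohorts across seeds (tested
with 96 synthetic subjects per task).

**Interaction grids** bin each subject's observations into quantile bins
of $\Omega$ and $u$ and average $\alpha$ per cell. Defaults put more bins
along the factor with the wider variation range in that task (4 $\Omega$
by 2 $u$ for magnitude, 2 by 4 for probability); empty cells are reported
as missing, not errors.

**Bias/variance decomposition.** For each (sequence, observation) cell
with at least two subject estimates, the MSE against the normative
estimate splits exactly into squared bias of the cohort mean plus cohort
variance; the identity holds per cell to $10^{-12}$ by construction and is
asserted on arbitrary cohorts. Totals sum cells unweighted (weighting by
the per-cell subject count is available); the plug-in estimators are used
without small-sample correction, so for an unbiased cohort of $n$ subjects
per cell the expected bias share is $1/n$ — a property the tests verify
against this closed form. Standard errors of the proportions come from
resampling *sequences* with replacement (10,000 resamples by default) and
taking the SD across resamples. Cells with a single subject are skipped,
not imputed.

**Update frequency.** An update is any report change above $10^{-6}$
normalized units; the statistics are the fraction of updates following a
single observation and the mean observations-per-update.

## Reproducibility and problem sizes

Every stochastic step takes an integer seed; sequence sets, cohorts,
permutations and bootstraps are bitwise reproducible, and
`run_pipeline()` chains all stages deterministically from one master seed.
The shipped test suite exercises the full study conditions where they are
cheap (100/150-sequence sets, 96-subject regressions, exhaustive
enumeration oracles) and scaled-down cohorts elsewhere (8–10 agents,
25–30 sequences, 5 seeds for the dynamics checks) — sizes chosen so the
qualitative claims are sign-stable across seeds.

One quantitative note: on freshly generated magnitude sequence sets at the
default parameters, the pooled Spearman correlation between $\Omega_t$ and
$|x_t - v_{t-1}|$ measures ≈ 0.96 (the probability task gives ≈ 1.0).
The residual scatter is structural: $\Omega_t$ depends on the prediction
error through $x \mapsto x^2/2\sigma_t^2 + \ln \sigma_t$, and
$\sigma_t$ varies with the model's relative uncertainty, so the
correlation is high but not perfect, and is insensitive to the hidden-mean
support and to $\tau_0$ (we probed both).

## Worked example

```{r example, eval = FALSE}
set.seed(1)
seqs <- generate_sequence_set(probability_config(), 30, seed = 1)
cohort <- simulate_cohort(seqs, n_agents = 10, agent_config("normative"),
                          n_sessions = 10, seed = 2)
smap <- setNames(seqs, sapply(seqs, `[[`, "sequence_id"))
series <- lapply(cohort, function(tr)
  compute_learning_rates(tr, smap[[tr$sequence_id]]))
dyn <- align_to_changepoints(series)
plot(dyn)
cluster_permutation_test(dyn, n_permutations = 1000, seed = 3)
```

## Known limitations

* The probability filter ignores the generative refractory period and odds
  constraint (conventional, but a real model mismatch).
* The magnitude observer is the reduced two-moment model; the full
  run-length posterior is implemented only as a test oracle on short
  sequences.
* The learning-noise controls are descriptive-level: the noise magnitude
  and its placement (pre-clipping, on the update) are package choices, not
  estimates from data.
* Reference values that depend on human datasets (subject-level
  correlations, empirical weight magnitudes, empirical bias/variance
  splits) are outside what synthetic cohorts can reproduce; the package
  documents them as external reference points only.
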