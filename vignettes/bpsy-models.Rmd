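---
title: "Models and methods in bpsy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in bpsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bpsy collects the Bayesian models a psychology lab reaches for most often —
a robust t-test, reaction times, success rates, sequential (linear) tasks,
color responses and the Bayesian bootstrap — behind one uniform workflow:
fit each group independently, check convergence, then compare groups
through posterior probabilities, highest density intervals (HDI) and an
optional region of practical equivalence (ROPE). This vignette documents
the models, the priors and their defaults, the sampler, the numerical
conventions, and what the synthetic-data generators do and do not emulate.

## The models

**t-test (`b_ttest`).** Data are modeled with a scaled and shifted
Student-t with location `mu`, scale `sigma` and degrees of freedom `nu`.
The heavy tails at small `nu` make the location estimate robust to
outliers; at large `nu` the model collapses to a normal. Each group is
fitted on its own and compared afterwards, which makes pairwise and
multi-group cross-comparison uniform across any number of groups. `sigma`
is treated throughout as a scale (standard-deviation-like) parameter, and
`mu` is the fit's "mean" for comparison purposes whatever `nu` turns out
to be.

**Reaction times (`b_reaction_time`).** Each subject's times follow an
exGaussian (normal plus independent exponential) with subject parameters
`mu[i]`, `sigma[i]` and the exponential *rate* `lambda[i]`; the rate
parameterization is what makes the subject mean equal `mu + 1/lambda`.
Group-level normals `N(mu_mu, sigma_mu)`, `N(mu_sigma, sigma_sigma)` and
`N(mu_lambda, sigma_lambda)` tie the subjects together; the normals on
`sigma` and `lambda` are truncated to positive support, because an
untruncated normal would put mass on negative scales and rates. The
group-level mean reaction time is reported as `E = mu_mu + 1/mu_lambda`
over aligned draws (`rt_group_mean_draws()`), and that vector is the
comparison currency. The model also accommodates normally distributed
data, recovering a large rate so the exponential component vanishes.
Only correct-response trials are normally analysed; that filter is a data
step (`--filter-correct` in the CLI), not part of the likelihood.

**Success rates (`b_success_rate`).** Bernoulli outcomes per subject with
rate `p[i]`, tied by the mean/concentration Beta prior
`Beta(p * tau, (1 - p) * tau)`: `p` is the group rate (the comparison
currency) and `tau` the concentration. `p` gets a Beta(1, 1) prior by
default; subject rates are sampled on the logit scale for stability and
reported as probabilities.

**Sequential tasks (`b_linear`).** Per-subject intercept/slope/noise
(`alpha[i]`, `beta[i]`, `sigma[i]`) with independent group normals on
each (the noise normal truncated positive). The comparison currency is
selectable — intercept, slope, or residual scale — because different
questions (adaptation level at the start vs. decay over trials) live in
different parameters. `x` is never centered internally, so the intercept
keeps its meaning at `x = 0`; centering is a one-line data step if wanted.

**Colors (`b_color`).** Six independent component fits: truncated normals
on [0, 255] for R, G, B, truncated normals on [0, 1] for saturation and
value, and a von Mises distribution for hue. Whichever color space is not
supplied is derived row-wise by the standard hexcone conversion (base R's
`rgb2hsv`/`hsv`, wrapped to a degree interface with the s = 0 ⇒ hue = 0
convention). Hue is handled in radians internally, degrees at the
interface; hue differences are always wrapped into (-pi, pi], so a ROPE
on hue behaves sensibly across the 0/360 seam.

**Bayesian bootstrap (`b_bootstrap`).** Posterior draws of an arbitrary
statistic via uniform Dirichlet observation weights (drawn as normalized
unit exponentials). Two modes: *weighted* (the statistic receives the
weights — the default whenever it accepts them) and *resampling* (n rows
resampled with probability equal to the weights). The two modes agree on
location, but the n-row resampling mode adds multinomial noise on top of
the Dirichlet draw, inflating the spread of a mean statistic by roughly
sqrt(2); the weighted mode is the exact scheme and the default.

## Priors

Uniform, normal, gamma and beta priors can be attached to any group-level
parameter (`bprior()`, or `"mu:normal(0,1)"` strings in the CLI); the
default everywhere is flat/improper, contributing zero log density on the
parameter's declared support. Three pure-concentration parameters carry
bounded flat defaults as numerical guards, because their likelihood
plateaus would otherwise make the posterior improper for degenerate data:
`nu` lives on [0.1, 1e4] (for normal data the t likelihood is asymptoting
in `nu`, so an unbounded flat-on-log prior never integrates), `tau` on
(0, 1000], and the von Mises `kappa` on (0, 1e4]. The truncated-normal
color components additionally keep the mean within two component ranges
of the interval and the sd below ten ranges: under flat priors the limit
(mean → -inf, sd → inf) approaches the same uniform distribution on the
interval as many finite parameter pairs, an unidentified ridge.

## Sampling

All fits run componentwise adaptive random-walk Metropolis on the
unconstrained scale (log for positive parameters, logit for interval
parameters, angle wrapping for hue) with the matching Jacobian terms,
implemented in compiled code. Proposal scales adapt toward a 0.44
acceptance rate during warmup with a diminishing Robbins-Monro step and
are frozen for sampling. Defaults: 4 chains, 1,000 warmup and 1,000
sampling iterations per chain (4,000 posterior draws); diagnostics only
ever see post-warmup draws. Identical settings and seed reproduce draws
bit-for-bit; chain c is seeded with `seed + 7919 (c - 1)`.

The hierarchical samplers exploit structure: subject-parameter updates
touch only that subject's likelihood (with O(1) sufficient statistics for
the linear, Bernoulli and truncated-normal cases), and each iteration adds
*translation moves* that shift a group location and all its subject
parameters jointly. The hierarchical prior terms cancel in such a move,
which decouples the location's mixing from the group scale — without it a
near-collapsed scale (e.g. with a single subject) pins the subject
parameters and stalls the chain.

Initial values are data-derived (moment estimates per subject, OLS for
the linear model, resultant-length estimates for the hue concentration)
with per-chain jitter, retried up to 100 times if the posterior is not
finite at the start. `sample_posterior()` exposes the same algorithm for
user-declared models (`model_spec()`), which is also how the package's
conjugate-oracle tests check distributional correctness against
closed-form Beta-Bernoulli and normal-mean posteriors.

## Diagnostics and summaries

The HDI is the shortest contiguous window of `ceiling(mass * n)` sorted
draws, ties broken toward the smallest lower bound — a convention chosen
because it is exactly reproducible by an exhaustive window scan, which
the test suite runs. Note that nesting of HDIs across masses is
guaranteed only for unimodal draw sets; genuinely multimodal draws can
move the shortest window discontinuously.

Split R-hat halves every chain and computes the classic potential scale
reduction factor over the half-chains; it is ~1 at convergence and
invariant under affine maps of the draws. The effective sample size
averages per-chain autocorrelations and truncates the sum by Geyer's
initial positive sequence rule; the estimate is deliberately capped at
the total draw count (no super-efficiency is reported, as antithetic
chains would otherwise produce), and is a crude measure by design.
`summarize_fit()` reports, per parameter, the posterior mean, Monte Carlo
standard error `se_mean = sd / sqrt(n_eff)`, sd, central 2.5%/97.5%
quantiles, `n_eff` and R-hat.

## Comparison semantics

Comparisons are *draw-aligned*: the difference `d_i = a_i - b_i` is formed
per draw index, never across the full cross product. With five aligned
draws per group of which four favour the first, the probability is
exactly 4/5 — the cross product would give 17/25 instead, which is not
the quantity the workflow prints. Without a ROPE, exact ties split evenly
between the two sides (ties have measure zero for continuous draws; the
rule only makes degenerate comparisons deterministic). With a ROPE
`[l, u]`, draws with `l <= d_i <= u` count as practically equal and the
strict probabilities come from the remaining draws, so the three
probabilities sum to one. Multi-group comparisons add, per group, the
fraction of draw indexes where it attains the maximum (minimum), ties
split evenly among the tied groups. The reported ± on a probability is
the sd of per-segment probabilities over ten contiguous segments of the
draw sequence divided by sqrt(10) — a pragmatic Monte Carlo error bar,
not a posterior quantity. `compare_distributions()` applies the same
machinery to posterior predictive draws simulated at each draw's
group-level parameters.

## Synthetic data

The four generators emulate the *structure* of classic experiments so
that every workflow runs end-to-end with recorded ground truth:

* `generate_flanker()` — two groups, per-subject exGaussian times drawn
  from group-level (truncated) normals plus Bernoulli correctness;
  defaults: 22 subjects x 80 trials per group, control `mu_mu = 0.35 s`,
  `mu_lambda = 8` (mean ≈ 0.475 s), a 0.05 s test-group shift and a 0.05
  drop in correct rate — magnitudes chosen as a plausible clinical
  contrast in a flanker task.
* `generate_adaptation()` — two groups of 20 subjects x 10 measurements
  with group intercepts 8.0 / 5.8 and slopes -0.11 / +0.12 on a 9-point
  scale, i.e. a pronounced initial contrast that decays over trials.
* `generate_stroop()` — a paired layout, 30 subjects x 4 conditions with
  means 43/46/55/69 s, subject random effect sd 8 s, residual sd 2 s.
* `generate_afterimages()` — responses around six stimulus hues with von
  Mises concentration 30 (hue sd ≈ 10 degrees), saturation/value near
  0.85; `hue_offset = pi` emulates opponent-style complementary
  responses.

These tables share only the *schema and effect structure* with real lab
data: no real dataset is shipped or reproduced, real reaction-time data
have condition effects and autocorrelation the generators omit, real
success rates overdisperse, and real color responses mix response styles.
Passing recovery tests therefore demonstrates that the samplers recover
known generating parameters under the stated conditions — not that any
substantive conclusion about real data is reproduced.

## Problem sizes used by the checks

The test suite fits most models with 2 chains x 400 warmup / 400 sampling
iterations — enough for the group-level locations that the assertions
touch — and runs 20-replicate recovery loops at the generator defaults;
the acceptance script uses 2 chains x 1,000/1,000. These sizes are the
package's own trade-off between Monte Carlo error and turnaround; for
real analyses the 4-chain defaults (or more iterations, e.g. `iter =
4000` for an effective sample size near 10,000 on well-mixing parameters)
are the right starting point.

## Known limitations

Random-walk Metropolis mixes slowly on strongly correlated hierarchical
scale parameters (`tau`, the group sds); their `n_eff` is routinely an
order of magnitude below the location parameters'. The comparison ± is a
segment estimate, not an autocorrelation-consistent MCSE. Rank-normalized
R-hat variants and sampler-internal diagnostics (divergences, tree depth)
are out of scope, as are correlated group priors for the linear model,
covariate-dependent success rates, alternative reaction-time likelihoods
and perceptually uniform color spaces.
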