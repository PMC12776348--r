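---
title: "Mutual hazard networks: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual hazard networks: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhnet)
```

## The model

A mutual hazard network describes tumor progression as a continuous-time
Markov chain on the $2^n$ subsets of $n$ binary, irreversible events.
Every tumor starts healthy (no events), acquires events one at a time,
and is eventually *observed* — genotyped and removed from the process —
by a competing terminal event. All rates are genotype-dependent and
parameterized by an $(n+1) \times n$ log-scale matrix $\theta$:

* $\lambda_i(x) = \exp(\theta_{ii} + \sum_{j \ne i, x_j = 1} \theta_{ij})$
  — event $i$'s rate out of genotype $x$: a spontaneous base rate
  $e^{\theta_{ii}}$, multiplied by $e^{\theta_{ij}}$ for every event $j$
  already present (the mutual-hazard assumption: effects are
  multiplicative on rates, i.e. additive on log scale);
* $\omega(x) = \exp(\sum_{j: x_j = 1} \theta_{\mathrm{obs},j})$ — the
  observation rate, bottom row of the matrix.

Modelling observation as a genotype-dependent competing event matters for
cross-sectional data: events that accelerate diagnosis are
over-represented among observed tumors, and a model with a constant
observation rate misattributes the resulting correlations to interactions
between the events themselves (a collider bias). The `classic` model kind
retains that older constant-rate variant for backward comparison; it is
exactly the `observation_aware` model with the bottom row fixed at zero,
and the package treats it that way (`kind = "classic"`, or
`freeze_observation = TRUE` in `fit_mhn()` — the two produce matching
fits, which the test suite asserts to $10^{-10}$).

**Time scale.** Only rate *ratios* are identified by cross-sectional
data: multiplying every rate by a constant rescales time without changing
which genotype is observed. The package fixes the observation event's
base rate to 1, so one model time unit is the expected healthy-state
waiting time to observation. The observation base rate is therefore not a
parameter; the bottom row holds only the effects of events on it.

## Exact likelihood by state space restriction

Writing $R(y) = \omega(y) + \sum_{i: y_i = 0} \lambda_i(y)$ for the total
exit rate, the probability that the chain is *at* genotype $y$ at the
moment of absorption satisfies the flow recurrence

$$q(0) = 1/R(0), \qquad
  q(y) = \frac{\sum_{i: y_i = 1} \lambda_i(y - e_i)\, q(y - e_i)}{R(y)},$$

and the probability of observing genotype $x$ is $p(x) = \omega(x) q(x)$.
Irreversibility makes the linear system triangular when states are
ordered by their integer bit encoding (acquiring an event strictly
increases the code), so $q$ is computed by forward substitution — exact,
$O(k\,2^k)$, with no iterative solver and no convergence tolerance.

For one sample with $k$ active events, mass that leaves the sub-lattice
of genotypes below $x$ can never return, so the recurrence restricted to
those $2^k$ states yields *exactly* the same $p(x)$ as the full $2^n$
computation. Two details are load-bearing and are pinned by tests:

* exit rates on the sub-lattice still sum the rates of **all** $n$
  events — omitting events outside the active set is the classic
  implementation mistake, and it is caught by comparing against the
  full-lattice computation and against an independent dense
  `solve()`-based oracle;
* the gradient needs one additional adjoint back-substitution (the
  transposed triangular system with mass $\omega(x)$ at the conditioning
  state), after which every $\theta$-entry's contribution — transition
  rates inside the lattice, exit rates including out-of-lattice events,
  and the absorption factor $\omega(x)$ — is accumulated in closed form.
  Analytic gradients match central finite differences (step $10^{-5}$) to
  better than $10^{-6}$ relative error in the tests.

Probabilities are computed in linear space; if a probability underflows
below $10^{-300}$ the engine raises an error rather than silently losing
precision. This is a documented limitation: it requires a pathologically
extreme $\theta$ (e.g. a log base rate near $-700$) at the $k \le 32$
scales the engine accepts.

## Training

`fit_mhn()` maximizes the per-sample objective

$$\frac{1}{N} \sum_d \log p_\theta(x_d) - s \cdot \mathrm{penalty}(\theta)$$

with L-BFGS-B and the exact gradient, starting from the independence
initialization ($\theta_{ii} = \mathrm{logit}\, f_i$ with frequencies
clipped to $[1/2N, 1 - 1/2N]$; this is the exact single-event MLE of the
classic model with no interactions). Identical genotypes are aggregated
first, so cost scales with the number of *unique* genotypes. The $1/N$
scaling makes penalty strengths comparable across cohort sizes.

Penalties act on all interaction entries — off-diagonals of the first $n$
rows and, by default, the observation row (`penalize_observation = FALSE`
exempts it; whether to shrink observation effects is a genuinely open
modelling choice, so it is a switch). Base rates are never penalized:
they set the time scale, and shrinking them would bias all dynamics.
Because L-BFGS assumes smooth objectives, the absolute value in the L1
and symmetric penalties is smoothed as $\sqrt{\theta^2 + \epsilon^2} -
\epsilon$ with $\epsilon = 10^{-4}$ by default — small enough that
"zeroed" entries land below $10^{-3}$ in practice, large enough for
stable curvature. The symmetric penalty couples each pair as
$\sqrt{\theta_{ij}^2 + \theta_{ji}^2 + \epsilon^2} - \epsilon$, a group
penalty under which the two directions of an interaction vanish or
survive together unless the data clearly favours asymmetry; published
variants of this penalty differ in detail, and this pairwise group form
is this package's choice.

`cv_mhn()` selects the strength on a default grid of 9 log-spaced values
in $[10^{-4}, 1]$ with 5 folds (seeded permutation, contiguous blocks),
scoring by held-out mean per-sample log-likelihood; exact ties go to the
smaller strength, and the final model is refit on all data. Convergence
defaults: projected-gradient tolerance $10^{-6}$, at most 500 iterations.

## The simulator

`sample_mhn()` draws tumors by the standard competing-exponentials walk:
at genotype $x$, wait $\mathrm{Exp}(R(x))$, then pick the observation
with probability $\omega(x)/R(x)$ or an inactive event $i$ with
probability $\lambda_i(x)/R(x)$ (one uniform against cumulative rate
fractions, fixed event order, observation last — so runs are
bit-reproducible). Each draw uses its own RNG substream (`seed` + draw
index), so any prefix of a cohort is reproducible regardless of the total
size requested.

The simulator is deliberately an independent derivation of the same law
the likelihood engine computes: the strongest cross-check in the test
suite compares empirical genotype frequencies of 100 000 simulated tumors
($n = 4$) against the analytic distribution (every frequency within
$4\sigma$; $\chi^2$ goodness-of-fit below its 0.999 quantile).

What the generator emulates — and does not. It produces exactly the
model's law: irreversible accumulation, multiplicative rate interactions,
genotype-dependent observation. Real cohorts additionally contain
genotyping error, copy-number events that are not well described as
irreversible binaries, inter-patient rate heterogeneity, and panel
differences. Passing tests on simulated data therefore validate the
*computations*, not the biological adequacy of the model for any given
cohort.

## Reconstruction of event orders

For an ordering $\sigma$ of a genotype's $k$ events,
`order_probability()` multiplies the stepwise competing-risk factors
$\lambda_{\sigma_s}(x_{s-1})/R(x_{s-1})$ and the final absorption factor
$\omega(x)/R(x)$. Summed over all $k!$ orderings this reproduces
$p(x)$ exactly (the path decomposition; asserted to $10^{-10}$), which
ties the reconstruction module to the likelihood engine.

`most_likely_order()` maximizes this path probability by dynamic
programming over the $2^k$ subsets (suffix values
$h(S) = \max_{i \notin S} \lambda_i(S)/R(S)\, h(S \cup i)$), then reads
the ordering forwards from the healthy state. Conditioning on the
observed genotype divides every path by the same constant $p(x)$, so the
maximizer is unchanged. Exact value ties are broken towards the smallest
event index at the earliest step, making trees reproducible; the DP is
verified against brute-force enumeration for $k \le 6$. The $k \le 25$
limit keeps the $2^k$ table in memory.

`trajectory_tree()` applies the reconstruction to every genotype shared
by at least `min_count` patients (default 3 — rare genotypes clutter the
display and their reconstructions are statistically fragile; the filter
applies to genotype groups, not to tree nodes) and merges the orderings
by common prefix. Node and edge sizes in the DOT export scale *linearly*
with patient counts between fixed minimum and maximum sizes; any
monotone scaling would do, and linear is the least surprising choice.

## Study sizes and numerical checks

The test suite and `scripts/acceptance.R` use problem sizes chosen so
that each property is tested at full strength while the whole suite runs
comfortably on one CPU: restriction exactness at $n = 8$ over 50 random
matrices (all $2^8$ genotypes each, $10^{-12}$ relative); normalization
for $n \le 10$; gradient checks at $n = 5$; simulator agreement at
$n = 4$, $N = 100\,000$; path decomposition and DP optimality for
$k \le 6$ over 50–100 random instances; recovery and compatibility
experiments at $N = 20\,000$ and $N = 1\,500$.

The recovery experiment plants a 5-event network with three interactions
of $|\theta| = 1$, one observation effect, and moderate base rates (event
frequencies 0.18–0.36), samples $N = 20\,000$ tumors, and refits with a
*small* L1 penalty. "Small" is calibrated a priori: the penalty's total
weight in the objective, $s \cdot N \cdot \sum |\theta^*| \approx 10^5
s$ log-likelihood units, should sit well below the $\approx \dim/2 = 15$
unit fluctuation scale of the maximum, giving $s = 10^{-5}$. The fitted
distribution then matches the truth to total-variation distance
$\approx 0.012$ — about the sampling error of the cohort itself — and
the planted signs are recovered. A noteworthy limitation surfaced by this
experiment: the *direction* of an interaction (whether
$\theta_{ij}$ or $\theta_{ji}$ carries an effect) has a nearly flat
profile likelihood at these scales, so substantial penalties push the
weaker direction to zero, and for occasional dataset draws even the
unpenalized MLE places a planted effect's mass in the opposite
direction. Direction estimates at cohort sizes of this order should be
read with corresponding caution.

## Degenerate inputs and edge cases

Healthy genotypes are fully supported everywhere (probability $1/R(0)$,
empty ordering, terminal tree root). Events absent from every sample (or
present in all) get finite initial base rates through frequency clipping.
Datasets are validated on entry: strictly binary cells (row/column
reported otherwise), unique labels, a hard error above 32 active events
per sample and a warning above 25. Duplicated genotypes are aggregated;
all summations run in a fixed sorted order, so results are independent of
row order and evaluation order. Model JSON is written with 17 significant
digits, so write/read round trips reproduce parameters bit-exactly, and
seeded CLI runs are byte-identical.
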