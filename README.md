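# mhnet — mutual hazard networks for cancer progression

Many cancers develop silently and are only genotyped once, at diagnosis.
Cross-sectional cohorts therefore show *which* alterations co-occur, but
not *in which order* they accumulated or how they influence one another.
`mhnet` addresses this with mutual hazard networks (MHNs): a tumor is
modelled as a continuous-time Markov chain on the $2^n$ genotypes built
from $n$ binary, irreversible progression events (e.g. driver-gene
mutations), terminated by a competing *observation* event whose rate
depends on the current genotype — which corrects the collider bias that
genotype-dependent detection induces in cross-sectional data.

The model is parameterized by an $(n+1) \times n$ matrix $\theta$ on log
scale. Event $i$ fires out of genotype $x$ at rate

$$\lambda_i(x) = \exp\Big(\theta_{ii} + \sum_{j \neq i,\; x_j = 1} \theta_{ij}\Big),$$

so $e^{\theta_{ii}}$ is event $i$'s spontaneous base rate and
$e^{\theta_{ij}}$ is the multiplier that an already present event $j$
applies to it. The observation event fires at rate
$\omega(x) = \exp(\sum_{j: x_j=1} \theta_{\mathrm{obs},j})$ (bottom row;
its own base rate is fixed to 1, since the process is only identified up
to a global time scale). The probability of observing a tumor with
genotype $x$ is $p(x) = \omega(x)\, q(x)$, where $q$ solves the flow
recurrence

$$q(0) = 1/R(0), \qquad
  q(y) = \frac{\sum_{i:\,y_i=1} \lambda_i(y - e_i)\, q(y - e_i)}{R(y)},
  \qquad R(y) = \omega(y) + \sum_{i:\,y_i=0} \lambda_i(y).$$

Because events are irreversible this system is triangular, and for a
sample with $k$ active events it can be solved *exactly* on the $2^k$
sub-lattice of genotypes below the observation — state space restriction.
This is what makes maximum-likelihood training tractable for large event
panels: cost scales with $2^k$ per sample (hard limit $k \le 32$, practical
up to ~25), not with $2^n$.

The package provides, in R:

* exact marginal likelihoods and analytic gradients (`genotype_probability`,
  `log_likelihood`, `loglik_gradient`, `marginal_distribution`),
* penalized maximum-likelihood training with smoothed-L1, L2, symmetric
  pairwise, or custom penalties, and cross-validated penalty-strength
  selection (`fit_mhn`, `cv_mhn`, `penalty_spec`),
* Gillespie sampling of artificial tumor histories and cohorts
  (`sample_history`, `sample_mhn`),
* most-likely chronological event orders per genotype and cohort-level
  trajectory trees (`most_likely_order`, `reconstruct_orders`,
  `trajectory_tree`),
* CSV/JSON/DOT/PNG input and output plus a command-line tool
  (`read_dataset`, `write_mhn`, `write_tree_dot`, `render_heatmap`,
  `mhn_cli` and the installed `exec/mhn` script).

## Worked example

Simulate a three-gene cohort from a known network in which TP53 promotes
KRAS 4.5-fold and EGFR raises the detection rate 2.7-fold, then refit it:

```r
library(mhnet)

th <- matrix(0, 4, 3)
diag(th[1:3, ]) <- c(0, -0.3, -1.2)  # log base rates
th[2, 1] <- 1.5                      # TP53 multiplies KRAS's rate by e^1.5 = 4.48
th[4, 3] <- 1                        # EGFR multiplies the observation rate by e^1 = 2.72
m <- mhn_model(th, events = c("TP53", "KRAS", "EGFR"))

cohort <- sample_mhn(m, 5000, seed = 1)   # binary 5000 x 3 matrix
fit <- fit_mhn(cohort, penalty_spec("l1", 0.001))
round(exp(fit$model$log_theta), 2)
#>             TP53 KRAS EGFR
#> TP53        0.97 1.00 1.00
#> KRAS        3.84 0.80 1.00
#> EGFR        0.85 0.94 0.34
#> observation 1.00 1.00 2.10

most_likely_order(fit$model, c(1, 1, 1))
#> most likely order: TP53 -> KRAS -> EGFR (probability 0.04673)
```

The fitted matrix is read row-by-column: the `KRAS`/`TP53` cell (3.84)
estimates the planted 4.48-fold promotion of KRAS by TP53; the bottom-row
`EGFR` cell (2.10) estimates the planted 2.72-fold observation-rate
increase; base rates sit in the diagonal. The reconstruction says that a
tumor observed with all three events most probably acquired TP53 first
and EGFR last; its probability (0.047) is the joint probability of that
path followed by observation. `render_heatmap(fit$model)` draws the
matrix with base rates as a separate column and observation effects as a
bottom row, and `trajectory_tree(fit$model, cohort)` aggregates the
reconstructions of all genotypes shared by at least three patients into a
patient-weighted tree.

The same pipeline from a shell, via the installed script:

```sh
mhn sample --model true.json --n 5000 --seed 1 --out cohort.csv
mhn train  --data cohort.csv --out fit.json --penalty l1 --strength 0.001
mhn tree   --model fit.json --data cohort.csv --min-count 3 --dot tree.dot
mhn plot   --model fit.json --out heatmap.png
```

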