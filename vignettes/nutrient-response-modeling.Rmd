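---
title: "Nutrient-response modeling with a single tanh neuron: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient-response modeling with a single tanh neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrfit)
```

## The model and its assumptions

`nrfit` describes a nutrient-response (N-R) relationship with

$$\mathrm{Response} = A\,\tanh(c\,\mathrm{Nutrient} + b) + B,$$

the input-output map of a network with one hidden tanh neuron. It is a
four-parameter sigmoid: monotone, saturating, with a single inflection
point at $(-b/c,\,B)$ and a plateau at $A + B$. The assumptions are
exactly those of the curve family:

* the response **increases monotonically** with nutrient supply and
  **saturates** — appropriate for essential nutrients below toxic
  ranges, and wrong for nutrients with toxicity thresholds or otherwise
  non-monotone responses (out of scope here);
* measurement noise is roughly **proportional to the signal**
  (heteroscedastic), which is how biological variability behaves in
  feeding trials — a 500 g weight gain fluctuating by ±25 g is the same
  relative noise as a 10 g gain fluctuating by ±0.5 g.

Because $\tanh$ is odd, $(A, c, b)$ and $(-A, -c, -b)$ draw the same
curve. All metric formulas assume the increasing orientation, so fitted
parameters are always reduced to the **canonical form** $A > 0$,
$c > 0$ (`canonicalize()`). A fit with $A \cdot c < 0$ describes a
decreasing curve; it cannot be canonicalized and is treated as a fit
failure (in the bootstrap: a skipped iteration).

The derivative $A c\,(1 - \tanh^2(c x + b))$ is the **marginal
utilization efficiency**: additional response per unit of additional
nutrient. Every reported metric is a closed form in the parameters (see
`?derive_metrics`); none requires numeric root finding.

### Undefined metrics

The half-life and requirement formulas invert the curve through
$\mathrm{arctanh}$; their arguments leave the domain $(-1, 1)$ for some
parameter combinations. The half-life argument $0.5 - 0.5 B/A$ drops to
$-1$ when $B/A \ge 3$, i.e. when the *observed minimum* of the curve
already exceeds half of the plateau — the "half-life" then simply does
not exist on the curve. Published parameter sets with exactly this
geometry occur in real poultry data, so this is not a corner case:
`derive_metrics()` reports such metrics as `NA` with a machine-readable
reason, and bootstrap summaries average over the defined iterations
while reporting the undefined count. No exception is thrown, by design.

## Training: Bayesian-regularized Levenberg-Marquardt

Both coordinates are min-max normalized to $[-1, 1]$; the network
weights $w = (w_1, b_1, w_2, b_2)$ live in that space and are converted
back to original-unit parameters by an exact affine composition
(`denormalize_params()`, tested against a round-trip oracle at 1e-10).

The training objective is the evidence-framework compromise

$$F = \beta E_D + \alpha E_W, \qquad
E_D = \tfrac12 \sum e_i^2, \qquad
E_W = \tfrac12 \sum w_j^2,$$

with **all four** normalized weights (biases included) penalized — the
simplest consistent convention. After every accepted LM step the
hyperparameters are re-estimated from the data:

$$H = \beta J^\top J + \alpha I, \qquad
\gamma = k - \alpha\,\mathrm{tr}(H^{-1}), \qquad
\alpha = \frac{\gamma}{2 E_W}, \qquad
\beta = \frac{N - \gamma}{2 E_D},$$

where $k = 4$ and $\gamma \in [0, k]$ is the effective number of
parameters. This is the classical MacKay re-estimation with the
Gauss-Newton Hessian, written in the half-sum convention; the same
framework is often quoted with full sums ($E_W = \sum w_j^2$, Hessian
$\beta J^\top J + 2\alpha I$), which differs only by factor-2
bookkeeping that the adaptive $\alpha, \beta$ absorb. We pinned the
half-sum form because it is internally consistent and matches the
original formulation.

Implementation notes (all in `src/br_train.cpp`):

* damping: $\mu$ starts at 0.005, multiplied by 10 on rejection,
  by 0.1 on acceptance; $\mu > 10^{10}$ ends the restart. This is a
  documented choice — the reference trainer's exact schedule is not
  published — so parameter estimates may differ from other
  implementations in the third significant digit.
* acceptance: a step is taken only if it decreases $F$ **under the
  current** $(\alpha, \beta)$; the per-step trace is returned and the
  monotonicity is asserted in the test suite.
* guards: $\gamma$ clamped to $[0, 4]$; $\alpha \in [10^{-8}, 10^8]$,
  $\beta \in [10^{-8}, 10^{12}]$ to survive $E_D \to 0$ on noiseless
  data.
* convergence: gradient norm $\le$ 1e-7, or relative objective change
  $\le$ 1e-7 over 5 consecutive accepted steps, or 300 iterations,
  or damping overflow — whichever comes first.
* initialization: each of 5 restarts draws all four weights from
  $\mathrm{Uniform}(-1, 1)$ from a seeded sub-stream. With bounded
  activations and one neuron this is well-behaved; Nguyen-Widrow-style
  schemes buy nothing here. The restart with the lowest final $E_D$
  wins, ties to the lowest index.

The trainer is compiled (Rcpp/RcppArmadillo) because the acceptance
experiments refit the model ~25 000 times on one CPU; a pure-R inner
loop would exceed the budget by an order of magnitude.

## Data augmentation

Each original point $(x, y)$ spawns `replicates = 10` synthetic points
$(x + \varepsilon_x,\, y + \varepsilon_y)$ with
$\varepsilon_x \sim N(0,\, 0.02\,x)$ and
$\varepsilon_y \sim N(0,\, 0.05\,y)$ (the second argument is a
**standard deviation**: 2 % noise on a 10 g/kg diet must mean a
0.2 g/kg sd). Originals are kept in the pool. Coordinates equal to zero
get zero noise — proportionality is literal. A perturbed nutrient that
lands negative is redrawn (at most 100 attempts; policies `clamp` and
`allow` are available); with the default 2 % fraction a negative draw
is a 50-sigma event, so resampling does not measurably distort the
noise law. The defaults are recommended settings for typical nutrition
data, not tuned constants, and are exposed as arguments and CLI flags.

## Bootstrap and the selected model

100 iterations; each draws, with replacement, a sample **of the
original dataset's size** from the augmented pool, refits, and derives
metrics using the original minimum nutrient (the lag anchor must not
jitter with augmentation). The protocol text and the figure captions of
the source literature pull in different directions on the sample size
(original-n vs the whole augmented pool); we follow the protocol text
and expose `sample_size = "augmented_n"` or an explicit count as
alternatives, logged in the manifest.

Per-quantity summaries are the mean over defined iterations and the
2.5th/97.5th percentiles by **linear interpolation between order
statistics** (R quantile type 7) — a fixed rule so bounds reproduce
bit-for-bit. Bounds are asymmetric whenever the distribution is.

The **selected model** — the equation that gets reported — is the
iteration with the lowest RMSE *relative to the ensemble's mean
prediction*, evaluated at the original nutrient values (the mean curve
is only constrained by data locations; the grid is configurable). Two
RMSEs coexist and are both exposed: the selection RMSE (vs the mean
prediction) and the reporting RMSE (vs the observed responses). Failed
iterations are recorded and skipped, never retried — retries would bias
the distribution; more than 50 % failures abort the ensemble.

## Group comparison

One-way ANOVA is applied to the full bootstrap distributions (n = 100
values per group per quantity), followed by Tukey HSD (Tukey-Kramer
standard errors for unequal counts, which arise from failed
iterations), and compact letters by insert-and-absorb. Treating
bootstrap replicates as observations is **not** a classical Tukey test
in the experimental sense; outputs are labelled as
bootstrap-distribution comparisons, and group skewness is reported as a
diagnostic (nothing is gated on it). $\alpha$ defaults to 0.05.

## The synthetic-data generator

`simulate_nr()` emulates the structure of real N-R trials: graded
levels (default 8 on $[2, 20]$), a few replicates per level (default
3), responses $\mu(x)\,(1 + \varepsilon)$ with proportional noise
(default 5 %). Default sizes and noise mirror the small-data regime the
framework targets (5-10 unique levels, single-digit replication,
within-trial CVs of a few percent). What it does **not** emulate:
between-study heterogeneity, non-monotone (toxicity) responses, design
imbalance, or measurement error in the nutrient axis of the *original*
data. A green coverage test therefore establishes calibration under the
stated world — proportional noise around a true tanh curve — not under
model misspecification.

True parameters ride along in the dataset metadata and are read only by
test code; fitting never sees them.

## Numerical choices and degenerate inputs

* Strictness at the tanh tails: beyond $|z| \approx 19$, $\tanh$
  saturates to exactly 1.0 in double precision, the slope underflows to
  an exact 0 and "strictly increasing" holds only up to float
  resolution; tests and documentation phrase tail properties
  accordingly.
* Constant nutrient or constant response data cannot be normalized and
  raise a degenerate-data error; fewer than 5 points refuse to fit.
* Requirement levels outside $(0, 1)$ are rejected; the level set is an
  argument (default $\{0.95, 0.99\}$), not hard-coded.
* Seeding: one master seed derives fixed, documented sub-streams
  (augmentation / bootstrap draws / restart initializations / plot
  resampling) via an affine hash below $2^{31}$, so stages can be rerun
  independently and full runs reproduce byte-identically.
* Boxplot notch: McGill's $\pm 1.57\,\mathrm{IQR}/\sqrt{n}$, the
  standard reading of an "approximate 95 % CI of the median".

## Known limitations

* Only monotone increasing, saturating responses; no toxicity branch,
  no alternative activations, one nutrient at a time.
* The bundled reference parameter table carries only the precision of
  its printed source; closed-form metrics recomputed from it can
  disagree with printed bootstrap-mean metrics by a few percent, and
  one row's steepness is printed with a single significant digit. The
  test suite documents this honestly rather than loosening the check.
* Tukey-on-bootstrap p-values inherit the caveat above; they support
  ranking and screening, not experimental-unit inference.
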