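---
title: "Constrained Kalman-filter estimation for sample surveys"
author: "kfsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained Kalman-filter estimation for sample surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kfsurvey)
```

## The estimation problem

A monitoring program — a national forest inventory is the motivating case —
measures study variables (tree counts by mortality class, basal area, forest
area by type) on a probability sample of field plots, and needs population
means for each variable at each year of a short annual time series.
Alongside the sample, remotely sensed and geospatial layers (damage-survey
polygons, satellite forest-cover classifications, ecoregions,
administrative boundaries) are available for *every* unit of the
population, so their population means are known *exactly* by GIS
enumeration — they are census constants, not estimates.

`kfsurvey` treats the full collection of population means as a state
vector

$$\mathbf{x} = \begin{bmatrix}\mathbf{x}_s \\ \mathbf{x}_a\end{bmatrix},$$

with the study block $\mathbf{x}_s$ ($k_s$ = number of study variables
$\times$ number of years, organised year by year) followed by the
auxiliary block $\mathbf{x}_a$ ($k_a$ entries, treated as time-invariant
layers the way a photograph is a fixed record of a changing subject).  A
simple random sample of $n$ units, each carrying the complete measurement
vector, gives the design-based initial estimate: the vector mean
$\hat{\mathbf{x}}_{SRS}$ with covariance
$\hat{\mathbf{V}}_{SRS} = S/n$, where $S$ is the sample covariance matrix
with divisor $n-1$ (`srs_estimate()`; no finite-population correction is
applied).  The estimator then *constrains* the auxiliary partition to its
census values $\mathbf{y}$: with $\mathbf{H} = [\,\mathbf{0} \mid
\mathbf{I}_a\,]$ the selector of the auxiliary block and gain
$\mathbf{W} = \mathbf{V} \mathbf{H}' (\mathbf{H} \mathbf{V}
\mathbf{H}')^{-1}$,

$$\hat{\mathbf{x}}_{KF} = (\mathbf{I} - \mathbf{W}\mathbf{H})\,
\hat{\mathbf{x}}_{SRS} + \mathbf{W}\mathbf{y}, \qquad
\hat{\mathbf{V}}_{KF} = (\mathbf{I} - \mathbf{W}\mathbf{H})\,
\hat{\mathbf{V}}_{SRS}\,(\mathbf{I} - \mathbf{W}\mathbf{H})'.$$

Because the observation vector is a known constant (its own covariance is
zero), this is the Kalman measurement update in its noiseless limit; with
a single study variable it reduces to the g-weighted regression estimator.
Every study variable correlated with any auxiliary loses variance; one
with zero covariance to the whole auxiliary block is untouched.

## The sequential scalar update

The batch gain requires inverting the $k_a \times k_a$ auxiliary block,
which is numerically fragile and outright singular whenever auxiliaries
are collinear (indicator sets that sum to one, duplicated layers) or
$k_a \ge n$.  `kf_sequential()` instead applies one constraint at a time.
For the constraint on coordinate $k$ (the position of auxiliary $i$):

1. if $V_{kk} < \mathrm{tol}$, skip — the constraint is already
   essentially satisfied, and the scalar inverse would explode
   (`skipped_low_variance` in the audit trail);
2. optionally inflate row and column $k$ against divergence (below);
3. form the weight vector $\mathbf{w} = \mathbf{V}_{\cdot k} / V_{kk}$
   (its $k$-th entry is always 1), set
   $\mathbf{x} \leftarrow \mathbf{x} + \mathbf{w}\,(y_i - x_k)$ and
   $\mathbf{V} \leftarrow \mathbf{V} - \mathbf{V}_{\cdot k}
   \mathbf{V}_{\cdot k}' / V_{kk}$, which is algebraically the
   complementary-weight sandwich $(\mathbf{I} - \mathbf{w}
   \mathbf{e}_k')\,\mathbf{V}\,(\mathbf{I} - \mathbf{w}\mathbf{e}_k')'$.

After the step, $x_k = y_i$ exactly and row/column $k$ of $\mathbf{V}$ are
exactly zero — the constrained coordinate is orthogonalised against the
rest of the state, which is what makes the next scalar step sufficient.
The implementation assigns the zeros (and $x_k = y_i$) explicitly after
the rank-one arithmetic so floating-point dust cannot accumulate on
constrained coordinates, and performs the update with vector operations
only ($O(k^2)$ per step); the dense complementary-weight matrix exists
only inside `kf_batch()`, which serves as the independent closed-form
cross-check in the test suite.  A redundant (e.g., duplicated) auxiliary
is harmless: the first constraint drives its variance to zero and the
tolerance rule skips the second copy.  With divergence handling off, the
sequence is order-invariant and every diagonal entry of $\mathbf{V}$ is
non-increasing at every step.

The update is applied across the full state vector at every step rather
than only over coordinates below $k$.  In the default descending order the
two are identical — rows above $k$ have already been zeroed — and the
full-range form remains correct under ascending order as well.

### Divergence handling

A residual $y_i - \hat{x}_k$ far larger than its estimated uncertainty
signals non-sampling error (a processing mistake, misregistration, an
anomalous layer).  Trusting the covariance at face value would hand the
constraint too much weight.  Two inflation rules are provided
(`kf_options(divergence = ...)`):

* `"as_printed"` (default): compute $c = 2\,|y_i - \hat{x}_k| / V_{kk}$
  and, when $c > 1$, scale row and column $k$ by $c$ (the diagonal by
  $c^2$).
* `"two_sigma"`: trigger when the residual exceeds two standard
  deviations, $|y_i - \hat{x}_k| > 2\sqrt{V_{kk}}$, and inflate so the
  post-inflation residual is exactly two SDs.
* `"off"`: never inflate.

The two rules are genuinely different: the first compares the residual to
a *variance*, the second to a *standard deviation*, and they coincide only
when $V_{kk} = \tfrac{1}{4}|y_i-\hat x_k|\,$.  On the standardized scale
(unit diagonal) the first rule triggers whenever the residual exceeds half
an SD — i.e., on a majority of perfectly ordinary sampling residuals.
Since inflation dampens the point correction while leaving the reported
variance reduction unchanged, routinely triggering it degrades both
efficiency and interval calibration.  Both rules are therefore exposed;
the Monte-Carlo harness (`monte_carlo_efficiency()`) defaults to
`divergence = "off"` because its synthetic data contain no non-sampling
anomalies for the guard to catch.  In production runs on real data the
audit trail records, for every constraint, the residual in SD units and
any inflation factor applied, which is the diagnostic an analyst should
review.

### Standardization and the tolerance

`kf_estimate()` centres the state on zero and scales it so
$\hat{\mathbf{V}}_{SRS}$ has unit diagonal before updating, then
transforms back; the census constants are mapped onto the same scale.
This serves numerical conditioning and makes `tol` scale-free: the default
`tol = 1e-4` means one ten-thousandth of a unit variance regardless of the
units of any variable.  Zero-variance variables keep scale 1 (avoiding a
division by zero) and are later skipped by the tolerance rule.  The
standardize–update–destandardize path agrees with the direct update to
within $10^{-8}$ relative error (tested), so the choice is one of
numerics, not of estimand.

## Covariance hygiene

With hundreds of auxiliaries, many estimated study–auxiliary correlations
are truly zero but estimated as small nonzero values; each would remove a
little variance, and the removals accumulate multiplicatively.  In the
extreme $k_a \ge n$ the sample covariance is rank-deficient and the filter
can condition a study variance essentially to zero on pure noise.
`sparsify()` tests every off-diagonal correlation against zero
($t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, a conventional reading of
"smaller than expected by chance") and sets non-significant entries to
exactly zero, before and/or after the filter run.

Two caveats are deliberate design positions:

* **Multiplicity.** At a per-entry $\alpha = 0.05$, two hundred
  truly-null auxiliaries still leave $\approx 10$ false survivors whose
  combined spurious reduction is material.  `sparsify_policy(p_adjust =
  "bonferroni")` applies a family-wise correction; the integration test
  demonstrating that sparsification preserves the study variance under
  pure noise uses it.  No correction is the default, matching the plain
  per-entry reading of the criterion.
* **PSD repair.** Zeroing entries of a covariance matrix can destroy
  positive semidefiniteness; the repair clips negative eigenvalues at
  zero.  The repair is itself dense — it can re-introduce small nonzeros
  in entries just zeroed — so when many entries are zeroed at once a
  family-wise level (fewer, better-supported survivors) is doubly
  advisable.  Repairs are flagged in the return value.

## Post-estimation transforms

Analysts need sums of table cells, differences, proportions and rates,
with valid variances.  `append_pseudo_estimate()` appends each transform
to the state with first-order (delta-method) covariance propagation using
the *full* state covariance: for gradient $\mathbf{g}$, the new variance
is $\mathbf{g}'\mathbf{V}\mathbf{g}$ and the covariance with the existing
state is $\mathbf{V}\mathbf{g}$.  Linear transforms are exact.  Because
the output joins the state, transforms chain — e.g., the difference of two
survival ratios — and chaining is exactly equivalent to the one-shot delta
method on the composite function.  First-order propagation (rather than
second-order) is accurate when coefficients of variation are small, the
regime of inventory-scale estimates; the test suite checks ratio and
product variances against Monte-Carlo truth at CV $\le 0.1$ within 10%.
Pseudo variables may feed later transforms but are never fed back into the
Kalman update (they are derived, not observed); `kf_sequential()` refuses
an estimate carrying them.

`mortality_rate()` encodes one domain convention worth stating: the
population-level annual mortality rate is the number of live infested
trees at year $t$ divided by the number of recent mortality trees at year
$t+1$ — in a rotating panel no tree is measured in consecutive years, so
the rate exists only at the population level.

## The comparator and the design effect

`poststratified_estimate()` implements the conventional alternative:
post-stratify the sample on a categorical auxiliary and reweight stratum
means by known stratum weights.  Strata with fewer than 10 sampled units
(the customary minimum) are merged into a designated similar stratum
following an explicit merge order; if merging cannot satisfy the minimum
the function falls back to SRS and flags it.  The variance estimator

$$\hat V = \frac{1}{n}\sum_h W_h s_h^2 +
\frac{1}{n^2}\sum_h (1 - W_h) s_h^2$$

is the standard form with the second term adjusting for the random
realised stratum sample sizes.  This exact form is an interpretation: the
estimator is named rather than printed in the source methodology, and the
classical textbook form is adopted.

Both estimators are compared through the design effect
$100\,(1 - \hat V_{est} / \hat V_{SRS})$: the percent variance reduction
relative to SRS, negative when the estimator loses efficiency.

## The synthetic population

`generate_population()` builds the finite population the tests and the
acceptance script sample from.  Latent Gaussian structure: each study
variable follows a stationary AR(1) across years
($z_t = \phi z_{t-1} + \sqrt{1-\phi^2}\,\varepsilon_t$); each auxiliary is
$\rho z + \sqrt{1-\rho^2}\,\varepsilon$ against its paired (study, year)
latent; binary auxiliaries threshold the latent at the upper prevalence
quantile, so their 0/1 correlation with the study variable is the
point-biserial attenuation of the latent $\rho$.  This is the simplest
mechanism that gives exactly enumerable census constants, controllable
correlations, and a mix of continuous and categorical layers.  Panels are
assigned systematically (unit index mod $p$), mirroring an
interpenetrating panel design and keeping the partition balanced and
reproducible.  All randomness flows from one integer seed; the same seed
and spec reproduce the population and samples bit for bit.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: spatial structure and misregistration
between plots and pixels, non-sampling errors in the layers, skewed and
zero-inflated study variables (tree mortality counts are rare events;
the generator's Gaussian marginals are symmetric), and the panel
estimator's temporal covariance bookkeeping (the estimators here require
the complete-measurement simple random sample; the panel design is
provided for structural realism only).

### Default study conditions

The Monte-Carlo harness runs at $N = 10^5$, $n = 200$, 2000 replicates —
large enough that a population correlation of 0.95 demonstrably yields
the roughly ten-fold MSE reduction the theory predicts
($1/(1-\rho^2) \approx 10.3$, so comfortably above eight-fold), and that
$\rho = 0.5$ shows the $\rho^2 \approx 25\%$ design effect, while a full
suite run stays in the tens of seconds.  Empirical 95% interval coverage
at $n = 200$ sits near 94–95%; slight undercoverage is expected because
the gain is computed from an estimated covariance.

## Known limitations

* The estimator assumes a simple random sample with complete measurement
  vectors; unequal-probability and cluster designs are out of scope.
* The constraint machinery strictly assumes exact census constants
  (observation noise zero); noisy auxiliary totals would need the general
  measurement update, which is not provided.
* One static recursion only: there is no process model, no smoothing, no
  multi-recursion dynamic filtering.
* First-order variance propagation for nonlinear transforms; ratios of
  small, noisy denominators should not be trusted.
* The printed divergence rule is dimensionally inconsistent with its
  two-SD motivation; both readings are implemented and the choice is the
  analyst's (see above).
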