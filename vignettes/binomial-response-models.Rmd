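---
title: "Binomial category response models for Likert items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binomial category response models for Likert items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(likertbin)
```

## The model

Most item-response models connect a continuous latent trait to the m
ordered categories of a Likert item through a normal or logistic
function. `likertbin` implements a discrete alternative: the respondent
is imagined to run n = m−1 independent latent "mini-trials", each
endorsing the item's statement with probability $p_B$, and the number of
endorsements selects the response category. Category $R_k$
(k = 1..m) then has probability

$$P(R_k) = \binom{n}{k-1}\, p_B^{\,k-1} (1-p_B)^{\,n-k+1},$$

the one-parameter binomial model (1PBM). For the default 5-point scale
these are the five closed forms from $(1-p_B)^4$ for "strongly
disagree" up to $p_B^4$ for "strongly agree". Two consequences drive
everything else in the package:

* **The family is tight.** The middle category of a 5-point scale can
  never exceed probability 0.375 (at $p_B = 0.5$) and the fourth
  category never exceeds 0.421875 (at $p_B = 0.75$). Observed
  frequencies above these ceilings are impossible under *any* single
  binomial — which turns deviations into a principled definition of
  response bias (`max_category_probability()`, `scan_item_bias()`).
* **$p_B$ is interpretable.** It is dimensionless, independent of m,
  and an affine transform of the classical item mean
  ($\bar{x} = 1 + (m-1)p_B$), so fitted probabilities and item means are
  nearly collinear across items.

Two extensions complete the family. The **mixed-binomial model (3PBM)**,

$$f_k = w\, b(k-1;\, n, p_B) + (1-w)\, b(k-1;\, n, q_B),$$

assumes two subpopulations endorsing the item with different
probabilities; it is the only member of the family that can produce the
V-shaped (bimodal) distributions seen on polarising items. The
**two-parameter normal model (2PNM)** is the continuous benchmark: a
latent normal$(\mu, \sigma)$ cut at the half-integer boundaries between
the category values 1..m, with open outer bins (a
truncate-and-renormalise variant is available via
`normal_probs(renormalize = TRUE)`; the bin-mass convention is the
simplest one consistent with treating categories as the integers 1..m,
and is the package default).

## Fitting: exhaustive chi-square minimisation

All fitters minimise the Pearson statistic
$\chi^2 = \sum_k (O_k - N e_k)^2 / (N e_k)$ over the m categories, by
exhaustive grid search:

* `fit_binomial()`: p swept at step $10^{-4}$ over
  $[\delta, 1-\delta]$ with boundary guard $\delta = 10^{-3}$, then one
  continuous refinement pass (golden-section within one grid step).
* `fit_mixed_binomial()`: all combinations of $p_B, q_B$ on a 0.01 grid
  (plus the guard endpoints) and $w \in [0.5, 1]$ at 0.01, then a local
  refinement grid at $10^{-3}$. The coarse resolution matches the two
  decimals at which mixture solutions are conventionally reported.
* `fit_normal()`: coarse $(\mu, \sigma)$ sweep followed by L-BFGS-B.

Numerical choices worth knowing:

* **Boundary guard and floor.** Observed mixture components can be as
  extreme as $q_B = 0.01$, so the grids must approach the boundary;
  expected probabilities are floored at $10^{-9}$ before division so
  $\chi^2$ stays finite.
* **Identifiability.** A mixture triple and its label swap
  $(q_B, p_B, 1-w)$ generate the same distribution; the package
  canonicalises to a dominant first component, $w \ge 0.5$. Grid ties
  are broken deterministically (larger w, then smaller $p_B$).
* **Dominance.** The single binomial is the boundary case $w = 1$ of
  the mixture. Because the 1PBM grid is finer than the mixture grid,
  the mixture fitter falls back to the single-model solution whenever
  that attains a lower $\chi^2$, so $\chi^2_{3PBM} \le \chi^2_{1PBM}$
  always holds.
* **Degrees of freedom.** The default (`df_mode = "paper"`) uses
  df = m−1 = 4 for every model, the convention under which the
  reference critical value 9.4877 (df 4, upper 5%) applies to all three
  fits; `df_mode = "corrected"` subtracts the parameter count.
  AIC = $\chi^2 + 2k$ with k = 1, 2, 3 is reported alongside.

Model selection follows the improvement rule: the mixture replaces the
single binomial when it reduces $\chi^2$ by at least 5%
(`improvement_pct`, computed against `fit_binomial()` on the same
counts; a perfect single fit is assigned improvement 0 to avoid a 0/0).

## Noise tolerance

Because $\chi^2$ scales with N, even tiny distortions are "significant"
at realistic sample sizes. `noise_misfit_curve()` asks a more useful
question: how much uniform random answering can be mixed into a perfect
binomial pattern before the fit is rejected? A noise fraction $\kappa$
replaces the distribution by
$(1-\kappa)\,\text{probs} + \kappa/m$; for each integer noise
percentage every item is contaminated, converted to counts, *refit*
with the 1PBM (the simulation measures misfit of the fitted model,
mirroring the empirical procedure), and compared against the df-4
critical value.

Two count modes are provided. The default **expected mode** uses exact
expected counts $N \cdot \text{probs}$: at zero noise there is no
approximation error at all, the curve is deterministic, and the misfit
proportion is provably nondecreasing. **Sampled mode** adds one
multinomial draw per item behind a seed. The default item bank for the
curve is 240 items at N = 1731 with endorsement probabilities drawn
from a normal(0.56, 0.13) truncated to [0.05, 0.95] — the two published
moments of the empirical probability distribution the surrogate stands
in for, truncated so expected counts stay positive. Under those
conditions half the items misfit at about 7–8% noise and all items
misfit from about 9%, consistent with the reported behaviour that
slightly more than 5% noise fails half the bank and 12% fails all of
it. (The surrogate is lighter-tailed than the unpublished empirical
probability set, so its crossings sit at or above the empirical ones.)

`estimate_noise_level()` inverts the simulated mapping by monotone
interpolation on a 1% grid, conditioned on N. Two summaries are
implemented without adjudicating between them — `"mean_chi2"` (matching
the mean item $\chi^2$) and `"pass_rate"` (matching the proportion of
items passing the test) — because the two inversions answer slightly
different questions and are known to disagree by a few points. A
summary beyond the simulated range is reported censored at the grid
maximum.

## Bias detection

`scan_item_bias()` applies the ten-point rule: a category whose
observed relative frequency differs from the model's prediction by at
least 0.10 (ten percentage *points*, not 10% relative — the reading
consistent with worked examples phrased as "56.4% observed against a
37.5% ceiling") flags the item. The benchmark is the selected model's
prediction by default (mixture if selected, else single binomial);
`scan_bank_bias(model = "single")` forces the single-model benchmark,
since either convention is defensible. `detect_v_shape()` flags a
middle category strictly below both neighbours — impossible under any
single binomial or discretised normal, as a brute-force sweep of the p
grid confirms.

## The synthetic item bank

`generate_item_bank()` emulates the features real Likert banks exhibit:
per-item endorsement probabilities from the truncated normal above
(240 items, N = 1731 by default), an optional fraction of two-component
mixture items, uniform noise, and injected single-category biases
(mass $\delta$ moved onto one category, the rest rescaled
proportionally — the simplest mechanism producing single-category
distortions). Every generating choice lands in a truth log that
round-trips through JSON. What it deliberately does **not** emulate:
respondent-level trait vectors correlated across items (items are
analysed in isolation throughout), structured careless responding, or
acquiescence that varies by item content. Passing recovery tests on
these banks therefore demonstrate that the fitters find the truth when
the model family is correct, not that real questionnaire data follow a
binomial law.

## Problem sizes and verification

The test suite exercises the fitters at the reference conditions:
240-item banks at N = 1731 for the noise curve and the mean–probability
link; 200 random count vectors for agreement between `fit_binomial()`
and an independent brute-force scan at step $10^{-5}$ (relative
tolerance $10^{-6}$); and mixture recovery over six (p, q, w) designs
with component separations 0.35–0.71 spanning the range of reported
mixture solutions, 100 multinomial items per design at N = 1731. Across
that design the median absolute recovery error per parameter stays
within 0.02. Identifiability degrades as the components approach each
other: at separation 0.35 the weight w is the weakest-recovered
parameter (its cell-level median error reaches about 0.05), which is a
property of the model, not of the search — the likelihood surface
flattens along the ridge that trades w against the component
separation.

## Worked example

A polarised item whose two subpopulations disagree strongly:

```{r example}
probs <- mixed_category_probabilities(p_B = 0.08, q_B = 0.80, w = 0.66)
round(as.numeric(probs), 4)
cnt <- response_counts(1731 * as.numeric(probs), item_id = "i112")
fit <- fit_mixed_binomial(cnt)
fit
fit_binomial(cnt)
```

The single binomial is hopeless on this V-shaped distribution, while
the exhaustive mixture search recovers the generating triple exactly
(improvement 100%).

## Limitations

* The binomial family is a per-item description; the package does not
  estimate person parameters or joint latent traits across items.
* The 5% improvement rule and the ten-point bias rule are conventions,
  not tests with controlled error rates.
* The paper-convention df = m−1 overstates the degrees of freedom for
  the 2- and 3-parameter models; use `df_mode = "corrected"` when
  calibrated p-values matter more than comparability.
* Expected-mode counts are real-valued; the Pearson statistic is still
  well-defined but its chi-square reference distribution is exact only
  for multinomial sampling.
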