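---
title: "Modelling 2AFC contrast detection under collinear lateral masking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 2AFC contrast detection under collinear lateral masking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(latmask)
library(dplyr)
```

## The experiment and the model

`latmask` analyses (and simulates) a classic lateral-masking experiment:
an observer reports which of two intervals contained a low-contrast,
vertically oriented Gabor target (two-alternative forced choice, chance =
0.5). In separate blocks the target appears alone (the *baseline*) or
between two high-contrast collinear flanker Gabors placed 1, 2, 3, 4, 6 or
12 carrier wavelengths above and below it. Each block crosses 7 Michelson
contrast levels (0.0075–0.09) with 20 repetitions: 140 trials per block,
980 per observer. Two groups are compared: controls and migraine-with-aura
observers, sized 31 and 24 by default.

Per trial the probability of a correct response is modelled with a probit
link,

$$
\Pr(\text{correct}_{ij}) = \Phi\!\left(\eta_{ij}\right), \qquad
\eta_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\, c_{ij}
          + \beta_2\, g_i + \beta_3\, g_i c_{ij},
$$

where $c$ is Michelson contrast (a proportion), $g$ indicates the
migraine-with-aura group (control is the reference level), and
$(b_{0i}, b_{1i}) \sim N(0, \Sigma)$ are the per-observer random intercept
and contrast slope. The *flanker* model adds flanker distance $d$ (in
wavelengths) and the interactions $c{\times}d$, $g{\times}d$ and
$g{\times}d{\times}c$ on top of the baseline terms, giving an 8-column
fixed-effects design; it is fit to the flanker blocks, which are the only
blocks with a distance coordinate.

Two modelling choices are worth spelling out:

* **No lapse/guess parameters.** The linear predictor maps through a plain
  probit, not a 0.5-floored 2AFC function. Chance behaviour corresponds to
  $\eta = 0$, and the model can in principle predict below-chance
  performance. This matches the analysis convention the package
  re-implements; it means the fitted "intercept" is interpretable only
  jointly with the slope, through the threshold.
* **Contrast in proportions.** The published level list carries percent
  signs ("0.0075%…0.09%"), but values that small would be undetectable and
  the reported slopes (≈29 per unit) are only consistent with proportions
  of 0.75%–9%. The package therefore treats the levels as proportions
  0.0075–0.09 throughout.

## Estimation

`fit_probit_glmm()` maximizes the *marginal* likelihood: the random effects
are integrated out per observer with adaptive Gauss–Hermite quadrature
(tensor-product nodes, 7 per dimension by default; `nAGQ = 1` is the
Laplace approximation). The integral is evaluated on the standardized scale
$b = L u$, $u \sim N(0, I)$, with $\Sigma = LL'$ parameterized by its
Cholesky factor: the estimate of $\Sigma$ is positive semi-definite by
construction, and the quadrature remains exact as $L \to 0$, where the
marginal likelihood collapses to the plain probit GLM likelihood. Each
observer's integrand is centred and scaled at its conditional mode (an
inner 2-D Newton iteration), so node placement adapts to the data.

Numerical choices:

* **Start values** are the plain probit GLM estimates for $\beta$ and
  $0.1 I$ for $\Sigma$. Fits with `nAGQ > 1` first converge the cheap
  Laplace objective, then refine under the full quadrature.
* **Optimizer**: `nlminb` (PORT), with parameters brought to a common
  scale (contrast slopes are two orders of magnitude larger than the
  covariance entries; without scaling PORT needs several times more
  evaluations). Convergence is the optimizer's relative-tolerance
  criterion at `rel.tol = 1e-10` — stricter than a relative log-likelihood
  change of 1e-8 — plus finite estimates; "false convergence" exits are
  retried from the current iterate before a fit is flagged
  `converged = FALSE`. An absolute gradient-norm criterion is not used: at
  log-likelihood magnitudes of $10^3$ a finite-difference gradient cannot
  resolve a sup-norm of $10^{-5}$.
* **Observation coding.** Trials can enter one per row (Bernoulli) or
  aggregated into (observer, condition, contrast) cells (binomial); the
  likelihood omits the data-only binomial coefficient, so the two codings
  give the same value and the same maximizer, and are tested to do so.
* **Quadrature order**: on default-scale fits, moving from 5 to 15 nodes
  per dimension changes the log-likelihood by well under 1e-4; 7 nodes is
  the default. The test suite checks the quadrature against a brute-force
  2-D grid integration.
* **Degrees of freedom** for the Wald t statistics use the residual
  convention, rows of the model frame minus the number of fixed-effect
  terms. Other conventions exist (and the original analysis's printed dofs
  are not unambiguously derivable from its design), so the dof is
  reported, never asserted against external values.
* **Degenerate inputs**: observers correct on every trial (complete
  separation) trigger a warning, not an error — their random effects are
  weakly identified but the marginal fit is still defined. A slope of
  exactly zero makes the threshold undefined (an error); a negative fitted
  slope returns a threshold with a degeneracy warning.

```{r fit-example}
pop <- population_params(group_sizes = c(control = 10, migraine_aura = 8))
trials <- simulate_dataset(pop, session_design(), seed = 7)
fit <- trials |>
  filter(condition == "baseline") |>
  fit_probit_glmm(model_spec("baseline"), nAGQ = 7)
tidy(fit)
glance(fit)
```

## Thresholds and the simulated-observer bootstrap

The group threshold at criterion $p$ (default 0.75) inverts the
population-average psychometric function,
$T = (\Phi^{-1}(p) - \hat a_g)/\hat b_g$, with $(\hat a_g, \hat b_g)$ the
group-level intercept and slope. `threshold_75()` and `predict_p()` are
exact inverses of one another (tested to 1e-10).

`bootstrap_threshold_sd()` re-enacts the experiment from the fitted model:
draw a population of simulated observers, simulate binomial responses at
every design contrast level through the probit function, refit the same
mixed model, record each group's threshold; repeat (1000 samples by
default) and take the per-group standard deviation. Non-convergent refits
are dropped and counted, never imputed; more than 20% dropped aborts.

The description this recipe comes from is ambiguous about *which*
covariance generates the simulated observers, so both readings are
implemented:

* `covariance = "ranef"` (default): per-observer draws around the fitted
  group means with the random-effects covariance $\hat\Sigma$ — a
  population of heterogeneous observers. This is the reading that actually
  produces "a population of simulated observers", and it is the default
  for reporting threshold SDs.
* `covariance = "fixef"`: one (intercept, slope) pair per group per
  bootstrap sample from the fixed-effect sampling covariance, shared by
  the group's observers — pure estimation uncertainty. In the
  zero-heterogeneity, many-trials regime this reproduces the delta-method
  SE of the threshold, which is how the package's calibration tests pin it
  down.

`compare_group_thresholds()` turns the bootstrap difference distribution
into a two-sided p value with the $(k+1)/(B+1)$ continuity correction, so
p is never exactly zero and label-swapping leaves it unchanged. For this
*significance test* the `"fixef"` mode is the calibrated choice: in null
simulations at small group sizes the `"ranef"` mode over-rejects
(roughly 10–14% at $\alpha = 0.05$ with 8 observers per group) because the
ML estimate of $\Sigma$ is biased low with few observers, which shrinks
the simulated spread; the `"fixef"` mode holds its size. With larger
groups the two modes converge.

## Facilitation profiles

`facilitation_profile()` composes the pipeline per flanker distance:
per-condition fits (the default; a joint flanker-model fit evaluated at
each distance is the alternative `mode = "joint"`), group thresholds, and
normalization by the *same group's* baseline threshold. Ratios below 1 are
facilitation, above 1 inhibition (`classify_interaction()`, strict by
default with a configurable tolerance band). Normalization is scale-free:
rescaling every threshold of a group leaves its relative profile
unchanged. Relative-threshold SDs, when requested, come from samplewise
ratios of condition to baseline bootstrap draws.

```{r profile-example}
prof <- facilitation_profile(trials, nAGQ = 3, seed = 2)
prof
```

## The synthetic-data generator

`population_params()` + `simulate_dataset()` generate data with exactly
the statistical structure the models assume: group-level fixed effects,
bivariate-normal observer deviations, binomial trial outcomes through the
probit, full factorial observer × block × level × repetition layout. The
defaults *are* the study conditions: 31 + 24 observers, the seven contrast
levels, 20 repetitions, six flanker distances plus baseline, and the
reported baseline fixed effects (contrast slope 29.141, group offset
−0.391, group-by-contrast offset 12.313) — the unreported baseline
intercept defaults to −0.5, which places the control 75% threshold near
0.04, in the plausible range for this stimulus, and the random-effects
covariance defaults to diag(0.04, 16) (SD 0.2 in intercept, 4 in slope),
heterogeneity large enough that ignoring it would visibly distort the
fixed effects. Flanker distance does not enter the generative model by
default (matching the finding the package models); per-condition intercept
offsets (`condition_effects`) exist as a hook to seed facilitation
scenarios.

Seeding uses a splittable counter scheme: a master seed expands into
per-(observer, block) streams, so the full table is bit-reproducible and
any subset can be regenerated in isolation.

What the generator deliberately does **not** emulate: lapses and finger
errors, learning or fatigue across blocks, serial dependence between
trials, block-order effects, and any clinical covariate structure. Tests
that pass on this generator therefore certify the *estimators* (identifiable
parameters are recovered, the quadrature is exact where it should be, the
bootstrap is calibrated under the assumed model) — they do not certify
that the probit-with-random-slopes model is adequate for any particular
real dataset.

## Stimulus rendering

The `stimulus` functions exist for design validation and documentation
figures, not experiment presentation. A Gabor is rendered as
$L = \bar L\,(1 + c\,\cos(2\pi f u + \phi)\, e^{-(x^2+y^2)/2\sigma^2})$
on a mid-grey background with the display calibration of the modelled
apparatus (0.7 arcmin per pixel). Parameters the source design leaves
unstated are defaults here: envelope $\sigma$ = one wavelength (0.25°, the
classic choice in this paradigm), flanker contrast 0.6 for
"high-contrast", cosine phase. `measured_contrast()` recovers the
carrier's Michelson contrast from the peak luminance excursion about the
background; the raw frame minimum is envelope-attenuated (the nearest
carrier trough sits λ/2 from the peak), so a naive min/max ratio over the
frame would systematically understate the nominal contrast for narrow
envelopes.

```{r stimulus, fig.width = 6, fig.height = 4}
plot_contact_sheet(session_design(flanker_distances = c(1, 3, 12)),
                   geom = display_geometry(image_size = 351))
```

## Problem sizes used by the test suite

The package's replicate studies are sized to be informative while keeping
a full test run in the minutes range: parameter recovery uses 200
replicate simulations at the study's 31 + 24 observers (non-convergent
replicates — a handful — are dropped, not imputed); bootstrap calibration
uses 200 null experiments at 8 observers per group with 50 bootstrap
draws each; profile checks use 8 observers per group with 30 bootstrap
draws per condition. Monte-Carlo tolerances are stated in the tests as
multiples of the corresponding Monte-Carlo standard errors.

## Known limitations

* Only the probit link, and only a 2-D (intercept, contrast-slope) random
  effect per observer; no crossed or higher-dimensional structures.
* Wald inference uses a single residual-dof convention; no
  Satterthwaite/Kenward-Roger approximation.
* The bootstrap reports SDs (matching the analysis it re-implements), not
  percentile or BCa intervals.
* ML estimation of $\Sigma$ is biased low in small samples; consumers of
  `"ranef"`-mode bootstrap SDs at small group sizes inherit that bias
  (see the calibration discussion above).
* The stimulus module renders static frames; timing, gamma correction and
  bit-depth control of a real display are out of scope.
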