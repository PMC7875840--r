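---
title: "Modelling cued number-line estimation with a central-tendency observer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cued number-line estimation with a central-tendency observer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuedenum)
```

## The scientific problem

When people report the numerosity of a briefly flashed dot cloud by clicking
a number line, their mappings are rarely linear: small numerosities are
overestimated and large ones underestimated. A long-standing explanation is
the *central tendency of judgment*: estimates are biased toward the mean of
the stimulus distribution, and the bias grows with sensory uncertainty.
`cuedenum` implements this account for a cued-enumeration design in which a
Posner/Egly-style cue manipulates attention trial by trial: the dot cloud
appears at the cued location (valid same location, VSL), at the uncued end
of the cued object (invalid same object, IS), or on the other object
(invalid different object, ID). Diverting attention raises sensory noise,
and — through the central prior — noisier conditions should show more
compressed number lines.

## The observer model

The response model is Bayesian cue combination with Gaussians. The
likelihood is centred on the presented numerosity $N$ with standard
deviation following a power law,

$$\sigma_R(N) = k\,N^{a},$$

and the prior is a Gaussian $\mathcal N(\bar P, \sigma_P)$ over the number
line. The posterior is again Gaussian with mean

$$\hat R(N) = \frac{\bar P\,\sigma_R^2 + N\,\sigma_P^2}
                   {\sigma_R^2 + \sigma_P^2},$$

a precision-weighted average that shrinks the sensory estimate toward the
prior. Equivalently, with Weber-fraction noise $\sigma_R = x\,\mathrm{WF}$,
the response is the convex blend $W_L\,x + (1 - W_L)\bar P$ with

$$W_L = \frac{\sigma_P^2}{x^2\,\mathrm{WF}^2 + \sigma_P^2};$$

`posterior_mean()` and `likelihood_weight()` satisfy this identity to
machine precision, and the test suite asserts it over $10^4$ random
parameter draws. Because $\sigma_R$ grows with $N$, shrinkage is stronger
at the high end of the range, which is exactly a compressive non-linearity:
power-function fits to posterior-mean mappings always return exponents
below 1 for any finite prior.

```{r mapping}
obs <- bayes_observer(prior_mean = 15, prior_sd = 5,
                      noise_k = 3, noise_exponent = 0)
predict_mapping(obs, c(5, 15, 30))$predicted_response  # 7.65, 15, 26.03
```

## What the simulator generates, and what it deliberately omits

`simulate_session()` / `simulate_experiment()` emulate the study design:
four sessions of 150 trials per subject, conditions drawn i.i.d. with
probabilities 0.75 / 0.125 / 0.125 (75% of 150 is not an integer, so exact
within-session counts cannot reproduce the stated percentages),
numerosities uniform on 5..30, and continuous responses clamped to the
1–35 line. The first 20 trials per session are flagged as training. Half
the trials carry an `area_control` flag mirroring the size-equated versus
area-equated stimulus manipulation (the flag is bookkeeping only; it does
not alter simulated responses).

A simulated response is

$$R = \mathrm{clamp}\bigl(\hat R(N) + \varepsilon\bigr),\qquad
  \varepsilon \sim \mathcal N\!\left(0,\ \sqrt{\sigma_R(N)^2 +
  \sigma_m^2}\right),$$

with $\sigma_m$ = `response_jitter_sd`, a constant motor/readout term. Tying
the trial-to-trial scatter to the same $\sigma_R(N)$ that sets the shrinkage
makes response SDs inherit the noise power law, so summary SD-versus-$N$
fits can recover the generating exponent. Setting `sensory_scatter = FALSE`
switches off the sensory component and, with zero jitter, yields the
deterministic mean observer — handy for validating fits against exact
algebraic identities.

Defaults encode the study conditions: a prior of $\mathcal N(15, 5)$,
square-root noise scaling ($a = 0.5$), and noise coefficients
$k = 0.58, 0.74, 1.0$ for VSL/IS/ID. The first two correspond to the
printed coefficients of variation (0.15 and 0.19 at mid-range numerosity
under square-root scaling); the ID value is not printed and was set to a
CV of about 0.26, consistent with the reported significant precision loss
in that condition. Motor jitter defaults to 0.5 response units. Between
subjects, `simulate_experiment()` scales all three noise coefficients by a
common log-normal factor (`subject_sd = 0.25`), so subjects spread along
the internal-noise axis while preserving the within-subject condition
ordering. Reaction times are a shifted log-normal (shift 0.25 s) with
condition means 1.07 / 1.13 / 1.27 s and SDs 0.14 / 0.17 / 0.20 s — a
minimal model chosen only to echo the reported means and ordering; no
claim is made about RT distribution shape.

The simulator does not model sequential (previous-trial) dependencies,
lapses, eye movements, numerical response preferences (e.g. round-number
anchoring), or any interaction between the area-equated control and
responses. Passing tests on these data therefore show that the *pipeline*
is correct and well calibrated, not that real observers satisfy its
assumptions.

Dot-array geometry is generated by `generate_dot_array()` with rejection
sampling (default cap 10,000 attempts, then an explicit packing error):
dots fully inside a 4° circular field, pairwise edge-to-edge gaps of at
least 0.15°, diameters within ±31% of the array's base diameter. In
size-equated mode the base diameter is the 0.25° default; in area-equated
mode diameters are jointly rescaled so the cumulative area hits the target
(by default the area of 15 default dots), which necessarily moves
individual diameters off 0.25° — the ±31% band then applies around the
rescaled base. Degrees are abstract units; no pixel geometry is modelled.

## Preprocessing

`clean_trials()` applies, in order: training-trial removal (first 20 per
session, by within-session rank) and a single-pass 2-SD outlier rule on
responses. The rule is deliberately non-iterative, group statistics use the
sample SD, and "more than 2 SD" is strict, so boundary responses and
zero-variance groups survive. Because per-condition removal percentages are
the quantity usually reported, grouping defaults to subject × condition;
pooling across subjects is a documented alternative (`group_by =
"condition"`). The 150-ms reaction-time floor is strict ("less than") and
applies only to the RT summary branch, never to response fits. On default
synthetic data the per-condition outlier drop stays below 5%.

## Estimation

`fit_linear_mle()` and `fit_power_mle()` maximise the scalar-variability
likelihood in which the response SD is proportional to the predicted mean:
$\mu_k = \alpha + \beta N_k$ (or $\mu_k = \alpha N_k^{\beta}$) and
$\sigma_k = \sigma_N\,\mu_k$, so $\sigma_N$ is the coefficient of
variation. The printed form of this likelihood in the source literature
contains two typographical slips (a sign inside the residual and a
misplaced multiplication in the SD term) that would permit negative SDs;
the implementation uses the standard reading above, which is what the
accompanying prose describes. Likelihood is combined across all target
values, which is what makes the estimates usable in this unbalanced design
(only 12.5% of trials per invalid condition).

Numerical choices: bounded L-BFGS-B with 10 starts by default (one
data-driven start from an OLS or log-log regression plus uniform random
starts within bounds); bounds intercept $[-10, 20]$, slope/scale $(0, 5]$,
exponent $(0, 2]$, $\sigma_N \in (10^{-4}, 2]$. Parameter points implying a
non-positive SD receive a large finite penalty rather than `NaN`, keeping
the optimiser stable. If no start converges, an explicitly unconverged fit
object is returned — never silent defaults. On 30-trial instances the
optimum matches a dense $50^3$ lattice search within one lattice step.

Two deliberate modelling notes. First, `fit_sd_power()` fits summary SDs
(one per numerosity) by least squares in log-log space rather than by
trial-level likelihood, because the quantity of interest is the scaling
exponent of a summary curve. Second, when the generating noise follows
square-root scaling while the fitted likelihood assumes Weber-type scalar
variability, the mis-specification biases the fitted power exponent
slightly below 1 even for an unbiased (flat-prior) observer (about 0.96 at
the default noise level); the exact-recovery tests therefore use matched
(Weber) noise, and exponents fitted to heterogeneous data should be read as
comparative indices, not absolute compression measurements.

The coefficient of variation is computed per condition as the mean over
numerosities of $\mathrm{SD}(R\mid N)/N$ (numerosities with at least two
responses), and the *internal noise* — the abscissa of the
non-linearity-versus-noise analysis — as $\mathrm{SD}(R/N)$.

## Fitting the prior and the noise–non-linearity curve

`fit_prior()` fits the central-tendency mapping to mean responses per
numerosity with the prior width as the free parameter, maximising
$R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ (the source text's "minimizing
$R^2$, the ratio between the Explained and Residual Sum of Squares" is
internally inconsistent; maximising variance explained is the only
coherent reading). The 1-D search is a coarse log-spaced grid refined by
`optimize()`, verified against a 0.01-resolution grid in the tests; an
identity dataset pegs the width at the upper bound with $R^2 \approx 1$,
as it should. The prior mean is handled by `prior_mean_mode`: fixed at a
given value (default 15, the reported best fit), fixed at the stimulus-range
midpoint (17.5 — the text's "mean of the stimulus range"), or free. Both
fixed options exist precisely because those two descriptions conflict.
The likelihood width can be supplied either as the power law
$(k, a)$ or as a per-numerosity table; the pipeline default takes $k$ from
each condition's CV with $a = 1$, the reading under which "$k$ is given by
the estimates of CV", with the pooled SD-scaling fit available as the
alternative (`sigma_r_from = "sd_power"`).

`nonlinearity_vs_noise_curve()` traces the model's signature prediction:
for each Weber fraction on a grid, it simulates posterior-mean responses
with $\sigma_R = N \cdot \mathrm{WF}$ (prior SD 17 dots by default, prior
mean at the range midpoint), clamps them to the line, and records internal
noise and the fitted power exponent. The exponent decreases monotonically
in WF (Spearman correlation $\le 0$ in the tests) — noisier observers,
more compression.

## The pipeline and its report

`run_pipeline()` chains simulation (or a supplied trial table), cleaning,
per-condition linear and power MLE fits, the pooled SD power law,
per-condition prior fits, per-subject power fits with the Pearson
correlation between internal noise and $1 - \beta$ (positive = noisier ⇒
more compressed), and RT summaries on the RT-filtered branch. Reports are
written as JSON with fixed field order and are byte-identical across reruns
with the same seed. No p-values are attached to the headline correlation:
at 45 subject × condition points from a simulation, direction and magnitude
are the informative quantities; significance machinery is left to the
user's stats package, to which the per-condition tables can be exported
directly.

Problem sizes used throughout the examples and tests are the study's own:
15 subjects × 520 post-training trials, 100-replicate recovery studies, 50
replicate experiments for the ordering checks, and 2,000 trials per
numerosity for precision-scaling recovery.

## Known limitations

* Condition differences are encoded purely as sensory-noise differences;
  attentional effects on the prior itself (or on motor noise) are not
  modelled.
* The number-line click is modelled as continuous and unbounded except for
  clamping; real click distributions are discrete at the pixel level and
  may cluster on tick marks.
* Clamping at the line ends induces a small truncation bias at the extreme
  numerosities, visible only at high noise levels.
* Per-subject fits need on the order of 30+ trials per cell; the invalid
  conditions sit near that floor in the real design, so their exponents are
  the noisiest quantities in the report.
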