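# cuedenum

Simulation and analysis of **cued number-line estimation**: how visual
attention (location-based and object-based cueing) shapes the precision and
linearity of numerosity estimates, modelled with a Bayesian
central-tendency observer.

## Who this is for

Researchers in numerical cognition and psychophysics who want a tested,
reproducible pipeline for number-line estimation data from Posner/Egly-style
cue-validity designs — or who want to simulate such experiments to plan
analyses, validate estimators, and explore the central-tendency account of
number-line compression.

## The model

On each trial a dot cloud of numerosity *N* (5–30) appears at the cued
location (**VSL**), at the uncued end of the cued object (**IS**), or on
the other object (**ID**), and the observer clicks a 1–35 number line.
Responses are modelled as the posterior mean of a Gaussian likelihood
centred on *N* — with SD following a power law σ_R(N) = k·N^a — combined
with a Gaussian prior N(P̄, σ_P) over the stimulus range:

    R̂(N) = (P̄·σ_R² + N·σ_P²) / (σ_R² + σ_P²)

Because σ_R grows with N, large numerosities are drawn toward the prior
more strongly, producing the familiar compressive (power exponent < 1)
number-line mapping. Attention enters as the noise coefficient *k*
(VSL < IS < ID): withdrawing attention raises sensory noise, which the
prior converts into compression.

Response data are fitted by maximum likelihood under **scalar
variability** (response SD proportional to the predicted mean; the
coefficient σ_N is the coefficient of variation), both with a linear mean
(α + β·N) and a power-function mean (α·N^β); summary SD-versus-N curves
are fitted by log-log least squares; and the prior width is fitted to mean
responses by maximising R² = 1 − RSS/TSS.

## Worked example

```r
library(cuedenum)
report <- run_pipeline(list(seed = 42L))
print(report)
```

```
Cued number-line estimation study report (seed 42)
Preprocessing report
  input trials:      9000
  training dropped:  1200
  outliers dropped:  130
    VSL   85 /  5830 (1.46%)
    IS    17 /   994 (1.71%)
    ID    28 /   976 (2.87%)
  fast RTs dropped:  0 (RT branch only)
  output trials:     7670

Per-condition summaries
 condition n_trials sigma_n power_exponent     cv internal_noise mean_rt
       VSL     5745  0.1615         0.8154 0.1555         0.1818   1.070
        IS      977  0.2039         0.7522 0.1942         0.2323   1.124
        ID      948  0.2702         0.6112 0.2556         0.3250   1.270

Pooled SD-vs-N power law: scale 0.656, exponent 0.518
Bayes fit VSL: prior SD   6.85, R-squared 0.998
Bayes fit IS : prior SD   6.58, R-squared 0.992
Bayes fit ID : prior SD   5.72, R-squared 0.967

Non-linearity vs internal noise: r = 0.954 (n = 45)
```

Reading the numbers: 15 simulated subjects ran 4 × 150 trials; the first
20 of each session are training and ~1.5–3% of responses per condition
fall to the 2-SD outlier rule. Estimation precision (σ_N, equivalently the
CV) degrades from the cued location (0.16) to the uncued object (0.27),
and the power exponent drops in step (0.82 → 0.61): noisier conditions
produce more compressed number lines. Pooled response SDs grow roughly as
√N (exponent 0.52). The central-tendency model fits each condition's mean
mapping (R² ≥ 0.97) with a prior width of 5–7 dots, and across subject ×
condition points, internal noise and non-linearity (1 − β) correlate
strongly and positively — the model's signature.

Individual pieces are available directly, e.g.:

```r
posterior_mean(5, prior_mean = 15, prior_sd = 5, sigma_R = 3)  # 7.647
trials <- simulate_experiment(n_subjects = 15, seed = 1)
clean  <- clean_trials(trials)$trials
fit_power_mle(clean$numerosity, clean$response)
generate_dot_array(20, mode = "area_equated", seed = 1)
nonlinearity_vs_noise_curve(prior_sd = 17, seed = 1)
```

A thin command-line front end (`inst/cli/cuedenum.R`) exposes
`simulate`, `clean`, `report` and `curve` subcommands over the same
functions.

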