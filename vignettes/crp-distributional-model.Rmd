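---
title: "Modelling the distribution of C-reactive protein across socioeconomic groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the distribution of C-reactive protein across socioeconomic groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

C-reactive protein (CRP, mg/L) is an acute-phase inflammation biomarker;
sustained values above 3 mg/L mark low-grade systemic inflammation and
elevated cardiovascular risk. Health-inequality research asks not only how
*average* CRP differs between socioeconomic groups (between-group
inequality) but also how *dispersed* CRP is within each group (within-group
inequality). `crpdist` implements a Bayesian treatment of both questions on
survey data shaped like a UK household panel's nurse-assessment wave:
person-level CRP plus occupational class (9 NS-SEC categories), educational
qualification (6 categories), equivalized household income, health
behaviours (sport activity 0–10, BMI, smoking status), self-rated health,
and sociodemographic controls (age, gender, house ownership).

## The models

Both models act on $y_i = \log \mathrm{CRP}_i$ with a Student-t likelihood,
chosen for robustness to the outliers a biomarker assay produces:

$$y_i \sim t_\nu(\mu_i,\ \sigma_i), \qquad
\mu_i = \beta_0 + \sum_j \beta_j x_{ij} + u_{e(i)} + u_{o(i)},$$

where $x_{ij}$ collects dummy-coded gender (reference male), house
ownership (owner), self-rated health (excellent) and smoking (smoker), plus
z-scored sport activity, age, equivalized income and BMI; $u_{e(i)}$ and
$u_{o(i)}$ are hierarchical deviations for the person's education and
occupation categories,

$$u_e \sim N(0, \sigma_\beta^{edu}), \quad u_o \sim N(0, \sigma_\beta^{occ}).$$

**Model 1** keeps $\sigma_i = \sigma$ constant (homoscedastic).
**Model 2** is distributional: the log residual scale gets its own linear
predictor in the same covariates,

$$\ln \sigma_i = \gamma_0 + \sum_j \gamma_j x_{ij} + v_{e(i)} + v_{o(i)},$$

so scale-side coefficients measure within-group dispersion differences —
e.g. a negative non-smoker coefficient means CRP is more homogeneous among
non-smokers than among smokers.

Priors: $\beta_0 \sim N(\mu_y, \sigma_y)$ with $\mu_y, \sigma_y$ the sample
mean/SD of $y$; all slope coefficients and group deviations (both sides)
standard normal on the non-centered scale; group-deviation SDs half-Cauchy
$(0, \sigma_y)$; $\sigma$ (Model 1) and the scale-side deviation SDs
(Model 2) half-Normal $(0, \sigma_y)$; $\nu - 1 \sim
\mathrm{Exponential}(1/29)$ (prior mean 30, the usual robust-regression
choice; the rate is exposed in `prior_config()`). Two notational readings
were fixed here as package decisions: "N(0, σ)" priors on scale parameters
are truncated to positive support (half-Normal/half-Cauchy), since an
untruncated normal on a standard deviation is not meaningful; and the
scale-model intercept $\gamma_0$ is centred at 0 on the log scale rather
than at $\mu_y$, because $\mu_y$ is a response-scale constant with no
meaning for $\ln \sigma$.

## Sampling

Sampling is plain Hamiltonian Monte Carlo written for this package: static
leapfrog paths with the step count jittered uniformly on `1:max_leapfrog`
(default 32), dual-averaging step-size adaptation targeting 0.8 acceptance,
and a diagonal mass matrix re-estimated over expanding warmup windows
(doubling window sizes, step size re-found and dual averaging restarted at
each window end), all frozen after warmup. The protocol default is 4 chains
× 2000 iterations with the first 1000 discarded; the discarded half is also
the adaptation window. Positive parameters are sampled as logs with
Jacobians, and group deviations are non-centered ($u = \sigma_\beta z$,
$z \sim N(0,1)$), which removes the worst funnel geometry.

Chains start from unconstrained coordinates drawn uniformly on
$[-1, 1]$ (`init_range`). Wider jitter proved genuinely harmful for the
distributional model: with ~60 coordinates at ±2 the scale-side predictor
can start near $e^{\pm 10}$, a chain can slide into the $\nu \to 1$
heavy-tail region, its within-window draw variance collapses, the estimated
mass matrix collapses with it, and the step size never recovers. Tight
jitter (the same remedy as the common `init_r` advice for Stan-based
distributional fits) eliminated this on every seed we tested; the jitter
width remains configurable.

Divergent transitions (energy error beyond 1000 or a non-finite target) are
rejected and counted; more than 10% divergences after warmup raises a
warning flag on the chain set rather than an error.

## The synthetic-data generator

The real nurse-assessment microdata are access-restricted, so the package
generates survey-like stand-ins by a Gaussian copula: a latent multivariate
normal with the published covariate correlation matrix (read as
latent-normal correlations — matching mixed-type product-moment
correlations on the observed scale is over-constrained), mapped through
inverse CDFs per margin:

* age: truncated normal on [16, 98], parent moments solved numerically so
  the *truncated* mean/SD match the published 52.07/16.71 (the published
  age range 20–65 is inconsistent with those moments; the wider support is
  the only reading compatible with them);
* BMI: truncated normal (lower bound 10, effectively untruncated);
* income: lognormal matched to mean 1978.7/SD 1534.2 — right-skewed and
  positive, as household income is;
* sport activity: truncated normal on [−0.5, 10.5] rounded to the integer
  0–10 scale;
* categorical margins: latent normal thresholded at the cumulative
  published proportions (printed proportions renormalize to 1 where the
  3-d.p. table sums to 0.999/1.001).

Household composition (adults ∈ {1,2,3} with probabilities 0.30/0.55/0.15,
children ∈ {0,1,2} with 0.60/0.25/0.15) is generated independently and
exists only to exercise OECD equivalization; body height is drawn by gender
(N(175.3, 7.2²)/N(161.9, 7.2²) cm) and weight back-solved from the copula's
BMI so that `weight/(height/100)^2` reproduces the BMI margin. Responses
are drawn from the model itself, so fits to generator output are true
parameter-recovery experiments; the generating values default to the
published posterior means.

The raw fixture reproduces the study's pre-exclusion counts exactly: 9896
records, 521 missing CRP, a disjoint 283 with inapplicable height/weight, a
further disjoint 132 missing one other covariate, leaving an 8960-row
analytic sample after the cascade (CRP missing → BMI inapplicable → CRP ≤ 0
→ covariate missing, each row counted once under its first matching
reason).

What the generator does *not* emulate: survey weights, PSU/stratification
design, household clustering, item-missingness correlated with covariates,
and any marginal law for CRP beyond the model equations. Passing recovery
tests therefore shows the estimation machinery is correct under the stated
generating process, not that the substantive published estimates are
reproduced from real data.

## Data preparation choices

* OECD equivalization uses the OECD-modified scale (1.0/0.5/0.3) by
  default, the contemporary UK convention; the original Oxford scale
  (1.0/0.7/0.5) is available via `oecd_scale = "original"`. Children are
  household members under 14.
* Equivalization precedes z-standardization of income; all z-scores use
  post-exclusion sample moments with the n−1 SD, because the prior and
  reporting scales must describe the modelled sample.
* CRP ≤ 0 is treated as missing (assay artefact); the natural log is used;
  the >3 mg/L high-risk flag uses a strict inequality.

## Numerical choices

* Posterior quantiles use the median-unbiased estimator (R's type 8).
* The 65% posterior bands are central (equal-tail) intervals by default;
  an HPD option exists (`density_interval(method = "hpd")`) since the
  published figures do not say which was drawn.
* The printed correlation matrix is repaired to the nearest
  positive-definite correlation matrix (eigenvalue floor 1e-8) before the
  Cholesky factorization — rounded 2-d.p. matrices are routinely slightly
  non-PD.
* Split R-hat and autocorrelation-based ESS (Geyer initial positive-pair
  truncation with a monotone cap) gate the pipeline at R-hat < 1.05 and
  ESS > 100 per reported parameter.
* Gradients are analytic (C++), verified against central finite differences
  at 1e-5 relative tolerance in the test suite.

## Problem sizes used in tests and reproduction

Parameter-recovery runs use n = 2000 with the full 4 × 2000/1000 protocol —
large enough that posterior SDs are ~2× the published ones and recovery is
sharp, small enough that a full Model 1 + Model 2 rerun takes a couple of
minutes. The generative-consistency property test uses 5 replicates of
n = 1200 with 2 short chains; interval coverage of the generating fixed
effects is checked against a 0.8 lower bound (nominal 0.9). These sizes are
the package's own simulation-design choices and are stated here so they can
be scaled up.

## Known limitations

* Static-path HMC with jittered step counts, not a tree-building sampler;
  adequate at this dimension (~30–60 parameters) but less turn-key on
  harder geometries.
* No survey weights, no imputation (complete-case only), no nonlinear age
  terms, no model comparison (LOO/WAIC) — all outside the analysis this
  package implements.
* Published posterior means are used as generating truth; they are inputs,
  not targets the fits are tuned toward.
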