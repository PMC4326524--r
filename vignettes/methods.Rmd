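---
title: "Comparing longitudinal HRQoL analysis strategies by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing longitudinal HRQoL analysis strategies by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

qolsim is a Monte-Carlo laboratory for a question that every oncology trial
with a patient-reported endpoint has to answer: *how should repeated
health-related quality of life (HRQoL) measurements be analysed when the
goal is to detect a differential evolution between treatment arms?* The
package generates longitudinal questionnaire data from a known latent
process, runs three families of analysis strategies on every simulated
trial, and estimates the type I error and power of each strategy's test of
the treatment-arm-by-time interaction.

This vignette documents the generating model, the three analysis engines,
the missing-data mechanism, and the numerical and design choices a user
should know before trusting (or extending) the results.

## The data-generating process

### Latent trait

Each simulated trial has $N$ patients (half per arm) measured at $T$
occasions. Patient $n$'s HRQoL is a latent trait
$\theta_n = (\theta_{n1}, \dots, \theta_{nT})'$ drawn from a multivariate
normal distribution with first-order autoregressive covariance

$$\Sigma_{st} = \sigma^2 \rho^{|s-t|}, \qquad \sigma^2 = 1,$$

so the correlation between two measurements decays with the number of
occasions separating them. Control-arm patients have mean $\mu^0$, a linear
trend over occasions; experimental-arm patients have mean $\mu^0 + \Delta$
with $\Delta_1 = 0$ (arms equal at randomization) and $\Delta_t = 0.4$
latent units for $t > 1$ — a *step* effect, deliberately not of the linear
form the analysis models assume, as in a trial where a treatment benefit
appears after the first cycle and then persists. The defaults are
$\mu^0 = (-0.4, -0.2, 0, 0.2, 0.4)$ for $T = 5$ and the analogous
$0.1$-step grid for $T = 10$, $\rho \in \{0.4, 0.7, 0.9\}$,
$N \in \{100, 200, 300\}$.

### Item responses and scores

At each occasion the patient answers $I$ polytomous items with $J$ ordered
categories. Given $\theta_{nt}$, responses are independent draws from the
adjacent-category (Masters) partial credit model

$$P(X = k \mid \theta) =
  \frac{\exp \sum_{l=1}^{k-1} (\theta - \delta_l)}
       {\sum_{k'=1}^{J} \exp \sum_{l=1}^{k'-1} (\theta - \delta_{l})},$$

with the empty sum equal to zero for the lowest category. The difficulty
vector is shared by all items and fixed at standard-normal quantiles:
$\delta = (-0.7, 0, 0.7)$ for $J = 4$ and
$(-1, -0.6, -0.2, 0.2, 0.6, 1)$ for $J = 7$, mirroring the category
granularity of the EORTC QLQ-C30 questionnaire. Conditional independence
across items and occasions given $\theta_{nt}$ enforces the Rasch local
independence assumption by construction.

A 0–100 score is computed per patient-occasion exactly as questionnaire
scoring manuals prescribe for a symptomatic scale:
$Y = (\bar X - 1) \times 100 / (J - 1)$ with $\bar X$ the mean of the
answered items, available only when at least half of the items were
answered (the *personal mean score* rule). Because the latent means rise
over time, the generated scale is read as symptomatic: higher = worse.

### What the generator does and does not emulate

The generator reproduces the measurement structure (polytomous items driven
by one latent dimension), the longitudinal correlation, the arm effect
geometry, and informative missingness. It does *not* emulate ceiling/floor
pile-ups beyond what the PCM itself produces, differential item
functioning, multi-dimensional HRQoL, assessment-time jitter, or death;
event times exist only on the occasion grid. Conclusions from these
simulations therefore speak to the comparative behaviour of the analysis
strategies under a clean item-response mechanism, not to every pathology of
real questionnaire data.

## Missing data

Only an MNAR (informative) mechanism is simulated: patients whose current
latent HRQoL is worse are more likely to go missing. The schedule follows
the study design — for $T = 5$, intermittent missingness at occasions 2–3
and monotone drop-out at 4–5; for $T = 10$, intermittent at 2–6 and
monotone at 7–10; never at baseline. At each scheduled occasion,
$\lfloor \pi \cdot n_{\text{at risk}} \rfloor$ patients are drawn without
replacement with probability proportional to $\exp(\kappa\, \theta_{nt})$
(symptomatic orientation; $-\theta$ for functional scales). Monotone
selection deletes everything from that occasion onward; intermittent
selection deletes the whole form (`forms` mode) or a uniform number of
uniformly chosen items (`items` mode) at that occasion only.

Two choices here were genuinely open and are worth recording. First, the
selection quota is count-based rather than Bernoulli, so the realized
per-occasion missingness proportion is exact by construction. Second, the
informativeness is a single exponential-tilt coefficient $\kappa$
(default 1) on the *current latent trait* — the simplest mechanism that
makes missingness depend on the present, unobserved HRQoL level; weighting
on the observed score or on past values would make the mechanism MAR-like,
which is exactly what the study design avoids.

## The three analysis strategies

All three test the same null hypothesis — no treatment-arm-by-time
interaction — at a two-sided $\alpha = 0.05$, with time coded $0, \dots,
T-1$ so the baseline interaction is structurally zero. None of the analysis
models is privileged with generator truth: the arm effect they estimate is
a single linear-in-time coefficient although the generated effect is a
step, and the random-effect structure they assume (intercept + slope) is
not the generating AR(1).

**Score and mixed model (SM).** A linear mixed model on the 0–100 scores,
$Y_{nt} = \beta_0 + \beta_1 t + \gamma\, \mathrm{arm}\cdot t + u_n + v_n t
+ \varepsilon_{nt}$, with correlated $(u_n, v_n)$ (unstructured 2×2
covariance) and iid residuals, estimated by maximum likelihood (not REML,
so that likelihoods are comparable across fixed-effect structures);
$\gamma$ is tested by a Wald $z$. Missing scores drop out of the
likelihood. An arm main effect is deliberately absent: arms are equal at
baseline by design, and the model states that.

**Time to deterioration (TTD/TUDD).** The score trajectory is reduced to a
survival endpoint: the first occasion at which the observed score is worse
than a reference score by at least the minimal clinically important
difference (MCID, 5 points), "worse" meaning higher for symptomatic scales.
Four definitions cross the reference (baseline vs best previous observed
score) with whether the deterioration must be *definitive* — never followed
by an observed score improved by at least one MCID relative to the
reference in force, with drop-out straight after deterioration also
counting as definitive. Intermittent gaps are skipped under a
last-status-carried-forward reading; patients without a qualifying event
are censored at their last observed assessment. Arms are compared by the
log-rank test on the occasion-valued event times (heavily tied, handled by
the hypergeometric variance); curves come from the Kaplan–Meier
product-limit estimator. Whether "improvement" at exactly 5 points cancels
a deterioration is ambiguous in the written definitions; this package reads
the threshold as $\geq$ MCID, symmetric with the deterioration side.

**Longitudinal partial credit model (LPCM).** The item-response analogue of
the SM model, fitted to the raw items rather than the score: the latent
trait is modelled as $\theta_{nt} = \beta t + \gamma\, \mathrm{arm} \cdot t
+ u_n + v_n t$ with $(u_n, v_n)$ bivariate normal (unstructured
covariance), and responses follow the PCM given $\theta_{nt}$ with one
*freely estimated* difficulty vector per item (`share_difficulties = TRUE`
constrains them equal across items instead). There is no global intercept:
the baseline latent location is absorbed by the difficulties, which
identifies the model. The marginal likelihood integrates the two
random effects out of each patient's observed responses.

## Numerical choices in the LPCM fit

The per-patient integral is evaluated by *adaptive Gauss–Hermite
quadrature*: a damped Newton search (the integrand is strictly log-concave
in $(u_n, v_n)$, so the mode is unique and backtracking guarantees
convergence) locates each patient's posterior mode and curvature, the
standard Gauss–Hermite grid — 7 nodes per dimension by default — is
recentred and rescaled there, and everything is accumulated in log space
with log-sum-exp, never as raw probability products. Seven nodes reproduce
a 15-node evaluation of a single-item $N = 100$ panel's total
log-likelihood to about $5\times10^{-3}$; nine nodes reach $10^{-4}$. The fitting default stays at
7 because the Wald test is insensitive at that level and the cost grows
with the square of the node count.

The covariance is parameterized by its log-diagonal Cholesky factor, which
keeps it positive definite and lets a degenerate slope variance be
approached smoothly; bounds of $e^{-6}$ on the Cholesky diagonal act as the
boundary fit. Optimization is quasi-Newton (L-BFGS-B) on the negative
log-likelihood with an analytic gradient accumulated at the quadrature
nodes (the dependence of the node locations themselves on the parameters is
neglected, a standard approximation that leaves a relative gradient error
well below $10^{-2}$ and does not move the optimum at the reported
precision); relative function tolerance $\approx 2\times10^{-8}$. On
non-convergence the fit restarts up to three times from deterministically
jittered starts. Standard errors come from the inverse of a
central-difference Hessian of the analytic gradient at the optimum;
$\gamma$ is tested by Wald $z$. Starting values are data-driven: pooled
adjacent-category log-odds for the difficulties and the slope of the
standardized naive score for $\beta$.

The SM engine delegates to `lme4::lmer` (ML, `bobyqa` with a Nelder–Mead
fallback); the survival engine delegates to `survival::survfit` and
`survival::survdiff`. Both are re-verified in the test suite against
independently coded oracles (a profiled-likelihood direct ML implementation
for the mixed model; hand-computed product-limit and log-rank tables plus a
permutation null for the survival side), and the LPCM likelihood is checked
against brute-force Monte-Carlo integration.

## Replication harness and reproducibility

`run_replicate()` generates one trial and runs all requested methods on the
same data; `run_scenario()` aggregates rejection rates with binomial
Monte-Carlo standard errors, excluding non-converged fits from the
denominator but reporting their count. Per-replicate seeds are drawn
up-front from the master seed, so results are independent of execution
order, and each replicate derives per-stage sub-seeds (latent, items,
missingness) so that a missing-data scenario deletes from exactly the
complete panel its $\pi = 0$ twin analyses. The study-scale run uses 500
replicates per cell for the score-based methods; the package's own
acceptance script scales the LPCM cells to 100–150 replicates, which bounds
the binomial SE of a rate near 0.9 by about 3 percentage points — the
trade-off chosen for a single-CPU desk run.

## Known limitations

* The LPCM fixes unit discrimination (Rasch family); generalized PCMs with
  estimated discriminations are out of scope.
* Event-time analysis is on the discrete occasion grid; interval-censored
  methods and the inclusion of death as a competing event are not
  implemented.
* The MNAR mechanism is one specific exponential-tilt construction; real
  informative missingness need not follow it, and no pattern-mixture
  correction is attempted in any engine.
* With a single item and four categories the score support has four values;
  the SM model's normality assumption is then frankly violated, which is
  part of what the simulation is designed to expose, not a defect to fix.
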