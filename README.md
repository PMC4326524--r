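# qolsim

Monte-Carlo comparison of longitudinal analysis strategies for
health-related quality of life (HRQoL) endpoints in randomized oncology
trials.

## The problem

HRQoL in oncology trials is measured by repeated questionnaires (EORTC
QLQ-C30 style: a handful of polytomous items per dimension, scored 0–100),
and the clinically relevant question is whether HRQoL *evolves differently*
between treatment arms — a treatment-arm × time interaction. Three families
of analysis compete in practice, and they differ both in power and in how
gracefully they survive informative (MNAR) missing data:

* **SM** — the score-and-mixed-model: a linear mixed model on the 0–100
  scores, `Y = β₀ + β₁·t + γ·arm·t + uₙ + vₙ·t + ε` with correlated random
  intercept/slope, interaction `γ` tested by Wald z;
* **TTD/TUDD** — time to (definitive) deterioration: the trajectory is
  collapsed to the first occasion where the score is at least one MCID
  (5 points) worse than a reference (baseline or best previous score),
  arms compared by log-rank on Kaplan–Meier curves — four definitions in
  all;
* **LPCM** — a longitudinal partial credit model fitted to the raw item
  responses: an adjacent-category Rasch-family measurement model whose
  latent trait carries the same fixed time and arm × time effects and
  correlated random intercept/slope, estimated by marginal maximum
  likelihood with adaptive Gauss–Hermite quadrature (the quadrature kernel
  is implemented in C++ in this package).

qolsim generates trials from a known latent process (multivariate-normal
trait with AR(1) correlation pushed through a partial credit model, with a
step arm effect of 0.4 latent units from the second occasion), optionally
deletes data through an MNAR mechanism (worse latent HRQoL ⇒ higher
selection odds; intermittent forms/items early, monotone drop-out late),
runs all six method variants on each replicate, and reports rejection
rates of the interaction test with binomial Monte-Carlo standard errors.

See `vignettes/methods.Rmd` for the full model, assumptions, and numerical
choices.

## Worked example

One replicate of the reference scenario — 300 patients, one 4-category
item, five occasions, AR(1) correlation 0.4, step arm effect 0.4:

```r
library(qolsim)

sc <- qol_scenario(n_patients = 300, n_items = 1, n_categories = 4,
                   n_times = 5, correlation = 0.4, arm_effect = 0.4)
rep1 <- run_replicate(sc, seed = 12345)
round(rep1$p_values, 4)
#>            SM  TTD_baseline      TTD_best TUDD_baseline     TUDD_best
#>        0.0000        0.3509        0.3205        0.1485        0.0788
#>          LPCM
#>        0.0000
```

The mixed model and the LPCM both see the interaction clearly (p < 1e-6);
the deterioration endpoints do not — with a single 4-category item the
score can only take the values 0/33.3/66.7/100, so a 5-point MCID turns
every category change into an "event" and the log-rank comparison loses
the size information entirely.

Aggregating over replicates estimates power (here 60 replicates for speed;
the study scale is 500):

```r
cells <- run_scenario(sc, n_replicates = 60, master_seed = 11,
                      methods = c("SM", "TTD_baseline", "LPCM"))
cells[, c("method", "rejection_rate", "mc_se", "n_nonconverged")]
#>         method rejection_rate      mc_se n_nonconverged
#> 1           SM      0.9833333 0.01652719              0
#> 2 TTD_baseline      0.2833333 0.05817439              0
#> 3         LPCM      0.9833333 0.01652719              0
```

`rejection_rate` is the proportion of converged replicates with a
two-sided interaction p-value below 0.05 — the empirical power of each
method at this scenario. `emit_tables()` writes such cells as a wide CSV
(one row per scenario, one column per method) plus a JSON diagnostics
file.

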