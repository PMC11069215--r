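# transhaz

Transformer-based prediction of **discrete-time cause-specific hazards
under competing risks**, for biostatisticians and epidemiologists working
with longitudinal cohorts in which a patient can experience the first of
several mutually exclusive events (death, disease diagnoses, ...) on a
discrete time grid, under censoring, and in which covariate effects need
not satisfy the proportional-hazards assumption.

## The model

For a patient with covariates $X$, competing events $e \in \{1,\dots,E\}$
and grid $t \in \{0,\dots,T-1\}$, the target is the matrix of
cause-specific hazards

$$\lambda_{e,X}(t) = P(\text{event } e \text{ at } t \mid \text{event-free up to } t),$$

from which cumulative incidence follows as
$I_{e,X}(t)=\sum_{\tau\le t}\lambda_{e,X}(\tau)\prod_{k<\tau}(1-\sum_j\lambda_{j,X}(k))$.
Two neural estimators are provided, both trained by minimizing the mean
negative **collapsed log-likelihood**

$$L(\lambda,e,t)=\sum_{j=1}^{E}\sum_{k=0}^{t}\delta^{et}_{jk}\log\lambda_{j,k}
+(1-\delta^{et}_{jk})\log(1-\lambda_{j,k}),$$

with censored patients contributing only steps strictly before their
censoring time:

* a **transformer encoder** over one token per $(e,t)$ output cell — each
  token concatenates a linear encoding of $X$ with a learned embedding of
  its $(e,t)$ index plus a sinusoidal positional encoding; a linear
  read-out and sigmoid yield the $E\times T$ hazard matrix;
* a **DeepHit-style baseline**: one independent 64-unit one-hidden-layer
  feed-forward subnetwork per event.

Around them: a synthetic competing-risks cohort generator with known
ground-truth hazards (proportional, increasing and non-monotonic regimes,
uniform censoring, ~40% censored), hazard-recovery benchmarking (MAE
x100), an IPCW integrated Brier score, cause-specific time-dependent
concordance, bootstrap confidence intervals, a Schoenfeld-residual
proportional-hazards screen, and integrated-gradients feature attribution.
The forward and backward passes are hand-written RcppArmadillo; gradients
are verified against finite differences in the test suite.

## Worked example

Simulate a 2,000-patient cohort under the built-in three-event design,
train the transformer on an 80/20 split, and score hazard recovery on the
held-out patients:

```r
library(transhaz)

design <- simulation_design(n_patients = 2000, seed = 42)
sim    <- simulate_cohort(design)
sim$data
#> Discrete-time competing-risks dataset: 2000 patients, 5 covariates
#>   3 competing events over 30 time steps; 39.8% censored

split <- split_dataset(sim$data, 0.8, seed = 1)
model <- hazard_model(transformer_config(p = 5, n_events = 3, horizon = 30),
                      seed = 1)
model <- fit(model, split$train, split$validation,
             train_config(epochs = 60, patience = 15, seed = 1))

pred  <- predict_hazard(model, split$validation$covariates)   # (n, E, T)
truth <- sim$truth[split$validation_idx, , , drop = FALSE]
round(sapply(1:3, function(e)
  hazard_mae(pred[, e, , drop = FALSE], truth[, e, , drop = FALSE])), 2)
#> [1] 0.60 0.86 0.76
```

The three numbers are the mean absolute errors (x100, so on the percent
scale of the hazard probabilities) between predicted and true hazards for
the proportional, increasing and non-monotonic events — e.g. a value of
0.60 means predicted per-step hazard probabilities are off by 0.006 on
average. Outcome-only metrics and the proportional-hazards screen:

```r
integrated_brier_score(pred, split$validation)
#> [1] 0.1186749
time_dependent_concordance(pred, split$validation)$mean
#> [1] 0.5805704

screen <- proportional_hazards_screen(sim$data)
subset(screen, flagged)
#>    event variable            p flagged
#> 7      2       Z2 4.024702e-02    TRUE
#> 8      2       Z3 3.522162e-02    TRUE
#> 11     3       Z1 4.212505e-49    TRUE
```

The screen fits a cause-specific Cox model per event and flags covariates
whose Schoenfeld residuals are associated with time (p < 0.05). None of
the proportional event's covariates are flagged; the non-proportional
events' are — at this cohort size only the strongest violations reach
significance (event 3's Z1 drives the location of its hazard peak), while
at n = 10,000 all five covariates of the increasing-hazard event are
flagged.
Feature attribution for the fitted model:

```r
head(cohort_importance(model, split$validation, steps = 64), 3)
#>   feature importance
#> 1      Z3 0.23070322
#> 2      Z2 0.19511717
#> 3      Z5 0.09446933
```

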