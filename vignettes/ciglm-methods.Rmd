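---
title: "Conditional-intensity GLMs for task-related prefrontal spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional-intensity GLMs for task-related prefrontal spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Prefrontal cortex (PFC) neurons recorded during delayed-response tasks fire
sparsely, and their discharge is shaped by two distinct influences: the
behavioral state of the task (waiting through a delay, running a maze arm,
consuming a reward) and the neuron's own recent spiking. The second
influence — spike-history-predicted discharge (SHPD) — is of particular
interest because recurrent cortical excitation is a candidate mechanism for
holding information across a delay, and acute stress is known to impair
PFC-dependent working memory. `ciglm` implements the point-process analysis
that separates and quantifies these influences for spike trains recorded in
a T-maze delayed-alternation task run once under baseline conditions and
once under loud-noise stress on the same day.

## The model family

Spike counts are binned at 250 ms (`obs_bin`). For the count $\Delta N_t$
in bin $t$ the log conditional intensity is modeled linearly:

$$\log \lambda_t = \mu + \beta S(t) + \sum_j B_j I_j(t)
  + \sum_{k=1}^{K} \left[\alpha_k (1 - S(t)) + \eta_k S(t)\right] N_{t,k},$$

where $S(t)$ indicates the stress session, $I_j(t)$ indicates behavioral
interval $j$ (Delay, Run, Branch, Choice, Reward, Pickup), and $N_{t,k}$ is
the spike count in the $k$-th lagged history window
$[t - k\Delta, t - (k-1)\Delta)$ with $\Delta = 250$ ms and $K = 10$, a
tenth-order autoregressive process spanning 2.5 s. Counts are Poisson and
the model is fitted by maximum likelihood (IRLS). The exponentiated history
weights $e^{\alpha_k}$, $e^{\eta_k}$ are the *spiking gains*: the
fold-change in expected discharge per spike observed $k$ windows in the
past, under baseline and stress respectively.

Six variants share this skeleton (`model_spec()`): `h0` (homogeneous
Poisson), `inhom` (intervals only), `1b` (condition-split history without
intervals), `1a` (the full model above), and the interaction models `2` and
`3`, which replace the condition-split main history with a global history
term $\gamma_k$ plus condition-split history-by-window interactions
confined to one composite window — the *extended delay* (Pickup plus Delay)
for model 2, the *response* epoch (Run-Branch-Choice) for model 3. Models 2
and 3 are not nested in one another and are never compared by deviance;
nested pairs (e.g. `1a` over `1b`) are compared with the likelihood-ratio
(deviance) test.

### Coding and scope choices

* **Reference interval.** The six intervals tile every trial, so a full
  dummy set plus intercept is rank deficient. Delay is the reference: its
  effect is absorbed into $\mu$, and $B_j$ are log rate-ratios against
  delay-period firing.
* **One grid for counts and lags.** The observation bin equals the history
  bin (250 ms), so $\mu$ is the log expected count per 250 ms and rates in
  Hz are counts divided by 0.25.
* **History crosses trial boundaries.** Lagged counts are computed over
  continuous session time, through interval changes, incorrect trials and
  inter-trial transitions. This avoids artificial zero-history edges at
  every trial start. Only bins inside analyzed trials — correct trials,
  excluding the always-rewarded first trial of a session — contribute
  likelihood terms, and bins whose 2.5 s history span precedes the session
  start are dropped from scope for every model so that all variants are fit
  on identical rows.
* **Joint two-session fits.** A unit's baseline and stress sessions are
  fitted together; $\mu$ and $B_j$ are shared, $\beta$ absorbs the overall
  stress shift, and the split history columns ($\alpha_k$ on baseline rows,
  $\eta_k$ on stress rows) cannot leak across conditions. When a
  single-condition input is supplied, the structurally zero columns are
  dropped for that fit.
* **Degeneracy guard.** Sparse history columns can separate (all responses
  zero where the column is nonzero), sending a coefficient to $\pm\infty$.
  Any fit with $|\hat\theta| > 15$ (a rate-ratio beyond $3\times10^6$) is
  flagged and excluded from population aggregation; exclusions are counted
  in every report.
* **Convergence.** IRLS runs to a relative tolerance of $10^{-8}$ with a
  cap of 100 iterations; the coefficient covariance is the inverse observed
  information at the optimum, and intervals on gains are Wald intervals
  exponentiated from the log scale (no profile likelihood), matching the
  rate-ratio reporting convention.

## Goodness of fit by time rescaling

If the fitted intensity is correct, transforming spike times through the
cumulative intensity $\Lambda$ makes the train unit-rate Poisson, so
$z_j = 1 - \exp(-[\Lambda(t_j) - \Lambda(t_{j-1})])$ is uniform on $[0,1]$.
`time_rescale()` integrates the fitted intensity as piecewise constant
within observation bins (spike times keep their recorded 5 ms resolution
inside a bin; exact ties are spread uniformly across their bin so no
rescaled interval is zero), and `ks_summary()` compares the ordered $z$
against uniform quantiles $(j - \tfrac12)/n$ with the standard
Kolmogorov-Smirnov equivalency band $1.36/\sqrt{n}$ at 95%
($1.63/\sqrt{n}$ at 99%). The familiar demonstration that history terms are
needed falls out directly: interval-only fits to history-driven data leave
the band, full fits do not.

## PETHs and interval rates

`compute_peth()` aligns 5 ms trial-by-trial bin counts to an interval onset
and reports spiking probability per bin (count over trials), so sessions
with different trial counts are comparable. Because interval durations vary
across trials, interval-wide averaging uses `normalized_peth()`: each
interval is resampled onto 20 equal sub-bins (the source analyses do not
state their normalization resolution; 20 gives 0.5 s resolution on a 10 s
delay) and rates are averaged across trials. Stress effects on rates are
expressed as percent of the baseline session (`percent_of_baseline()`,
undefined and excluded when the baseline rate is zero), matched on T-maze
arm where both arms are represented (per-arm percents averaged; pooled
fallback otherwise). Cohort-level tests are a one-way ANOVA across
intervals plus two-sided one-sample t tests against 100 with
Benjamini-Hochberg correction at $q = 0.05$; sidedness and $q$ are package
choices, configurable.

## Population summaries

Per-lag gains of non-degenerate fits are averaged across units
(`cohort_gains()`), tested with a two-way repeated-measures ANOVA
(Condition x History-lag, unit as subject) on the *gain* scale — the
convention in this literature is to average and test rate-ratios against
1.0, not their logarithms — with LSD (unadjusted) paired post-hocs per lag
and FDR-corrected one-sample tests per cell. The decay of cohort-mean gains
over lag is summarized by nonlinear least squares of
$g(x) = a + b\,e^{-(x-\Delta)/\tau}$ with multi-start over
$\tau \in \{0.25, 0.5, 1, 2\}$ s; an exactly flat profile is reported as
the degenerate $b = 0$ limit. The "delay-related unit" criterion used for
population fractions is not defined in the source analyses; the package's
explicit stand-in flags a unit when its baseline delay-interval rate
exceeds its whole-trial rate at $p < 0.05$ under a within-trial
circular-shift permutation test, and the flagged fraction is compared with
a configurable null proportion (default 0.05) by a one-proportion
chi-square test. This rule is documented as non-faithful and is exposed via
arguments.

## The synthetic-session generator

Because no recordings are deposited, every stage is validated by parameter
recovery from `simulate_cohort()`. Sessions follow the task structure: 41
trials, the first always rewarded and never analyzed; an exact imposed
delay (default 10 s, task range 10-40 s); jittered Run/Branch/Choice/
Reward/Pickup durations (means 2 / 1.5 / 2.5 / 4 / 8 s, uniform +/-20%,
about 28-30 s per trial); alternating arms with a configurable error rate
(errors repeat the previous arm and omit the Reward interval). Spikes are
drawn by discrete-time Bernoulli thinning on a 5 ms grid — the PETH
resolution — from exactly the log-linear intensity the fitting side
estimates, with the sliding-window lagged counts updated online across
trial and interval boundaries. The guard $\lambda \cdot \delta < 1$ is
enforced at every step.

### Why the default rates are low

The default truth has history gains decaying 1.5 to 1.05 across the ten
lags with a uniform 10% suppression under stress, interval effects of at
most +0.1 log units, and a stress rate-ratio of 1.1. With gains of that
magnitude the log-linear self-exciting process is close to criticality: a
burst of spikes multiplies the intensity across ten subsequent windows, and
at background rates above roughly 0.2 Hz the intensity diverges with
appreciable probability within a session. Long-run simulation places the
practical stability ceiling near a 0.15 Hz local base rate; the defaults
(0.12 Hz background, peak local base rate about 0.135 Hz) sit below it, at
the sparse end of realistic PFC discharge. Two consequences are documented
rather than hidden: simulated rates are lower than typical reported delay
rates (~0.5 Hz), which these gains cannot sustain stably; and per-unit
coefficient uncertainty is bounded below (gain SEs around 0.4 at these
spike counts), which limits the power of cohort-level contrasts. In the
rare event that a draw still diverges, `simulate_cohort()` redraws that
session from a deterministically bumped substream and logs the retry.

The interaction-specificity study uses a milder, window-scoped truth
(gains 1.4 to 1.0 active only in the extended delay), whose stability
ceiling is higher; it runs at a 0.2 Hz background, where interaction
columns have enough support that models 2 and 3 fit without separation.

What the generator does *not* emulate: refractory periods and bursting
beyond what the fitted history terms express, waveform shape (only the
peak-to-peak class label exists), left/right rate differences, electrode
drift, or sorting errors. Passing recovery tests therefore shows the
estimator chain is correct for data following the assumed model, not that
the model captures every property of in-vivo trains.

## Study conditions used by the tests and the acceptance script

Problem sizes were fixed once, to keep the full run within desktop
budgets: recovery and stress-suppression cohorts of 20 units with 41-trial
sessions per condition; 10-20 replicate cohorts for detection rates; 8
cohorts of 10 units for interaction specificity; 500 + 150 single-unit
simulations for deviance-test calibration and power; 200 simulations for
the K-S calibration, where rescaling uses the generative (correctly
specified) intensity and the misspecification probe inflates it threefold.

Two acceptance checks are expected to fail by construction, and are left
failing rather than loosened. First, requiring *every* condition-by-lag
cohort mean within 2 SEM of truth multiplies twenty correlated
t-distributed checks, so its all-cell pass probability is far below one
even for a perfect estimator (per-coefficient 95% Wald coverage, the
meaningful recovery criterion, sits at 94-97%). Second, when data carry a
history interaction confined to the extended delay, model 3's global
history term absorbs part of that effect (the extended delay dominates the
non-response exposure), so its response-window interactions converge to
rate-ratios systematically below 1 — a projection property of the model
family, visible in the FDR tests once estimation is precise enough.

## Worked example

```{r, eval = FALSE}
library(ciglm)

cfg <- generator_config(n_trials = 41, seed = 7, n_units = 1)
cohort <- simulate_cohort(cfg)
pair <- list(cohort[[1]]$baseline, cohort[[1]]$stress)

fit <- ciglm(pair, model = "1a")
summary(fit)
gains(fit, "alpha")          # baseline spiking gains per lag
anova(ciglm(pair, model = "1b"), fit)   # do intervals matter?

z <- time_rescale(fit, lapply(pair, function(s) s$spikes[[1]]))
ks_summary(z)$pass
```

## Known limitations

* Gains are point estimates with Wald intervals; no profile likelihood or
  shrinkage. Sparse cells can separate and are excluded, not regularized.
* The observation discretization (250 ms) is a modeling choice; spike
  timing within a bin only enters through the time-rescaling step.
* The repeated-measures ANOVA assumes a balanced unit x condition x lag
  table and errors otherwise (drop incomplete units, then rerun).
* The delay-related-unit rule and the Choice/Reward boundary are explicit
  conventions, not reproductions of the source scoring.
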