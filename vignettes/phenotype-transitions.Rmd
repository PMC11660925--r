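---
title: "Modelling multiple sclerosis phenotype transitions from registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multiple sclerosis phenotype transitions from registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`msphase` implements a complete analysis pipeline for longitudinal multiple
sclerosis (MS) registry data: a day-resolution phenotype classifier, a
continuous-time multi-state Markov model for phenotype transitions with
transition-specific covariate effects, the surrounding survival and
relapse-rate estimators, and a synthetic registry generator used to validate
all of it. This vignette is the package's methodological account: the models
and their assumptions, the tunable parameters and why their defaults are what
they are, the numerical choices, and what the validation does and does not
demonstrate.

## 1. The phenotype classifier

Registries record a physician-assigned date of conversion from
relapsing-remitting MS (RRMS) to secondary progressive MS (SPMS), together
with dated relapses. The operational split of the SPMS phase is
activity-based: on each day `t` of follow-up the patient is

* **RRMS** if `t` precedes the SPMS diagnosis date (or none exists);
* **rSPMS** (relapsing SPMS) if at least one relapse falls in the
  retrospective window `(t - W, t]` with `W = 730` days;
* **nrSPMS** otherwise.

Three conventions deserve comment.

*Window length.* Two years rather than the one-year activity window sometimes
recommended for the "active/non-active" modifier, because clinical visits in
a registry can be more than a year apart; a one-year window would reclassify
patients as non-relapsing merely for not having been seen.

*Window edges.* The window is half-open: a relapse on day `t` itself makes
day `t` relapsing, and an isolated relapse at day `r` keeps the patient
relapsing through day `r + 729`, so the first non-relapsing day is
`r + 730`. Relapses recorded before the SPMS diagnosis (and even before the
RRMS diagnosis — registries enter early history retrospectively) count toward
the window. These choices jointly reproduce the canonical worked example: a
patient diagnosed SPMS at day 0 with a relapse 100 days earlier is rSPMS
through day 629, nrSPMS from day 630, and rSPMS again from a new relapse at
day 6547 to the end of follow-up at day 6721. The tests pin this example
exactly.

*Implementation.* `classify_timeline()` is event-driven: each relapse at `r`
contributes the relapsing cover `[r, r + W - 1]`, covers are merged, and the
complement within the post-diagnosis span is non-relapsing. This is
`O(#relapses)` and is verified against a literal day-by-day evaluation of the
rule on hundreds of random patients.

Dates are integer day offsets from a fixed epoch (2000-01-01). Day
arithmetic avoids calendar ambiguity; durations become years by `/365.25`.

## 2. Panel construction

The Markov model consumes *panel data*: the state observed at discrete visit
times with unobserved transition times in between. The default observation
schedule for a patient is their EDSS visit days plus the RRMS and SPMS
diagnosis days — visits are when a registry actually observes a patient, and
including the diagnosis day guarantees an initial-state observation even for
patients whose first recorded visit is late. Death is appended as an exactly
observed final record, since registries register death dates exactly.

Covariates evaluated at each observation day:

| covariate | unit | notes |
|---|---|---|
| `sex_female` | 0/1 | fixed |
| `age` | years | anchored to age at onset |
| `hedmt_years`, `medmt_years` | years | cumulative time on high-/moderate-efficacy DMT |
| `edss` | 0–10 | last observation carried forward |
| `dx_year` | years since epoch | calendar year of RRMS diagnosis, fixed |
| `cum_relapses` | count | relapses since RRMS diagnosis (pre-diagnosis relapses excluded: the quantity is "since diagnosis", though they still count for the classifier window) |
| `disease_duration` | years | onset to RRMS diagnosis, fixed |

EDSS is carried forward indefinitely between visits, as in registry
practice. A day before the first EDSS visit takes the first subsequent score
if it is within 365 days; otherwise the patient cannot be covariate-complete
and is dropped from the Markov fit with a warning (the ids are reported).

Drug names map to efficacy classes case-insensitively: ten high-efficacy
agents (alemtuzumab, cladribine, daclizumab, fingolimod, natalizumab,
ocrelizumab, ofatumumab, ozanimod, rituximab, siponimod) and the
moderate-efficacy group (dimethyl fumarate, diroximel fumarate, glatiramer
acetate, the interferon-beta family matched by substring to absorb spelling
variants, teriflunomide). Anything else — registries contain non-DMT entries
— is kept but excluded from both exposure covariates. Overlapping episodes
of one class are merged before exposure is accumulated, so exposure is
piecewise-linear and never double-counted; overlapping episodes of
*different* classes accrue both exposures in parallel, since neither
dominates the other on record.

## 3. The multi-state model

Four states: RRMS, nrSPMS, rSPMS transient, Death absorbing. Allowed
instantaneous transitions: RRMS→nrSPMS, RRMS→rSPMS, nrSPMS↔rSPMS, and death
from every transient state. RRMS has no incoming transitions — an SPMS
assignment is never revoked. The SPMS sub-phenotypes may alternate freely,
which is exactly what the classifier produces as relapses occur and wash out
of the window.

Intensities are log-linear in covariates with transition-specific covariate
subsets: the two RRMS exit transitions carry the full set above; transitions
between the SPMS sub-phenotypes carry sex, age, the two DMT exposures and
EDSS (diagnosis-anchored covariates are not re-used there); death
transitions carry age and sex only, death being driven by demography at
these sample sizes. `exp(β)` is the hazard ratio per covariate unit for that
transition; time is measured in years so intensities are per-year and
effects are "per additional year/point/relapse".

The likelihood over an observation interval of length Δ with covariates `z`
(taken at the interval's *left* endpoint — the standard panel convention for
time-varying covariates, which makes the within-interval generator constant)
is the matrix exponential `P = exp(Q(z)Δ)` entry for the observed state
pair. An exactly observed death at the end of an interval contributes the
density `Σ_s P[s_i, s] · q_{s,Death}(z)` over transient `s`, not a panel
probability; non-death censoring needs no extra term because the last
observed state pair already is the panel likelihood.

### Numerics

* **Matrix exponential.** The likelihood core computes `exp(QΔ)` by
  *uniformization*: with `λ ≥ max_r |Q_rr|`, the matrix `M = I + Q/λ` is
  stochastic and `exp(QΔ) = Σ_k Pois(k; λΔ) M^k`. Every term is
  non-negative, so there is no cancellation, the Poisson tail bounds the
  truncation error below `1e-15` of total mass, and no eigendecomposition is
  assumed (a generator may be defective). Rate masses too large for the
  series (`λΔ > 500`, which only arises from extreme optimiser proposals)
  fall back to a scaling-and-squaring Padé exponential, and a failure there
  marks the likelihood `-Inf` so the optimiser backtracks. The user-facing
  `transition_probability()` uses the Padé routine directly.
* **Caching.** Transition-probability matrices are computed once per unique
  (covariate vector, interval length) combination per likelihood evaluation
  and shared across intervals — a large saving when covariates are piecewise
  constant.
* **Optimisation.** BFGS from crude-rate starting values: baseline
  log-intensity initialised at `log(jumps r→s / person-years in r)` (half a
  pseudo-jump for never-observed allowed transitions, which are also
  flagged), coefficients at zero. By default covariates are centred
  internally — a linear reparameterisation that changes neither coefficients
  nor hazard ratios but conditions the baseline/coefficient coupling (ages
  near 40 otherwise couple the intercepts to the age slopes badly); the
  reported baselines are mapped back to the uncentred scale
  (`control = list(center = FALSE)` disables this).
* **Covariance.** Inverse of the numerically differenced observed
  information at the optimum (central differences, step
  `1e-4 · max(1, |θ|)`), symmetrised; a singular information matrix falls
  back to the Moore–Penrose pseudo-inverse with a warning. 95% intervals use
  `z = 1.959964`.
* **Predicted probabilities.** Point estimates evaluate the fitted model;
  intervals are 2.5/97.5 percentiles of `n_draws = 100` multivariate-normal
  draws of the *full* parameter vector (baseline log-intensities *and*
  coefficients — drawing only the intensities would understate the
  uncertainty that the coefficients contribute), each propagated through the
  transition-probability map. Draws are seeded for reproducibility. A
  weakly identified transition can make the numerically differenced
  covariance indefinite; `ridge` (off by default) floors its eigenvalues,
  and draws that remain too extreme to propagate are dropped with a warning
  rather than silently distorting the percentiles.
* **Goodness of fit.** `expected_prevalence()` compares, on a time grid
  since first observation, the observed state distribution (state carried
  forward, death persisting, denominators restricted to patients under
  observation) with the average of model transition-probability rows along
  each patient's own covariate path.

## 4. The synthetic registry

Real MS registry microdata cannot be shared, so validation rests on a
generator with known ground truth, in two deliberately different modes.

**Mechanistic mode** (`simulate_cohort()`) builds the four registry tables
from processes a registry plausibly aggregates: relapses from a thinned
inhomogeneous Poisson process whose log-rate declines with age and disease
duration, differs by sex, drops under treatment and collapses (to a residual
15% by default — no published value exists for post-progression relapse
rates, so this is a documented free knob) after latent SPMS onset; a latent
EDSS that drifts upward (gamma increments, expectation 0.18/year, doubled
after SPMS onset) and is observed on the half-point grid at jittered
~annual visits; an SPMS-onset hazard log-linear in age and current EDSS; a
recorded SPMS diagnosis lagging latent onset by an exponential delay (mean 2
years — progression dates are recognised late, which is exactly the
under-diagnosis registries describe); alternating DMT episodes of the two
efficacy classes with occasional unclassifiable entries; and a competing
age-increasing death hazard with administrative censoring 22 years after
diagnosis. Defaults target the published cohort shape: 70% female, age at
onset 34.1 ± 9.2 years, an annualised pre-diagnosis relapse rate near 1.7,
roughly a third of patients converting by the end of follow-up, and a
roughly 3:1 nrSPMS:rSPMS split at diagnosis. These are calibration goals for
realism, not assertions the tests enforce.

This mode intentionally **violates** the Markov model (latent states, delays,
non-exponential sojourns), which is what makes it a fair end-to-end exercise
of classification, robustness and goodness of fit.

**CTMC mode** (`simulate_panel_ctmc()`) simulates exact continuous-time
Markov chain trajectories under a given intensity model — competing
exponential clocks within each segment of a piecewise-constant covariate
path — recorded only at scheduled observation days, with death recorded
exactly. Because the data-generating process *is* the inferential model,
parameter recovery is a sharp test: with 1000 patients observed annually
over 20 years under the four-state structure, every true baseline
log-intensity and coefficient is recovered within three estimated standard
errors, and pooled 95% Wald coverage over 50 scaled-down replicates lies in
the nominal range. What passing these tests does **not** show is robustness
to the ways real registries deviate (informative visit timing,
misclassified states, diagnostic delay); the mechanistic mode probes those
qualitatively, and the prevalence plots are the diagnostic a user should
look at on real data.

## 5. Supporting estimators

* **Aalen–Johansen / Kaplan–Meier** (via the `survival` package's
  counting-process machinery): cumulative incidence of each competing event
  — e.g. first SPMS classification split by sub-phenotype, with death
  competing — with survival-plus-incidence conservation holding to 1e-12.
  Ties between events and censorings resolve events-first.
* **Cox milestones**: Breslow-tie partial likelihood for time from MS onset
  to the first EDSS record at or above 3, 4 and 6, censored at SPMS
  diagnosis, adjusted for age at onset and sex. The first crossing is used
  unconfirmed — confirmed-progression logic is a different estimand and is
  deliberately not applied. Zero-variance covariates are reported as
  coefficient 0 with a warning rather than an error.
* **Poisson relapse rates**: log-link with log-exposure offset and
  HC0 sandwich variance; the intercept-only model reduces exactly to total
  events over total person-years.
* **GEE relapse trajectories**: relapses counted per integer year of age
  during the relapsing-remitting phase (onset to end of follow-up for
  never-SPMS patients; onset to *two years before* SPMS diagnosis otherwise,
  so the relapses that define the sub-phenotype labels cannot leak into the
  comparison), modelled with terms for age, sex, phenotype group and the
  group-by-age interaction. The estimating-equation solver is written in the
  package (no GEE solver ships with the environment's R): independence,
  exchangeable and unstructured working correlations, cluster-robust
  sandwich covariance, falling back from unstructured to exchangeable with a
  warning when unbalanced age bins leave correlation entries unestimable.
  The age effect is linear by default (`age_degree` raises the polynomial
  degree); the trajectory literature does not fix a functional form, so the
  degree is an explicit knob rather than a hidden choice.

## 6. The pipeline

`run_msphase()` chains the stages — load or simulate, classify, descriptive
tables, cumulative incidence, Cox milestones, relapse-rate models, Markov
fit, hazard-ratio and transition-probability tables, prevalence goodness of
fit — writing each artifact as CSV with a `MANIFEST.json` recording seed,
package version and a hash of the semantic configuration (output paths
excluded). Runs are deterministic given configuration and seed. A cohort
with too few SPMS patients skips the SPMS-specific stages with an explicit
notice instead of failing. Attrition is logged per stage (patients dropped
from the panel, never-observed transitions) because registry analyses live
or die by that accounting. Formatted tables use the field's reporting
conventions: hazard ratios as `1.044 (1.035–1.053)` at three decimals,
probabilities as percentages at one decimal, and covariates excluded from a
transition's model rendered as `not included`. No multiplicity adjustment is
applied anywhere, and p < 0.05 is the significance convention.

## 7. Problem sizes used in validation

The shipped validation uses: 200 random patients for the classifier-oracle
equivalence; 50 random three-state instances (ODE likelihood agreement to
1e-6) and exact two-state closed forms (1e-10); parameter recovery at
n = 1000 with 21 annual observations plus 50 coverage replicates at n = 150;
1000 randomised conservation instances; and two full pipeline runs at
n = 2000 for byte-identical determinism. The determinism runs use a reduced
per-transition covariate set and a capped optimiser iteration budget — the
property under test is reproducibility of the full artifact bundle, which is
configuration-conditional, not the asymptotics of the full covariate
specification (covered by the recovery tests above).

## 8. Known limitations

* The classifier trusts the physician's SPMS diagnosis date; diagnostic
  delay therefore propagates into every downstream analysis, exactly as it
  does in the source registries.
* No MRI activity: the relapsing/non-relapsing split is relapse-based only.
* The Markov model assumes exponential sojourns given covariates and
  left-endpoint-constant covariates within observation intervals; neither
  holds exactly in registry data (the prevalence diagnostic is the check).
* No hidden-Markov extension: state misclassification is not modelled.
* Cox milestone models use unconfirmed first EDSS crossings and no
  time-varying covariates.
* The proportional-hazards diagnostic provided (`survival`'s
  Schoenfeld-residual machinery via `cox.zph` on the returned fit) is a
  standard substitute for score-process-based checks, not a reimplementation
  of them.
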