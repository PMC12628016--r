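---
title: "Semantic foraging: models, scoring rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic foraging: models, scoring rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semforage)
```

## The scientific model

When people freely produce associations to an ambiguous cue word, their
retrieval alternates between *exploiting* one meaning of the cue (successive
responses from the same semantic patch: clustering) and *exploring* other
meanings (switching). Under the marginal value theorem (MVT) of optimal
foraging, the efficient moment to leave a patch is when the local return
rate falls to the environment-wide average: here, when the time to retrieve
the next within-cluster word reaches the individual's long-term average
inter-response time (IRT). `semforage` scores fluency logs against exactly
this yardstick and layers three analyses on top: adherence tests, brain
connectivity prediction of individual search phenotypes, and mediation of
brain–creativity relations through search behavior.

### Per-response measures

For responses ordered by rank within a (participant, cue) trial:

* **IRT** (spoken mode): onset of response *k* minus offset of response
  *k−1*; the first response of a cue has no IRT. In typed mode the raw IRT
  runs from the previous validation keypress (trial start for the first
  response) to the first keypress of the current word, and a thinking-time
  correction is added: measured typing duration minus the theoretical
  duration at the participant's fastest observed typing speed (computed on
  responses longer than four characters), floored at zero. The first typed
  response's IRT is computed but never enters transition-typed statistics,
  because the first response is neither clustering nor switching.
* **IRS**: cosine similarity between the embedding vectors of consecutive
  words; undefined when either word lacks a vector.
* **IRTr / IRSr**: the response's IRT (IRS) divided by the participant's
  mean IRT (IRS) for *that cue* — the per-cue marginal value. This makes the
  per-cue mean of IRTr exactly 1, a property the test suite asserts at
  1e−9. The grand long-term IRT (mean of the per-cue means) is reported
  descriptively and anchors the pre-switch gap.
* **Speed**: *fast* when IRTr < 1, *slow* when IRTr ≥ 1. The boundary case
  IRTr = 1 is classified slow so that the fast/slow partition is exhaustive;
  on continuous data the boundary has measure zero.
* **Positions**: around each switching response S, the up-to-two clustering
  responses before it are −2 and −1 and the up-to-two after it (before any
  further switch) are +1 and +2. A clustering response wedged between two
  switches one step apart legitimately serves as +1 for the earlier switch
  and −1 for the later one; both assignments are retained in the long
  position table, and the scalar per-response label prefers the pre-switch
  role. Position averages therefore match a per-switch reading of the
  design rather than an exclusive partition.

Aggregation always follows response → cue → participant: response-level
values are first averaged within a cue, cue means are then averaged per
participant, and tests run across participants. This ordering prevents
prolific cues from dominating participant summaries.

## Statistical machinery

**Signed-rank tests.** The paired Wilcoxon statistic is the positive rank
sum after dropping zero differences and midranking ties. For n ≤ 25 the
null distribution is computed exactly by convolution over all 2^n sign
assignments (midranks are doubled so the mass sits on integers); this is
algebraically identical to exhaustive enumeration and the tests verify the
equivalence for all n ≤ 10, ties included. Beyond the threshold a normal
approximation with continuity correction and tie-corrected variance is
used. Two-sided p is twice the smaller tail, capped at 1.

**Optimality regression.** OLS of fluency on the absolute pre-switch gap
|pre-switch IRT − long-term IRT|. R² is reported from the fit and equals
the squared Pearson correlation to 1e−10; a constant outcome is treated as
R² = 0 rather than NaN.

**IRT→IRS mixed model.** `irs ~ irt + response_index + (1|participant) +
(1|cue)` by REML (lme4), run separately for clustering and switching rows;
the response rank controls for time on task. "R²" is marginal
(fixed-effect variance over total). Singular fits fall back to a
fixed-effects OLS with a flag — with only a handful of cues the cue
intercept variance is often on the boundary, and the fallback keeps the
fixed-effect estimate interpretable.

**CPM.** Edge selection uses Pearson correlation (standard CPM practice for
continuous edge weights) at alpha = 0.01 per fold; prediction quality uses
Spearman's rho, which is robust to the monotone-but-nonlinear relation
cross-validated predictions often have with skewed count outcomes. One
combined OLS with positive strength, negative strength and the motion
covariate serves as the fold model; a fold that selects no edges predicts
from intercept + motion and is flagged. Only the strict upper triangle
defines edges; matrices are symmetrized by averaging when asymmetry is
below 1e−6 and rejected otherwise. The permutation p uses the
(1 + exceedances)/(n_perm + 1) estimator so it can never be exactly zero.

**Mediation.** Variables are z-scored once on the full sample; the
percentile bootstrap resamples the standardized rows (the standardization
is part of the estimand, not of the resampling). The percentile — not
bias-corrected — interval is used, matching the 2.5th/97.5th percentile
definition. The OLS identity c = c′ + a·b is asserted to 1e−10 on every
fit.

## The synthetic-cohort generator

No raw cohort accompanies the analysis, so validation rests on a generator
whose defaults emulate the study conditions: 86 participants, three
polysemous cues with five meanings each, one-minute spoken trials, 200-node
connectomes grouped into 17 networks.

**Foraging policy.** Within a cluster, the k-th retrieval time is lognormal
with arithmetic mean `mu_cluster * ramp^(k−1)` (lognormal because empirical
latencies are strictly positive and right-skewed; the ramp makes
within-patch retrieval slow down as the patch depletes). Before each
emission the agent draws the candidate time for the next within-cluster
item and compares it to the running mean of the IRTs it has emitted so far
— its causally available estimate of the long-term IRT, which converges to
the scored marginal value. If the candidate exceeds the running mean the
agent abandons the cluster: the long retrieval *is* the switch, emitted
with IRT = candidate + `switch_cost`. Two deviance channels break MVT
adherence: with probability `p_fast_switch` the agent switches although the
candidate was still below the running mean (emitted at the candidate time
with no switch cost, hence a genuinely fast switch), and with probability
`p_slow_cluster` it persists although the threshold was crossed (emitting a
slow clustering response). With both rates and the noise at zero, every
switch IRT exceeds the session mean and every clustering IRT falls below
it, so the scored ratios separate exactly at IRTr = 1 — the idealized MVT
pattern.

Within a cluster the agent retrieves the unused word most similar to its
previous response, so similarity decays as the patch depletes while
retrieval time ramps up; this builds the negative IRT→IRS coupling the
mixed model is designed to detect. Switches jump to a uniformly chosen
word of another meaning. Word offsets are onset + 0.4 s of articulation:
the IRT definition needs both ends of a response, but their separation is
irrelevant downstream.

**Default calibration.** The policy defaults (`mu_cluster` 2.1 s,
`switch_cost` 2.2 s, `ramp` 1.15, `p_fast_switch` 0.22, `p_slow_cluster`
0.55, `noise_sd` 0.55, 60 s trials) were chosen once so that scored
default cohorts land on the study's descriptive statistics — roughly
50/14/20/15% of Fast-Clustering / Fast-Switching / Slow-Clustering /
Slow-Switching responses, a fluency near 15 unique words per cue, and a
long-term IRT near 3.5 s. The ramp magnitude before a switch has no
published generative account, so `ramp` is a free parameter rather than a
fitted one. Connectivity defaults (40 planted edges per sign per phenotype,
effect 0.5 per standardized trait unit, background SD 0.1) give
cross-validated prediction strengths of the magnitude the brain analysis
reports (rho ≈ 0.2–0.4); the prediction ceiling is set by the
brain–behavior path (a ≈ 0.4), not by the edge noise.

**Mediation structure.** Sessions are simulated first; the realized, scored
Fast-Switching and Slow-Clustering counts are standardized; and the
planted-edge trait and creativity scores are then constructed as
`a_true·count + √(1−a_true²)·noise` and `b_true·count + √(1−b_true²)·noise`.
Anchoring the chain on the *measured* phenotype (rather than a latent
propensity that binomial session noise would attenuate) makes the
configured `a_true`/`b_true` the actual population paths of the observable
triple (network strength, count, creativity score), so parameter recovery
has a well-defined target. Policies still vary across participants through
latent deviance propensities, which is what gives the counts stable
individual differences. Each phenotype gets its own disjoint planted
network, mirroring the separate brain models for fast switching and slow
clustering. The creativity noise scale implies a behavior→creativity R² of
`b_true²` ≈ 0.1–0.25 at the defaults, the magnitude of the correlations
the behavioral literature reports.

**What the generator does not emulate.** Real lexical statistics and
polysemy structure (meanings are abstract vector clusters), BOLD
time-series and preprocessing artifacts (matrices are drawn directly),
response-onset measurement error, and semantic drift over the session.
Passing recovery tests therefore shows the *pipeline* is correct and
well-calibrated under the stated generative assumptions, not that those
assumptions exhaust real data.

## Deviance-rate recovery

Scored four-type proportions cannot estimate the deviance rates directly:
retrieval-time noise alone produces slow clustering responses (exactly as
real cohorts show ~20% slow clustering), so the proportion of slow
clustering does not vanish when `p_slow_cluster = 0`.
`estimate_deviance_rates()` instead reconstructs every switch/stay decision
from the scored sequence: the agent's running mean is recomputable from the
scored IRTs, a fast switch satisfies IRT ≤ running mean, and a slow switch
satisfies IRT > running mean + switch cost, so every opportunity and its
outcome can be classified exactly (values in the gap between the bounds
arise only from forced switches on patch exhaustion and are binned slow).
The resulting estimates are binomial around the true rates — including
exactly zero events at rate 0 — and the recovery suite checks the
{0, 0.1, 0.3} grid against 99% binomial intervals over 200 sessions.

## Numerical choices and degenerate inputs

* Seeds: every stochastic function takes an explicit integer seed and
  restores the caller's RNG state. `generate_cohort` draws its stage
  sub-seeds and all cohort-level noise from a single master stream —
  deriving many streams from affinely related seeds left detectable
  cross-stream correlations in recovery experiments, so sub-seeds are
  themselves random draws.
* IRSr is left undefined when a cue's marginal IRS is within 1e−6 of zero
  (the ratio would explode); empirical long-term IRS sits well away from
  zero.
* Zero paired differences are dropped before ranking; an all-zero
  difference vector raises a degenerate-test error rather than returning
  p = 1.
* Constant columns in the correlation battery yield NA correlations and
  are excluded from the FDR family instead of failing the whole battery.
* Bootstrap resamples with a constant variable are redrawn (at most 10
  times) before erroring.
* Edge correlations with zero variance are skipped during CPM selection;
  exact collinearity in mediation zeroes the aliased coefficient rather
  than propagating NA.

## Problem sizes used in the validation suite

The packaged tests run the recovery studies at sizes chosen to estimate
each property precisely while staying lightweight: 200 sessions per
deviance-rate grid point; 50 zero-noise participants for the exact
separation property; 200 null cohorts of 30 subjects × 20 nodes (199
permutations each) for the permutation-test calibration; and 100 cohorts of
300 participants (500 bootstrap resamples each) for mediation bias and
coverage. These sizes give Monte-Carlo standard errors a factor of several
below the asserted tolerances.

## Known limitations

* The running-mean marginal value is one defensible operationalization of
  the agent's threshold; the scored marginal value is the final per-cue
  mean, so early responses are classified against slightly more
  information than the agent had.
* The mixed model reports Wald z p-values for fixed effects; with few cues
  the cue variance component is weakly identified (hence the singular-fit
  fallback).
* Only the single-mediator model is implemented; multiple-mediator and
  sensitivity analyses are out of scope.
* LOO is the only cross-validation scheme (it is deterministic, so the
  reported rho comes from a single pass).

## A minimal end-to-end run

```{r, eval = FALSE}
cohort <- generate_cohort(cohort_config(n_participants = 20, n_nodes = 16),
                          seed = 1)
dir <- tempfile()
write_cohort(cohort, dir)
cfg <- pipeline_config(
  log = file.path(dir, "responses.tsv"),
  embeddings = file.path(dir, "embeddings.txt"),
  manifest = file.path(dir, "connectivity", "manifest.tsv"),
  node_labels = file.path(dir, "connectivity", "nodes.tsv"),
  covariates = file.path(dir, "covariates.tsv"),
  out_dir = file.path(dir, "out"), n_perm = 100, n_boot = 500, seed = 2,
  mediations = list(list(x = "strength_pos_n_fast_switching",
                         m = "n_fast_switching", y = "cat_cr")))
res <- run_pipeline(cfg)
```
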