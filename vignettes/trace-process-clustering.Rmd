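---
title: "From trace logs to weekly activity processes and actor clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From trace logs to weekly activity processes and actor clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Information systems such as learning platforms log every action their users
perform as *trace data*: rows of (actor id, date, target–action pair), e.g.
`submission>graded`. For knowledge workers whose tasks largely pass through
such a system, these by-product logs carry objective, continuously sampled
information about the *content* and *temporal rhythm* of their workload —
information that periodic surveys cannot provide. `traceproc` turns such a
log into:

1. actor–week **documents** (bags of target–action tokens with counts),
2. **topics** via latent Dirichlet allocation (LDA), selected by BIC,
3. **themes** — manually defined topic groups — and per-actor weekly theme
   **processes** $P_i(t)$ with activity counts $C_i(t)$,
4. a pairwise, activity-weighted Jensen–Shannon **dissimilarity**,
5. **clusters** of actors via complete-linkage agglomeration, and
6. cluster-level weekly summaries with **peak-week** detection.

Because real platform logs of this kind are typically confidential, the
package ships a seeded synthetic generator with planted cluster structure,
so that every stage can be exercised and validated end-to-end.

## Preprocessing

Two filters are applied, in a fixed order:

* **General-use removal.** Six target–action pairs reflect general use of
  the platform rather than a specific work task and are removed:
  `user>loggedin`, `user>loggedout`, `notification>sent`,
  `notification>viewed`, `course>viewed`, `course_module>viewed`.
* **Weekly activity threshold.** Actor-weeks with fewer than 25 recorded
  pairs are omitted entirely. The threshold is strict: 24 events are
  dropped, 25 are kept.

The order is deliberate: the threshold is applied *after* general-use
removal, so that it gates meaningful task activity rather than logins and
passive page views. Weeks follow ISO-8601 numbering (January-start academic
spring semesters map onto ISO weeks 1–22); both ISO (`2019-06-17`) and
day-first (`17.6.2019`) date dialects are read.

## Topic model

Documents are actor-weeks; the vocabulary is the set of surviving
target–action tokens. LDA is fit by batch variational Bayes with symmetric
Dirichlet priors $\alpha = \eta = 1/K$, all exposed as arguments. The
variational parameters for the topic–word distributions are initialized
from the pooled counts of a few randomly chosen documents plus Gamma noise;
document-seeded starts are far more reliable than pure-noise starts, and
the seed makes each fit a pure function of (corpus, seed,
hyperparameters).

Model selection fits every combination of a topic range (the canonical
full-scale choice is 10–20) and restart seeds `master_seed + 0..n_inits-1`
(canonically 50 restarts, interpreted per topic number), and scores each
fit with

$$\mathrm{BIC} = -2\,\hat\ell + k \ln n,$$

where $\hat\ell$ is the fit's evidence lower bound (the standard
variational likelihood proxy; labeled as such), $n$ is the total token
count, and $k = K(V-1)$ counts the topic–word parameters only. Counting
the per-document topic proportions as free parameters as well
(`bic_mode = "full"`, $k = K(V-1) + D(K-1)$) penalizes the document count
twice under the generative view in which the proportions are latent
per-document draws; the topic–word-only count is therefore the default,
and the alternative is one switch away. Selection is automatic min-BIC
(ties: fewer topics, then smaller seed); the report retains all candidates
sorted by BIC plus the selected model's top tokens so an analyst can
inspect and, if desired, pin a different topic number with
`force_n_topics` — mirroring workflows in which the final model is chosen
by manual inspection among low-BIC candidates.

## Themes and processes

A *theme map* is user configuration (YAML): named themes are lists of topic
indices, and unassigned topics fall into the catch-all `"Others"`. A
document's theme distribution is the sum of its topic probabilities within
each theme — exact mass conservation, and linear, so theme-aggregating a
mean equals averaging theme vectors. When the manual theme step is skipped
the identity map is used and flagged.

Each actor's process over a week window (default weeks 1–22, the spring
semester) is the pair $(P_i(t), C_i(t))$: the weekly theme distribution for
active weeks and the weekly event count, with $C_i(t) = 0$ and no $P$
defined for weeks without a surviving document. Weekly averages across
actors are unweighted over the actors active that week (an
activity-weighted alternative is available via `weighted = TRUE`; the
unweighted form is the default because the average should describe the
typical active actor, not the most active one).

## Dissimilarity

For two actors $i, j$:

$$d_{ij} = \sum_{t=1}^{T} w_{ij}(t)\,\mathrm{JS}\!\left(P_i(t)\,\|\,P_j(t)\right),
\qquad
w_{ij}(t) = \frac{C_i(t)\,C_j(t)}{\sum_{\tau=1}^{T} C_i(\tau)\,C_j(\tau)},$$

where $\mathrm{JS}$ is the Jensen–Shannon *distance* (square root of the
divergence). Weights make similarity depend mostly on the weeks where both
actors are highly active; weeks where either is inactive carry zero weight
and provably cannot influence the value.

Numerical and design choices:

* **Logarithm base 2**, so each weekly JS distance — and hence $d_{ij}$,
  a convex combination — lies in $[0, 1]$. Base $e$ is available
  (`log_base`); it rescales but never reorders single-week comparisons.
* **Square root by default** (the metric form of JS); the raw divergence is
  available for sensitivity analysis (`sqrt_js = FALSE`).
* **No epsilon smoothing**: JS is finite for zero probabilities, with the
  convention $0 \log 0 = 0$.
* **Pairs with no co-active week** are undefined under the formula. The
  default assigns the maximal dissimilarity 1 (such actors share no
  observed behavior) and records the pair; a `drop` mode excludes those
  actors before clustering instead.
* Although JS itself is a metric, the *weighted average* is not — the
  weights differ per pair. The test suite contains a constructed
  three-actor instance that violates the triangle inequality, documenting
  this deliberately.

## Clustering

Complete-linkage agglomeration runs on the precomputed matrix:
inter-cluster dissimilarity is the maximum pairwise value, which makes
merge heights non-decreasing for any input. The implementation uses the
Lance–Williams max-update with an explicit tie-break — among pairs at the
minimal dissimilarity, the lexicographically smallest pair of cluster
creation indices merges first (leaves in input order, then merge order) —
so results are bit-reproducible. The test suite checks it step-for-step
against a naive agglomerator that re-scans all pairwise maxima from the
original matrix, and against `stats::hclust` on tie-free inputs. The
result is an `hclust` object, so `stats::cutree` provides flat cuts by
count or height and `ape` exports Newick text.

The flat cut defaults to `k = 6` clusters, the canonical choice for this
analysis; a mean-silhouette-versus-k table is produced as a diagnostic but
never auto-selects, since no automatic criterion is part of the method.
Each spring window is clustered independently by default; a joint run can
concatenate windows into one longer week axis.

## Reporting and peak weeks

Cluster summaries are per-cluster, per-week unweighted means over active
actors (matching the "no data" treatment of fully inactive cluster-weeks;
an imputation switch is not provided because an inactive week carries no
theme information). A *peak week* of a theme group — e.g.
{Evaluation, Final grading} as the grading demand — is operationalized as
a strict interior local maximum of the group's share series with
prominence at least `min_prominence` (default 0.02 on the share scale):
$s(t) > s(t\pm1)$, endpoints never peaks, prominence measured against the
higher of the two minima separating the peak from the nearest higher
points or the series ends. The narrative notion — the climax of an
increasing trend after which activity decreases — has no canonical
formula; this rule is the package's operationalization, and a sensitivity
scan across thresholds is one call away (`min_prominence = 0`).

## The synthetic generator

The generator emulates the statistical structure the analysis assumes:

* **Scale defaults** mirror one real deployment: 423 actors over 90 weeks
  at about 288 events per actor-week (≈ 11 million rows), 6 planted
  clusters, 17 true topics, 6 themes. Tests use much smaller configs.
* **Counts**: actor-week task-event counts are negative binomial
  (default dispersion 2), since real weekly activity is strongly
  overdispersed and no distributional form is prescribed by the setting.
* **Tokens**: each cluster has piecewise-linear weekly theme-weight
  trajectories (normalized per week); a topic within a theme is uniform;
  tokens come from the topic's word distribution. The hierarchy is
  marginalized into one per-(cluster, week) token law — the identical
  distribution, drawn in a single multinomial sample per actor-week.
* **General-use events** are injected at a Poisson rate chosen so their
  expected share of the whole log equals `general_use_rate` (default 0.30,
  a realistic share for login/viewing noise). True topics place no mass on
  the six general-use tokens, so the removal filter's effect is exactly
  known.
* **Low-activity weeks**: with probability `low_activity_week_prob`
  (default 0.05) an actor-week's count is redrawn uniformly below the
  25-event threshold, exercising the filter.
* **Dates** are synthesized as Monday-plus-uniform-offset of each ISO week
  from ISO week 1 of the origin year, so the ingest module's date→week
  mapping round-trips exactly.
* Ground truth (cluster membership, true topic–word rows, trajectories,
  per-week drawn and injected counts) is emitted as a JSON sidecar, never
  embedded in the log.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: actors switching behavioral regime mid-window,
token vocabularies drifting over time, dependence between consecutive
weeks beyond the smooth trajectory, platform schema quirks, and
student-side activity. Recovery results on synthetic data are evidence of
implementation correctness, not of how cleanly real populations separate.

## Problem sizes used in validation

The test suite and the acceptance script validate on deliberately small
studies chosen to exercise every code path with known ground truth: JS
metric properties on 1,000 random distribution triples; brute-force
equality of the dissimilarity matrix on 20 random fixtures (≤ 10 actors,
≤ 30 weeks); naive-agglomerator equality up to 12 leaves including tie
cases; topic recovery on a 4-topic, 40-token corpus of 200 documents of
about 200 tokens (mean best-matched total-variation ≤ 0.15); min-BIC
selection over K = 2..8 with 5 restarts on the same corpus (10 replicate
master seeds); and full-pipeline recovery of 3 planted clusters of 10
actors over 22 weeks (adjusted Rand index ≥ 0.9 across 5 seeds).

## Known limitations

* The BIC uses a variational lower bound, not the marginal likelihood;
  comparisons across very different hyperparameters should be read with
  care.
* The dissimilarity is undefined for actor pairs with no co-active week;
  both fallbacks (maximal value, drop) are conventions, and sparse windows
  make the choice matter.
* Day-level dates mean sub-week ordering is unknown and is not modeled.
* Theme formation is manual by design; the package ships an example map
  (`inst/extdata/example_theme_map_17topics.yaml`) but cannot validate
  that a grouping is substantively meaningful.
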