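---
title: "Modelling proactive interference in the recent-probes task with the diffusion decision model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling proactive interference in the recent-probes task with the diffusion decision model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Proactive interference (PI) is the intrusion of previously learned, now
irrelevant information into current short-term memory retrieval. The
recent-probes task isolates it: participants hold a target set of four
lowercase consonants, and after a delay judge whether a probe consonant
belongs to it. Negative probes come in two kinds — *non-recent* negatives
absent from the current and the two preceding target sets, and *recent*
negatives that belonged to the immediately preceding target set. Recent
negatives are harder to reject: responses slow down and errors rise. The
question of interest is whether this PI cost grows with age, which has been
taken as evidence for declining inhibitory control in older adults.

Raw response times (RTs) and error rates answer that question ambiguously,
because group differences in speed, caution, and peripheral (encoding/motor)
time all contaminate RT differences. The diffusion decision model (DDM)
separates these contributions. Evidence accumulates noisily at drift rate
$v$ toward one of two boundaries a distance $a$ apart, starting from $z$;
crossing a boundary triggers the associated response after an additional
nondecision time $T_{er}$. The full model adds intertrial variability:
Gaussian drift variability $\eta$, a uniform starting-point range $s_z$ and
a uniform nondecision range $s_t$. The diffusion constant is fixed at
$s = 0.1$ and all times are in seconds, so the parameters live on the
conventional scale (drift rates around 0.2–0.4, boundaries around 0.15–0.25).

Under this lens the published finding this package re-implements is a null
result with teeth: the PI effect lives in the drift rate (recent negatives
are processed less efficiently), older adults show higher boundaries, longer
nondecision times and globally lower drifts — but the *PI-specific* drift
cost is the same in both age groups. The apparent age deficit in RT-based PI
scores is an artefact of the nonlinear mapping from drift to RT.

Because the original trial-level data are not publicly deposited, the
package validates the pipeline by simulation: known parameters in, the same
analysis chain, known parameters out (parameter recovery), which is the
standard validation strategy for sequential-sampling model software.

## Model variants

All six variants free the drift rate and its variability across the three
conditions; they differ in what else may vary and in the starting point:

| Model | free across conditions | starting point | free parameters |
|-------|------------------------|----------------|-----------------|
| 1 | $v, \eta$ | $z = a/2$ | 10 |
| 2 | $v, \eta, a, s_z$ | $z = a/2$ | 14 |
| 3 | $v, \eta, a, s_z, T_{er}, s_t$ | $z = a/2$ | 18 |
| 4 | $v, \eta$ | estimated, shared | 11 |
| 5 | $v, \eta, a, s_z$ | estimated, shared | 15 |
| 6 | $v, \eta, a, s_z, T_{er}, s_t$ | estimated, shared | 19 |

Response coding: the unbiased models (1–3) are accuracy-coded — the upper
boundary is the correct response and condition drifts are positive. The
biased models (4–6) are stimulus-coded: the upper boundary is the
*positive* ("probe present") response, negative-condition trials drift at
$-v_c$, and the shared estimated starting point expresses a response bias
toward "present" or "absent". For the biased models with per-condition
boundaries the shared start is parameterized as a fraction of the smallest
boundary separation, which keeps $0 < z < a_c$ for every condition. This
coding is the package's own convention; any defensible alternative changes
only the interpretation of $z$, not the likelihoods of the unbiased models.

## Likelihood machinery

The first-passage-time density uses the classical pair of series expansions
(small-time and large-time), switching adaptively to whichever needs fewer
terms at truncation tolerance $10^{-10}$. Gaussian drift variability is
integrated *analytically*: the drift-dependent factor of the density is
itself Gaussian in $v$, so the $\eta$-integral has a closed form — no
quadrature error on the hardest dimension. The uniform $s_z$ and $s_t$
integrals use fixed-order Gauss–Legendre quadrature, 11 nodes per dimension
by default. At the parameter scale of this task the likelihood of a
480-trial session changes by less than 0.002 log-units between 5 and 21
nodes, so the analysis scripts and the test suite fit with 5–7 nodes; the
default stays at 11. With all variabilities zero the full density collapses
exactly (bitwise) to the plain density.

Degenerate inputs are handled by flooring: any trial whose density falls
below $10^{-10}$ (outlier RTs, or RTs inside the nondecision support)
contributes $\log 10^{-10}$ rather than $-\infty$, keeping the simplex
search finite. RT cutoffs of 0.200 s and 7.000 s are applied before fitting,
and the number of trials actually fitted — not the pre-cutoff count — enters
the BIC.

## Estimation

Per participant and model, the log-likelihood is maximized by Nelder–Mead
simplex on an unconstrained transformed space: log for $a$ and $T_{er}$,
scaled logistic for $\eta$ (capped at 0.5), the bias fraction, $s_z$ (at
most 90% of the distance from the start to the nearer boundary) and $s_t$
(at most $2 T_{er}$). By construction the optimizer can never propose
$z \ge a$, a starting-point range poking outside the boundaries, or
$T_{er} < s_t/2$ — the bounds also pin the weakly identified variability
parameters, which are known to wander toward boundaries.

Starting values are moment-based (EZ-style closed forms mapping accuracy
and the mean and variance of correct RTs to $v$, $a$, $T_{er}$ per
condition, with accuracies of exactly 0, ½ or 1 clamped by a $1/(2n)$ edge
correction), averaged as the model's constraints require; variabilities
start at $\eta = 0.1$, $s_z = 0.02$, $s_t = 0.1$. The search runs up to
$400 \cdot \mathrm{dim}$ iterations per restart at relative tolerance
$10^{-6}$ — measured on this problem the 10-dimensional simplex needs
roughly 2200–2800 evaluations, so a smaller cap would routinely return
non-converged fits. The default five restarts jitter the transformed start
(SD 0.25); because the moment-based start is already in the right basin,
the analysis scripts use one or two restarts and the refits agree.

## Model selection and group statistics

Selection is by BIC, $-2\ln L + k \ln n$; per participant the lowest BIC
wins, exact ties break toward fewer parameters and then the lower model id
(logged whenever invoked), and participants with no converged fit are
excluded from the ranking rather than assigned infinite BIC.

The group layer mirrors the study's conventions: a classical mixed-design
ANOVA (condition within, age between) with partial $\eta^2$ per effect
against its own error stratum; Greenhouse–Geisser $\varepsilon$ is computed
and reported, but uncorrected degrees of freedom are primary, matching the
printed $F(2, 122)$ shape. The planned PI contrast is the per-participant
recent-minus-non-recent difference; its interaction with age is the
pooled-variance two-sample $t$ on those differences (reported with
$F = t^2$), and group comparisons of boundary separation and nondecision
time use the equal-variance $t$ with $n_1 + n_2 - 2$ degrees of freedom
(61 at the study's 25/38 group sizes). Welch corrections are deliberately
not applied, to match that convention.

## The synthetic-data generator

The generator emulates the study design exactly: sessions of 3 × 160 trials
with exact per-session counts (240/120/120), target sets of four consonants
from a 20-consonant pool, recent-negative probes drawn from the preceding
target set, non-recent negatives avoiding the two preceding sets. The
recency look-back is undefined at a session's start, so the first two trials
are drawn from the positive/non-recent conditions and the counts are
balanced over the remainder — totals stay exact. Trial order is randomized
uniformly subject to these constraints; the original study does not state
its randomization scheme.

Cohorts draw each participant's $v_c$, $a$, $T_{er}$ from normal
distributions centred on the published group means. The study prints group
standard errors, not SDs, so between-subject SDs default to
$SE \sqrt{n_{\text{group}}}$; draws violating parameter bounds are
resampled. No group values exist for the intertrial variabilities, so they
are fixed at $\eta = 0.1$ per condition, $s_z = 0.02$, $s_t = 0.1$ s —
mid-range values for this literature — and carry no between-subject
variation. These defaults are the study conditions of every simulation in
the package and are not tuned per analysis.

The trial simulator is Euler–Maruyama with step $10^{-4}$ s (halving the
step changes accuracy and mean RT by less than Monte-Carlo error at
$2\times10^4$ trials), per-trial draws of drift, start and nondecision
time, and an absorption cap of 10 s; non-absorbed paths are redrawn and
counted, with a warning above a 0.1% rate. Draws come sequentially from R's
global RNG, so a fixed seed reproduces a dataset exactly; datasets are not
order-independent across participants, which matters only for parallel
generation. Euler first-passage simulation has a small systematic bias
(missed within-step crossings, order $\sqrt{dt}$); the density-vs-simulator
tests allow for it explicitly with small absolute slack terms on top of the
binomial error bands.

What passing tests do *not* show about real data: the generator produces
stationary, exchangeable trials — no sequential effects, fatigue, practice,
block effects, fast guesses, or contaminant RTs — and its participants are
exactly DDM-generated. Recovery under these conditions demonstrates that
the estimation chain is correct, not that the DDM is the right model of any
particular human dataset.

## Validation design and problem sizes

Two study designs deserve explanation:

* **Recovery cohorts** simulate every participant *exactly at* the
  published group means (between-subject SD zero). The comparison of
  recovered group means against the published values then isolates
  estimator bias and variance; with the SE-derived dispersion included, the
  sampling noise of a small cohort's true mean would be confounded with
  estimation error. The test suite asserts recovery of the positive and
  recent-negative drifts within ±0.05, boundary separation within ±0.02 and
  nondecision time within ±0.03 for both groups, at 6 participants per
  group and 480 trials each.
* **Null-interaction cohorts** for the headline result set the older
  group's recent-negative drift so the generative PI-in-drift difference
  between groups is exactly zero, keep the between-subject dispersion, and
  ask how often the PI × age interaction on *recovered* drifts is declared
  significant. The suite runs 10 replicate cohorts of 4 + 4 participants
  and requires a non-significant interaction in at least 90% of them;
  nominal calibration of the same test is checked separately on 1000
  analytic null replicates.

Simulation sizes throughout (e.g. $8\,000$–$40\,000$ trials for
density-vs-simulator checks, 6–8 participants per group for fitted-cohort
checks) were fixed once from power and precision considerations: binomial
or DKW bands at those sizes are several times tighter than the asserted
tolerances. The acceptance script reruns the full chain — session
generation, density checks, recovery of both groups' parameters, Model 1
vs 4 selection, and the group statistics on a full-size 25/38 behavioral
cohort — from a single command-line seed.

## Known limitations

* Only the plain joint likelihood of (RT, response) is used; no
  down-weighting of sparse error cells. With accuracies near 0.99 the error
  side of the quantile-probability plot rests on few trials, and cells with
  fewer than five RTs are flagged unreliable rather than interpreted.
* The variability parameters $\eta$, $s_z$, $s_t$ are weakly identified at
  480 trials; their recovery is loose and their bounds are part of the
  estimator. Substantive conclusions should rest on $v$, $a$, $T_{er}$.
* The Bayesian model-averaged evidence for the absence of the interaction
  reported alongside the original ANOVA is prior-dependent and is
  deliberately out of scope; the package's statement of the null is the
  frequentist one.
* Hierarchical (joint across participants) estimation and alternative
  accumulator models are out of scope.
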