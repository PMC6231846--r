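---
title: "Selecting peer change agents on partially observed friendship networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting peer change agents on partially observed friendship networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcanet)
```

## The problem

Peer-driven health interventions (for example, promoting pre-exposure
prophylaxis among young Black men who have sex with men) recruit *peer
change agents* (PCAs): individuals in network positions from which
information diffuses widely. When the friendship network comes from the
online friend lists of a surveyed cohort, it is only partially observed:
friendships among the cohort ("respondents") and between respondents and
their friends ("nonrespondents") are seen, but friendships *between
nonrespondents* are not. Treating those unobserved dyads as absent biases
any centrality-based selection, because it systematically starves
nonrespondents of network position.

`pcanet` implements the full workflow for this setting:

1. **Boundary specification** — keep only nonrespondents with at least
   *k* observed respondent friendships;
2. **Dyad-model estimation** — fit a three-parameter exponential random
   graph model (ERGM) to the observed dyads;
3. **Multiple imputation** — draw *M* completed networks from the fitted
   model, holding observed dyads fixed;
4. **PCA selection** — eigenvector centrality and the keyplayer-positive
   set measure, on the observed network and on every imputed network, with
   a sufficiency cutoff defining the consensus ("sPCA") sets;
5. **Evaluation** — sensitivity, stability, algorithm overlap and
   boundary sensitivity of the selected sets.

## The dyad model

Every dyad of the bounded network is classified observed-present,
observed-absent, or unobserved (exactly the nonrespondent–nonrespondent
pairs). The imputation model for a tie between nodes $i$ and $j$ is

$$\operatorname{logit} P(Y_{ij} = 1) =
  \theta_{\text{edges}} + \theta_{\text{soc}} (c_i + c_j)
  + \theta_{\text{mix}} \, m_{ij},$$

where $c_i$ is node $i$'s *sociability* — its observed number of
respondent friends — and $m_{ij} = 1$ iff exactly one endpoint is a
respondent (*selective mixing*). The sociability term carries the observed
information into the unobserved quadrant: nonrespondents who are popular
with respondents are modelled as more social with each other too. The
mixing term absorbs the systematic density difference between the mixed
quadrant and the rest; because the boundary deliberately selects the most
respondent-connected nonrespondents, a positive $\theta_{\text{mix}}$
*dampens* the imputed nonrespondent–nonrespondent density below what
proportional scaling of their observed sociability would predict.

All three statistics are dyad-independent (sociability covariates are
frozen at their observed values — imputation never changes a degree with
respondents, so the covariate is well defined throughout). The ERGM
likelihood conditional on the observed dyads therefore factorises over
dyads, and `fit_dyad_model()` computes the exact MLE as a logistic
regression over observed dyads, with standard errors from the observed
information matrix. For the same reason, a draw from the fitted model
conditional on the observed data is an *independent Bernoulli* draw over
the unobserved dyads (`impute_ensemble()`); the constrained
Metropolis toggling sampler of the original procedure
(`toggling_sampler()`) has an identical stationary law and is retained
purely as a fidelity check, which the test suite exercises.

Model scope is deliberately dyad-independent: no triad-closure or shared-
partner terms (which are notoriously unstable on dense online friendship
networks at this scale), and no Bayesian estimation.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_respondent_friends` (k) | 30 | boundary threshold, in friendships with respondents |
| `M` | 100 | number of imputations; diagnosed by the max deviation of imputed edge counts (report `< 1.8%` of the mean as adequate) |
| `m` | 300 | PCA set size, ~8% of the target population in the motivating study |
| `kp_restarts` | 1 | keyplayer hill-climbing restarts (first is greedy seeding) |
| `kp_max_sweeps` | 10 | swap-improvement sweeps per restart |
| power-iteration `tol` | 1e-10 | relative-change stopping rule, capped at 10,000 iterations |

## Selection algorithms

**Eigenvector centrality** (`eigenvector_scores()`) is computed by power
iteration from a deterministic uniform start. The iteration runs on
$A + I$: the shift leaves the principal eigenvector unchanged while ruling
out the period-two oscillation possible on bipartite graphs. Scores are
normalised to unit Euclidean length; nodes outside the dominant component
decay to zero. A dense eigendecomposition serves as the independent oracle
in the tests (agreement below $10^{-8}$ on random graphs).

**Keyplayer-positive** (`kpp_select()`) maximises distance-weighted reach

$$D_R(S) = \frac{1}{n} \sum_{j \notin S} \frac{1}{d(S, j)},$$

with $d(S,j)$ the shortest-path distance to the nearest member and
$1/\infty = 0$. Members are excluded from the sum but included in $n$
(Borgatti's KPP-Pos convention). The published description of the measure
is verbal; this formula is the package's documented interpretation of it,
matching the reach criterion implemented by the R packages the field uses.
The optimiser is exact greedy seeding — implemented incrementally so an
~900-node network takes well under a second — followed by swap
hill-climbing (full neighbourhood scans on graphs up to 100 nodes,
seeded stochastic proposals above that). On small graphs the tests compare
it against exhaustive search over all $\binom{n}{m}$ sets.

**Aggregation.** Selecting $m$ nodes on each of $M$ imputed networks
yields per-node selection counts; the sufficiency cutoff is the threshold
$t$ whose set $\{v : \text{count}_v \ge t\}$ is closest in size to $m$,
with ties resolved toward the larger $t$ — the *smallest* such set. Ties
at the top-$m$ boundary of a score vector are broken lexicographically by
node id, so every selection is deterministic.

## The synthetic generator

No real friend-list data can ship with the package, so
`generator_config()` / `generate_dataset()` create cohorts with a known
ground truth, emulating the structure of the motivating study: 298
respondents, a nonrespondent pool trimmed by the k = 30 boundary to
roughly 587, respondent–respondent density near 7.4%,
respondent–nonrespondent density near 15.1%, and right-skewed degree
distributions.

Generation is sequential, each quadrant conditioning on covariates
realized before it, so that the observed quadrants follow the estimation
model:

1. respondent–respondent dyads are Bernoulli($p_{rr}$); realized
   respondent degrees become the respondent sociabilities;
2. nonrespondents draw gamma propensities on the expected-degree scale;
   respondent–nonrespondent dyads are Bernoulli with logit
   $\theta_e + \theta_s(c_r + \text{prop}_n) + \theta_m$;
3. nonrespondent–nonrespondent dyads use the *realized*
   degree-with-respondents, exactly matching the estimand of the
   imputation model (a `nn_covariate = "propensity"` toggle provides a
   misspecified variant for robustness experiments).

Because the nonrespondent covariate is the realized row sum of the very
dyads being modelled, the mean observed tie share of a nonrespondent with
degree $c$ is mechanically $c/n_{\text{resp}}$. A generator whose slope
disagrees with that mechanical logit slope at the operating density cannot
be recovered by the fit, no matter how much data. The default coefficients
are therefore *derived*, not hand-picked:
$\theta_{\text{soc}} = 1 / (n_{\text{resp}}\, \bar d\, (1-\bar d))$ — the
logit-scale slope of the mean mixed-quadrant density $\bar d = 0.151$ with
respect to one friendship — with $\theta_{\text{edges}}$ and
$\theta_{\text{mix}}$ then fixed by the two density targets
(`calibrated_theta()`). At the study scale this gives
$\theta = (-3.68,\ 0.026,\ 0.20)$. The propensity distribution
(gamma, shape 30, mean $0.146\,n_{\text{resp}}$) keeps the retained band
centred at that operating point with moderate spread and mild right skew;
under these conditions the fitted coefficients recover the truth within a
few standard errors, which the acceptance suite verifies over 20 seeded
replicates (each parameter within 3 SE in at least 90% of replicates).

**What the generator does not emulate.** The real cohort's nonrespondent
pool is enormous (hundreds of thousands) with a heavy-tailed boundary
table; the synthetic pool is a few hundred with a propensity band
concentrated near the boundary, because a heavy upper tail of
nonrespondent degrees makes the self-referential covariate bend away from
the logistic form and would turn parameter recovery into a
misspecification study. Consequences worth keeping in mind: the synthetic
boundary table is flatter than the study's, and observed-network PCAs are
dominated by respondents (there are few nonrespondent "hubs"), so the
*sensitivity* of both algorithms measured on synthetic cohorts is far
lower than the values reported for the real data. Passing tests show the
machinery is correct under the model, not that real Facebook cohorts
satisfy the model — in particular the generator, like the imputation
model, has no triadic closure.

## Numerical and design choices

* Node ids are opaque strings; all outputs are ordered lexicographically,
  and every random stage is seeded (imputation member *i* uses
  `seed + i`), which is what makes pipeline reruns byte-identical.
* Densities are proportions internally; percentages appear only in
  reports, rounded half-away-from-zero to one decimal.
* Edges between two nonrespondents in an input *partial* network are a
  validation error, not silently reclassified — the observation design
  makes them impossible.
* Degree histograms use half-open bins $[b, b + w)$ with $w = 10$ by
  default.
* The boundary threshold is an absolute count k; the percentage form
  (e.g. 10.1% of respondents) is derived output.
* Sensitivity denominators are the sPCA sets (the imputed side); the mode
  of a stability distribution breaks ties toward the smallest value.
* Boundary sensitivity is operationalised as the Jaccard overlap of sPCA
  sets between consecutive k values — an extension of the published
  minimum-degree observation, reported by `compare_boundaries()`.
* Separation (all observed dyads present or absent) and collinear designs
  raise classed errors rather than returning garbage coefficients.

## Problem sizes used by the tests

The unit suite runs on networks of tens of nodes; the acceptance suite
uses 20 study-scale replicates (298 respondents, pool 615) for parameter
recovery, 100 random graphs of up to 12 nodes for each selection oracle,
2,000 imputations of a 20-node fixture for the imputation law, and a
60/120-node end-to-end determinism check. The `analysis/` drivers run the
full study-scale pipeline (M = 100, both algorithms) in a few minutes.

## Known limitations

* The imputation model is dyad-independent by design; it cannot express
  triadic closure, which online friendship platforms actively promote.
* Proper multiple-imputation variance pooling is out of scope — point
  selections are aggregated, but no combined variance is reported.
* `kpp_select()` is a heuristic for an NP-hard problem; optimality is
  verified only on small graphs, and on large networks different seeds may
  return sets of marginally different fitness.
* Sensitivity/stability compare algorithms under the fitted model; they
  say nothing about which algorithm finds the *true* influencers, which is
  unknowable without intervention outcomes.
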