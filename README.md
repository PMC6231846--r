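# pcanet

Peer change agent (PCA) selection on partially observed friendship
networks.

Peer-driven health interventions recruit individuals whose network
position lets them diffuse information widely — for example, to promote
PrEP uptake among young Black men who have sex with men. When the
friendship network is compiled from the online friend lists of a surveyed
cohort, it is only *partially observed*: ties among respondents and
between respondents and their friends are seen, but every tie between two
nonrespondents is missing. Treating those dyads as absent starves
nonrespondents of network position and biases any centrality-based
selection. `pcanet` implements the model-based remedy end to end:

1. **Boundary specification** — retain nonrespondents with at least `k`
   observed respondent friendships (`apply_boundary()`,
   `boundary_table()`);
2. **Dyad-model estimation** — exact ML fit of a dyad-independent ERGM
   over the observed dyads (`fit_dyad_model()`),

   `logit P(Y_ij = 1) = θ_edges + θ_soc (c_i + c_j) + θ_mix m_ij`,

   where `c_i` is the node's *sociability* (observed degree with
   respondents) and `m_ij` flags mixed respondent–nonrespondent dyads;
3. **Multiple imputation** — `M` completed networks drawn from the fitted
   model with observed dyads held fixed (`impute_ensemble()`, with a
   Metropolis `toggling_sampler()` equivalence check);
4. **Selection** — eigenvector centrality (`eigenvector_scores()`) and
   keyplayer-positive distance-weighted reach (`kpp_select()`) on the
   observed network and on every imputed network, aggregated through a
   sufficiency cutoff into consensus "sPCA" sets (`select_pcas()`);
5. **Evaluation** — sensitivity, stability, algorithm overlap and
   boundary sensitivity (`evaluation_report()`, `compare_boundaries()`).

A seeded synthetic-cohort generator with known ground truth
(`generator_config()`, `generate_dataset()`) makes the whole pipeline
testable without access to any private social-media data.

## Worked example

Simulate a study-scale cohort (298 respondents; a nonrespondent pool of
whom ~580 survive the 30-friend boundary), fit the dyad model, impute and
select:

```r
library(pcanet)

cfg <- generator_config(seed = 42)         # θ = (-3.68, 0.026, 0.20)
d   <- generate_dataset(cfg)
quadrant_summary(d$network)
#> Quadrant summary: 298 respondents, 581 nonrespondents
#>   RR edges 3340 (density 7.5%), RN edges 27029 (density 15.6%)
#>   unobserved NN dyads: 168490
#>   mean degrees: respondent 113.1 (RR 22.4, RN 90.7), nonrespondent observed 46.5

fit <- fit_dyad_model(build_dyad_design(d$network))
fit
#> Dyad-independent ERGM fit (logistic MLE over observed dyads)
#>   edges         -3.668 (SE 0.0317)
#>   sociability   0.0257 (SE 0.0005694)
#>   mixing         0.185 (SE 0.02399)
#>   observed dyads: 217391

ens <- impute_ensemble(d$network, fit, M = 100, seed = 1042)
imputation_diagnostics(ens)$mean_imputed_nn_density   # ~0.22
res <- select_pcas(d$network, ens,
                   selection_config(m = 300, algorithm = "eigenvector"))
res
#> selection_result (eigenvector, m = 300, M = 100)
#>   observed PCAs: 300 (11.7% nonrespondent)
#>   sufficiency cutoff: selected on >= 48 networks -> 300 sPCAs (100.0% nonrespondent)
```

The fitted coefficients recover the generator's ground truth within one
standard error each, the negative edges / positive sociability / positive
mixing sign pattern matches the published fit for the real cohort, and the
imputed nonrespondent–nonrespondent density (~22%) exceeds both observed
quadrant densities, as the degree-based boundary predicts. Evaluating the
selection (`evaluation_report(res, d$network, k = 30)`) shows the
signature behaviour of the two algorithms: keyplayer selects nonrespondent
sPCAs right down at the boundary minimum (sociability 30), eigenvector
stays well above it (44), and eigenvector's sPCA sets are markedly more
stable across boundary choices.

The `analysis/` directory contains the same workflow as numbered drivers
(`01_simulate.R` … `05_boundary_sensitivity.R`) that narrate what they
find and write their tables under `results/analysis/`.

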