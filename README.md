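# dccmst

Time-varying brain network analysis: DCC-GARCH dynamic connectivity,
per-timepoint minimum spanning trees, and covariate-adjusted group
inference.

## What it is for

Functional coupling between cortical regions fluctuates over a
resting-state scan, and the *dynamics* of network topology — not just its
average — differ between clinical groups. `dccmst` implements a complete
pipeline for that question, aimed at researchers analysing extracted ROI
time series (e.g. from a default mode network parcellation):

1. **Dynamic connectivity.** Each demeaned ROI pair
   $y_t$ (2×T) is modelled with the bivariate dynamic conditional
   correlation (DCC) GARCH model:

   $$\sigma_{i,t}^2 = \omega_i + \alpha_i y_{i,t-1}^2 + \beta_i\sigma_{i,t-1}^2,
     \qquad \varepsilon_t = D_t^{-1} y_t,$$
   $$Q_t = (1-\theta_1-\theta_2)\bar Q + \theta_1 \varepsilon_{t-1}\varepsilon_{t-1}'
     + \theta_2 Q_{t-1}, \qquad
     R_t = \mathrm{diag}\{Q_t\}^{-1/2} Q_t\, \mathrm{diag}\{Q_t\}^{-1/2},$$

   estimated by two-stage Gaussian quasi-maximum likelihood. Unlike
   sliding windows there is no window length to pick, and a correlation is
   produced at every repetition time.
2. **Minimum spanning trees.** At each time point, edge weights are the
   reciprocals of connection strength and Kruskal's algorithm extracts the
   binarized MST — the strongest-connection backbone, free of the
   density-threshold problem of dense graph analysis.
3. **Tree parameters and summaries.** Twelve node- and network-level
   parameters per tree (degree, betweenness, eccentricity, leaf fraction,
   diameter, global efficiency, characteristic path length, degree
   divergence, tree hierarchy, ...), each reduced to a per-subject temporal
   mean and temporal variance.
4. **Inference.** Covariate-adjusted (age, IQ, motion, sex, site) group
   contrasts with Benjamini–Hochberg FDR over node-level families, and
   covariate-adjusted partial correlations with ADOS symptom-severity
   scales.

A synthetic cohort generator (`simulate_dcc_cohort()`) draws multivariate
DCC-GARCH processes with configurable group effects and symptom couplings,
so every stage can be validated against known ground truth. The 18-ROI DMN
parcellation (PCC–aMPFC core, dMPFC and MTL subsystems, 10 mm spheres)
ships as a fixture:

```r
library(dccmst)
load_dmn_parcellation()[1:3, c("index", "abbrev", "subsystem", "mni_x", "mni_y", "mni_z")]
#>   index abbrev subsystem mni_x mni_y mni_z
#> 1     1  aMPFC      core    -6    52    -2
#> 2     2    PCC      core    -8   -56    26
#> 3     3  dMPFC     dMPFC     0    52    26
```

## Worked example

Simulate a small two-group cohort (5 patients + 5 controls, 6 nodes,
T = 300) and push one subject through the stack:

```r
library(dccmst)

spec <- cohort_spec(n_per_group = c(ASD = 5, TD = 5), n_nodes = 6,
                    t_len = 300, seed = 42)
sim <- simulate_dcc_cohort(spec)

ts1 <- sim$series[[1]]
ts1
#> Subject 'sub001': 6 ROIs x 300 time points (tr = 2s, raw)

fit_garch(demean(ts1$data[1, ]))
#> GARCH(1,1) Gaussian QML fit
#>  omega  alpha   beta
#> 0.1737 0.0433 0.8133
#> logLik -455.654 on 300 obs; unconditional var 1.211

conn <- connectivity_tensor(ts1)
conn
#> Dynamic connectivity for 'sub001': 6 x 6 x 300 tensor
#>   15/15 pair fits converged

tree_series(conn)
#> Tree series for 'sub001': 300 trees on 6 nodes
```

The GARCH coefficients sit near the generator's truth
(ω, α, β) = (0.1, 0.1, 0.8); all 15 pairwise correlation-stage fits
converge, and each of the 300 connectivity matrices yields one spanning
tree with exactly 5 edges. Summarize everyone and run the group analysis:

```r
su <- cohort_summaries(lapply(sim$series, summarize_subject))
res <- run_full_analysis(sim$cohort, su)
res
#> MST cohort analysis (10 subjects in design, alpha = 0.05)
#>   group differences: 9 on temporal means, 3 on temporal variances (unadjusted p)
#>   ADOS correlation rows: 108 (means) + 108 (variances)

res$group_mean[res$group_mean$metric == "global_efficiency", ]
#>              metric summary_kind    mean_sd_group1    mean_sd_group2     t      p
#> 6 global_efficiency         mean 0.6073 ± 0.005642 0.6569 ± 0.009673 -4.11 0.0545
```

The patient-like group was generated with long-run correlations scaled to
half and a more volatile correlation recursion; accordingly its temporal
mean of global efficiency is lower (0.607 vs 0.657, t = −4.1) — at n = 5
per group with six covariates this sits just above the 0.05 threshold, as
expected at toy size. `run_pipeline(pipeline_config(...))` wraps the whole
chain (simulate or load → connectivity → trees → summaries → statistics)
with per-stage caching and a JSON manifest.

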