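---
title: "Dynamic tree networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic tree networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dccmst)
```

# The problem

Static functional connectivity compresses an entire resting-state scan into
one correlation per region pair, discarding the fact that coupling between
cortical regions fluctuates over the scan. `dccmst` analyses that temporal
structure in three layers:

1. **Time-resolved connectivity.** Every pair of region-of-interest (ROI)
   signals is modelled with the bivariate dynamic conditional correlation
   (DCC) GARCH model, giving a correlation estimate at every repetition
   time rather than per sliding window.
2. **Tree topology.** At each time point the connectivity matrix is turned
   into a minimum spanning tree (MST): the acyclic backbone of strongest
   connections. MSTs avoid the arbitrary threshold that plagues dense graph
   analyses — every network has exactly $N-1$ binary edges, so parameters
   are comparable across subjects and time.
3. **Temporal summaries and inference.** Twelve tree parameters are tracked
   over time, reduced to per-subject temporal means and variances, and
   compared across groups (and against symptom severity) with
   covariate-adjusted linear models and Benjamini–Hochberg FDR control.

The packaged parcellation is an 18-ROI default mode network (DMN)
definition — PCC–aMPFC core, dMPFC subsystem, MTL subsystem — with 10 mm
spherical ROIs at fixed MNI coordinates (`load_dmn_parcellation()`).

# The connectivity model

For a demeaned pair of signals $y_t = (y_{1,t}, y_{2,t})'$:

$$\sigma_{i,t}^2 = \omega_i + \alpha_i y_{i,t-1}^2 + \beta_i \sigma_{i,t-1}^2$$
$$D_t = \mathrm{diag}\{\sigma_{1,t}, \sigma_{2,t}\}, \qquad
  \varepsilon_t = D_t^{-1} y_t$$
$$Q_t = (1-\theta_1-\theta_2)\,\bar Q + \theta_1\,
  \varepsilon_{t-1}\varepsilon_{t-1}' + \theta_2\, Q_{t-1}, \qquad
  \bar Q = \tfrac1T \textstyle\sum_t \varepsilon_t \varepsilon_t'$$
$$R_t = \mathrm{diag}\{Q_t\}^{-1/2}\, Q_t\, \mathrm{diag}\{Q_t\}^{-1/2}$$

Estimation is the standard two-stage Gaussian quasi-maximum likelihood:
stage 1 fits GARCH(1,1) per series (`fit_garch()`), stage 2 maximizes the
correlation-stage quasi-likelihood over $(\theta_1, \theta_2)$ per pair
(`fit_dcc_pair()`). Constraints ($\omega > 0$; $\alpha, \beta \ge 0$,
$\alpha + \beta < 1$; $\theta_1, \theta_2 \ge 0$, $\theta_1 + \theta_2 < 1$)
are enforced by a log/softmax reparameterization, so the optimizer
(Nelder–Mead, objective tolerance `reltol = 1e-8`) is unconstrained.
`connectivity_tensor()` runs both stages over all $N(N-1)/2$ pairs and
returns the $N \times N \times T$ tensor plus a per-series / per-pair
convergence report.

## Numerical choices

* **Initialization.** $\sigma_1^2$ is the sample variance; $Q_1 = \bar Q$.
  Both recursions therefore start at their stationary targets.
* **Multi-start.** Three fixed starting points per stage (configurable via
  `starts`). Among optima whose objectives differ by less than 1 — a
  negligible amount on the quasi-log-likelihood scale — the solution
  farthest from the persistence boundary is preferred. This matters on the
  $\alpha \approx 0$ ridge (e.g. white-noise input), where boundary
  solutions with $\beta \to 1$ fit equally well but leave the stationary
  variance $\omega/(1-\alpha-\beta)$ ill-conditioned.
* **Boundary and failure handling.** Solutions with
  $\hat\alpha + \hat\beta$ (or $\hat\theta_1 + \hat\theta_2$) within
  tolerance of 1 are flagged `boundary`; a pair whose correlation stage
  fails entirely falls back to its constant rescaled $\bar Q$ correlation
  with `converged = FALSE`, keeping the tensor complete but visible in the
  fit report.
* **Degenerate input.** Series with variance below $10^{-12}$ are rejected
  outright rather than fitted.
* $|r_t| \le 1$ holds by construction: every $Q_t$ is a nonnegative
  combination of positive semi-definite matrices.
* **Hot loops.** The $O(T)$ variance/correlation recursions and their
  likelihoods are implemented in C++ (Rcpp); everything else is plain R.

# Trees and their parameters

Edge weight is the reciprocal of connection strength — the cost of
information exchange. The default mode takes $w_{ij} = 1/|c_{ij}|$: the
literal signed reciprocal would rank strong *negative* correlations as the
cheapest edges of all, contradicting the idea that the tree collects the
strongest connections. The signed variant remains available
(`mode = "signed_reciprocal"`) for exact-literal replication; near-zero
correlations are capped at $10^{12}$ so arithmetic stays finite.

`kruskal_mst()` implements Kruskal's algorithm with union–find and a
deterministic `(weight, i, j)` lexicographic tie-break, so equal-weight
inputs give the same tree on every platform. Trees are binarized; all
distances are hop counts.

Per tree, `node_metrics()` / `tree_metrics()` compute: degree $k_i$ and
maximum degree $K$; leaf number $L$ and leaf fraction $L/(N-1)$;
betweenness centrality $BC_i$ and its maximum $BC$; eccentricity
$ecc_i$; diameter $D$; global efficiency $E$ (mean of $1/d_{ij}$ over
pairs); characteristic path length (mean of $d_{ij}$); degree divergence
$\kappa = \langle k^2\rangle / \langle k \rangle$; and tree hierarchy
$T_h = L / (2 M \cdot BC)$ with $M = N - 1$ edges.

Two definitional points deserve emphasis:

* **Betweenness normalization.** $BC_i$ counts the unordered node pairs
  (both distinct from $i$) whose unique tree path passes through $i$,
  divided by $(N-1)(N-2)/2$. This is the normalization under which a star's
  hub scores exactly 1 — the anchor the field uses for this statistic. The
  superficially natural denominator $\binom{N}{2}$ is inconsistent with
  that anchor and is not used.
* **Assortativity.** Computed as the Pearson correlation over the $2(N-1)$
  directed edge-endpoint degree pairs. Under this formulation a star is
  maximally disassortative ($R = -1$), and the value is undefined only
  when endpoint degrees are constant (two-node trees); undefined values are
  recorded as missing — never coerced to zero — and excluded from temporal
  summaries with the retained count reported in `n_used`.

The two symbols the literature overloads are disambiguated here as
`leaf_number` vs `char_path_length`.

`temporal_summaries()` reduces each parameter's time course to its temporal
mean and temporal variance. The variance estimator is the $n-1$ sample
variance by default, with a `"population"` switch, since the choice is not
canonical in this literature.

# The synthetic cohort generator

`simulate_dcc_cohort()` inverts the estimation model: per subject it draws
an $N$-dimensional series whose conditional variances follow GARCH(1,1)
and whose correlation matrix follows the matrix DCC recursion around a
subject-specific long-run matrix $\bar Q$, with Gaussian innovations
(Student-$t$, df 5, available for robustness experiments). One coherent
multivariate process is generated per subject — not independent bivariate
processes — so that the pairwise estimator downstream faces the same
misspecification it faces on real data. The recursion starts at $\bar Q$
and a 200-sample burn-in is discarded.

Default study conditions (all overridable in `cohort_spec()`):

* GARCH $(\omega, \alpha, \beta) = (0.1, 0.1, 0.8)$ per node — persistent,
  unit stationary variance; DCC $(\theta_1, \theta_2) = (0.05, 0.85)$.
  $\theta_2 = 0.85$ (rather than 0.90) leaves room for the patient group's
  $\theta_1$ shift of $+0.05$ without violating
  $\theta_1 + \theta_2 < 1$.
* **Hub-structured $\bar Q$**: node 1 correlates 0.6 with every other
  node, all other pairs 0.25. A flat (exchangeable) $\bar Q$ would make
  tree topology invariant to uniform rescaling of the correlations — the
  weight *ranks* would not change — which is both unrealistic (resting-state
  networks have core hubs) and uninformative for group effects. With a hub
  backbone, weakening the long-run structure pushes trees away from the
  star-like backbone and makes them noisier over time, so the patient-like
  group shows lower temporal-mean and higher temporal-variance global
  efficiency — the qualitative regime of interest. An exchangeable option
  is retained.
* **Group effects**: patient-group off-diagonals scaled by 0.5 (lower mean
  connectivity) and $\theta_1$ shifted by $+0.05$ (more volatile
  connectivity). These effect sizes are calibration choices, labelled as
  such, since no effect-size scale is available a priori.
* **Between-subject variability**: each subject's off-diagonal scale gets
  log-normal jitter (sd 0.1 on the log scale) around a base scale of 0.9,
  clipped to $(0.05, 1]$ to preserve positive definiteness. Without
  between-subject variation, symptom couplings would have no variance to
  correlate with.
* **Phenotypes**: age $\sim N(16, 6)$ years clipped to 6–45, IQ
  $\sim N(108, 13)$ clipped to 76–150, mean FD $\sim N(0.09, 0.04)$ mm
  clipped below 0.2, percent FD below 25, 85% male, sites assigned
  round-robin — values chosen to resemble a multi-site developmental
  resting-state cohort after quality control.
* **ADOS scores** (patient group only): communication and social scores are
  linear in the subject's realized time-averaged connectivity of a chosen
  node plus Gaussian noise, truncated to non-negative integers; total is
  their sum. Coupling coefficient 0 (the default) makes the scores pure
  noise.

What the generator does *not* emulate: hemodynamics, head motion,
physiological noise, scanner artifacts, or spatial structure beyond the
hub. Passing recovery and calibration tests on this generator demonstrates
that the estimator and inference chain are correct under the model's own
assumptions — not that real fMRI obeys those assumptions.

# Inference layer

"Controlling for" confounds is implemented as a single linear model
`summary ~ group + age + IQ + meanFD + percentFD + sex + site` with the
group coefficient's two-sided $t$-test — the conventional estimator, which
reduces exactly to the pooled two-sample $t$-test when no covariates are
given. Sites are reference-coded against the largest site; single-site
cohorts drop the site columns with a warning; rank deficiency is an error
naming the collinear columns.

Symptom correlations residualize both the summary statistic and the ADOS
score on the covariates (patient group only, complete cases required) and
assess the residual Pearson correlation with
$t = r\sqrt{df/(1-r^2)}$, $df = n - 2 - k$.

The FDR family is, by default, one node-level parameter type crossed with
one summary kind across the $N$ nodes (e.g. variance of eccentricity over
18 ROIs); network-level parameters are unadjusted. A `"global"` family
option pools every parameter of a summary kind instead. Correlations are
computed for *all* parameters, not only those with significant group
differences — group significance and predictive value are different
questions.

# Validation strategy and problem sizes

The test suite validates each layer against an independent oracle:

* Kruskal vs exhaustive enumeration of all $n^{n-2}$ labelled trees
  (Prüfer sequences) on 100 random weight matrices, $n \le 7$;
* tree metrics vs Floyd–Warshall distances and the
  $d(s,v)+d(v,t)=d(s,t)$ path-membership criterion on 100 random trees;
* closed-form star/path values on 18 nodes (hub betweenness 1, path leaf
  count 2, $E = 85/153$, etc.);
* estimator recovery: $(\theta_1, \theta_2) = (0.05, 0.90)$ at $T = 4000$
  over 20 seeds (median error bounds 0.05 / 0.10), GARCH truth within
  $\pm 0.1$ at $T = 5000$;
* statistical calibration on 50 null cohorts of 10+10 subjects, $N = 6$
  nodes, $T = 300$ — sizes chosen so the full pipeline run completes in a
  few minutes while keeping the binomial check on the 5% rejection rate
  meaningful. Power at $n = 40$/group is assessed by resampling subjects
  from the pooled null-pipeline summaries and injecting a 1-SD shift into
  the patient group: the summary distribution is the pipeline's own, and
  only the test stage needs replication at the larger $n$.
* direction recovery: 20 cohorts under the default group effects must show
  the lower-mean / higher-variance global-efficiency pattern in at least
  80% of replicates.

# Known limitations

* The estimator is strictly pairwise; a joint $N$-dimensional DCC fit
  (with a single shared $\theta$) is out of scope, as are sliding-window
  methods.
* $\bar Q$ is computed from stage-1 standardized residuals before stage 2
  — the standard two-stage convention; alternatives (e.g. iterated
  re-estimation) are not provided.
* Tree parameters are computed on binarized trees only; weighted-distance
  variants are deliberately excluded.
* The inferential layer assumes Gaussian-ish summary distributions; no
  permutation alternative is implemented.
* Group comparisons on real multi-site data depend on site coding and FDR
  family choices; both are exposed in the configuration precisely because
  no single convention can be recovered from summary tables alone.
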