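# metabodyn

Analysis toolkit for **time-resolved challenge metabolomics**: studies in
which a small, homogeneous cohort is sampled densely — dozens of time points
over multi-day blocks — before, during and after standardized physiological
challenges (extended fasting, oral glucose and lipid tolerance tests,
mixed-meal drinks, exercise, cold stress), and metabolite levels are measured
in plasma and urine on several platforms. The package is aimed at researchers
who need the full computational pipeline behind such a resource as tested,
scriptable functions rather than a web GUI.

It implements, end to end:

* **Data model** — a long-format profile dataset keyed by (subject, time
  point, platform-qualified metabolite uid) with missing = absent key, plus a
  study-design object carrying per-block clock times and challenge windows.
  A built-in two-block design with 56 plasma / 16 urine time points and eight
  challenge windows ships as `build_schedule("challenge56")`; any design can
  be supplied as JSON.
* **Curation & preprocessing** — log2 transform; the mean ± 4 SD per-(metabolite,
  time point) outlier rule with a 30-min challenge-onset exemption;
  strict <30% missingness filtering; block-wise linear and
  correlation-preselected KNN imputation; z-score and fold-change transforms.
* **Trajectory similarity** — a time-banded discrete Fréchet distance
  (points may only couple within ±30 min, widened to ±120 min during extended
  fasting), plus Euclidean/Manhattan/Pearson, with per-subject and
  mean-trajectory aggregation and ranked search.
* **Challenge statistics** — paired t-tests of each tested time point against
  the challenge baseline with a *reactive* Bonferroni threshold
  `0.05 / (n_metabolites × n_timepoints)` and Benjamini–Hochberg control;
  Hedges-corrected effect sizes `d·(n−2)/(n−1.25)`; exact noncentral-t
  sample-size calculation.
* **Longitudinal Gaussian graphical models** — dynamical (trapezoid
  time-weighted) correlations pooled over subjects, Schäfer–Strimmer-type
  shrinkage toward the identity, partial correlations
  `−Ω_ij/√(Ω_ii Ω_jj)`, edge significance under the null density
  `f0(r;κ) ∝ (1−r²)^((κ−3)/2)` with a Pearson co-significance gate,
  fixed-cutoff networks, and multi-fluid merging with same-metabolite edges.
* **Network validation** — pathway (reaction-step) distances of network edges
  on a reference compound graph and a 1,000-network node-relabeling bootstrap
  with add-one empirical p-values.
* **Synthetic study generator** — kinetic templates (washout, postprandial,
  fasting ramp, circadian, flat), latent AR(1) module structure,
  detection-limit censoring, MCAR missingness, cross-platform duplicates and
  planted outliers, with full ground truth, so every stage is testable
  without cohort data.

## Worked example

Simulate the default synthetic study (15 subjects, 56 plasma time points, 40
metabolites in 8 latent modules of 5), preprocess, scan the OGTT window, and
infer the network:

```r
library(metabodyn)

design <- build_schedule("challenge56")
cfg <- sim_config(
  design = design, n_metabolites = 40,
  modules = lapply(0:7, function(i) list(members = i * 5 + 1:5, loading = 0.8)),
  missing_mcar = 0.02, missing_lod_quantile = 0.05, seed = 1)
sim <- simulate_dataset(cfg)
sim$dataset
#> Profile dataset (raw scale): 40 metabolites, 15 subjects, 31262 observations

ds <- impute_knn(impute_linear(filter_missingness(log2_values(sim$dataset))))

scan <- paired_t_scan(ds, "OGTT")
attr(scan, "p_bonf_threshold")   # reactive: 0.05 / (40 metabolites x 6 tps)
#> [1] 0.0002083333

fit <- dyn_pcor(ds)
fit
#> Dynamical shrinkage partial correlations: 40 metabolites, 15 subjects x 56 time points
#>   shrinkage intensity lambda* = 0.0606, n_eff = 840
#>   |pcor| off-diagonal: median 0.036, max 0.305

net <- build_ggm(fit, mode = "significance", correction = "bonferroni",
                 R_plain = pooled_pearson(ds), catalog = ds$catalog)
net
#> GGM network: 40 nodes, 58 partial-correlation edge(s)
#>   significance: bonferroni + Pearson gate
```

Reading the output: roughly 7% of scheduled samples are missing (5%
detection-limit censoring plus 2% at random) before imputation; the shrinkage
intensity λ\* ≈ 0.06 says the 840 pooled (subject × time point) observations
support the 40×40 correlation matrix well; and the 58 Bonferroni-significant
edges recover the planted within-module associations (here with precision
1.00 and recall 0.73 against the ground truth in `sim$truth$true_edges`).
`export_ggm(net, "net.graphml", "graphml")` writes the network with node
attributes (log2 fold change, −log10 p after `annotate_ggm()`) for any graph
viewer, and `bootstrap_relabel()` tests its biochemical coherence against a
compound graph.

Complete analyses can also be driven from a single YAML/JSON file via
`load_config()` / `run_pipeline()`, which write all artifacts together with a
provenance JSON (settings, seed, input checksums).

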