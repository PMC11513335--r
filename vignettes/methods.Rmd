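---
title: "Models and methods behind metabodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metabodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabodyn)
```

metabodyn analyzes time-resolved challenge metabolomics: a small, homogeneous
cohort is sampled densely before, during and after standardized physiological
perturbations — extended fasting, oral glucose and lipid tolerance tests
(OGTT/OLTT), mixed-meal drinks (SLD), exercise and cold stress — and every
metabolite's trajectory is compared within subject against a challenge-specific
baseline. This vignette explains the models the package implements, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not demonstrate.

## The study design object

A `study_design` holds the time-point grid (per-block clock times, the fluids
sampled at each point) and the challenge windows (baseline time point, tested
time points, onset time). The built-in `build_schedule("challenge56")` design
has 15 subjects, 56 plasma and 16 urine time points across two 2-day blocks,
and eight challenge windows with the standard tested periods (fasting tested
12–36 h into the fast, OGTT 0–2 h, SLD 0–3 or 0–4 h, exercise and stress
0–30 min, OLTT 0–4 h). The exact clock times are an *approximation* of this
protocol class — dense 15–120 min postprandial sampling, sparser fasting and
overnight sampling — and every algorithm is schedule-agnostic, so a
user-supplied design (JSON, `read_design()`) replaces it without code changes.

Two design decisions deserve emphasis:

* **Blocks are never treated as contiguous time.** The weeks-long break
  between blocks is not represented as elapsed minutes. For operations that
  need one monotone axis (trajectories, the banded Fréchet distance, trapezoid
  weights), blocks are concatenated with a fixed 720-min spacer
  (`block_spacer_min`). Any finite spacer larger than the widest matching
  window gives identical results, because the ±30/±120 min bands make
  cross-block matching impossible; the spacer merely keeps the axis monotone.
* **Missing values are absent keys**, never sentinel numbers. All operations
  treat absence as missingness.

## Preprocessing and curation

Raw abundances are log2-transformed (`log2_values()`); all downstream
statistics operate on the log2 scale.

**Outlier flagging** (`flag_outliers()`) implements the curation rule "flag a
point outside the mean ± 4 SD window for that metabolite and time point,
unless it falls within the first 30 minutes after a challenge onset" (the
exemption protects genuine challenge-induced peaks; the window is the closed
interval [onset, onset + 30 min]). The SD estimator is a real design choice.
With 15 subjects, a per-time-point SD that *includes* the tested value can
never be exceeded four-fold: the maximum standardized deviation among $n$
values is $(n-1)/\sqrt{n} = 3.61$ at $n = 15$, so the literal rule is
inoperative for cohorts of this size. The default therefore uses the
per-time-point *mean* but a per-metabolite *pooled residual SD* — residuals
around the time-point means, pooled over the metabolite's time points with
denominator $\sum_{tp}(n_{tp}-1)$. Under a Gaussian null the flag statistic is
then slightly *conservative* relative to a 4-SD normal bound
($\mathrm{sd} = \sqrt{1-1/n}$), and a genuinely aberrant single point inflates
the pooled SD only marginally, so gross outliers are reliably caught. The
literal per-time-point estimator remains available as `sd_method = "per_tp"`
for larger cohorts. Flagging only reports; `drop_flagged()` removes points
wholesale, because in practice flagged points go through manual review that no
algorithm can reproduce.

**Missingness filtering** retains metabolites with strictly less than 30%
missing entries over all scheduled samples of their own fluid
(`filter_missingness()`, threshold configurable).

**Imputation** offers the two self-contained methods: per-(subject, block)
linear interpolation against clock time (`impute_linear()`, via
`stats::approx`, interior gaps only — no extrapolation) and
correlation-preselected KNN (`impute_knn()`). The KNN details are
conventional choices, all configurable: the top `n_preselect = 20` metabolites
by absolute Pearson correlation with the target (at least 10 complete pairs),
z-scored; Euclidean distances over shared non-missing coordinates divided by
$\sqrt{\#\text{shared}}$ so unequal overlaps compare fairly; the unweighted
mean of the target in the `k = 10` nearest samples; graceful fallbacks (all
candidates if fewer than `k`, the target's overall mean if none). Random-forest
and predictive-mean-matching imputation are deliberately out of scope —
externally imputed tables re-enter through the same long format.

**Transforms**: per-metabolite z-scores (zero-variance metabolites cannot be
standardized and are emitted all-missing with a warning); log2 fold changes
against the block's first sample; log2 fold changes against the challenge
baseline (each time point is attributed to the first challenge window
containing it, in design order; baselines map to 0; points in no window become
missing).

## Trajectory similarity

All similarity measures operate on z-scored data. The centerpiece is the
**time-banded discrete Fréchet distance** (`banded_frechet()`): the classic
dynamic programme
$c(i,j) = \max\{d(i,j), \min(c(i-1,j), c(i,j-1), c(i-1,j-1))\}$ over monotone
couplings, with point cost $d(i,j) = |v_i - u_j|$ if the two time stamps
differ by at most the window and $+\infty$ otherwise. The window is ±30 min
everywhere except during the extended fasting span, where it widens to
±120 min (sampling is sparse there); if either stamp of a candidate pairing
lies in the fasting span the wider window applies. Time enters *only* through
the band — the cost compares values. This makes the "window approach" precise:
with window 0 on identical grids the distance reduces to the Chebyshev
distance; with an unbounded window it is the classic discrete Fréchet
distance; curves from different blocks can never couple. `Inf` signals that no
finite monotone coupling exists. Euclidean, Manhattan and Pearson measures
(`pointwise_distance()`) align on shared observed time points.

Two aggregation modes (`trajectory_similarity()`): *per-subject* — compute the
measure within each subject on their shared observed points (subjects with
fewer than 3 shared points are skipped; 3 keeps the distance and Pearson modes
comparable) and average; *mean-trajectory* (the default for ranking) — average
the z-scores across subjects at each time point first and apply the measure
once. `rank_similar()` orders candidates ascending for distances, descending
for correlation, ties broken by uid, incomputable candidates listed last
with `NA`.

## Challenge statistics

`paired_t_scan()` tests, per metabolite and tested time point, the paired
difference of log2 values against the challenge baseline over subjects with
both values observed. Results with fewer than 3 pairs, or zero-variance
differences, are returned as null statistics rather than infinities. Multiple
testing is *reactive*: the Bonferroni threshold is
$0.05 / (\#\text{metabolites} \times \#\text{time points})$ of the scan
actually submitted, and Benjamini–Hochberg q-values are computed within the
scan (`stats::p.adjust`). `volcano_table()` exports (log2fc, $-\log_{10} p$)
for exactly the non-null rows.

Effect sizes use the Hedges-corrected paired Cohen's d,
$d_\mathrm{corr} = d\,(n-2)/(n-1.25)$. `solve_n_for_power()` inverts the
exact two-sided noncentral-t power function
$P(|T'_{n-1,\,d\sqrt n}| > t_{1-\alpha/2,\,n-1})$ by bracketing and bisection
on continuous $n$ (tolerance $10^{-4}$); both rejection tails are included —
the second tail carries negligible mass at the relevant $\alpha$ but costs
nothing to keep exact. The returned fractional $n$ and its ceiling are both
reported.

## Longitudinal Gaussian graphical models

The network estimator (`dyn_pcor()`) treats the repeated measurements
per subject as curves rather than independent samples:

1. **Trapezoid time weights** $w_1 = (t_2-t_1)/2$,
   $w_k = (t_{k+1}-t_{k-1})/2$, $w_T = (t_T-t_{T-1})/2$, normalized — each
   observation represents the time interval it covers, so irregular sampling
   does not overweight dense stretches.
2. **Per-subject dynamical covariance**
   $c_s(g,h) = \sum_k w_k (x_{skg}-\mu_{sg})(x_{skh}-\mu_{sh})$ with weighted
   means $\mu_{sg}$, pooled as the plain average over subjects and converted
   to a correlation matrix $R$.
3. **Shrinkage toward the identity** with the Schäfer–Strimmer-type intensity
   $\lambda^* = \mathrm{clip}_{[0,1]}\left(\sum_{i<j}\widehat{\mathrm{Var}}(r_{ij})
   \big/ \sum_{i<j} r_{ij}^2\right)$, where
   $\widehat{\mathrm{Var}}(r_{ij})$ is the weighted empirical variance of the
   per-(subject, time point) products of standardized residuals with
   normalized weights $\omega_{sk} = w_k/S$ and variance factor $h/(1-h)$,
   $h = \sum \omega^2$ (for uniform weights this reduces to the familiar
   $1/(n-1)$ behavior).
4. **Partial correlations**
   $-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$ from
   $\Omega = (\lambda^* I + (1-\lambda^*) R)^{-1}$.

`lambda` can be forced: 0 reproduces plain inversion (checked in the tests
against an inversion-free cofactor/determinant oracle to $10^{-10}$), 1 zeroes
every off-diagonal. A singular matrix at $\lambda = 0$ aborts with advice to
floor $\lambda \ge 10^{-6}$. Note that individual $|pcor_{ij}|$ need not be
monotone in $\lambda$ — conditioning renormalizes, so small entries can grow
slightly while the dominant ones shrink; the maximum always shrinks.

**Edge significance.** Partial correlations are tested against the null
density $f_0(r;\kappa) \propto (1-r^2)^{(\kappa-3)/2}$ with effective degrees
of freedom $\kappa$ fitted by maximum likelihood; two-sided p-values follow
from $R^2 \sim \mathrm{Beta}(1/2, (\kappa-1)/2)$ (at $\kappa = 3$ the density
is uniform and $p(r) = 1-|r|$). Because the observed values are a mixture of a
large null bulk and a minority of genuine associations, the default fit is a
*truncated* likelihood on the central bulk: the top `trim = 0.2` fraction of
$|r|$ is dropped and the density renormalized to the retained region. The
plain all-values MLE (`trim = 0`) is biased toward small $\kappa$ exactly when
real modules exist — on the synthetic 8-module benchmark it halves $\kappa$
and suppresses every Bonferroni edge — while the truncated fit is unbiased on
pure null draws and robust under contamination. (Estimators in the
GeneNet/fdrtool tradition solve the same problem with a two-component mixture
fit; the truncated fit is the minimal in-package alternative.)

`build_ggm()` draws an edge either above a fixed partial-correlation cutoff
(signed by default, matching the "partial correlations ≥ c" convention;
absolute optionally) or when the partial correlation is significant after
Bonferroni/BH/raw-5% correction over all $p(p-1)/2$ pairs *and* — by default —
the pooled Pearson correlation is significant at 5% (correlation t-test with
$df = n_\mathrm{eff} - 2$ pooled observations; pooling inflates the nominal
degrees of freedom, which is documented rather than corrected, matching the
pragmatic convention of the field). `merge_multifluid()` unions two
single-fluid networks and links same-metabolite nodes across fluids
(case-insensitive match on display name, KEGG or HMDB id; multi-matches get
one edge per partner). Exports: GraphML (igraph), edge TSV, JSON bundle with
provenance (mode, cutoffs, $\lambda^*$, $\kappa$).

## Validation against a compound graph

`pathway_distance_profile()` measures, for every partial-correlation edge
whose endpoints map into a reference compound graph (accession pairs one
reaction step apart, supplied as an edge list), the unweighted shortest-path
distance; pairs mapping to the same accession are counted separately (distance
0) and excluded from the distance-1 statistic. `bootstrap_relabel()` compares
the observed distance-1 count against networks with identical topology but
node labels permuted uniformly among the *mapped* nodes (unmapped nodes carry
no information), with the add-one empirical p-value
$(1 + \#\{null \ge obs\})/(n_{iter}+1)$. KEGG extraction itself is out of
scope (version drift, licensing); any two-column accession edge list works.

## The synthetic study generator

`simulate_dataset()` draws, per metabolite $m$, subject $s$, time $t$:

$$\log_2 x = b_m + s_{scale}\cdot f_m(t) + \rho_m L_{mod(m)}(s,t) +
\varepsilon,\qquad x = 2^{\log_2 x}$$

with baselines $b_m \sim N(10,1)$, per-subject amplitude scale
$s_{scale} \sim N(1, 0.2^2)$, kinetic templates $f_m$, latent module processes
$L$ — stationary unit-variance AR(1) with coefficient 0.6 per (module,
subject) across the time grid, giving the longitudinal correlation structure
the dynamical GGM assumes — and noise SD 0.5 on the log2 scale. Templates:
washout $A e^{-\Delta t/\tau}$ resetting at each block start; postprandial
gamma kernel $A(u/\theta)^a e^{-u/\theta}$ (peak-normalized; the simplest
smooth rise-and-fall), summed over the subject's preceding meals in the block;
fasting ramp $A u/(u+h)$ decaying after refeeding; circadian sinusoid; flat.
Missingness: left-censoring below the metabolite's 5% quantile (emulating
detection-limit dropout of low-abundance compounds) plus 2% MCAR.
Cross-platform duplicate metabolites add independent noise calibrated so the
expected Pearson correlation with the original equals a configured
attenuation. Identical configurations (including the seed) give bit-identical
output.

These defaults — 15 subjects, 56/16 time points, 8 modules of 5 with loading
0.8 for network benchmarks, AR 0.6, noise 0.5 — are the emulated study
conditions and are fixed once; recovery results are reported at exactly these
settings. `inject_outliers()` plants gross outliers (≥ the requested multiple
of the larger of per-time-point and pooled SD, directed away from the
time-point mean so the deviation survives the SD inflation the injection
itself causes) and returns the list for recall tests.

**What passing these tests shows — and what it does not.** The generator
produces log-normal abundances with factor-structured modules, AR(1) temporal
dependence, MCAR + censoring missingness, and clean template kinetics. Real
cohort data additionally contain platform batch effects, heteroscedastic and
platform-specific noise, non-Gaussian tails, correlated missingness, and
kinetic shapes no template captures. Recovery on the synthetic study therefore
validates the *implementations* (and their statistical calibration under the
stated model), not biological performance on any particular cohort.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full study geometry
(15 × 56) with 20–250 metabolites, 1,000-iteration bootstraps, a 50,000-rep
Monte-Carlo power oracle and an exhaustive Fréchet coupling sweep (130,560
pairs); these sizes were chosen so that each property is measured with
comfortable margin while a complete run stays in the minutes range on one
CPU. Other numerics: bisection tolerances $10^{-4}$ (power solver) on $n$;
$\kappa$ optimized on the log scale over $(1, 10^7]$; ties in similarity
rankings broken lexicographically by uid; zero-variance groups skipped rather
than producing infinities; long-table values printed with 17 significant
digits so read/write round trips are bit-exact.

## Interface

`load_config()` validates a YAML/JSON run configuration (inputs,
preprocessing choices, exactly one analysis block; unknown keys rejected) and
`run_pipeline()` executes it, writing TSV/GraphML/JSON artifacts plus a
provenance file (settings, seed, package version, input checksums) sufficient
to re-run bit-identically. The package's functions are the primary interface;
the configuration runner exists so complete analyses are reproducible from a
single declarative file.

## Known limitations

* The pooled-SD curation default is a deliberate deviation from the literal
  per-time-point reading, which is inoperative at $n = 15$ (see above).
* Pearson edge gating uses pooled repeated measurements with nominal degrees
  of freedom; a subject-clustered correction is not implemented.
* The null-model fit is a truncated likelihood, not an empirical-Bayes
  mixture; local false-discovery-rate machinery is intentionally absent.
* `log2fc_challenge` attributes overlapping windows to the first challenge in
  design order; protocols with genuinely nested windows need a custom design.
* Breath platforms are handled only as generic long-format data.
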