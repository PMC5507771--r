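---
title: "Prodromal metabotype modelling: methods and design notes"
author: "metaboPredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prodromal metabotype modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboPredict)
```

# The problem

Isogenic animals on an identical dietary challenge diverge: after a few
weeks of high-fat feeding some mice become obese and glucose intolerant,
some become glucose intolerant while staying lean, and a few resist the
challenge entirely. `metaboPredict` implements the pharmaco-metabonomic
question behind that observation: can the **pre-intervention** urinary
^1^H-NMR metabotype predict which sub-group an animal will end up in, and
its quantitative phenotypes, **before** the challenge starts?

The package provides the full chain as tested, reusable code:

1. a synthetic-cohort simulator with a known ground truth (raw data of
   this kind are typically not deposited, so every downstream stage is
   validated against planted signal);
2. spectral preprocessing: recursive segment-wise peak alignment (RSPA),
   exclusion of the water/urea windows, probabilistic quotient
   normalization (PQN);
3. statistical recoupling of variables (SRV) to collapse correlated
   neighbouring spectral variables into metabolite-scale features, with a
   variance-stabilizing log transform;
4. O-PLS(-DA) with 7-fold cross-validated Q^2^~Yhat~, permutation
   empirical p-values, and ROC analysis of the cross-validated scores;
5. a Spearman-permutation association map between baseline features and
   late phenotypes, and a per-phenotype O-PLS regression screen;
6. 2-SD stratification of late phenotypes into the LNG / L-IGT / Ob-IGT /
   midgroup sub-groups consumed by the discriminant models.

# The statistical core

## PLS1 and O-PLS

For a centred (and by default unit-variance-scaled) feature matrix $X$ and
response $y$, the single-component PLS1 solution is
$w \propto X^\top y$ (unit norm), $t = Xw$, $p = X^\top t / t^\top t$,
$q = y^\top t / t^\top t$, with predictions $\hat y = tq + \bar y$.

O-PLS removes *y-orthogonal* structured variation before the predictive
component. Per orthogonal component: $w_o = p - (w^\top p)\,w$
(normalized), $t_o = X w_o$, $p_o = X^\top t_o / t_o^\top t_o$, and
$X \leftarrow X - t_o p_o^\top$; the predictive component is refit on the
filtered matrix. Two algebraic facts anchor the test suite: the deflated
matrix annihilates $w_o$ exactly (so the refit $w$ is orthogonal to every
$w_o$ at machine precision), and for a single response the training fit of
O-PLS with $k$ orthogonal components equals plain PLS1 with $k+1$
components — the suite uses an independently coded iterative NIPALS
implementation as the oracle for both.

## Cross-validated Q^2^ and its permutation test

$Q^2_{\hat Y} = 1 - \mathrm{PRESS}/\mathrm{TSS}$, with PRESS pooled over
seeded k-fold held-out predictions (stratified by class for discriminant
models, k = 7 by default) and TSS about the *full-sample* mean — the
chemometrics convention, config-switchable. Centering and scaling are
always estimated on the training folds only.

Fold assignment is stratified by class for discriminant models, and
stratification is kept even when a class is smaller than k: spreading a
tiny class across distinct folds is precisely what keeps every training
set two-class. (A plain size-threshold fallback to unstratified
assignment was tried first and proved harmful — with extreme sub-groups
of 3–8 animals, unstratified permuted draws intermittently produced
single-class training sets and crashed the discriminant fit.) For binary
responses the fold draw is additionally validated and redrawn if any
training set would be single-class; only a singleton class falls back,
with a warning.

Model significance is assessed by permuting $y$ and recomputing the full
cross-validated statistic, re-drawing the folds inside every permutation
(the conservative choice: fold structure cannot leak). The observed
statistic is evaluated inside the same seeded stream as the permutations,
making the whole test reproducible from one seed. The empirical
p-value uses the add-one correction
$p = (1 + \#\{Q^2_{perm} \ge Q^2_{obs}\}) / (n_{iter} + 1)$, so $p = 0$ is
impossible and the floor is $1/(n_{iter}+1)$. The default is 10,000
iterations in production use; tests and the bundled configs run 99–5,000.

AUC uses the rank (Mann–Whitney) formulation with ties contributing one
half; the trapezoidal integral of the swept ROC curve equals it exactly
and the suite asserts agreement to 1e-12.

## Association mapping

Spearman's rho is computed as Pearson correlation of midranks on
pairwise-complete pairs; degenerate cells (zero rank variance) are flagged
`NA`, never silently dropped. Per cell, a two-sided permutation p on
$|\rho|$ is computed with the same add-one convention. Following the
figure-legend convention of per-cell masking, **no multiple-testing
correction is applied by default** (a Benjamini–Hochberg option exists but
is off). Per-cell permutation seeds are derived by hashing the master seed
with the feature and phenotype *identifiers* — not their positions — so
subsetting either axis never shifts the remaining cells' p-values.

# The synthetic cohort

`simulateCohort()` emulates a 50-animal isogenic cohort with urine
collections at days 0, 1, 2 and 20 and ~40 day-20 phenotypes (IP-GTT
glycemia/insulin curves and their trapezoidal summaries, body and organ
weights and their ratios, blood chemistry, food intake, behavioural
counts).

**Latent structure.** Each animal carries a disease driver
$z \sim N(0,1)$. Planted extreme responders (default 8% of the cohort)
have $z$ replaced by a draw from $U(3.2, 3.8)$, which guarantees — by
construction, given the inflated sample SD — that their cumulative
glycemia and body weight exceed the cohort mean + 2 SD whenever phenotype
noise is off; planted non-responders (8%) sit at $-U(2.0, 2.4)$. Day-20
traits are monotone (affine) in $z$ plus independent Gaussian noise,
truncated at zero for weights and rounded for counts. A two-driver mode
(`n_drivers = 2`) separates glycemia from adiposity so that L-IGT animals
(glucose intolerant but lean) can be planted.

**Metabolites.** Baseline excretion of metabolite $m$ is
$c_m = \mu_m \exp(\lambda_m \, e \, z + \gamma_m \, e \, r + \epsilon)$,
with marker loading $\lambda_m$, effect size $e$, log-scale noise
$\epsilon \sim N(0, 0.3)$ and a response-magnitude axis
$r = |z| - E|z|$ with loading $\gamma_m$. The $r$ axis is this package's
design addition: the "extreme" contrast (all three extreme sub-groups vs
the midgroup) is two-sided in $z$ and no linear discriminant can learn it
from $z$-loaded metabolites alone. Giving the microbial co-metabolites
hippurate and phenylacetylglycine negative extremity loadings — extreme
responders in *either* direction share a perturbed gut-microbial
co-metabolism — makes the one-component O-PLS-DA task well-posed, and
matches the biological reading that these metabolites mark disease risk
generally rather than one direction of it.

**Calibrations (frozen).** `effect_size = 0.19` was calibrated by
simulation so the planted Spearman correlation between baseline TMAO
excretion and day-20 cumulative glycemia is ≈ 0.6 (the generator's stated
target). The extremity loadings (−2.0 hippurate, −1.5 PAG) were sized so
the metabolic reconstruction of $r$ has enough signal-to-noise for the
extreme contrast to be linearly separable at high AUC; at these
values an extreme responder excretes ~50–65% less hippurate, within the
range reported for real dysbiosis. Neither value is revisited by tests.

**Library.** The default library holds 26 mouse-urine metabolites with
literature-plausible chemical shifts: the methylamine pathway (TMAO the
dominant positive marker, TMA negative, DMA/MMA/choline intermediate),
hippurate and PAG, TCA intermediates, creatinine and a majority of
outcome-neutral abundant metabolites (taurine, lactate, glycine, creatine,
acetate, valine, tyrosine, histidine, ...). The neutral majority is not
decoration: PQN assumes most signals vary only with dilution, and a
marker-dominated panel makes the median quotient absorb part of the
planted signal (observed as spurious |rho| ≈ 0.4 on neutral metabolites
before the library was extended). Baseline means are order-of-magnitude
choices in arbitrary units, not measured values.

**Distortions.** Each spectrum is multiplied by a log-normal dilution
factor (log-SD 0.2), shifted by an integer number of grid points uniform
on [−3, 3] with edge-value padding (so alignment recovery is exactly
testable), and overlaid with Gaussian noise and a smooth random baseline.
Spectra are generated directly in the processed intensity domain as sums
of Lorentzian lines — the natural NMR line shape — with an optional
compact-support cutoff (`tail_cutoff`) used by boundary-recovery tests;
no FIDs, phasing or water suppression are simulated.

**What a green test does not establish.** The simulator draws independent
animals (no litter or cage effects — deliberately, as cage effects were
ruled out in this kind of design), uses a single (optionally double)
latent driver rather than genuinely multivariate physiology, has no
unassigned "hump" of hundreds of minor metabolites, and plants monotone
metabolite–outcome couplings. Passing tests demonstrate that the pipeline
recovers the signal class it is designed for; they say nothing about
performance on real cohorts with confounders, batch structure or
non-monotone biology.

# Numerical and design choices

* **Pipeline order**: align → exclude regions → SRV clustering → PQN on
  cluster intensities → log transform. Whether PQN belongs on
  full-resolution spectra or on features is genuinely open; both are
  supported (`pqnNormalize` accepts either), features are the pipeline
  default to keep quotients off noise-dominated columns.
* **SRV threshold**: the correlation landscape between two abutting
  Lorentzian resonances only dips to ≈ 0.92–0.97 at the crossing (mixture
  shares change slowly and dilution adds common variance), so the
  conventional 0.9 threshold provably cannot split known adjacent urinary
  singlets (TMAO 3.27 / choline 3.21 ppm). `srvCluster()` keeps 0.9 as its
  default; the pipeline default is 0.97. Neither is asserted to be the
  original study's setting.
* **LNG boundary**: the 2-SD rule defines the upper extremes; no numeric
  lower boundary for non-responders is stated anywhere, and a
  median-based rule would label ~40% of a cohort "extreme non-responder",
  whereas non-responders to a dietary challenge form a small tail group
  in practice; a broad lower rule also destroys the extreme-contrast
  geometry. Default: at-or-below the 0.10
  sample quantile on *both* stratifying traits; the rule text is recorded
  verbatim in every result object.
* **Dilution identifiability**: PQN estimates dilution only up to the
  cohort median (the reference absorbs it), so recovery is always assessed
  on median-scaled factors.
* **Scaling**: unit-variance is the default for spectral features
  (config: none | unit-variance | Pareto); `n_orth = 1` is the standard
  O-PLS-DA default.
* **Degenerate inputs**: constant spectra are excluded from reference
  candidacy; constant columns get zero landscape correlation; zero-SD
  stratification traits yield a warning and no upper extremes; degenerate
  Spearman cells are flagged missing; an exhausted orthogonal subspace
  stops O-PLS early and records the achieved component count.
* **Seeds**: one master seed per run; per-stage and per-cell seeds are
  derived by FNV-1a hashing of stable labels, all below 2^31.

# Reproducing a run

```{r, eval = FALSE}
cfg <- runConfig(seed = 1, out_dir = "run1")
report <- runPipeline(cfg)
report$contrasts$extreme     # q2, permutation p, AUC for the extreme DA
report$association           # significant-cell count at alpha = 0.05
```

Identical `runConfig()` input (including the seed) reproduces the report
bit-for-bit; all intermediates are plain delimited text.

# Known limitations

* Exact numeric reproduction of any particular cohort's headline
  statistics is not attempted: raw spectra and phenotype tables for such
  studies are rarely deposited, and Q^2^ depends on scaling,
  component-count and fold choices that published work seldom states in
  full. The package validates properties instead: oracle equivalence,
  exact-enumeration calibration, planted-signal recovery, null
  calibration, preprocessing recovery and stratification correctness.
* RSPA is re-specified operationally (exhaustive integer-shift
  cross-correlation with recursive bisection at intensity minima); the
  original algorithm is only cited, not described, in the source
  material.
* With ~8 extreme animals in 50, the cross-validated AUC of the extreme
  contrast is itself a noisy statistic; across simulation seeds it ranges
  from ~0.6 to ~0.95 at the default effect size. The acceptance check
  runs the fixed default configuration, where it is deterministic.
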