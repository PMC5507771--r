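# metaboPredict

Pre-intervention urinary ¹H-NMR metabotypes as predictors of
post-intervention metabolic disease: an R implementation of the
pharmaco-metabonomic pipeline for isogenic-cohort dietary-challenge
studies.

## The problem

Genetically identical mice on the same high-fat diet diverge within
weeks into obese glucose-intolerant (Ob-IGT), lean glucose-intolerant
(L-IGT), resistant lean-normoglycemic (LNG) and unremarkable "midgroup"
animals. The scientific question this package operationalizes: does the
**baseline (day 0)** urinary metabolic profile already predict that
divergence — and the quantitative phenotypes behind it — before the diet
starts?

`metaboPredict` implements the full analysis chain:

* **Synthetic cohort generator** — urinary spectra (sums of Lorentzian
  lines over a ppm grid) at 4 timepoints plus ~40 day-20 phenotypes for
  50 animals, with a latent disease driver *z*, planted extreme
  responders, known metabolite→outcome couplings (TMAO and the
  methylamine pathway as positive baseline markers), per-spectrum
  dilution factors and chemical-shift jitter. All ground truth is
  recorded, so every downstream stage is testable without any external
  data.
* **Preprocessing** — recursive segment-wise peak alignment (RSPA:
  exhaustive integer-shift cross-correlation with recursive bisection),
  water/urea window exclusion, probabilistic quotient normalization
  (PQN).
* **SRV features** — statistical recoupling of variables: maximal runs of
  the consecutive-column correlation landscape become clusters, collapsed
  to per-sample features, annotated against the metabolite library, and
  variance-stabilized by a log transform.
* **O-PLS(-DA)** — NIPALS PLS1 with orthogonal-component filtering,
  7-fold cross-validated Q²_Ŷ = 1 − PRESS/TSS, out-of-sample prediction
  with training-fold-only centering/scaling.
* **Validation** — permutation empirical p-values for Q²_Ŷ (folds
  re-drawn inside every permutation; add-one correction), ROC/AUC of the
  cross-validated scores by the tie-aware rank formulation.
* **Association mapping** — feature × phenotype Spearman matrix with
  per-cell two-sided permutation p-values and an α-mask, plus a
  per-phenotype O-PLS regression screen across timepoints.
* **Stratification** — the 2-SD rule on cumulative glycemia and body
  weight defining Ob-IGT / L-IGT, a configurable lower rule for LNG, and
  the binary contrasts consumed by the discriminant models.

## Worked example

```r
library(metaboPredict)

cfg <- runConfig(seed = 1, validate = list(n_iter = 999))
report <- runPipeline(cfg)

report$groups
#> $LNG        [1] 5
#> $midgroup   [1] 42
#> $`Ob-IGT`   [1] 3

as.data.frame(report$contrasts$extreme)[, c("q2", "p", "auc", "n")]
#>        q2     p   auc  n
#> 1   0.331 0.001 0.946 50
```

Reading: the 2-SD rule on day-20 cumulative glycemia and body weight
finds 3 obese-IGT animals and (with the 0.10-quantile lower rule) 5
non-responders; an O-PLS-DA trained on **day-0** SRV features separates
these 8 extreme animals from the 42 midgroup animals with cross-validated
Q²_Ŷ = 0.33, an AUC of 0.946 on the held-out predictive scores, and an
empirical p of 0.001 against 999 response permutations — the planted
prodromal signal (baseline TMAO, methylamines, hippurate, PAG) is
recovered from the spectra end to end.

```r
am <- report$objects$association
am
#> AssociationMatrix: 32 features x 42 phenotypes (n_iter 199)
#>   significant cells at alpha 0.05: 100 of 1344
tb <- associationTable(am)
head(tb[order(tb$p, -abs(tb$rho)), c("feature", "phenotype", "rho", "p")], 3)
#>                feature phenotype   rho     p
#> 528 3.1923:3.3139:TMAO       RFP 0.595 0.005
#> 560 3.1923:3.3139:TMAO RFP_ratio 0.593 0.005
#> 784 3.1923:3.3139:TMAO   BW_gain 0.583 0.005
```

The strongest baseline predictors of day-20 adiposity and glycemia are the
TMAO-labelled cluster and its methylamine relatives — the planted
prodromal markers. The TMAO × cumulative-glycemia cell reads rho = 0.48
(p = 0.005): the generator plants rho ≈ 0.6 on true concentrations, and
dilution correction absorbs a fraction of it, exactly as it would on real
urine.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete default pipeline from scratch at the given seed —
simulation, alignment, SRV/PQN/log features, stratification, the
permutation-validated extreme-contrast O-PLS-DA and the association map —
printing a one-line summary per stage and writing the JSON report to
`--out`.

## Layout

```
R/                      S4 classes (SpectralSet, SrvFeatureSet, OplsModel,
                        CvResult, PermutationTest, RocResult,
                        AssociationMatrix, StratificationResult, ...) and
                        the stage functions
tests/testthat/         unit, property and acceptance suites
scripts/acceptance.R    end-to-end acceptance run
inst/scripts/metabo.R   thin command-line wrapper (run | simulate)
vignettes/              methods vignette: models, assumptions, design
                        decisions, limitations
```
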