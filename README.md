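# refstab

Validation of endogenous loading controls (reference proteins) for
quantitative western blot, for toxicology and molecular-biology labs that
need to know *which* housekeeping protein — or which geometric-mean
combination of several — can safely normalize band intensities across a
designed animal study.

The package grew out of the reference-protein problem in mouse models of
dioxin (TCDD) toxicity: TCDD is a transcriptional modulator, so classical
controls such as ACTB or GAPDH cannot be assumed stable and must be
validated per experimental system. It implements the full screening
pipeline for a study of 7 candidates (ACTB, EEF1A1, GAPDH, HPRT, PGK1,
PPIA, SDHA) plus a CYP1A1 positive control across 192 animals in 47
treatment conditions, and a synthetic-data generator that reproduces that
design so everything is testable without the original data.

## Methods at a glance

* **Fold-difference screen.** For each treated group paired with its
  control, the fold-difference `M = mean(treated) / mean(control)` and an
  unpaired two-tailed Welch *t*-test; candidates are summarized by
  `n_sig / n_comparisons` at p < 0.05.
* **Stability value (NormFinder).** On log2 intensities `y_igj` (candidate
  *i*, group *g* ∈ {TCDD, control}, animal *j*), intra-group variances are
  estimated from double-centered residuals,
  `σ̂²_ig = max(0, n/(n−2) · (MS_ig − Σ_i' MS_i'g / (n(n−1))))`,
  inter-group differences `d_ig` are shrunk by their empirical-Bayes factor
  `γ²/(γ² + σ̂²_ig/n_g)`, and the stability value is
  `ρ_i = mean_g(|d̃_ig| + posterior SD)` — lower is more stable. Scores are
  computed per cohort (training = experiments 1,4,6,8,9; validation =
  2,3,5,7,10; overall) for single candidates and for all 127
  geometric-mean combinations.
* **Comparative normalization.** Each candidate in turn normalizes the
  other six (per-animal ratio rescaled by the reference median); the mean
  within-group SD of the normalized values measures how much variation the
  reference removes.
* **Attribution.** OLS fit of combination stability on the seven Boolean
  inclusion indicators (no intercept), with Benjamini–Hochberg FDR —
  negative coefficients mark candidates that stabilize combinations.
* **Protein–mRNA concordance.** Spearman correlation (AS 89 significance)
  between log2 band intensity and qPCR mean Cq per gene, and between the
  protein- and mRNA-based combination-stability vectors.

## Worked example

```r
library(refstab)

sim <- simulateDataset(syntheticConfig(seed = 1L))  # 192-animal design
res <- runPipeline(sim$abundance, sim$cq)
res$table2_like
#>   candidate n_sig n_comparisons nf_training nf_validation compnorm_score
#> 1      ACTB     5            31      0.0418        0.0222            113
#> 2    EEF1A1    13            31      0.0526        0.0390            402
#> 3     GAPDH     8            31      0.0528        0.0295            344
#> 4      HPRT     0            31      0.0617        0.0747            333
#> 5      PGK1     4            31      0.0397        0.0282            481
#> 6      PPIA     7            31      0.0553        0.0406            415
#> 7      SDHA    16            31      0.0361        0.0491            349
```

Reading the table: `n_sig/n_comparisons` counts treated-vs-control
conditions in which the candidate moved significantly (a good loading
control scores low — here the simulated HPRT, planted with the smallest
treatment response, is altered in 0 of 31 conditions, while the EEF1A1-
and SDHA-like candidates, planted with the largest shifts, are altered
most often). `nf_training`/`nf_validation` are the stability values in
the two cohorts (log2 units; lower = more stable), and `compnorm_score`
is the comparative-normalization mean SD in intensity units.

```r
head(res$combinations[order(res$combinations$stability), ], 1)
#>                               combination size     cohort stability
#> 254 ACTB+EEF1A1+GAPDH+HPRT+PGK1+PPIA+SDHA    7 validation         0

res$stability_concordance
#>             entity   rho p   n
#> 1 stability-vector 0.767 0 127
```

The all-7 geometric mean is the most stable normalization factor in every
cohort, and the protein- and mRNA-based combination rankings are strongly
concordant because the simulated treatment effects transfer across
platforms.

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/refstab.R simulate --seed 5 --out sim/
Rscript inst/scripts/refstab.R run --abundances sim/abundances.tsv \
    --cq sim/cq.tsv --out results/
```

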