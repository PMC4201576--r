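---
title: "Validating western-blot loading controls: models and design choices"
author: "refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating western-blot loading controls: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Quantitative western blot reports band intensities in arbitrary
fluorescence units that vary well-to-well and blot-to-blot. The standard
remedy is to divide by an endogenous loading control, which silently
assumes the control itself is unaffected by the experiment. For a
transcriptional toxicant such as TCDD that assumption is dangerous:
candidate reference proteins must be validated in the model system at
hand. `refstab` implements a validation pipeline built around a designed
mouse study — 10 experiments varying strain, sex, *Ahr* genotype, dose
(0–1000 µg/kg) and harvest time (6–144 h), 192 animals in 47 groups, one
western blot per experiment — together with a generator that simulates
data with exactly that structure.

## The data container

An `AbundanceExperiment` (a `SummarizedExperiment`) holds the
background-subtracted band intensity matrix (proteins × animals), a
logical `excluded` mask for wells with unsatisfactory loading patterns,
and the animal metadata. Exclusions are flags, not deletions: provenance
is kept, and every statistic sees the masked view (`maskedIntensities()`),
so flagging a record and physically deleting it are verifiably
equivalent. Non-excluded intensities must be finite and positive —
background subtraction (`backgroundSubtract()`) returns `NA` for bands at
or below background, and such wells must be excluded.

## The stability model

All stability computations run on log2 intensities, where multiplicative
densitometry error becomes additive. For candidate $i$, group $g$
(TCDD-treated vs control), animal $j$:

$$y_{igj} = \alpha_{ig} + b_{gj} + \varepsilon_{igj},$$

with a per-animal sample effect $b_{gj}$ (loading, blot) shared across
candidates. Within each group the residuals are double-centered, and the
mean square $MS_{ig}$ is corrected to an intra-group variance estimate

$$\hat\sigma^2_{ig} = \max\!\Big(0,\ \tfrac{n}{n-2}\big(MS_{ig} -
\tfrac{1}{n(n-1)}\textstyle\sum_{i'} MS_{i'g}\big)\Big),$$

where $n$ is the number of candidates; the subtracted term removes the
leakage of every candidate's noise into the estimated sample effects.
Averaged over candidates, the (untruncated) estimate equals the classical
two-way ANOVA residual mean square exactly — that identity, checked
against `aov()`, is the suite's independent oracle for this code path.
Inter-group differences $d_{ig}$ (which sum to zero over the candidate
panel) are shrunk by the empirical-Bayes factor
$\gamma^2 / (\gamma^2 + \hat\sigma^2_{ig}/n_g)$, where $\gamma^2$ is the
estimated variance of true inter-group differences, and the stability
value is the group average of $|\tilde d_{ig}|$ plus its posterior SD.
Lower is more stable.

Two consequences are worth understanding before reading results:

* **The model measures deviation from the panel.** Because $d_{ig}$ is
  centered across candidates, a candidate whose treatment response equals
  the panel-average response gets $d = 0$: stability is relative to the
  chosen panel, not to an absolute notion of constancy.
* **Degenerate inputs hit the floor.** Variance components are truncated
  at zero. When the data carry no inter-group signal at all,
  $\hat\gamma^2 = 0$ and every stability value collapses to the
  algorithm's exact floor of 0 — the intended behaviour in the zero-noise
  limit, but also the reason a simulated panel needs *some*
  candidate-specific treatment structure for the scores to discriminate.

**Combinations.** For each non-empty subset the geometric-mean
pseudo-candidate is scored against the sample-centering terms, MS-sum
correction and $\gamma^2$ estimated once from the full candidate matrix.
The sample effect is a property of the animal, not of the subset, and
this convention makes singleton scores equal the single-candidate scores
exactly. It also makes the all-$n$ combination's score exactly 0 — the
full geometric mean *is* the estimated sample effect. Re-centering per
subset would be the main defensible alternative; it breaks singleton
consistency, so it was not adopted. Animals missing any candidate are
dropped listwise, with a reported count.

## The fold-difference screen

Fold-differences are reported in log2; the Welch test runs on
linear-scale intensities by default (the densitometry convention;
`test_scale = "log2"` is available). The significance threshold is an
uncorrected p < 0.05 per condition — this is a screen, not an inference
procedure. Conditions with fewer than two measured animals on either side
(the design contains one single-animal group) are flagged untestable and
excluded from the denominators, which are candidate-specific because
exclusions are.

Two operating characteristics of the linear-scale Welch test at this
study's group sizes (3–5), both measured by the suite's Monte-Carlo
checks, deserve mention: at $n = 5$ per group under a heteroscedastic
normal null the empirical type-I error is at its nominal 0.05 (the
acceptance check's conditions); at $n \le 4$, and under multiplicative
(log-normal) noise, the Welch–Satterthwaite approximation is mildly
*conservative* (empirically ≈ 0.04), so the screen under- rather than
over-flags tiny groups. Relatedly, a strongly induced positive control
(+6 log2 units) is detected in ≈ 99.6% of testable condition instances
across seeds, with the rare misses confined to $n = 3$ treated groups
where the test has ~2 degrees of freedom.

## Comparative normalization

The pairwise statistic adapts the comparative ΔCq idea to intensities:
target over reference per animal, rescaled by the reference's median so
the result keeps intensity units, then the SD within each experimental
group (biologically equivalent animals), averaged over groups and over
the six targets. Averaging SDs *within* groups — rather than one SD over
all animals — is the reconstruction's main judgment call: it prevents
genuine treatment responses of the targets from dominating what is meant
to be a technical-variation measure. Because the score carries intensity
units, it scales linearly with overall intensity, so candidates measured
at much higher absolute intensity carry proportionally larger scores —
rank, not magnitude, is the meaningful comparison.

## Attribution and concordance

Combination stability is regressed on the seven Boolean inclusion
indicators with no intercept (the model form is the seven α terms plus
error); two-sided t-tests and Benjamini–Hochberg FDR across the seven
coefficients. The 127 × 7 design has full rank by construction and exact
algebra is tested against a normal-equations oracle.

Protein–mRNA concordance uses Spearman's rank correlation with the AS 89
p-value (`cor.test`): exact enumeration for $n \le 9$ without ties,
Edgeworth approximation above, t-approximation under ties (exactness is
impossible there; ties get average ranks). Cq is inverse to abundance, so
platform agreement appears as negative rho against Cq; `abundance_scale =
TRUE` correlates against −Cq and flips the sign exactly. mRNA combination
stability reuses the identical variance-decomposition code path on −Cq,
which is already a log2-scale abundance proxy.

## The synthetic generator

`simulateDataset()` draws, for animal $j$ on blot $b$:
$\log_2 I_{ij} = \text{baseline}_i + \delta_i(\text{dose}, t) + b_b +
\varepsilon_{ij}$ — log-additive noise, i.e. multiplicative on the
intensity scale, which is how densitometry error behaves and what the
stability model assumes. One blot per experiment carries a shared
$N(0, 0.25^2)$ log2 shift. Defaults emulate the study panel: baselines
around $2^9$–$2^{10}$ with ACTB far higher ($2^{13.5}$), candidate
σ (log2) between 0.10 and 0.22, small candidate-specific treatment
shifts (|log2| ≤ 0.22 — no real housekeeping protein is perfectly inert
to a transcriptional toxicant, and a panel with literally no
inter-group structure degenerates to the stability floor), and a
CYP1A1-like positive control induced by +6 log2 units at any dose. Mean
Cq values carry the same treatment effect (one cycle per log2 unit, sign
inverted) plus noise coupled to the protein noise by a Gaussian copula
targeting a Spearman correlation of `mrna_coupling` (default 0.2, the
weak protein–mRNA coupling typical of such panels). The copula target is
achieved within sampling error for i.i.d. noise; when the shared blot
component is active, the realized per-seed coupling spreads more widely
(only 10 distinct blot values exist), which is why the calibration checks
run with the blot component off.

All draws come from per-blot and per-animal substreams keyed on one seed,
so simulation is bit-reproducible and subsetting the design never shifts
the remaining animals' draws.

What the generator does **not** emulate: scanner saturation or censoring,
within-animal technical replicates (the study has one measurement per
animal × candidate), correlated noise between candidates beyond the blot
effect, and real exclusion patterns (exclusions are an input, not
generated). Tests passing on synthetic data therefore demonstrate
correctness of the estimators under the stated model, not robustness to
every artefact of real blots.

## Calibration experiments and problem sizes

The test-suite and acceptance-script Monte-Carlo experiments use these
sizes, chosen to make each measurement informative at interactive run
times: 10,000 null conditions for the type-I check (n = 5 per group,
2× SD ratio); 1,000 replicates of a 6-protein, 2 × 40 balanced design for
variance-estimator calibration, with σ ≥ 0.15 so the max(0, ·) truncation
probability is negligible (near the floor, truncation inflates small
variance estimates — a known property, not an estimator defect); 100
simulated 192-animal studies for rank recovery, with planted intra-group
variances doubling at each step and treated-shift deviations growing in
the same order (a zero-sum deviation pattern, so the model's centered
inter-group component sees the same ranking as the planted total
variation); full 8! permutation enumeration for the AS 89 agreement
check; and 1,000 fits for attribution CI coverage.

## Known limitations

* Stability values depend on the candidate panel (centered $d$); adding
  or removing a candidate changes the others' scores.
* The comparative-normalization statistic is scale-bearing and only
  rank-interpretable across candidates of different absolute abundance.
* With two groups and weak inter-group structure, $\hat\gamma^2$
  truncates to zero and the stability values lose resolution.
* The Welch screen is conservative for groups of ≤ 4 under multiplicative
  noise; single-animal groups are untestable by design.
* AS 89 p-values are approximate under ties.
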