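---
title: "Dropout-aware eQTL mapping in single-cell qPCR data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dropout-aware eQTL mapping in single-cell qPCR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(monoqtl)
```

## The measurement model

Single-cell qPCR panels report a threshold cycle (CT) per cell and gene:
the PCR cycle at which fluorescence crosses threshold, so *lower* CT means
*more* transcript. Two conventions anchor everything downstream:

* a **limit of detection (LOD)** — CT values at or above 28 cycles (the
  default) are scored non-detected; and
* an **expression value** defined as cycles above threshold,
  `expression = total_cycles - ct`, with non-detected and missing reactions
  assigned 0, so higher numbers mean more expression.

`total_cycles` defaults to 40, the usual cycle count for these
instruments, and is configurable (`--total-cycles` at the command line).
Because detected CTs lie below the LOD, detected expression values live in
the window `(total_cycles - lod, total_cycles]` — 12 to 40 cycles with the
defaults — while dropout produces exact zeros. This mix of a point mass at
zero and a bounded continuous part, together with strong within-person
correlation (cells from one donor are not independent), drives every
modelling choice below.

## Quality control

* **Capture flags.** Only wells scored as singlets on microscopy enter the
  analysis (`exclude_nonsinglets()`).
* **Failure score.** Each cell's total CT over all assays; cells more than
  2 SD above the mean are excluded (`failure_score_filter()`). Missing CTs
  contribute `total_cycles` to the score by default so low-yield cells are
  penalised; the mean and SD are computed per capture run
  (individual × cell type) by default because CT totals drift between
  runs, with a `scope = "global"` option. Both choices are configurable
  because instrument exports do not record which convention was used
  upstream.
* **Missing-CT sentinels.** Instrument software writes `999` for failed
  reactions; the reader treats a configurable sentinel list
  (`""`, `"NA"`, `"999"`) as missing.

## The association ensemble

For each SNP (minor-allele dosage 0/1/2), gene and cell type the package
fits four complementary models, each with a person-level random intercept
to absorb the within-donor correlation:

1. **Tweedie GLMM** (`fit_tweedie_mixed()`): a compound Poisson-gamma
   response with log link and power index in (1, 2) models the zero mass
   and the positive part jointly. The power index is estimated by maximum
   likelihood alongside the other parameters (it may be fixed via the
   `power` argument). Variance parameters are estimated by **REML**: in
   simulation at 15 donors, maximum likelihood left the dosage Wald test
   anti-conservative (empirical size near 0.09–0.10 at nominal 0.05)
   while REML brings it close to nominal.
2. **Logistic GLMM** (`fit_logistic_mixed()`): the detection indicator
   (`expression > 0`) as a binary outcome — the dropout channel itself.
   Genes whose average on-proportion exceeds 98% are excluded from this
   method only (`drop_saturated_genes()`): an almost-always-detected gene
   carries no dropout signal. The rule is a strict `>`, so exactly 0.98
   is kept.
3. **Gaussian LMM on detected values** (`fit_gaussian_nonzero_mixed()`):
   the amplitude channel, fitted to non-zero values only, with
   Satterthwaite denominator degrees of freedom. In the degenerate limit
   (no random-effect variance, balanced design) its p-value agrees with
   the ordinary least-squares t-test.
4. **On-proportion ANOVA** (`fit_proportion_anova()`): per-individual
   detection proportions as the outcome and genotype as a categorical
   factor, making individuals (not cells) the analysis units. When fewer
   than two donors are homozygous-minor, that group is merged into the
   heterozygotes (logged in the fit's `reason`) — with 15 donors the
   homozygous-minor group is routinely this sparse.

**Inference.** Genotype varies only between individuals, so the effective
sample size for the dosage coefficient is the number of donors, not the
number of cells. Wald statistics for the tweedie and logistic models are
therefore referred to a t distribution with `n_individuals - 2` degrees of
freedom (containment df) rather than a normal; the Gaussian model uses
Satterthwaite df, which converges to the same in this design. Genotype is
coded additively in the three regressions (standard for eQTLs) and as a
factor in the ANOVA.

A deliberately naive per-cell **Mann-Whitney** comparison
(`fit_naive_mw()`, major-homozygote cells vs minor-allele-carrier cells,
dominant collapse since the U test is two-sample) is included only as the
pseudoreplication contrast: treating correlated cells as independent units
inflates its type I error severalfold (about 0.7 at nominal 0.05 under the
synthetic null with person SD 1.0), which is exactly why the mixed models
exist.

**Multiplicity.** `bh_fdr()` applies Benjamini-Hochberg step-up adjustment
(via `stats::p.adjust`; an independent brute-force implementation serves
as the oracle in the test suite) and retains records with adjusted q
strictly below 0.1. Correction families are per (cell type × method): each
approach is corrected over all SNP-gene pairs it tested. Non-convergent or
skipped fits never enter the ranks; their counts are tallied in the scan
log. `bonferroni_threshold()` reproduces the single-threshold alternative
(0.05 / (90 × 7) ≈ 8e-5) used by naive scans.

## Sharing bookkeeping

A (SNP, gene) pair is a **shared eQTL** when it is retained in both
monocyte subsets *and* the direction of association agrees
(`sharing_analysis()`). Direction is the sign of the dosage coefficient;
for ANOVA-only hits it is the sign of the carriers-minus-major-homozygote
mean proportion difference, so every hit carries a sign. When several
methods retain the same pair, the canonical direction comes from the
best-FDR method. Pairs significant in both subsets with opposite
directions are flagged discordant and counted exclusive on each side.
`sharing_test()` and `celltype_imbalance_test()` are two-sided exact
binomial tests of the sharing proportion (against 0.5) and of the NCL
share of hits; the test behind the comparable published p-values is not
identified, so these implement their own stated contract rather than
reverse-engineering one.

## Co-expression: individual-averaged correlation PCA

Within each cell type: restrict to the **common gene universe** (genes
with positive expression variance in every donor, so each per-donor
Pearson correlation is defined), compute one gene-gene correlation matrix
per donor, average them element-wise, and eigendecompose the average. The
averaging removes between-donor mean differences before the PCA, so the
leading axes describe within-cell co-expression rather than donor
identity. Choices worth making explicit:

* **Loadings** are eigenvector entries scaled by the square root of the
  eigenvalue — the gene-component correlation. Unit-norm eigenvector
  entries could not exceed 0.7 for 30+ genes simultaneously, so a
  |loading| > 0.7 module rule is only meaningful on this scale.
* **Module extraction** keeps genes with |loading| strictly above 0.7 on
  the "highly explanatory" components, by default PC1 only: in data of
  this type PC1 explains an order of magnitude more variance than PC2
  (~35-40% vs ~3%), and `pcs = "auto"` (variance share at least 10× the
  median) is available when that pattern is less clear-cut.
* **Zeros are included** in the correlations (Pearson, configurable):
  nothing in the upstream convention justifies discarding them, and
  dropout co-occurrence is part of the signal on this scale.
* **Projection** standardises each gene by its pooled mean and SD over
  all cells of the cell type before multiplying by the eigenvectors.
  Per-donor centring would remove donor effects trivially and make the
  heterogeneity-removal comparison meaningless.
* **Sign convention:** each component is flipped so its largest-magnitude
  loading is positive; module membership is invariant to such flips.

`individual_eta2()` quantifies donor separation in a score column as the
one-way eta-squared of donor identity; projecting onto the averaged-matrix
PCA yields visibly and reproducibly lower eta-squared than projecting onto
the pooled-correlation PCA.

## The synthetic-data generator

`simulate_expression()` generates data with the structure the analysis
assumes, with known truth, at the scale of the motivating study (15
donors × 2 subsets × 30 cells × 90 genes × 7 SNPs under Hardy-Weinberg
genotypes):

* latent log-mean per (gene, donor):
  `log(baseline) + person intercept + mean-channel effects`, with
  baselines drawn from 14-24 cycles above threshold and person intercepts
  Normal with SD 1.0 on the log scale (an order-of-magnitude choice; no
  published variance estimates exist for this design);
* the person intercept splits into a component shared across genes (50%
  of variance by default) and a gene-specific remainder — the shared part
  is what makes donors separate in pooled correlation space;
* detection probability `plogis(-2 + 1 × log-mean + detection-channel
  effects)`, i.e. dropout is missing-not-at-random, rising for
  low-expression cells as in real qPCR; an MCAR toggle with fixed
  detection probability exists for oracle checks;
* detected amplitudes are Normal around `exp(log-mean)`, truncated to the
  detectable window; the Normal noise is correlated within planted
  co-expression blocks and enters the truncated marginals through a
  Gaussian copula, so block correlation survives truncation without a
  boundary point mass; `ct = total_cycles - expression`, and non-detected
  reactions carry a missing CT;
* optional per-(gene, donor) on/off switches force all of a donor's cells
  off with a given probability, reproducing the person-level binary
  pattern seen for IRF1-like genes;
* everything is driven by a single mandatory seed; identical seeds give
  byte-identical output.

What the generator does **not** emulate: amplification efficiency
differences between assays, melt-curve artefacts, cell-cycle or cell-size
covariates, batch effects between capture runs beyond the person effect,
and any empirical calibration to the (unavailable) source data. Passing
tests therefore demonstrate correctness of the machinery under a
plausible generative model, not performance guarantees on real exports.

### Validation fixtures and problem sizes

The canned fixtures document the conditions used by the validation
studies (all sizes are the package's own choices, stated here so results
are interpretable):

* **Calibration** (`type1_error_study()`): 200 null replicates, 15
  donors × 30 cells, person SD 1.0, MAF 0.3. Expected behaviour: mixed
  methods near 0.05, naive Mann-Whitney far above 0.15.
* **Fitter recovery** (`effect_recovery_study()`): 200 replicates drawn
  directly from the tweedie (compound Poisson-gamma) and logistic GLMMs,
  15 donors × 40 cells. The CT-level generator is unsuitable here by
  design: its detectable window (12-40 cycles) cannot host an exactly
  log-linear mean, so fitter bias is assessed on the model's own family
  and the CT generator is reserved for calibration and power.
* **Scan power** (`scan_power_study()`): 50 replicates of the powered
  fixture — 6 genes × 2 SNPs, one cell type, 40 cells per donor, a
  detection-channel effect of 1.5 logits per allele planted on the
  highest-MAF SNP (0.4), and `detection_intercept = -3.5` so baseline
  detection sits mid-range. At the generator default (-2) most genes sit
  near detection saturation, where a dropout-channel effect is
  uninformative — the same phenomenon the 98% saturation rule addresses.
* **Null scans** (`null_scan_study()`): 20 replicates, 12 genes × 2
  SNPs; under the global null BH's FDR equals its familywise error, so
  the per-family any-retention rate is bounded by q = 0.1.
* **Co-expression recovery** (`coexpression_recovery_study()`): 50
  replicates, 30 genes with a 10-gene block at within-block correlation
  0.8, person SD 0.5 with 60% shared across genes, and **no dropout**.
  The no-dropout configuration isolates the correlation-averaging PCA:
  on the absolute expression scale (zeros at 0, detected values ≥ 12),
  Pearson correlations through dropout are dominated by co-detection, so
  module recovery with dropout would measure the detection process
  rather than the PCA. This also documents a real limitation of
  correlations computed on LOD-censored expression values.

These sizes keep the default test suite and the acceptance script within
routine runtimes while leaving Monte-Carlo error small relative to the
bands being checked.

## Numerical and degenerate-input conventions

* Monomorphic SNPs give a Hardy-Weinberg chi-square of 0 with a warning.
* All-zero genes, single-class outcomes, fewer than three donors with
  detected cells, zero residual variance, and (quasi-)separation (SE
  above 10 on the logit scale) produce non-converged fits with a machine-
  readable `reason`; they are excluded from FDR ranks and tallied, never
  silently dropped.
* A dosage with no between-donor contrast is an error, caught and logged
  per fit by the scan rather than aborting it.
* Eigenvalues of averaged correlation matrices are clipped at zero before
  the square root; matrices must be symmetric to 1e-8.
* Ties in the best-FDR method choice for a pair's canonical direction are
  broken by the smaller p-value, then first occurrence.

## Known limitations

* With 15 donors, Wald-type inference in GLMMs is approximate even with
  containment df and REML; empirical size ~0.05-0.08 rather than exactly
  0.05 should be expected.
* The tweedie model is the most fragile of the ensemble on LOD-censored
  data (the true positive part is a bounded window, not gamma-like),
  mirroring its modest yield in practice.
* Power to detect a 1.5-logit detection-channel effect with 15 donors and
  person SD 1.0 is near the 80% design target only with ~40 cells per
  donor and a well-balanced SNP; smaller panels or rarer alleles drop it
  quickly.
* Pearson correlations including zeros on this scale conflate
  co-detection with co-expression amplitude; the module analysis is
  validated in the no-dropout regime and should be interpreted
  accordingly on real data.
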