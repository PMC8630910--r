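# monoqtl

Expression quantitative trait locus (eQTL) mapping for **single-cell qPCR
panels** in purified immune-cell subsets — built for the design where a
small cohort (~15 donors) contributes tens of cells per donor in two
closely related subsets (classical CD14++CD16− and non-classical
CD14dimCD16+ monocytes), a ~90-gene panel is measured as threshold cycles
(CT) on a Fluidigm-style instrument, and a handful of disease-risk SNPs is
genotyped per donor.

Data of this type are zero-inflated (reactions at or above the limit of
detection are non-detected) and strongly correlated within donor. A naive
per-cell test treats correlated cells as independent — pseudoreplication —
and rejects true null hypotheses many times more often than its nominal
level. `monoqtl` implements the dropout-aware alternative: an ensemble of
four association methods, each with a person-level random intercept,

| method | response | model |
|---|---|---|
| `tweedie` | expression incl. zeros | Tweedie GLMM, log link, power ∈ (1,2), REML |
| `logistic` | detection indicator | logistic GLMM (genes >98% detected excluded) |
| `gaussian_nonzero` | detected values only | Gaussian LMM, Satterthwaite df |
| `proportion_anova` | per-donor on-proportion | one-way ANOVA, genotype as factor |

with additive minor-allele dosage as the fixed effect, Wald t inference on
donor-level degrees of freedom, and Benjamini-Hochberg retention at
FDR < 0.1 within each (cell type × method) family. On top of the scan it
provides cross-cell-type **sharing bookkeeping** (shared = significant in
both subsets with the same direction), person-level **on/off pattern
detection**, and **co-expression modules** from an individual-averaged
gene-gene correlation PCA (|loading| > 0.7 on the dominant component),
plus a seeded synthetic-data generator with known ground truth that backs
every claim with simulation.

The package is tidyverse-native: readers return long tibbles, every
analysis function takes a data frame first and returns a tibble, fitted
objects have `tidy()`/`glance()` methods, and result types have plot
functions (`plot_pc_scores()`, `plot_gene_by_individual()`, `autoplot()`).

## Worked example

Simulate a powered dataset (a detection-channel eQTL of 1.5 logits/allele
planted on gene `G001` × SNP `snp2`), run QC and the scan, and inspect the
hits:

```r
library(monoqtl)
library(dplyr)

sim  <- make_powered_fixture(seed = 5002, n_genes = 6, n_snps = 2,
                             cell_types = "CL")
expr <- ct_to_expression(sim$ct, total_cycles = 40, lod = 28)
res  <- run_eqtl_scan(expr, sim$genotypes,
                      methods = c("logistic", "proportion_anova"))
filter(res, gene == "G001", rsid == "snp2") |>
  select(method, estimate, p_value, fdr_q, retained, direction)
#> # A tibble: 2 × 6
#>   method           estimate p_value  fdr_q retained direction
#>   <chr>               <dbl>   <dbl>  <dbl> <lgl>    <chr>
#> 1 logistic            1.48  0.00280 0.0336 TRUE     +
#> 2 proportion_anova    0.368 0.0226  0.272  FALSE    +
```

The logistic mixed model recovers the planted log-odds (1.48 vs 1.5) and
retains the pair at FDR < 0.1; the direction `+` means detection rises
with minor-allele dosage. The coarser on-proportion ANOVA sees the same
direction but misses the cutoff on this replicate.

The sharing bookkeeping, run on the bundled table of 25 published
significant monocyte eQTL associations:

```r
sharing_analysis(monocyte_eqtl_hits())
#> <sharing_summary>
#>   25 significant records over 24 SNP-gene pairs
#>   shared: 1 | CL-exclusive: 5 | NCL-exclusive: 18 | discordant: 0
#>   transcripts hit by multiple SNPs: IRF1, TNFA, TYK2
```

One pair (SPP1 rs9138 with the IRF1 transcript) is shared between the
subsets; 18 pairs are exclusive to non-classical and 5 to classical
monocytes, and in non-classical cells IRF1 is associated with three
different risk SNPs.

## Command line

A thin CLI over the same functions ships in `inst/cli/monoqtl.R`:

```sh
Rscript inst/cli/monoqtl.R simulate --seed 1 --out-dir sim/ --powered
Rscript inst/cli/monoqtl.R run --ct sim/ct_matrix.csv \
    --genotypes sim/genotypes.tsv --out-dir results/ --fdr 0.1
```

`run` executes the full pipeline (QC → scan → sharing → on/off →
co-expression) and writes TSV/JSON outputs plus a manifest with per-stage
record counts.
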