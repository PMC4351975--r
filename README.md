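# conetdiff

Differential co-expression network analysis between two cohorts.

`conetdiff` is an R package for asking how the *organization* of a
transcriptome — not just the expression level of individual genes — differs
between two groups of subjects, and how that organization relates to a
quantitative phenotype such as the insulin sensitivity index (S_I). It was
built for two-cohort microarray studies (e.g. adipose tissue expression in
two ethnic groups of unequal size, 99 and 37 subjects), but applies to any
pair of expression matrices with per-sample covariates and phenotypes.

## What it computes

Starting from probes × samples expression matrices, covariates (age, sex)
and phenotypes, the pipeline performs:

1. **Preprocessing** — detection-p probe filtering (p ≤ 0.01 in ≥ 90% of
   samples), covariate adjustment by OLS (`expression ~ age + sex`, fitted
   jointly across cohorts so group differences survive into the
   residuals), two-group differential expression (Student's t on
   residuals, ≥ 1.2-fold intensity change, p ≤ 0.05), and a per-probe
   Spearman screen against each trait with Benjamini–Hochberg FDR.
2. **Weighted co-expression networks** (per cohort) — Pearson correlation
   → unsigned power adjacency `a_ij = |r_ij|^β` (β chosen by the
   scale-free topology criterion; the study setting is β = 5) → the
   topological overlap matrix

   `TOM_ij = (ℓ_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
   `ℓ_ij = Σ_{u≠i,j} a_iu a_uj`, `k_i = Σ_{u≠i} a_iu`

   → average-linkage clustering of `1 − TOM` with a tree-variant dynamic
   cut (static cut at 0.99, gap-based branch refinement, minimum module
   size 10). Modules are named by the usual colour vocabulary; "gray"
   collects unassigned probes. Each module's hub is the member with the
   highest TOM-based intramodular connectivity.
3. **Module–trait statistics** — module eigengenes (first principal
   component of standardized module expression), Pearson eigengene–trait
   correlations, and a permutation FDR obtained by shuffling the trait
   across samples (associated: p ≤ 0.05 and FDR ≤ 0.05).
4. **Modular differential connectivity (MDC)** — per module, the ratio of
   the summed pairwise adjacency of its gene pairs in cohort A to the
   same pairs in cohort B; MDC > 1 is a gain of co-regulation, < 1 a
   loss. Significance comes from two permutation nulls — shuffled samples
   and shuffled gene labels — with the **larger** of the two FDR
   estimates taken as final.
5. **Cross-network conservation** — module-membership overlap between the
   two cohorts' partitions by one-sided Fisher's exact test (log-space
   hypergeometric tails, Bonferroni threshold `α / (m_A · m_B)`), gene
   signature enrichment, and conserved / cohort-specific classification
   of trait-associated modules.
6. **Key-driver analysis** — per-module mutual-information networks
   (Gaussian-copula MI with a permutation significance screen), indirect
   edges removed by the data processing inequality (DPI), and key drivers
   nominated as nodes whose 2-hop neighbourhood count (NHNN) exceeds
   mean + SD.

A synthetic-data module (`simulationConfig()`, `generateCohorts()`)
plants modules, trait correlations, connectivity differences and mean
shifts through a latent-factor model, so every stage can be benchmarked
against known ground truth.

## Worked example

```r
library(conetdiff)
library(SummarizedExperiment)

sim <- generateCohorts(simulationConfig(seed = 42))   # 99 + 37 samples
adj <- adjustCovariatesJoint(sim$cohortA, sim$cohortB)

net <- buildCoexpressionNetwork(adj$A, beta = 5)
cm  <- clusterModules(net, hierCutoff = 0.99, minModuleSize = 10)
cm$partition
#> ModulePartition: 1000 probes, 5 modules, 748 gray
#>   largest: blue (51), turquoise (51), brown (50), green (50), yellow (50)

eg <- moduleEigengenes(adj$A, cm$partition)
mt <- moduleTraitCorrelation(eg, as.data.frame(colData(sim$cohortA)),
                             traits = "S_I", nPerm = 1000, seed = 42)
mt
#>      module trait       r        p      fdr associated
#> 1      blue   S_I -0.5531 2.91e-09 0.000500       TRUE
#> 2 turquoise   S_I  0.6334 1.99e-12 0.000500       TRUE
#> 3     brown   S_I  0.4204 1.48e-05 0.000667       TRUE
#> 4     green   S_I  0.1395 1.68e-01 0.200500      FALSE
#> 5    yellow   S_I -0.0859 3.98e-01 0.388600      FALSE
```

The generator planted trait correlations (0.6, 0.4, −0.5, 0, 0) on its
five modules: the three wired modules are recovered as associated with
S_I (with matching signs), the two null modules are not. Differential
connectivity between the two equally-wired cohorts is, correctly, never
called:

```r
mdc <- mdcPermutationFDR(adj$A, adj$B, cm$partition, beta = 5,
                         nPerm = 100, seed = 42)
mdc[, c("size", "mdc", "fdrFinal", "call")]
#>           size   mdc fdrFinal call
#> blue        51 1.900    1.000 none
#> turquoise   51 0.533    0.835 none
#> brown       50 0.773    0.978 none
#> green       50 1.014    0.998 none
#> yellow      50 1.541    0.967 none
```

(The spread of raw MDC values around 1 reflects the fifth-power
amplification of correlation noise at n = 37; the dual-permutation FDR
absorbs exactly this.) Cross-network overlap p-values are computed in log
space, so extreme significance stays representable:

```r
overlapTestP(57, 441, 268, 17434)
#> FET p = 2.25e-36 (log10 p = -35.65)
```

`runPipeline(cohortA, cohortB, outDir)` executes all six stages and
writes tab-delimited result tables plus a JSON manifest with file hashes,
parameters and the seed; a rerun with the same inputs and seed reproduces
every output bit for bit. A thin command-line wrapper with `simulate` and
`run` subcommands is installed under `inst/scripts/conetdiff`.

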