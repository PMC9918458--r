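# trendsig

Three-state disease-progression gene signatures for thyroid cancer
evolution, with interaction-network module extraction, NanoString-style
validation statistics and ChIP-seq/RNA-seq core-program integration.

## What it does, and for whom

Anaplastic thyroid carcinoma (ATC) is modelled as a de-differentiation of
differentiated thyroid carcinoma (DTC). For an analyst holding a pooled
multi-study log2 expression matrix over normal / DTC / ATC tissue,
`trendsig` derives the genes whose expression moves *monotonically* along
that axis and localizes each gene's deregulation to one of the two
progression steps:

1. **Differential statistics** — per-probe two-sided equal-variance Student
   t-tests for the three pairwise comparisons (DTC vs normal, ATC vs DTC,
   ATC vs normal), Benjamini–Hochberg adjusted within each comparison.
2. **Trend classification** — a gene is deregulated when at least one of its
   probes has q < 0.05 in *all three* comparisons; monotone probes make it
   Trend Up / Trend Down; genes with discordant significant probes are
   excluded.
3. **Standardized fold change (sFC)** — per comparison,
   `sFC = (FC − mean(FC)) / sd(FC)`; with cutoffs `lo = 2`, `hi = 4` the
   trend genes partition into signature **S1** (mainly normal→DTC, e.g. up:
   sFC₁ > 4 and sFC₂ < 2), **S2** (mainly DTC→ATC: sFC₁ < 2 and sFC₂ > 4)
   and **S3** (both steps: sFC₁ > 2 and sFC₂ > 2), with mirrored negative
   cutoffs for down-regulated genes.
4. **Gene module** — signature genes are mapped into a STRING-style edge
   list and the disease module is the largest connected component.

Companion stages normalize NanoString panel counts (negative-control
background, positive-control and housekeeping geometric-mean factors) and
reproduce the validation statistics (panel differential test, matched-pair
comparison, percent-expressing, ΔΔCt); the regulome stage filters ChIP-seq
peaks to a ≥ 2-of-3 replicate consensus, assigns peaks to genes within a
±3 kb TSS window, and intersects knockdown DEG tables from two cell lines
with the ChIP targets into a core transcription-factor program. A
synthetic-data generator with planted truth makes every stage testable
without external data. The methods vignette
(`vignettes/trend-signatures-methods.Rmd`) documents the model, parameter
choices and limitations.

## Worked example

```r
library(trendsig)

cfg <- synth_expression_config(n_norm = 30, n_dtc = 30, n_atc = 20,
                               n_genes = 600, planted = default_planted(10),
                               seed = 42)
sim <- gen_multistudy_expression(cfg)
res <- derive_signatures(sim$matrix, sim$sheet, sim$probe_map)
res$counts$signature_sizes
#>         down_S3 down_unassigned           up_S3   up_unassigned
#>              10               1               6               2

head(res$signatures[res$signatures$signature != "unassigned", ], 3)
#>   gene_id direction sfc_step1 sfc_step2 signature
#> 1   g0041        up  3.378123  2.735160        S3
#> 2   g0042        up  2.598860  2.932924        S3
#> 4   g0044        up  3.109746  2.616249        S3

evaluate_signature_recovery(res, sim$truth)[c("n_recovered",
  "direction_sensitivity", "archetype_accuracy")]
#> $n_recovered          [1] 18
#> $direction_sensitivity[1] 1
#> $archetype_accuracy   [1] 0.8888889
```

Reading the output: of 60 planted genes, 18 are recovered as trend genes —
at these effect sizes only the S3-like archetypes can satisfy the
all-three-comparisons rule (S1/S2 have a zero effect in one comparison), so
recovery is evaluated conditionally. Every recovered gene has the planted
direction, and 16/18 land in their planted archetype; the two misses are
sFC values that fall just outside the strict cutoffs. The up-regulated S2+S3
genes then feed the network stage:

```r
edges <- gen_interaction_network(
  sim$truth$gene_id[sim$truth$direction == "up" &
                      sim$truth$archetype %in% c("S2", "S3")],
  setdiff(unique(sim$probe_map$gene_id), sim$truth$gene_id)[1:150],
  seed = 43)
mod <- extract_module(res$signatures, edges)
length(mod$module); mod$fraction
#> [1] 6
#> [1] 100
```

All 6 mapped signature genes aggregate into one connected component
(module fraction 100%). File-level wrappers (`run_signature_pipeline()`,
`run_core_pipeline()`, `write_synthetic_bundle()`) perform the same
computations from TSV/GTF/BED inputs and write signature tables, module
lists, consensus BED and Venn-count JSON; `inst/cli/trendsig.R` exposes them
as a small command line.

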