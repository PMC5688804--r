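# tnbctriage

Triple-negative breast cancer (TNBC) — tumors lacking estrogen receptor (ER)
and progesterone receptor (PR) expression and HER2 amplification — has no
targeted therapy. `tnbctriage` implements, as a tested and reusable R
package, the computational chain used to nominate new drug targets for TNBC
from multi-omics tumor data:

1. **Receptor classification.** Log2 expression of *ESR1*, *PGR* and *ERBB2*
   is fitted per marker with a two-component Gaussian mixture by EM (equal
   "E" or variable "V" component variances); the E/V combination with the
   highest concordance against available immunohistochemistry labels is
   selected, samples are called positive when the posterior of the
   high-expression component exceeds 0.5, and TNBC = negative for all three
   markers.
2. **Differential expression.** An empirical-Bayes moderated t-statistic on
   log2(x+1) upper-quartile-normalized values with posterior variance
   s̃² = (d0·s0² + d·s²)/(d0 + d), Benjamini-Hochberg FDR, and the published
   gates: up means log2FC ≥ +1 (fold-change ≥ 2) and FDR ≤ 0.05, inclusive.
   Category enrichment uses the Wallenius noncentral hypergeometric
   distribution (exact sequential-urn recursion).
3. **Methylation integration.** Beta values are quantile normalized and
   logit transformed to M-values (M = log2(β/(1−β))); probes are tested with
   the same moderated-t engine, annotated with CpG island/shore (≤2 kb) /
   shelf (≤4 kb) / open-sea context, mapped to the nearest TSS, averaged per
   gene over promoter-island probes, and correlated with expression
   fold-change. Genome tracks average both signals in 5-Mbp bins.
4. **Proteomics concordance and triage.** Protein fold-changes are
   correlated with mRNA fold-changes; genes upregulated in all three
   comparisons (TNBC vs non-TNBC tissue, TNBC vs normal, TNBC vs non-TNBC
   cell lines) pass through four sequential druggability gates — fewer than
   2 publications, structure available, structurally druggable, ligand-based
   druggability percentile ≥ 75 — and survivors are ranked by percentile.

Because the original cohorts are controlled-access, the package ships a
synthetic-cohort generator (`simulate_cohort()` and friends) that plants
bimodal markers, negative-binomial fold-changes, promoter hypomethylation,
mRNA-correlated protein levels and exactly one fully druggable novel target,
with every latent quantity recorded in a truth table — so the whole pipeline
is testable end-to-end on a laptop.

## Worked example

```r
library(tnbctriage)
run <- run_scenario(simulation_config(seed = 7))
glance(run)
#> # A tibble: 1 × 13
#>    seed n_tumors tnbc_accuracy modes mean_de_recall mean_de_fdp n_common_up
#>   <int>    <int>         <dbl> <chr>          <dbl>       <dbl>       <int>
#> 1     7      180         0.994 EEE                1      0.0136          20
#> # i 6 more variables: n_common_down <int>, meth_expr_r <dbl>,
#> #   protein_mrna_r <dbl>, target_rank <int>, n_passing <int>,
#> #   target_unique_top <lgl>

run$triage$stage_counts
#> # A tibble: 5 × 2
#>   stage                   n
#>   <chr>               <int>
#> 1 common_up              20
#> 2 novelty                 9
#> 3 structure               4
#> 4 structure_druggable     4
#> 5 ligand_percentile       1
```

Reading the output: 180 simulated tumors were classified from the marker
mixtures with 99.4% TNBC-call accuracy against the planted truth (the
equal-variance mode was selected for every marker, matching the generator);
all planted differentially expressed genes were recovered with a 1.4% false
discovery proportion; 20 genes were upregulated in all three comparisons,
and the druggability cascade narrowed 20 → 9 → 4 → 4 → 1, leaving the
planted target as the unique rank-1 candidate. `run$meth_expr_r` and
`run$protein_mrna_r` hold the methylation-expression (negative) and
protein-mRNA (positive) fold-change correlations. Individual stages are
exposed as plain functions (`fit_two_component()`, `moderated_t_test()`,
`bh_adjust()`, `wallenius_enrichment()`, `annotate_context()`,
`map_probes_to_genes()`, `triage()`, ...) that take tabular data and return
tibbles; `autoplot()`/`plot_volcano()`/`plot_fc_concordance()`/
`plot_binned_track()` draw the standard figures.

## Package layout

- `R/io.R`, `R/config.R` — TSV/BED3/YAML readers and writers, thresholds.
- `R/normalize.R` — upper-quartile scaling, log2(x+1), quantile
  normalization, beta/M transforms.
- `R/mixture.R` — EM mixtures, model-combination selection, TNBC calls.
- `R/diffexpr.R`, `R/wallenius.R` — moderated t, BH, enrichment.
- `R/methylation.R` — differential methylation, CpG context, TSS mapping,
  gene summaries, genome binning.
- `R/integrate.R`, `R/run.R` — intersections, concordance, triage,
  knockdown metrics, the end-to-end scenario runner.
- `R/simulate.R` — the planted-truth generator and scenario writer.
- `vignettes/tnbc-target-discovery.Rmd` — models, assumptions, parameter
  choices and limitations.
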