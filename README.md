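# trajectome

Longitudinal two-timepoint transcriptome/epigenome integration for
case–control designs, built around the analysis pattern of rodent traumatic
brain injury (TBI) studies: RNA-seq at an acute (day 1) and a recovery
(day 14) timepoint in injured vs sham hippocampus, with matched promoter
H3K4me3 ChIP-seq pileups at day 1.

## What it computes

1. **Moderated differential expression per timepoint** (`fit_moderated_de`).
   Voom-style precision weights from a lowess mean–variance trend on
   log2 CPM, empirical-Bayes shrinkage of residual variances, moderated *t*
   with augmented degrees of freedom, Benjamini–Hochberg FDR. Effective
   library sizes are TMM-scaled by default. DEGs are called at adjusted
   *p* < α (default 0.05) with direction from the sign of log2 FC
   (injury − sham).

2. **Eight-way trajectory classification** (`classify_trajectory`,
   `assign_trajectories`). Every gene DE at either timepoint is assigned to
   exactly one module from its (day 1, day 14) status pair and the relative
   magnitude |log2FC₁₄| vs |log2FC₁|:
   i persistent/growing up, ii up with partial recovery, iii delayed up,
   iv acute up with full recovery, v acute down with full recovery,
   vi delayed down, vii down with partial recovery, viii persistent/deepening
   down; sign-flipping genes are `discordant`, everything else `unassigned`.
   Profiles are anchored to the sham day-14 baseline (mean log2 RPKM) with
   model fold changes: `value_t = baseline + log2FC_t`.

3. **Per-module GO over-representation** (`hypergeom_ora`, `enrich_modules`).
   Hypergeometric upper tail P(X ≥ k) against the universe of tested genes,
   BH adjustment plus Storey q-values (fixed λ = 0.5), cutoffs applied as
   adj p ≤ 0.05 and q ≤ 0.05.

4. **Promoter H3K4me3 differential scoring** (`score_promoters`). Mean
   bedGraph pileup coverage over TSS ± 1 kb, depth-normalized to
   signal-per-million, within-sample fractional ranks (the
   sensitivity-compensation device for cross-dataset comparison), and the
   signed Poisson log₁₀ likelihood ratio per gene

   score = sign(x − y) · [x ln(x/m) + y ln(y/m)] / ln 10,  m = (x + y)/2

   with x, y the pseudo-count-stabilized injury/sham normalized coverages —
   the `bdgdiff`-style statistic restricted to promoters. Top-100 up/down
   gene lists and a "strong enrichment" rank-box flag (sham rank ≤ 0.2,
   injury rank ≥ 0.8) come with it.

5. **Module–epigenome association** (`module_anova`). One-way ANOVA of the
   signed score over groups {i…viii, NS} where NS = never-DE genes, with
   Tukey–Kramer (studentized range, unequal n) family-wise adjusted
   module-vs-NS contrasts and star annotations.

6. **Synthetic data with ground truth** (`simulate_counts`,
   `simulate_pileups`): negative-binomial counts with per-module effects,
   one batch per timepoint, log-normal library sizes; Poisson promoter
   pileups correlated with expression, with per-sample sensitivity factors
   and condition-dependent promoter-mark shifts. Analysis stages never see
   the truth table.

## Worked example

```r
library(trajectome)

sim <- simulate_counts(2000, seed = 7)          # 2 sham/4 injury at day 1, 4/4 at day 14
d1  <- fit_moderated_de(sim$cm, "day1")
d14 <- fit_moderated_de(sim$cm, "day14")
asg <- assign_trajectories(sim$cm, d1, d14)
table(asg$module)
#> discordant          i         ii        iii         iv unassigned          v
#>          1         10         21         10        188       1510        253
#>         vi        vii       viii
#>          4          2          1
```

188 genes are called acutely upregulated with full recovery (module iv) and
253 acutely downregulated with full recovery (module v) — the two dominant
trajectories in this simulated injury, as in real TBI hippocampus — while
the rare persistent modules (i, viii) stay small. Cross-tabulating against
`sim$truth$true_module` shows per-module recall ≥ 0.8 at these effect sizes
with ~1% false assignment among null genes.

Promoter side:

```r
chip <- data.frame(id = c("sham_c1","sham_c2","injury_c1","injury_c2"),
                   condition = rep(c("sham","injury"), each = 2),
                   timepoint = "day1")
tracks <- simulate_pileups(sim$truth, sim$cm$genes, chip, seed = 8)
ptab   <- score_promoters(tracks, sim$cm$genes, chip)
res    <- module_anova(setNames(ptab$score, ptab$gene), asg)
res[, c("group","n_genes","contrast_vs_ns","tukey_p_vs_ns","stars")]
```

Positive `contrast_vs_ns` with stars marks modules whose promoters gained
H3K4me3 after injury relative to non-DE genes.

## Pipeline and CLI

`run_all(config)` orchestrates dge → trajectory → enrichment and
chip → integration from a JSON config, writing TSVs with `#` provenance
headers (`dge_day1.tsv`, `trajectory_modules.tsv`, `sankey.tsv`,
`enrichment_module_*.tsv`, `promoter_scores.tsv`, `top100_up.txt`,
`module_h3k4me3_association.tsv`, …). The installed `trajectome` script
exposes `simulate`, `run-all` and per-stage subcommands.

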