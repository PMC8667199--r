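---
title: "Methods: two-timepoint trajectory modules and promoter H3K4me3 integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory modules and H3K4me3 integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajectome)
```

## The problem

Moderate experimental brain injury produces transcriptional programs that
differ not only in direction but in *timing*: cell-death and inflammatory
genes surge within a day and mostly recover by two weeks, while
cholesterol-metabolism and neurodegeneration-associated genes can emerge or
deepen only at the later timepoint. A two-timepoint injury/sham design
(day 1 and day 14) supports a compact description of these dynamics: call
differential expression separately at each timepoint, then classify every
affected gene by its (day 1, day 14) status pair and by whether the effect
grew or shrank. On the chromatin side, promoter H3K4me3 — a mark tracking
transcriptional activity — lets one ask whether expression trajectories are
mirrored by epigenetic changes already present at day 1.

This vignette records the model choices, defaults, and limitations behind
each stage.

## Differential expression model

Counts are modelled on the log2 CPM scale,
`log2((count + c0) / (L + 2 c0) * 1e6)` with prior count `c0 = 0.5`
(default; recorded in output headers). Per timepoint, a linear model with
condition (sham reference) — plus batch when two or more batches exist
*within* the timepoint — is fitted by weighted least squares, with
observation weights derived from a lowess trend (span 0.5) of sqrt residual
standard deviation against mean log count; residual variances are shrunk
toward a global prior by empirical Bayes, and the moderated *t* uses the
prior-augmented degrees of freedom. This is the voom/limma construction and
is delegated to limma behind the package's interface; with `use_weights =
FALSE, moderate = FALSE` the same code path reduces to an ordinary per-gene
least-squares *t*-test, which the test suite verifies against `stats::lm`
gene by gene.

**Effective library sizes are TMM-scaled by default.** This is a deliberate
addition beyond the plain-CPM formula: in realistic simulations where ~10%
of genes are induced four-fold at day 1, raw library sums absorb part of
the induction and push null genes into apparent downregulation (~5% of
nulls called DE, all one direction). Trimmed-mean scaling removes the
composition bias; `norm_method = "none"` restores plain library sizes. A
corollary worth stating: if *every* gene changed by the same factor, no
global-scaling normalization could detect it — the data would be
indistinguishable from deeper sequencing. Recovery claims are therefore
made for dominant-but-partial DE fractions, never for 100%.

The low-expression filter keeps genes with CPM > 1 in at least
min-group-size samples (voom-standard; configurable). Filtered genes carry
no p-values and are `ns` by definition. BH adjustment runs across all
unfiltered genes at the timepoint; DEG calls use strict `adj_p < alpha`
(α = 0.05), with the raw-p variant exposed (`use_adjusted = FALSE`) because
display conventions sometimes use it, but corrected p is the default
everywhere.

Each timepoint is fitted independently rather than through one interaction
model: the scientific contrasts are "injury vs sham at day 1" and "… at
day 14", and the independent fit matches them directly. In the default
confounded design (one batch per timepoint) the batch term drops out of the
within-timepoint contrast automatically.

## Trajectory modules

Genes significant at either timepoint are partitioned by the decision table
in `?classify_trajectory`. Two choices were genuinely open:

* **Magnitude splits.** Modules i/ii (both-up) and vii/viii (both-down) are
  separated by comparing |log2FC₁₄| with |log2FC₁| from the fitted models.
  Exact ties go to the closed side of the inequality (ii and viii); with
  continuous estimates ties have measure zero, so this is a determinism
  guarantee rather than a scientific claim.
* **Sign-flipping genes.** A gene significantly up at one timepoint and
  down at the other fits none of the eight modules; forcing it into one
  would corrupt the partition property (Σ module sizes = genes DE at either
  timepoint). Such genes get their own `discordant` label. They are rare in
  practice (0–2 per few thousand genes in simulations).

Profiles anchor to sham at day 14 — sham animals having recovered from the
acute surgical insult, this is the most "uninjured" cell of the design —
as the mean log2 RPKM (RPKM = count / (length-kb · library-millions), prior
count 0.5 inside the log), and add the *model* fold changes rather than raw
group means, so the displayed trajectory inherits the batch correction and
shrinkage of the fit.

## Over-representation analysis

Per module, the overlap k between module genes and each gene-set term is
tested with the hypergeometric upper tail P(X ≥ k); the universe is the set
of genes that survived the expression filter (genes that could never have
been called DE do not belong in the background). Terms are testable when
their in-universe size lies in [10, 500] (clusterProfiler-like defaults,
configurable). Multiplicity is handled twice, as is conventional for this
output format: BH-adjusted p, and a Storey q-value with fixed λ = 0.5 and
no smoother — deterministic, and within a constant π₀ ≤ 1 of BH, which the
tests assert. Cutoffs are applied as ≤ 0.05 on both adjusted p and q. An
empty enrichment for a module is a legitimate result and is preserved as an
empty table.

## Promoter H3K4me3 scoring

The promoter is TSS ± 1,000 bp (half-open, strand-aware TSS; the
conventional window for this mark — no universal definition exists, so the
flank is explicit config). Pileup coverage is averaged over the window
exactly (interval-overlap arithmetic, IRanges-backed), normalized to
signal-per-million of each track's total signal, and summarized per
condition by averaging replicates *after* normalization (the pairing of
injury to sham samples in unequal-n designs is otherwise arbitrary).

Two comparison devices coexist deliberately:

* **Fractional ranks within sample** are invariant under any monotone
  per-sample distortion — the defensible way to compare ChIP datasets of
  different sensitivity. The rank pair (sham, injury) per gene feeds the
  scatter and the strong-enrichment box (sham rank ≤ 0.2 · N and injury
  rank ≥ 0.8 · N by default; the thresholds are explicit because the
  original visual selection has no stated bounds).
* **The signed Poisson log₁₀ likelihood ratio** on normalized coverages,
  `sign(x−y)·(x ln(x/m) + y ln(y/m))/ln 10` with `m = (x+y)/2`, scores the
  *strength* of differential marking; a pseudo-coverage of 1
  signal-per-million guards the near-zero promoters (the role of bdgdiff's
  minimum-depth guard, without re-implementing its genome-wide scan).

Input-control subtraction (floored at zero, before normalization) is
available but off by default. Top-k selection (k = 100 per direction) uses
lexicographic gene-id tie-breaks so repeated runs agree byte-for-byte.

## Module association test

The signed scores of genes in modules i–viii are compared against the NS
reference (genes never DE) in one linear model: its omnibus F is the
one-way ANOVA, its coefficients with NS as reference level are the
contrasts, and each module-vs-NS comparison receives a Tukey–Kramer
family-wise adjusted p. The studentized-range tail uses `stats::ptukey`
(exact CDF) rather than ad-hoc numerical integration. Unequal group sizes
are the norm here — module sizes can span two orders of magnitude — which
is precisely what the Kramer correction addresses. At k = 2 the procedure
collapses to the pooled two-sided t-test (q = √2·|t|), an identity the
tests exploit as an oracle. Groups with fewer than 2 genes are dropped with
a warning; `discordant` genes are excluded from the family.

## Synthetic data: the stated world

`simulate_counts` draws negative-binomial counts (the standard bulk RNA-seq
noise model) with:

* design 2 sham / 4 injury at day 1 and 4 / 4 at day 14 by default — the
  source design is internally inconsistent about day-14 sham n (2 vs 4),
  so group sizes are an explicit, required-to-override parameter;
* per-module log2 effects of ±`effect_scale`, with the larger-magnitude
  timepoint of two-significant modules at 1.5× — a fixed encoding of
  "further increased" / "partial recovery";
* module fractions defaulting to the rough relative sizes seen in injured
  hippocampus (iv and v dominant, vi–viii rare), ~20% of genes DE overall;
* base means log-uniform in [10, 2000], NB dispersions log-uniform in
  [0.02, 0.2] (typical bulk tissue), log-normal library-size factors
  (sd 0.2) to exercise normalization, and one batch per timepoint
  (per-gene batch offsets, sd 0.3 log2) reproducing the confounded
  two-batch design.

`simulate_pileups` gives each promoter a coverage level proportional to an
expression-correlated baseline times the condition's promoter-mark shift
(default `2^(0.5·log2FC)`, i.e. chromatin tracks expression at half
strength; overridable per module) times a per-sample sensitivity factor,
with Poisson bin noise (`noise = 0` produces exact expectations for
invariance fixtures) and constant low background between promoters.

What the generator does **not** emulate: per-cell-type composition shifts,
fragment-length/GC structure, peak shape within promoters, spatial
correlation of coverage, or any sham time-course drift. A green recovery
test therefore establishes that the pipeline recovers the stated NB/Poisson
world — not that real TBI hippocampus data would behave as cleanly.

## Numerical and degenerate-input choices

* BH and Storey computations are hand-written (they are contract surface),
  verified against brute-force references in the tests.
* All coordinates are 0-based half-open internally; 1-based closed gene
  records are converted at the reader boundary (TSS = start−1 for `+`,
  end−1 for `−`).
* A constant response across all association groups yields F = 0 (not NaN)
  by explicit guard.
* `diff_loglr` defines 0·ln 0 = 0, so two dead promoters score exactly 0.
* Every stochastic stage requires an explicit seed; the analysis stages are
  RNG-free and rerun-deterministic, which the pipeline test checks
  byte-for-byte on non-header lines.

## Known limitations

* The moderated fit delegates to limma; numerics can drift across limma
  versions at the last decimals, though all contract properties are
  version-independent.
* The day-1-only focus of the promoter acceptance experiments mirrors the
  design it emulates; the code accepts any timepoint.
* The strong-enrichment box and the 1.5× secondary-effect ratio are
  package conventions where the source analysis left the quantity visual or
  unstated; both are parameters, not constants.
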