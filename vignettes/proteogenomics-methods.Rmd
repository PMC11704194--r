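---
title: "Methods: integrative proteogenomics with protegrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative proteogenomics with protegrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protegrate)
```

`protegrate` implements the statistical core of an integrative tumor
proteogenomics analysis: copy-number effects on mRNA, protein and
phosphoprotein abundance; label-free quantification; single-sample
enrichment and kinase-activity scoring; consensus molecular clustering; and
survival statistics. This vignette records the models, the parameter
choices, and the reasoning behind the design decisions that were genuinely
open.

## Copy-number summaries

Segment tables use 1-based inclusive coordinates (the SEG convention);
overlap lengths are `end - start + 1` on the intersected interval. The
gene-level copy number is the length-weighted mean of the log2 copy ratios
of segments overlapping the gene body. The arm-level score combines the
segment log2 ratios overlapping the arm with each segment weighted by its
overlapped length, **normalized by the total overlapped length**. A raw
weighted sum would scale with arm length and segment coverage; normalizing
keeps arm scores on the log2-ratio scale, so the same symmetric cutoff of 1
defines amplification (value ≥ 1) and deletion (value ≤ −1) at both gene
and arm level. The boundary is inclusive so calls are deterministic at the
cutoff; the raw weighted sum remains available via `normalize = FALSE`.

Tumor mutational burden counts every somatic base substitution and indel,
synonymous alterations included, divided by the captured coding size in Mb
(a user input: capture designs differ and no single constant is correct).

## Mutational signatures

Single-nucleotide variants are tallied into 96 pyrimidine-centred
trinucleotide contexts; purine-reference records are reverse-complemented,
making the matrix invariant to the reported strand. Signatures are
extracted by non-negative matrix factorization under the Frobenius
objective with multiplicative updates: best of 10 seeded restarts, at most
2,000 iterations, stopping when the relative change of the reconstruction
error drops below 1e-6. Profiles are column-normalized to probability
vectors, exposures rescaled accordingly, and each extracted profile is
matched to the reference profile of maximal cosine similarity. The package
does not redistribute any reference catalogue; `reference_signatures()`
constructs synthetic, well-separated profiles (each concentrating mass on
one substitution class with a flank preference) that serve as the reference
in tests and simulations.

## Label-free quantification

iBAQ divides a protein's summed peptide XIC intensity by its count of
theoretically observable peptides. The observability rule — fully tryptic
peptides (cleavage C-terminal of K/R, suppressed before proline), no missed
cleavages, length 7–30 — is a common iBAQ convention; it is exposed as
arguments because the choice is not canonical. FOT normalization divides
each iBAQ by the sample's total over all quantified proteins of that run
and scales by 1e6, so each column sums to 1e6 before imputation; missing
values are then set to 1e-5 and recorded in an imputation mask. Imputation
after scaling follows the natural order of the procedure (the imputed
constant is a floor value, not a measured fraction). Rank-based statistics
downstream exclude masked cells by default, because a constant imputed
value would otherwise create massive ties at the bottom of every ranking.
Phosphosites require localization probability strictly greater than 0.75;
reported residue percentages are rounded half-up to one decimal.

## The cis-effect ledger

For each gene, Spearman's correlation (average ranks on ties; two-sided p
from the t approximation) is computed between gene-level copy number and
that gene's own abundance per layer, on pairwise-complete non-imputed cells
with at least 10 shared samples. *Cis* is defined at gene resolution — the
copy number of a gene against its own mRNA, protein, or phosphoprotein
(phosphosites collapsed to the protein's most abundant site). A peak-based
definition of the aberrant locus would be an alternative; gene resolution
was chosen because it needs no peak caller and makes the ledger
self-contained. BH adjustment is applied within each (layer, mode) family
separately, mirroring per-layer reporting of significant cis counts.

## Enrichment and activity scores

One rank-based single-sample engine serves all set-level scores. Per
sample, features are ranked by abundance; the enrichment score of a set is
the summed difference between the weighted in-set ECDF (weights
|rank|^alpha, alpha = 0.25) and the unweighted out-of-set ECDF. Scores are
invariant to any strictly monotone transform of a sample's abundances.
Cohort-level normalization divides all scores by the max − min enrichment
score. Alpha and the normalization are exposed since neither is canonical.
TF activity is the same score on a TF's target set; single-target TFs fall
back to the target's z-scored abundance (the rank-ECDF score of a singleton
set is nearly degenerate). The multi-gene proliferation score is the mean
of per-gene z-scores across samples, with zero-variance genes contributing
0. Over-representation uses the one-sided hypergeometric upper tail with BH
across sets.

KSEA scores a kinase per sample as z = (s̄ − p̄)·√m / δ, where s̄ averages
the kinase's m mapped substrate-site log2 abundances and p̄, δ are the mean
and SD over all sites of that sample. Sites, not proteins, are the
aggregation unit, and a site shared by several kinases counts for each.
Two modes are provided because cohort designs differ: absolute abundance,
and fold change against the cohort mean per site. The fold-change mode is
the appropriate choice for differential questions — persistent site-level
baselines otherwise dominate s̄ − p̄ — and is what the package's own
acceptance analysis uses. Kinases with fewer than 3 mapped sites are
dropped by default.

## Consensus clustering

Per repetition, 80% of samples (`pItem`) are drawn without replacement and
partitioned by PAM on 1 − Spearman correlation between sample profiles,
computed on the top 50% most variable features (variance by default, MAD
optional — the dispersion statistic is not canonical). The same subsamples
are reused across the candidate k. The consensus of a sample pair is its
co-clustering count over its co-sampling count; final labels come from
average-linkage hierarchical clustering of 1 − consensus, the convention of
the resampling-clustering packages this reproduces. Model selection reports
the consensus CDF, the relative delta-area of its AUC, and the mean
silhouette on 1 − consensus; `chosen_k` maximizes the mean silhouette,
which on planted-structure cohorts agrees with the delta-area elbow while
being a single deterministic rule. Repetitions default to 200 in the
package's own analyses — consensus entries are binomial proportions over
co-sampling counts, so 200 repetitions give standard errors below 0.04,
sufficient to resolve the near-0/1 block structure that drives k selection;
the `reps` argument accepts the much larger values used in production
cohort studies. Degenerate repetitions in which all subsampled profiles are
effectively identical are assigned a single cluster rather than an
arbitrary k-way split.

## Survival statistics

Kaplan–Meier curves and the log-rank test delegate to the `survival`
package; the univariate Cox fit uses Efron tie handling (the better
approximation under tied event times; the data are months, so ties occur).
The maximally selected rank-statistic cutpoint scans all admissible splits
of a continuous marker — both groups at least `minprop` = 0.1 of the cohort
(the convention of the cutpoint tools this mirrors) — and maximizes the
standardized log-rank score statistic computed from Nelson–Aalen log-rank
scores, with ties resolved toward the lower cutpoint. The naive log-rank p
at the selected cutpoint ignores the selection and is anti-conservative (on
null simulations it rejects at several times the nominal rate); the
permutation-adjusted p — the fraction of marker permutations whose own
maximal statistic reaches the observed one — restores the nominal type-I
error and both are reported. Differential abundance offers Wilcoxon,
Student t, Kruskal–Wallis and one-way ANOVA; fold changes are ratios of
group means on the unlogged scale with imputed cells excluded, and
significance flags follow configurable fold-change and BH-q thresholds
(analyses in this domain use 2 for tumor/normal contrasts and 1.5 for
subgroup contrasts; both are wired through configuration, not hard-coded).

## The synthetic cohort generator

`generate_cohort()` emulates the data a proteogenomic cohort provides:
SEG-style segments with planted arm-level events (default: one arm loss in
35% of samples, shift −1.2) and focal events (one deletion, one
amplification, ~5 genes each); dosage-coupled cis genes whose log2
abundance gains `slope × copy ratio` (default 20 genes, slope 1.5);
three proteomic clusters with disjoint program genes up-shifted by 1 log2
unit; kinases whose substrate phosphosites shift with the sample's cluster;
mutation contexts drawn per sample from a Dirichlet-distributed mixture of
the synthetic reference signatures; and exponential survival with
cluster-specific hazard ratios (default 2 for the second cluster) under
independent Uniform(0, 120 months) administrative censoring — the simplest
mechanism satisfying the non-informative censoring assumed by log-rank and
Cox. Abundances are generated on the log2 scale and exponentiated to
positive FOT-like values, matching the log-based statistics downstream
while keeping files realistic. One global seed drives fixed, documented
substreams (segments, expression, survival, mutations, peptides, clusters),
so adding a stream never perturbs another and outputs are bit-identical
under a fixed seed.

Defaults were chosen once for testability: effect sizes (dosage slope 1.5
against residual SD 0.5, i.e. slope/noise = 3; program shift 1.0) are large
enough that a correctly implemented pipeline recovers the planted structure
with high sensitivity at n = 100, yet small enough that a subtly wrong
statistic fails. What the generator does **not** emulate: tumor-purity
admixture, batch effects, missing-not-at-random dropout, correlated gene
programs beyond the planted ones, or raw reads/spectra. Passing tests
therefore demonstrate correctness of the statistical machinery on its
stated model, not robustness to every artefact of real cohorts.

## Problem sizes in the packaged analyses

The packaged tests and the acceptance analysis run on scaled cohorts chosen
as the smallest sizes at which the planted effects are identifiable with
comfortable margins: cis recovery on 20 cohorts of n = 100 samples × 300
genes; consensus clustering on n = 60 × 300 with 200 repetitions; KSEA on
20 cohorts of n = 50 with 8 decoy kinases; signature recovery from ~10,000
SNVs; null calibration on 20 null cohorts and 200 null survival datasets
with 300 marker permutations each. The same code paths accept
production-scale inputs unchanged.

## Known limitations

Gene-resolution cis definition (no peak-based loci); no spillover
compensation between correlated cell-type signatures; no Gaussian-kernel
variant of the enrichment score (the rank-ECDF form is the one
implemented); the consensus-clustering final-label step follows the
hierarchical-on-consensus convention rather than re-running PAM on the full
cohort; the Cox interface is univariate (multivariate selection is out of
scope); and the anti-conservativeness of naive selected-cutpoint p values
means reported survival splits should cite the permutation-adjusted p.
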