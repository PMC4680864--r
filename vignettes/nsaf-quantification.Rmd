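---
title: "Label-free quantification with normalized spectral abundance factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free quantification with normalized spectral abundance factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsafq)
library(dplyr)
```

## The problem

In label-free shotgun proteomics, the number of MS/MS spectra assigned to a
protein (its spectral count, SpC) is a proxy for its abundance — but a biased
one, because longer proteins yield more tryptic peptides and therefore more
spectra, and because the total number of spectra acquired differs between
runs. nsafq implements the standard correction, the **normalized spectral
abundance factor**, and the downstream statistics of a two-condition
comparison with biological replicates: which proteins are differentially
abundant, how reproducible the replicates are, which functional categories
are over-represented among the changes, and how the protein-level changes
relate to mRNA-level changes.

The motivating design is a mouse embryonic stem cell experiment comparing
"2i" ground-state culture against conventional serum culture, with three
biological replicates per condition and roughly 1,500–2,000 reproducibly
identified proteins — but nothing in the package is specific to that system
beyond the defaults.

## The abundance model

For protein $k$ in sample $i$ with spectral count $\mathrm{SpC}_{ik}$ and
length $L_k$ residues,

$$
\mathrm{NSAF}_{ik}
  = \frac{(\mathrm{SpC}_{ik} + f)/L_k}
         {\sum_j (\mathrm{SpC}_{ij} + f)/L_j},
$$

so NSAF is a *composition*: within each sample the values are positive and
sum to exactly 1. Two details matter.

**Length.** When a protein's sequence length is not available it is
estimated as molecular weight divided by the average amino-acid residue
mass, `avg_aa_mw_da = 111.1254` Da (the mean residue mass of proteins; no
authoritative constant exists, so it is exposed as a parameter). An
explicit `length_aa` always takes precedence. Because the constant cancels
in the normalization only when applied uniformly, it is applied uniformly.

**Pseudo-count.** The spectral fraction $f$ (default 0.5) is added to every
raw count *before* length division and normalization, which keeps each
sample's NSAF sum exactly 1 and makes every value strictly positive, so the
natural-log transform `log_nsaf` is always finite. The alternative reading
— adding $f/L_k$ after length division — is available via
`pseudo_after_length = TRUE` for sensitivity analysis; both keep the
per-sample sum at 1 and the choice barely moves anything except zero-count
proteins. The pipeline refuses $f = 0$ combined with an all-zero sample,
where the normalization is undefined.

The base of the log is a display choice only: the t statistic is invariant
to it. Natural log is used throughout and axes are labelled accordingly.

## Reproducibility filter and differential test

A protein is *reproducibly identified* when at least one condition detects
it (count > 0) in **every** replicate and its total raw count within that
same condition reaches `min_total = 5`. The phrase "total count of minimum
5" is ambiguous between within-condition and across-all-samples totals;
the within-condition reading is the default and the other is available as
`scope = "overall"`.

Testing is a per-protein unpaired two-sample t-test on `log_nsaf`.
Student's pooled-variance form is the default — with three replicates per
group there is little information to estimate separate variances, and
pooled t is the common practice in NSAF studies — with Welch available via
`equal_var = FALSE`. The implementation is a vectorized closed form
(pooled variance, $df = n_a + n_b - 2$); the test suite checks it against
`stats::t.test` to $10^{-10}$. Degenerate inputs follow explicit
conventions: zero variance in both groups with identical means gives
$p = 1$; zero variance with different means gives $p = 0$ (the limit of
the t formula).

The headline significance criterion is raw $p < \alpha$ with
$\alpha = 0.05$, matching how such experiments are usually reported;
Benjamini–Hochberg adjusted values are computed over the tested set and
reported alongside (`bh_fdr`) but do not drive the `direction` call. The
fold `ratio` is built from the *unlogged* condition means of NSAF and
reported as $\max(\bar a/\bar b,\ \bar b/\bar a) \ge 1$ with a categorical
direction, which together reconstruct the signed log2 fold change
losslessly.

## Sample-level diagnostics

`scatter_table()` gives the mean log NSAF of each filtered protein in the
two conditions — the scatter in which unchanged proteins hug the diagonal
and an $r$-fold change sits $\log r$ away from it (only approximately when
many proteins change at once: NSAF is compositional, so large planted
effects shift the normalizing denominator of everyone else).

`spearman_matrix()` computes pairwise Spearman correlation between samples
over the filtered proteins and clusters samples by average linkage on the
distance $1 - \rho$. Spearman is rank-based, so it is identical on NSAF,
log NSAF, or any strictly monotone transform — which is also why nothing
hinges on whether correlations are computed on the raw or logged scale.
Neither the linkage nor the distance is canonical; both are exposed as
arguments.

## Enrichment and category abundance

`fisher_enrich()` is a transparent, local stand-in for web enrichment
services: a one-sided hypergeometric upper-tail p-value per term
($P(X \ge k)$ for $k$ query hits in a term of size $K$, background $N$,
query $n$), BH-adjusted across terms. The background defaults to the
reproducibly identified proteins, not a whole genome — enrichment against
an inflated background flatters every term. No EASE-style deflation of
$k$ is applied. Terms with zero overlap report $p = 1$ under the
upper-tail convention (or can be dropped).

`category_abundance()` sums the per-condition mean NSAF over a term's
members: because NSAF is compositional, a category's sum is directly the
fraction of total spectral signal that category accounts for, and disjoint
categories covering the proteome sum to 1.

## Proteome–transcriptome concordance

`classify_concordance()` joins the protein result to an mRNA log2
fold-change table (both oriented condition a over condition b) and assigns
genes with at least a 2-fold change in *both* layers to one of four
sign-pattern quadrants: both down in a (`i`), protein up / mRNA down
(`ii`), both up (`iii`), mRNA up / protein down (`iv`). By default only
proteins called significant by the t-test are eligible — the fold filter
alone is noisy at low counts — with `significant_only = FALSE` to classify
all quantified proteins. Genes present in only one table are kept with
`joined = FALSE` rather than silently dropped, so join losses are
auditable.

## The synthetic-data generator

`simulate_spectral_counts()` states the world the test suite measures the
pipeline in:

* counts within a sample are **one multinomial draw** of `depth` spectra
  (default 30,000), not independent Poissons — spectral counting is
  compositional, which is exactly why NSAF normalizes to the sample total;
* spectrum-generation probability is proportional to **abundance × length**,
  the premise that justifies NSAF's division by length (the suite verifies
  that expected NSAF recovers true relative abundance at depth $10^6$);
* base abundances are lognormal (sd 1.5 natural-log units), molecular
  weights lognormal with median ≈ 50 kDa (sdlog 0.5, the quartile spread
  typical of proteome molecular-weight distributions);
* a fraction `frac_diff = 0.1` of proteins carries a planted fold change
  (levels 2, 4, 8, sign-balanced between conditions);
* biological replicates get lognormal abundance jitter (sd 0.1) on top of
  counting noise, since real replicates overdisperse; the value is a
  modelling choice the data cannot pin down, and it is a parameter.

What the generator does **not** emulate: identification dropout beyond
multinomial zeros, peptide-level structure, shared peptides, run-order or
batch effects. A green simulation test therefore establishes that the
statistics do what they claim *under the stated model*, not that the model
exhausts real data. One consequence the suite documents honestly: at depth
30,000 over ~2,000 proteins most counts are small integers, so occasional
null proteins show near-zero within-group variance by discreteness (e.g.
(1,1,1) vs (2,2,2)), inflating the extreme tail of the null p distribution.
Aggregate type-I error stays nominal, but the empirical FDR of the BH list
exceeds its nominal level — a known pathology of unmoderated t-tests on
spectral counts; moderated-variance testing is deliberately out of scope.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pseudo_fraction` | 0.5 | spectral fraction added to every count |
| `avg_aa_mw_da` | 111.1254 Da | residue mass for length estimation |
| `min_total` | 5 | within-condition total count for the filter |
| `alpha` | 0.05 | raw-p significance level |
| `equal_var` | TRUE | Student pooled t (Welch if FALSE) |
| `threshold_fold` | 2 | concordance magnitude threshold (both layers) |
| `depth` | 30,000 | simulated spectra per sample |
| `replicate_logsd` | 0.1 | simulated biological overdispersion |

## Known limitations

* Raw $p < 0.05$ as the headline criterion is liberal; use `bh_fdr` when
  error control matters.
* NSAF is compositional: a large change in an abundant protein moves every
  other protein's NSAF in the opposite direction. Fold ratios between
  conditions inherit this.
* The t-test trusts 3-replicate variances; proteins with tiny counts can
  reach significance on discreteness artifacts (see above).
* Identifier joining (protein ↔ gene ↔ annotation) is taken at face value;
  no identifier mapping service is wrapped.
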