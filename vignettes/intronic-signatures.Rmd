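---
title: "Intronic probe-set signatures: models, assumptions and design choices"
author: "intronsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intronic probe-set signatures: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronsig)
```

# The problem

A 3'-biased expression microarray interrogates each transcript with a
probe set of (typically) 11 oligonucleotides of 25 nt. Because probe sets
were designed against mRNA and EST collections, a substantial fraction of
them happen to match the coding strand *inside introns*: they detect
unspliced pre-mRNA, not mature message. In stem cells, where full-length
unspliced transcripts are held at bookmarked loci, this "contaminating"
signal is biologically meaningful: a genotype or differentiation stage can
change a gene's **unspliced fraction** while leaving its **total mRNA**
unchanged. `intronsig` provides the annotation, testing, clustering and
qRT-PCR machinery to detect and interpret exactly this situation, plus a
synthetic-data generator that plants it with known ground truth.

Throughout the package genomic coordinates are 0-based, half-open, with
strands `"+"`/`"-"`; sequences are over A/C/G/T.

# Probe-set re-annotation

The annotation criterion is *perfect* 25/25 identity, so alignment is
replaced by an exact k-mer index: every 25-mer of every target sequence is
enumerated, and a probe hits the minus strand of a target exactly when its
reverse complement occurs among the forward 25-mers. This makes matching
exhaustive, deterministic and trivially testable against a brute-force
sliding-window scan (the test suite verifies equivalence with
`Biostrings::matchPattern`).

The decision cascade for a probe set is:

1. ≥ `min_probes` (default 8 of 11) probes matching any reference (RefSeq)
   transcript sequence → **mRNA**. Reference transcripts are tried first;
   a probe set that matches both a transcript and introns is mRNA.
2. otherwise, if any probe occurs at more than `repeat_threshold` genomic
   windows (default 10; counted over both strands) → **repeat**. The
   repeat check precedes the gene-span stage because a multi-copy probe
   set would otherwise surface as a multi-gene ambiguity.
3. otherwise, ≥ `min_probes` probes matching exactly one gene span (all
   bases from the 5'-most exon start to the 3'-most exon end):
   **intronic** if *every* matching probe lies on the coding strand and
   entirely within intron intervals; **ambiguous** if any matching probe
   overlaps an exon or an exon/intron junction, or if all matches are
   antisense.
4. matches on more than one gene span → **ambiguous**.
5. otherwise → **unmapped**.

Design choices the cascade leaves open:

* *Multi-span and antisense-only matches* have no dedicated label; they
  are absorbed into **ambiguous**, the natural catch-all category.
* `repeat_threshold = 10` distinct genomic windows is a configurable
  convention — there is no canonical value.
* Finer mRNA sub-labels (non-RefSeq, ncRNA, putative alternative 3'UTR)
  depend on annotation metadata that generic transcript models do not
  carry; the classifier emits the five coarse categories and leaves
  sub-labeling to the model metadata.

The array's **background intronic fraction** is the number of intronic
probe sets over all probe sets retained after removing an exclusion list
(control probe sets); on the Mouse 430 2.0 array this is 6780/45037 ≈ 15%.

# Filtering and paired differential expression

Technical replicates are averaged on the log2 scale before filtering; a
merged detection call is Absent only when *all* replicates are Absent.
A probe set is then excluded when (i) every sample is Absent, (ii) every
intensity is strictly below log2(100) ≈ 6.64, or (iii) the interquartile
range across samples is strictly below 0.5. The IQR uses
linear-interpolation quantiles (`stats::quantile` type 7) — the exact
quantile rule is a convention, so the mainstream default is used and the
threshold is configurable. "Marginal" calls count
as not-Absent.

Differential expression uses two-sided paired Student t-tests on log2
intensities. The fold change is `2^|mean paired log2 difference|` — the
paired variant, consistent with the paired test, rather than the ratio of
group means (the two differ only in unbalanced designs; the choice is
configurable by operating on the emitted means). Both cut-offs are strict:
p < 0.05, fold change > 1.5. When all paired differences are identical
the t statistic is undefined; such probe sets are flagged `degenerate`
and emitted only if the fold-change criterion holds. No multiple-testing
correction is applied by default: the cut-offs are deliberately raw-p,
and a false-discovery-rate step can be layered on the emitted table.

# The enrichment model

Differentially expressed probe sets are tallied by
{mRNA, intronic, repeat, ambiguous} × {up, down}; unmapped or unannotated
sets count as ambiguous (with a warning). The expected intronic count per
direction under the background rate f is

$$E = \mathrm{round}\left(\tfrac{f \cdot N_{DE}}{2}\right),$$

with halves rounded away from zero and the expectation split evenly
between the up and down directions (e.g. a total of 60 DE probe sets at
f = 0.15 gives 4.5 → 5 expected intronic sets per direction).

Enrichment is tested with a Pearson chi-square (1 df, two-sided) on the
2 × 2 table contrasting the tested probe sets (intronic vs not) with the
remainder of the array background. The **Yates continuity correction is
on by default**: with it, the 15-of-35 case against 6780/45037 gives
χ² ≈ 19.05 and p ≈ 1.27 × 10⁻⁵ (1.3 × 10⁻⁵ at two significant digits);
without it p ≈ 4 × 10⁻⁶. The corrected statistic is clamped at zero, so
an observed fraction exactly at background returns χ² = 0, p = 1. When
only one direction shows intronic changes, the test is run on that
direction's probe sets (`enrichment_direction = "down"` in the pipeline);
this is configurable because either denominator — one direction or all
DE probe sets — is defensible.

# Signature clustering and its randomization null

To avoid overweighting genes detected by several intronic probe sets, the
signature keeps one probe set per gene: the most highly expressed
intronic set, or — for the mRNA counterpart — the set with the largest
absolute mean difference in a reference contrast.

Samples are clustered on `1 − Pearson correlation` over the signature
rows with `stats::hclust`. **Complete linkage** is the default (the method does
not dictate a linkage; average and single are selectable, and the
package's conclusions on synthetic data are insensitive to the choice). Ties in agglomeration follow hclust's
deterministic order, so a fixed input order gives a reproducible tree.
Row z-scoring (population standard deviation, the heat-map convention)
only affects exported heat-map matrices — Pearson distance between
samples is invariant to per-row location/scale only in the limit of many
rows, so the dendrogram is computed on the expression values as given.

"Clean separation" of a target population is operationalized as the
**clade criterion**: the target samples are all and only the leaves of
some subtree — equivalently some tree cut isolates exactly the target
set; the implementation enumerates subtree leaf sets and is
cross-checked in the tests against exhaustive `cutree` enumeration. The
randomization null redraws `k` probe sets (without
replacement, `n_draws` times) from an eligible pool — e.g. all expressed
intronic probe sets — and reports the fraction of draws whose tree
separates the targets cleanly. A planted signature is "special" when it
separates the targets while that fraction is small; a full-scale run
uses on the order of 10,000 draws of a signature-sized k, while the
bundled tests use 200 draws, enough to bound the null fraction at the
5% level they assert.

# qRT-PCR splicing ratios and protein prediction

Relative quantities use the 2^−ΔΔCt method with ideal doubling per
cycle: ΔCt = Ct(target) − Ct(reference gene, same sample), ΔΔCt =
ΔCt − mean ΔCt of the calibrator group (per gene, amplicon type and
experiment), quantity = 2^−ΔΔCt. Per-gene genotype ratios are the
**median across independent experiments with unscaled median absolute
deviation** as dispersion — the robust summary used for the ratio
scatter plots. Exon–intron and intron-spanning amplicons are ingested
and summarized separately; only exonic and intronic amplicons enter the
classification, which compares both ratios to a closed 1.5-fold band
[1/1.5, 1.5]:

| mRNA ratio | intronic ratio | class |
|---|---|---|
| within | within | `no_change` |
| within | outside | `selective_intronic` |
| outside | outside | `proportional` |
| outside | within | `mRNA_only` |

For protein prediction, only spliced message is translatable, so the
protein ratio between conditions A and B should track

$$\frac{T_A - c\,U_A}{T_B - c\,U_B}$$

where T is total and U unspliced signal. The calibration constant `c`
maps intronic-amplicon units onto total-mRNA units; how to make the two
amplicons unit-commensurable is genuinely open, so `c` defaults to 1
(appropriate when both quantities are expressed on a common relative
scale, e.g. 2^−ΔCt against the same reference gene) and is exposed as a
parameter. Negative spliced estimates raise an error with a diagnostic
rather than silently flipping sign. The naive full-length ratio F and
the full-over-unspliced ratio F/U are reported alongside for comparison.

# The synthetic-data generator

The generator is first-class, tested code; its defaults describe the
study conditions the analysis assumes.

**Genomes and models.** Uniform-random A/C/G/T background, one synthetic
chromosome, non-overlapping genes with 2–5 exons of 100–300 bp separated
by introns of 200–800 bp, random strands, intergenic gaps of 200–500 bp.
Repeat-class probe blocks (35 bp, giving 11 overlapping 25-mers) are
planted at 12 intergenic locations, above the default repeat threshold
of 10. A fixed seed yields bit-identical outputs; stage seeds are small
deterministic offsets of the master seed.

**Expression model.** An exonic probe set reads `log2(total)`; an
intronic or boundary set reads `log2(total × unspliced_fraction)`;
antisense and repeat sets read a flat background (log2 = 5). Gaussian
noise (sd 0.1 by default) is added on the log2 scale — matching the
downstream log-intensity analysis — and detection calls are thresholded
at log2(100). Per-gene baseline log2 totals are uniform on [10, 14], so
that even a 10% unspliced fraction stays detectable. In the paired
design both genotypes of a pair share a per-(gene, pair) effect (sd
0.25), a biological-sample effect common to all probe sets of a gene —
this is what makes the paired t-test the right analysis and leaves the
intronic/exonic contrast within a sample unconfounded. Selective genes
switch the unspliced fraction from 0.4 (reference) to 0.1 (mutant) with
totals equal — a 4-fold intronic change and no mRNA change.

**The celltype design** emulates the one structural fact the clustering
analysis relies on: stem cells are *not* globally distinct — only their
unspliced program is. For non-signature genes, every target-population
sample mimics the mRNA profile of a different mature population
(round-robin "decoy" profiles, reflecting multilineage priming), so a
random draw of uninformative probe sets scatters the target samples
among mature populations and essentially never isolates them. Signature
genes carry a population-specific unspliced excess (per-gene unspliced
fraction 0.3–0.9 in the target vs 0.02–0.08 elsewhere) whose intronic
signal follows the sample's *true* population, so the planted signature
separates the targets cleanly. What passing tests show is therefore that
the statistics behave correctly *given* this structure; they do not show
that real arrays have it — cross-hybridization, GC-dependent background
and probe-affinity effects are deliberately out of the generator's scope.

**qRT model.** Ct = intercept − log2(quantity) + noise with intercept 30
and a constant-quantity reference gene in every sample; 3 independent
experiments with 3 samples per group per experiment — a typical qRT
validation layout, and enough replication for the median/MAD summary to
be meaningful. Exonic amplicon quantity is the gene's
total; intronic is total × unspliced fraction.

# Problem sizes and numerical choices

The test suite and the acceptance script measure recovery at sizes chosen
to make every planted effect identifiable while keeping runs interactive:
annotation-vs-brute-force equivalence on 20 seeded genomes of ~10–20 kb;
selective-intronic recovery with 250–500 gene pairs, 6 pairs, noise sd
0.1 (a planted 4-fold change at 10+ standard errors); clustering nulls
with 200 draws from pools of 40 probe sets. Other numerical conventions:
type-7 quantiles for the IQR; population-sd row z-scores; rounding halves
away from zero in expected counts; chi-square statistic clamped at 0
under continuity correction; hclust's deterministic tie handling; errors
(never silent recovery) for zero-variance samples in correlation
distances, missing reference-gene Ct values, and negative spliced
estimates.

# Known limitations

* Exact matching only: a single mismatch hides a probe, unlike
  heuristic alignment with near-perfect hits. This is faithful to the
  "aligned perfectly" criterion but means degenerate or SNP-containing
  probes fall through to `unmapped`.
* The expected-count model assumes directions are exchangeable under the
  null; strongly asymmetric DE lists violate the 50/50 split.
* The clade criterion is all-or-nothing; near-separations (one stray
  sample) count as failures both for the signature and for the null.
* The protein prediction treats translation as proportional to spliced
  message and ignores translational regulation and protein stability;
  its calibration constant c is an interpretation, not a measurement.
* Synthetic expression is Gaussian on the log2 scale with a single noise
  component; real microarray noise is intensity-dependent.
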