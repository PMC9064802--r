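---
title: "Methods: trio inheritance classification and gene-panel burden testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio inheritance classification and gene-panel burden testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioburden)
```

## The analysis

`trioburden` implements a case-control analysis of whole-exome sequencing
trios: probands with a clinical outcome (here, epilepsy following acute
symptomatic neonatal seizures) and their biological parents, compared with
outcome-free probands and their parents. The question is whether probands in
one group carry a heavier burden of rare, predicted-deleterious variants —
de novo or inherited — in a hypothesis gene set than probands in the other.

The pipeline has four stages:

1. **Variant-level filtering.** A variant is retained when it is a
   functional coding change (missense, nonsense, frameshift) or lies within
   a small window of a splice site, is rare in both reference population
   panels, scores as deleterious by CADD, and is carried by a proband with
   high genotype quality.
2. **Trio inheritance classification.** Each retained proband variant is
   compared with the parental genotypes and called de novo, transmitted
   (maternal / paternal / biparental), or unresolved. Independently,
   parental variants absent from the proband are collected as
   *non-transmitted* — alleles the proband could have inherited but did not,
   a within-family negative control for the burden comparison.
3. **Burden statistics.** Probands are cross-classified by group and by
   exposure ("carries at least one qualifying variant") and the resulting
   2x2 table is summarized by the cross-product odds ratio with an exact
   conditional confidence interval, the Pearson chi-square test and the
   Fisher exact test.
4. **Functional categorization.** Genes carrying de novo
   pathogenic/likely-pathogenic/VUS variants exome-wide are mapped to KEGG
   orthology categories and tabulated per group, as descriptive counts and
   within-group proportions.

## Filter thresholds and their meaning

All thresholds live in one object, `filter_thresholds()`, and every
inequality direction is part of the contract:

| parameter | default | direction | meaning |
|---|---|---|---|
| `max_pop_freq` | 0.001 | `<` (max over both panels) | rare in *both* reference panels; a variant common in either is excluded |
| `min_cadd` | 20 | strict `>` | CADD Phred; >20 is roughly the top 1% most deleterious |
| `min_gq_proband` | 50 | strict `>` | Phred-scaled genotype quality of the proband call |
| `min_depth_denovo` | 10 reads | `>=` | total depth at a candidate de novo site |
| `min_alt_reads_denovo` | 3 reads | `>=` | alternate reads supporting the candidate |
| `min_ab_exome` | 0.25 | strict `>` | allelic balance (alt reads / depth) in exome-wide mode |
| `min_ab_targeted` | 0.1 | strict `>` | relaxed allelic-balance floor inside targeted panels |
| `min_gq_parent` | 50 | `>=` ("a minimum of") | parental genotype quality for a de novo call |
| `max_parent_alt_reads` | 0 | `<=` | a single parental alternate read vetoes a de novo call |
| `splice_window_bp` | 3 bp | `<=` | distance to a splice site within which any consequence class is kept |

The asymmetry between the proband rule (strictly greater than 50) and the
parental rule (at least 50) is deliberate and mirrors how the two criteria
are usually stated; both are configurable, including through a YAML file
(`read_thresholds_config()`).

The mode switch matters: the allelic-balance floor drops from 0.25 to 0.1
inside targeted panels, so the targeted analysis accepts lower-balance
heterozygous calls that the exome-wide analysis rejects. A consequence worth
knowing is that the exome-wide de novo call set is always a subset of the
targeted-mode call set on the same data — the property suite checks exactly
this, including the flip of every call when simulated allelic balance is
planted inside the interval (0.1, 0.25].

Annotation conventions: `splice_distance_bp` is the distance in bp to the
nearest exon-intron boundary as supplied by the annotator. Variants whose
consequence class is already on the functional whitelist pass the region rule
regardless of this field; for other classes (synonymous, in-frame indels) a
distance within `splice_window_bp` rescues the variant as splice-proximal.
Missing annotation fields exclude a variant with an explicit
`ANNOTATION_MISSING` reason — never a silent pass — and every decision is
logged per variant, trio and stage, so `survivors + failures = input` holds
for every run.

## Inheritance calls

For each proband-carrier variant in each trio exactly one call is made:

* a carrier parent makes the call `transmitted_maternal` /
  `transmitted_paternal`, or `transmitted_biparental` when both parents
  carry the allele (phase cannot be resolved from genotypes alone);
* with both parents confidently homozygous reference, the call is `de_novo`
  only when the proband evidence clears the depth, alternate-read and
  allelic-balance thresholds and both parents clear the quality rules with
  zero alternate reads; otherwise the call is `unresolved` with
  machine-readable reasons (`DP_LOW`, `AB_LOW`, `PARENT_HAS_ALT`, ...),
  never silently discarded and never counted as de novo;
* a hemizygous son of a heterozygous mother (non-PAR X) is
  `transmitted_maternal`;
* mitochondrial and Y-chromosome sites are flagged `unresolved`
  (`UNSUPPORTED_CHROM`): biparental carrier logic does not apply and no
  special rules are defined for them.

Allelic balance is `alt_depth / total_depth` from the decomposed AD field,
undefined (and flagged) at zero depth. Multi-allelic records are split into
one record per alternate allele before any of this, with AD decomposed per
allele and "no reads showing the alternate" enforced against the specific
allele. Variant identity is `(chrom, pos, ref, alt)` after trimming shared
suffix then prefix bases, so differently padded indel representations meet
on one key.

No allelic-balance floor is applied to inherited (transmitted) variants:
the de novo evidence thresholds exist to guard against sequencing artifacts
masquerading as new mutations, a failure mode that parental carriage already
rules out. "Depth" is the total site depth (DP), not informative reads.

## The exact odds-ratio confidence interval

Small studies (10 + 10 probands) make asymptotic intervals untrustworthy:
the Woolf logit interval is undefined with a zero cell and badly
anti-conservative at these counts, and demonstrably cannot reproduce
exact-software output (it is provided as `woolf_or_ci()` for comparison
only). The package therefore inverts Fisher's exact test under the
noncentral hypergeometric distribution: conditioning on both margins, the
case-exposed count has

$$P(X = x \mid \psi) \propto \binom{m_1}{x}\binom{m_2}{n_1 - x}\,\psi^x,$$

and the Cornfield-type exact bounds are the $\psi$ values at which the
upper (resp. lower) tail probability of the observed count equals
$\alpha/2$. Numerically: the probability mass is computed in log space over
the full conditional support, and each bound is found by plain bisection on
$\log\psi$ over $[10^{-8}, 10^8]$ — both tails are monotone in $\psi$, so
bisection cannot miss, and 120 halvings leave an interval far below any
tolerance of interest. Plugging a returned bound back into its defining
tail reproduces $\alpha/2$ to well within $10^{-8}$ (asserted in the test
suite). When the observed count sits at the edge of the conditional
support the corresponding bound degenerates to 0 or $\infty$; a table with
an empty margin has no defined interval and is reported as such rather
than raising mid-pipeline.

Two variants of the inversion exist in the literature; the package computes
both. For the worked-example table (5, 5, 1, 9) the exact bounds are
0.639-471.7 and for (1, 9, 1, 9) they are 0.0115-87.1 — which round to the
intervals the motivating study printed (0.6-472 and 0.01-87) — whereas the
mid-p variant gives clearly different, narrower intervals (0.83-236 and
0.023-43). The exact variant is therefore the default and mid-p is an
explicit option (`exact_or_ci(..., method = "midp")`).

The reported point estimate is the sample cross-product $ad/bc$ (the
convention of the motivating analysis: (5·9)/(5·1) = 9.0), not the
conditional maximum-likelihood estimate; the conditional MLE is computed
too (`conditional_mle_or()`) and carried in `method_notes`. The Pearson
chi-square is applied without continuity correction — that choice, and no
other, reproduces the printed cohort-characteristics p-values (0.18, 0.33,
0.14) from their published counts. 2xk tables are supported for
multi-category characteristics; a table with an all-zero row or column
margin has an undefined statistic and is flagged degenerate rather than
assigned a forced degrees-of-freedom value.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates everything the pipeline reads (VCF, PED,
annotation table, panel files, KO mapping) plus a truth table, so every
stage is testable with no sequencing data. Its defaults are the study
conditions the package targets: 10 case and 10 control trios, a
panel-pathogenic carrier probability of 0.5 in cases versus 0.1 in controls
(expected exposure odds ratio $(0.5/0.5)/(0.1/0.9) = 9$), mean site depth
60 reads, mean heterozygous allelic balance 0.5. Where the motivating study
publishes no value (background variant counts, de novo and non-transmitted
rates, genotype-quality noise), defaults were chosen once at values typical
of exome trio data — about 20 background variants per trio surviving
upstream decomposition, one expected de novo and one expected
non-transmitted planted variant per trio, 95% of background genotypes at
high quality — and the annotation spectra deliberately straddle every
filter boundary (CADD mixture around 20, allele-frequency tail spanning
0.1%, allelic-balance options spanning 0.1 and 0.25) so threshold behaviour
is exercised on both sides.

Planted genotypes are Mendelian-consistent except at de novo sites (and at
explicit "artifact" sites planted to fail the evidence thresholds); all
randomness flows from a single seed, and a fixed configuration reproduces
every output file byte for byte.

The simulator does **not** model read-level errors, mapping artifacts,
indel-realignment noise, mosaicism, relatedness errors, or locus-specific
coverage structure. Genotype-quality noise is a two-point mixture, not a
calibrated error model, and genes are synthetic symbols at synthetic loci.
Passing recovery tests on simulated cohorts therefore demonstrates that the
classification logic is faithful to its stated rules — not that those rules
are robust to every failure mode of real exome data.

## Worked-example cohorts

Two generated fixtures embed the motivating study's published variant
tables in a synthetic 10 + 10 trio cohort with qualifying read evidence:
`example_targeted_cohort()` (29 epilepsy-panel variants, of which six
pathogenic/likely-pathogenic in six probands, plus CAD-panel and
non-transmitted plantings for the sensitivity and negative-control
analyses) and `example_denovo_cohort()` (the seventeen exome-wide de novo
variants, seven in six case probands and ten in six control probands, with
a synthetic KO mapping for their genes). These fixtures are what the test
suite and the acceptance script run end to end; the cohort-level numbers
they reproduce (exposure tables (5,5,1,9) and (1,9,1,9), odds ratios 9.0
and 1.0, the 17-variant split, table (6,4,6,4)) are the published
summary-level results. The study's raw sequence-level findings are not
reproducible — no sequence data were deposited — and are out of scope.

## Problem sizes in the test suite

The suite runs everything at deliberately small scale: property checks use
one-to-eight-trio cohorts; the brute-force oracle comparison runs 1,000
random one-trio cohorts of three sites each; the coverage check runs 200
replicates of a 500 + 500-proband exposure model (exact CIs on tables of
that size are cheap because the conditional support, not the sample size,
drives the cost); the law-of-large-numbers depth check uses one 10,000-site
cohort. These sizes make the full suite complete in a couple of minutes
while still exercising every code path at its boundaries.

## Known limitations

* ACMG pathogenicity is consumed as a curated label; the package does not
  classify variants, and a burden analysis is only as good as that label.
* Phase is not resolved for biparental heterozygous transmission; such
  calls are reported as their own category rather than guessed.
* Non-PAR X handling relies on the caller emitting hemizygous genotypes
  ("1" rather than "1/1") for males; no pseudo-autosomal boundary logic is
  implemented.
* KEGG categorization counts genes (once per category) rather than
  variants, reports no significance test, and is descriptive by design.
* The KO mapping is a user-supplied snapshot, never a live query; results
  are only as current as that file.
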