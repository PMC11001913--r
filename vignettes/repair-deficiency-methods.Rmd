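---
title: "Scoring DNA repair deficiency from sequencing derivatives: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring DNA repair deficiency: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repairscan)
```

This vignette explains the models and procedures repairscan implements, the
conventions chosen where the published decision rules leave details open,
and what the synthetic-data generators do and do not emulate.

## The scientific problem

Tumors that have lost homologous recombination (HR) cannot accurately repair
double-strand breaks; they accumulate a characteristic pattern of large
chromosomal scars and respond preferentially to platinum agents and PARP
inhibitors. Tumors that have lost nucleotide excision repair (NER) fail to
remove bulky adducts such as cisplatin lesions and UV photoproducts, and are
flagged by a different mutational-signature pattern. Neither deficiency is
reliably identified by single-gene sequencing alone: many HR-deficient cases
carry no BRCA1/2 mutation, so scar- and signature-based scores that read out
the *consequences* of the deficiency are used instead. repairscan implements
that desk pipeline end to end.

## Genomic scar scores

The input is an allele-specific copy-number (ASCN) profile: ordered,
non-overlapping segments with integer major/minor allele copies `(a, b)`,
1-based inclusive coordinates (SEG convention; a segment's length is
`end - start + 1`). Profiles are normalised on read so `a >= b`; the A/B
labels carry no phase information and no downstream rule depends on them
beyond "minor allele zero" (LOH) and "unequal alleles" (imbalance).

Three components are counted on the smoothed profile:

* **HRD-LOH** — maximal runs of `b = 0` segments strictly exceeding 15 Mb
  but not spanning the whole chromosome. The comparative "exceeding" is
  implemented as a strict `>`; copy-neutral LOH (`a = 2, b = 0`) counts
  because the definition is allele-based, not dosage-based.
* **LST** — junctions between two copy-number states where both flanking
  maximal state-blocks are at least 10 Mb (inclusive `>=`) and the gap
  between them is at most 3 Mb (inclusive `<=`), counted per chromosome
  arm so that breakpoints separated by the centromere are ignored.
* **TAI** — maximal allelic-imbalance runs (`a != b`) that reach position 1
  or the chromosome's last base, do not span the centromere interval, with
  no minimum size by default (`tai_min_mb = 0`, configurable): the printed
  definition states no size filter.

The total is the HRD score; `total >= 42` (inclusive) calls HR deficiency.
The genomic LOH fraction is the length-weighted fraction of profiled bases
in LOH runs, excluding whole-chromosome runs, and `>= 16%` (inclusive)
calls LOH-high.

### Conventions chosen where the rules are silent

* **Smoothing** (`preprocess_segments()`): segments shorter than 3 Mb are
  removed; identical-state flanks merge across the hole, differing flanks
  split the hole at its midpoint. This is the preprocessing implied by the
  LST rule's 3 Mb gap tolerance. Smoothing is applied per chromosome rather
  than per arm: whole-chromosome LOH/TAI logic needs cross-centromere run
  continuity, and smoothing is purely local, so arm splitting happens only
  inside the LST scorer. A short segment with no neighbour within 3 Mb is
  kept, so isolated coverage is never silently deleted; the operation is
  idempotent either way.
* **Run adjacency**: consecutive qualifying segments separated by at most
  3 Mb belong to one run, mirroring the LST gap tolerance; run length is
  measured end-to-start across tolerated gaps, while the LOH *fraction*
  sums only covered bases.
* **Whole-chromosome exclusion** applies to HRD-LOH (printed rule) and is
  extended to the LOH fraction, following the convention of the commercial
  LOH assays that motivated the 16% rule; this is recorded as an assumption
  since those definitions are proprietary. Whether the 16% refers to loci
  or genome length is also unstated; the length-based proxy is used.
* **TAI "crossing"** means strictly spanning the centromere interval
  (`start < cen_start` and `end > cen_end`); a run ending inside the
  interval does not cross.

Every scorer is checked against `scar_counts_exhaustive()`, a deliberately
naive segment-by-segment transcription of the three definitions, and the
test suite additionally carries an independent transcription of its own;
all three agree on hundreds of random profiles.

## Biallelic genotype classification

Somatic variant records carry MuTect2-style evidence fields and must pass
all seven hard filters — `TLOD >= 6`, `NLOD >= 3`, `NORMAL.DEPTH >= 15`,
`TUMOR.DEPTH >= 20`, `TUMOR.ALT >= 5`, `NORMAL.ALT = 0`, `TUMOR.AF >= 0.05`
— with every inequality inclusive and the normal-alt rule a strict
equality. Germline records carry no tumor/normal contrast and bypass these
somatic-specific filters; they are filtered only on the pathogenicity and
exonic rules. Deleterious = exonic, non-synonymous, classified Pathogenic
or Likely Pathogenic (the classification itself, e.g. InterVar output, is
consumed as an input column, not re-derived).

Gene-level LOH is any-overlap: one base pair of a `b = 0` segment inside
the gene registers the event, since a partial deletion still inactivates
the allele. The six genotype classes follow from the deleterious variant
count and the LOH flag; two or more records sharing one `variant_key` are
homozygous, distinct keys are compound-heterozygous. Phasing is not
inferred — distinct variants are assumed in trans, and the call carries a
`phase_assumed` flag. HR deficiency is the biallelic rule: genotype in
{HetMutantLOH, HomozygousMutant, CompoundHetMutant}.

Promoter methylation is summarised as the median beta value over
promoter-associated probes. No published beta cut-off accompanies the rule,
so the call threshold defaults to 0.2 and is configurable
(`methylation_high_beta`).

## Signature refitting

Catalogs are fixed-channel count vectors (SBS-96 trinucleotide, ID-83
indel, SV-32 rearrangement). Refitting solves the non-negative
least-squares problem `min ||m - P e||, e >= 0` with an active-set solver
(`pracma::lsqnonneg`), then zeroes signatures whose proportion of the total
catalog falls below 6% and re-runs the fit on the survivors until the
active set is stable — the standard refitting convention. One solver serves
all three channel sets; the original analyses used different packages per
catalog type, but all reduce to constrained refitting against fixed
references, so unifying them is an engineering choice. The residual is
non-increasing across prune iterations by construction, and the final
solution satisfies the NNLS KKT conditions (zero gradient on the active
set, non-negative gradient off it), which the tests verify against an
independent projected-gradient solver. Reconstruction quality is the cosine
similarity between the catalog and `P e`; catalogs with fewer than 20
mutations are flagged unstable rather than rejected.

The **NER composite score** is driven by the SBS5 and ID8 proportions. The
exact functional form of the originally trained composite is not public;
the implemented stand-in is a weighted mean of the configured component
proportions (default weights 1/1), which lives on the same `[0, 1]` scale,
with the published decision threshold (>= 0.7, inclusive) applied. Both
components and weights are configurable so a trained combination can be
substituted. ID6 presence ("ID6 > 0"), an HR-deficiency indicator on indel
catalogs, is exposed as `id6_positive()`.

The shipped reference matrices are **synthetic**: deterministic sparse
Gamma-draw profiles with COSMIC-style names (files named
`synthetic_*_signatures.tsv`). They exist so the code paths, tests and
examples run offline; real COSMIC references load through
`read_signature_matrix()` unchanged because columns are re-normalised at
load time.

## Cohort statistics

* **Fisher exact test**: `stats::fisher.test` — exact hypergeometric with
  the minimum-likelihood two-sided rule and the conditional-MLE odds ratio;
  the tests cross-check the p-value by direct `dhyper` enumeration.
* **Survival**: Kaplan-Meier product-limit estimate with the median defined
  as the earliest event time where the curve reaches 0.5 or below; 1-df
  log-rank; Cox partial likelihood with Breslow ties (the simplest
  documented convention, adequate at these sample sizes) and a Wald 95% CI
  on the log scale. Complete separation or a diverging estimate raises a
  non-convergence error instead of returning an arbitrary hazard ratio.
* **Ferroptosis signature score**: per-gene z-scores across samples,
  averaged over the 11 iron-associated genes (ACO1, CD44, CISD1, IREB2,
  NCOA4, NFS1, PHKG2, STEAP3, TFRC, ZFP36, ZEB1). A constant gene row
  contributes 0 (with a warning) rather than NaN so degenerate fixtures
  cannot poison a cohort. The published description calls this a "GSEA
  score" while the single-cell analogue used module scoring; the mean-z
  implementation is the chosen middle ground and is flagged as such.
* **Quantiles**: linear interpolation between order statistics (R type 7)
  everywhere — Tukey fences (Q1 - 1.5 IQR, Q3 + 1.5 IQR) and the
  HRD-quartile split. The extreme split uses `k = round-half-up(fraction
  * n)` per stratum, the convention that reproduces groups of 131 from 327
  samples at 40%; boundary ties are broken by stable input order.
* **Mann-Whitney**: exact by enumeration when the combined sample size is
  at most 12 without ties, normal approximation with tie and continuity
  correction otherwise.

## The synthetic-data generators

The generators define the conditions everything is tested under; each
output is paired with ground truth that is *recomputed from the emitted
object*, never echoed from the request.

* `simulate_scar_profile()` plants interstitial LOH blocks (16-20 Mb,
  `a=1,b=0`), LST junction blocks (two 11 Mb imbalanced states) and
  telomere-anchored imbalance runs (12-17 Mb, `a=2,b=1`) on distinct arms
  of a toy genome (3 x 100 Mb by default, centromere at 45-55%). Every
  block is wrapped in 4 Mb balanced `a=2,b=2` buffers so the three
  definitions cannot interact (a buffer flank is always below the 10 Mb
  LST rule, planted LOH never reaches a telomere, planted imbalance always
  keeps `b >= 1`). Because the definitions do interact in general, the
  only safe truth is a recount: the generator re-scores its own output
  with the exhaustive scorer and retries placement (bounded at 1000
  attempts) until the recount equals the request.
* `simulate_catalog()` draws `P e` exactly (noiseless, the algebraic
  inverse of refitting) or channel-wise Poisson.
* `simulate_variants()` builds records that pass all seven filters (the
  first exactly on every boundary) plus single-filter failures at
  boundary-adjacent values (e.g. TLOD 5.99, AF 0.049).
* `simulate_survival()` draws exponential event times at a baseline rate
  with hazard ratio applied to group B and independent exponential
  censoring. Defaults are the study conditions the package emulates:
  baseline median 1015 days (the platinum-treated HR-deficient median),
  hazard ratio 2.43, censoring intensity giving roughly one fifth of
  records censored.
* `simulate_expression()` plants a shift on every signature gene in a
  fraction of samples over a standard-normal background; defaults are 327
  samples, the 11-gene signature, a 40% affected fraction and a 2 SD
  shift (the shift magnitude is not published; 2 SD is a realistic planted
  effect chosen once).

What these do **not** emulate: tumor purity/ploidy and segmentation noise
(profiles are integer ASCN by construction — the upstream ASCN inference
is out of scope), read-level evidence, realistic rearrangement breakpoint
mechanics, correlated gene-gene expression structure, and non-proportional
hazards. Passing tests therefore demonstrate that the decision rules and
estimators are implemented correctly and are well calibrated on data with
the assumed structure, not that the scores are clinically valid on any
particular cohort; the published cohort-level figures require protected
TCGA/ICGC/Caris data and are deliberately not reproduced here.

## Problem sizes and numerical choices

The verification runs use sizes chosen to make the checks sharp yet quick:
200 random profiles (<= 50 segments, 3-chromosome toy genome) for oracle
equivalence; planted-truth sweeps of each component 0-5; 100 Poisson
refits at 5000 mutations (mean absolute proportion error < 0.03 for
signatures at >= 10% truth); 200 null simulations for log-rank and
Mann-Whitney type-I calibration (acceptance band 2-10% at alpha = 0.05);
100 Cox fits at 500 per group for hazard-ratio recovery (HR = 2 within
[1.6, 2.5] in >= 90% of runs). Floating-point tolerances: noiseless
refits recover exposures to 1e-6; KKT gradients are checked at 1e-8
relative to the catalog norm; cosine similarity is clipped into
[-1, 1] against rounding.

Degenerate inputs are handled explicitly: empty variant files yield empty
tables (not errors); zero-total catalogs, empty profiles, zero vectors,
single-event survival data and unknown configuration keys are errors that
name the offending object; all-tied score vectors stratify with a warning.

## Known limitations

* The NER composite is a documented stand-in for a trained model whose
  form is unavailable; only its drivers and threshold are reproduced.
* The 16% LOH rule is proxied by genome length rather than assay loci.
* Genotype phasing is assumed, not inferred.
* WES catalogs are assumed to be on the reference's channel scale; no
  trinucleotide-context renormalisation is applied.
* The shipped signature references are synthetic stand-ins; conclusions
  about real tumors require real reference matrices and real segment
  profiles from an upstream ASCN caller.
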