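---
title: "Methods: clinical exome analysis of degraded DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clinical exome analysis of degraded DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relicdx)
```

relicdx implements the computational stages of a clinical exome analysis
performed on highly degraded (ancient) DNA: authentication of the
sequence data as genuinely ancient, quality control of the exome
capture, a two-arm clinical variant prioritization cascade, and
cis/trans phase inference for a candidate compound-heterozygous variant
pair when one member is absent from the phased reference panel. Every
stage is paired with a seeded synthetic-data generator that carries
ground truth, so the whole pipeline is validated by planted-truth
recovery rather than by external datasets.

## The damage model and read simulator

Post-mortem DNA is fragmented and accumulates cytosine deamination at
single-stranded overhangs, observed as C>T substitutions at the 5'
end of reads and G>A at the 3' end, decaying with distance from the
terminus. `simulate_adna_fragments()` models this with a
single-exponential per end: at position $i$ from an end, a reference C
(resp. G) is flipped with probability

$$p_i = p_1 \cdot d^{\,i-1},$$

with `terminal_ct_rate` $p_1 \in [0,1]$ and `decay` $d \in (0,1]$, the
two ends independent. This is the standard first-order approximation to
empirical misincorporation profiles. Defaults are $p_1 = 0.25$,
$d = 0.5$ — a typical untreated medieval bone library; a partially
UDG-treated library is emulated with `udg_mode = "partial"`, which
retains damage only at the terminal base of each end, because the
enzyme removes internal uracils but leaves the terminal overhang signal
that authentication relies on.

Fragment lengths are log-normal with arithmetic mean
`mean_fragment_length` (default 90 bp, the scale seen in degraded
libraries) and log-sd `length_dispersion` (default 0.35), chosen as the
simplest right-skewed family; lengths below 15 bp are floored since
shorter fragments do not align uniquely. A `contamination_fraction` of
fragments is drawn from the same length model but receives no damage,
emulating a modern human contaminant.

What the generator does *not* emulate: indel damage, non-uniform base
quality, GC-biased capture, and strand-specific library chemistry.
Passing recovery tests therefore show the estimators are correct under
the stated model, not that they are robust to every artifact of real
libraries.

## Authentication statistics

`compute_misincorporation_profile()` counts, at each position from each
end, mismatch opportunities (reference C at a 5' offset, reference G at
a 3' offset) and realized mismatches, and reports the ratio. Positions
with zero opportunities are reported as `NA`, never 0 — on tiny inputs
a zero would otherwise masquerade as evidence of an undamaged (hence
suspect) library.

`determine_genetic_sex()` computes the Ry statistic
$R_y = n_Y/(n_X+n_Y)$ with binomial standard error. Classification uses
the published cutoffs for shotgun data — consistent-with-XX when
$R_y + 1.96\,\mathrm{se} < 0.016$, consistent-with-XY when
$R_y - 1.96\,\mathrm{se} > 0.075$ — so a call is made only when the 95%
interval clears the relevant cutoff; everything else, including inputs
below 100 alignments, is indeterminate.

### Mitochondrial contamination

`estimate_mt_contamination()` uses a two-source mixture at diagnostic
sites (endogenous consensus differs from the putative contaminant
allele). With per-base error $e$ (flip to one of the three other bases,
default 0.01, overridable), the likelihood of the pileup is maximized
over a grid $c = 0, 0.001, \dots, 1$; the standard error comes from the
curvature of the log-likelihood at the maximum. This is deliberately a
single-round estimator over a fixed contaminant frequency table —
iterative consensus deconvolution is out of scope — and the result is
tagged `mt-likelihood` so reports are explicit about the method. A unit
test pins the grid maximizer to an independent per-read brute-force
oracle.

### X-chromosome heterozygosity

A male is hemizygous on the X, so minor-allele signal at polymorphic X
sites beyond the error baseline measured at flanking monomorphic sites
indicates contamination. The base statistic is the poly-minus-mono
mismatch-rate difference, truncated at 0; uncertainty is a 20-block
jackknife over sites. The raw difference is attenuated by a factor
$1 - 4e/3$ under the uniform error model: an error restores a
contaminant base to the reference one time in three, and contaminant
reads displace endogenous reads that would otherwise contribute error
mismatches. Because $e$ is exactly what the monomorphic sites measure,
the default estimate divides the difference by
$1 - \tfrac{4}{3}\hat e_{\mathrm{mono}}$; `correct_attenuation = FALSE`
gives the plain subtraction. The correction matters only when the
contaminant fraction is large relative to its standard error (about
half a standard error at a 10% mixture with $e = 0.005$), but without
it the estimator is systematically low. The method refuses female
samples, where it is undefined.

## Capture QC

`compute_library_metrics()` is plain ratio arithmetic — human content
as mapped/sequenced fragments, duplication as the fraction of mapped
reads removed — with report fields rounded half-up to two decimals and
exact values retained. `compute_coverage_summary()` reports mean target
coverage, breadth at 10×, genotypability approximated as the fraction
of target bases at or above a callable depth (default 4; the full
caller-side callability logic with mapping/base-quality tracks is out
of scope), and the fold-80 base penalty, mean coverage divided by the
20th percentile of per-base depth. The percentile uses linear
interpolation between order statistics (R's default type 7); the
convention is stated because fold-80 on small arrays depends on it. A
20th percentile of zero yields an infinite penalty with a warning
rather than an error. Ti/Tv in `summarize_variant_set()` counts
A↔G and C↔T transitions over biallelic SNVs.

## Variant prioritization

Two disjoint arms, mirroring how clinical laboratories separate
already-interpreted from merely predicted variants:

* **Annotated arm** — retain variants with ClinVar class Pathogenic,
  Likely Pathogenic, Conflicting, Uncertain Significance or Other, or
  HGMD class DM or DM?. ClinVar multi-label strings
  ("Pathogenic/Likely pathogenic") retain if *any* component is in the
  list; the benign spectrum never does.
* **Predicted arm** — retain exonic/splice-site variants with *no*
  ClinVar or HGMD class, a LOF/Missense/Splice_region effect, at least
  3 of 5 damaging predictor calls (SIFT, Polyphen2, MutationTaster,
  MutationAssessor, FATHMM — modeled as abstract calls, never
  computed), and functional-genomics database frequency below 2%.

Frequency rules (5% for the annotated arm, 1% for the predicted arm)
*flag* variants as rare rather than removing them: downstream
selections act on the flag, so retention by clinical class is never
overridden by a frequency. A variant absent from every population
database is rare-flagged — absence of evidence of commonness is not
evidence of commonness, and ultra-rare pathogenic alleles are exactly
the ones missing from panels. Severity ("associated with more severe
disease") is manual curation in practice, so
`clinical_intersection()` takes an optional caller-supplied severity
lookup; without one the rare-clinical subset is severity-unfiltered and
labeled as such. `recessive_candidates()` emits a candidate per gene
with ≥2 heterozygous retained variants (possible compound heterozygote,
phase unresolved) or ≥1 homozygous one. `modifier_scan()` splits
exonic missense variants in a caller-supplied lysosomal-modifier gene
list into common (any database frequency strictly above 5%) and rare;
a frequency exactly at the threshold counts as rare.

## Phase inference from a haplotype panel

When one variant of a candidate pair is absent from the reference
panel, statistical phasing discards it; the package instead asks what
the panel says about the haplotype that carries the panel-present
(anchor) variant. `find_anchor_block()` takes the anchor-carrier
haplotypes and extends site-by-site outward from the anchor, admitting
a site while the fraction of carriers matching the *carrier-modal*
allele is at least the threshold (default 0.98) and stopping each
direction at the first failure. Concordance is measured against the
carrier-modal allele, not the panel-major one, because the question is
what the carriers co-inherit. The greedy contiguous extension is the
simplest reading of "longest shared haplotype", and the test suite
holds it equal to a brute-force enumeration of all contiguous intervals
on small panels. Concordance is per haplotype by default; an
individual-level mode (an individual concordant when all of its carrier
haplotypes match) is provided since published descriptions sometimes
count individuals — the two differ only through rare double-carrier
individuals.

`infer_configuration()` then requires the proband to be heterozygous
for both variants, checks that the block spans the query position, and
reads the query allele off the carrier haplotypes: carrier query-allele
fraction ≤ 1 − threshold ⇒ the carrier haplotype bears the reference at
the query site ⇒ the two alternative alleles lie on opposite
chromosomes (**trans**); fraction ≥ threshold ⇒ **cis**. The decision
thresholds are symmetric to avoid an asymmetric bias neither direction
justifies; anything between, or a non-spanning block, is indeterminate.
`frequency_cooccurrence()` attaches independent evidence: under
independence the same-haplotype probability is the frequency product,
and a product below $10^{-5}$ in a doubly heterozygous individual
supports trans.

The panel simulator builds haplotypes as founder mosaics (default 8
founders, Poisson breakpoints, default rate 1 per region) rather than
from a coalescent model — sufficient to create linkage-disequilibrium
blocks with controllable carrier concordance at trivial runtime. The
anchor allele lives on one founder lineage only, so carriers share a
surrounding block by construction; the planted query sits on the
neighbouring site, monomorphic reference in the panel (trans) or
planted onto the carriers (cis). Defaults — 500 haplotypes, anchor
frequency 3% — reflect the reference-panel scale and the anchor allele
frequency of the motivating use case.

## Numerical and interface choices

* All internal coordinates are 1-based closed, the R/Bioconductor
  convention; VCF, SAM and pileup I/O are already 1-based.
* Every generator takes an explicit integer seed; with `NULL`, a seed
  is drawn from entropy and logged. A fixed seed gives byte-identical
  outputs, which the orchestrator tests verify at file level.
* Report percentages round half-up at two decimals; exact values are
  kept alongside.
* The contamination grid step is 0.001 over $[0,1]$; at a boundary
  maximum, the curvature for the standard error uses the one-sided
  second difference, and a non-concave curve falls back to a standard
  error of 1 with a warning (flat-likelihood case).
* Degenerate inputs error explicitly (empty reference, no diagnostic
  sites, no carriers, female X-het input) or degrade with a warning
  and a well-defined value (low-count sex call, infinite fold-80).
* `run_pipeline()` skips stages whose inputs are absent and captures
  stage errors by name; composition embeds stage outputs verbatim.
  The exported functions plus `run_pipeline()`/`make_demo_dataset()`
  are the interface; there is no separate shell entry point.

## Problem sizes used by the test suite

Recovery tests run at the sizes the statistics are designed for:
damage-profile recovery on $10^5$ fragments, sex calls on 200
simulations of $10^5$ sex-chromosome reads, contamination recovery at
50 sites × 500× (mitochondrial) and 1344 polymorphic sites × 30×
(X-chromosome) across mixtures of 0–10%, prioritization truth-equality
over 100 random tables, block-finding oracle equivalence over 100
random small panels, and phase recovery over 100 panels of 500
haplotypes per configuration. Unit tests use smaller sizes with
3-standard-error bands.

## Known limitations

The estimators are validated against the package's own generative
models; real libraries add alignment artifacts, reference bias,
quality-score miscalibration and population structure that the
generators deliberately omit. The mitochondrial estimator assumes a
known contaminant allele table; the genotypability metric is a
depth-threshold approximation; the prioritization arms reproduce the
documented filter semantics but no annotation content — annotations
are inputs, never computed. Phase inference assumes the panel is
correctly phased and that the anchor's carrier block is identical by
descent; recurrent mutation or gene conversion inside the block would
mislead it, which is why the frequency co-occurrence evidence is
reported alongside rather than folded into the call.
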