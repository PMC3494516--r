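---
title: "Bootstrap estimation of expression from multi-mapping alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap estimation of expression from multi-mapping alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bootrpkm)
```

## The problem

When short RNA-seq reads are aligned to a set of transcript-level gene
models, a substantial fraction cannot be placed uniquely: duplicated genes,
paralog families and homologous genes from different organisms in one sample
(a metatranscriptome) share long identical or near-identical stretches.
Expression in RPKM — reads per kilobase of gene model per million aligned
reads — is only defined once every read is attributed to one gene, so the
treatment of ambiguous reads decides the result. Discarding them biases
expression of high-identity genes toward zero; letting the aligner place each
one once at random gives a point estimate with no notion of how much of it is
assignment luck.

## The model

Let read *r* have a set of candidate alignment locations (gene, offset)
reported by an all-alignments aligner run. In each of *B* bootstrap
iterations, every read is independently assigned to one of its locations,
selected uniformly **over locations, not over distinct genes**: a gene hit at
two positions by one read receives that read with probability 2/|locations|.
Each iteration yields a complete count vector (every read assigned exactly
once, so counts always sum to the number of aligned reads *N*) and hence an
RPKM vector, with *N* held constant across iterations so values are
comparable. The per-gene RPKM sample is summarised by its mean μ and sample
standard deviation σ (n − 1 denominator, since the iterations are a sample
from the assignment distribution).

Reads whose candidate locations all fall on a single gene are that gene's
*unique reads*: their assignment never varies, they lower-bound the gene's
count in every iteration, and they are reported separately
(`unique_reads`, `unique_rpkm`) because they are the only evidence that can
discriminate between members of a near-identical family. `unique_rpkm` uses
the same denominator *N* as the bootstrap columns so the two are directly
comparable within a row; the unique-reads-only *baseline* (below) instead
models a separate aligner run that discards ambiguous reads, and therefore
uses its own aligned total as denominator.

Detection is tested against zero under a normal model for the bootstrap
distribution:

p = P(X ≤ 0) with X ~ Normal(μ, σ), i.e. Φ(−μ/σ),

small when the distribution sits far from zero. Two degenerate cases are
decided by exact floating-point equality, deliberately without tolerance: a
gene never assigned a read has μ exactly 0 (p is set to 1 — nothing was
detected), and a gene whose count is identical in every iteration has σ
exactly 0 (p is set to 0 — detection is certain given the alignments). The
rules are checked in that order; μ = 0 with σ > 0 cannot occur, since an
all-zero mean forces all-zero counts. Raw p-values are Benjamini–Hochberg
adjusted (`stats::p.adjust`) and a gene is called expressed when the adjusted
p-value is strictly below α.

### Baselines

Two non-bootstrap references frame the comparison. *Random assignment*
allocates each ambiguous read once, uniformly over its locations — exactly
one bootstrap iteration — mirroring the aligner-default behaviour (the
per-location convention is kept for consistency with the bootstrap).
*Unique-only* counts only reads with exactly one alignment location and
normalises by the number of such reads. Neither returns a significance
measure, so both are called expressed at RPKM > 0; this asymmetry of call
criteria is inherent to the comparison and worth remembering when reading
accuracy side by side.

## Tunable parameters

* `iterations` (default **100**): bootstrap iterations. The standard error of
  μ shrinks as σ/√B; at B = 100 the residual Monte-Carlo error is already an
  order of magnitude below the assignment spread itself, and detection calls
  are driven by μ/σ, which stabilises quickly. At least 2 are required (σ is
  undefined below that).
* `seed`: governs every random assignment. Each iteration derives its own
  stream from (seed, iteration index).
* `workers` (default 1): worker processes for the iteration loop; affects
  wall time only, never the result (see below).
* `alpha` (default **0.05**): significance level applied to the BH-adjusted
  p-value, strict `<`.

## Numerical and scheduling choices

* **Streaming moments.** Iterations are aggregated with Welford updates
  (count, mean, M2), so memory is O(genes), not O(genes × iterations). M2 is
  clamped at 0 before the square root to absorb pathological round-off.
* **Worker-count invariance.** Iterations are partitioned into a fixed set of
  chunks independent of `workers`; chunk moments are combined in chunk order
  with the pairwise (Chan) formula. The floating-point reduction tree is
  therefore identical whatever the worker count, and output is bit-identical
  for `workers` ∈ {1, 2, 4, …}.
* **Exactness where it matters.** A gene covered only by unique reads has the
  same count in every iteration, so Welford yields σ = 0 and μ =
  `unique_rpkm` *exactly*, which is what makes the σ = 0 degenerate p-value
  rule safe to apply with equality.
* **Degenerate inputs.** Zero aligned reads yield an all-zero estimate table
  with p = 1 everywhere rather than an error; a zero-length gene table, a
  duplicate gene name, an alignment against a gene absent from the gene-size
  file, or a malformed alignment line are hard errors naming the offending
  line — a silent index/size-file mismatch would corrupt the RPKM denominator
  invisibly.
* **Parsing.** The alignment contract is the legacy Bowtie v1 tab-separated
  text format (read, strand, reference, 0-based offset, …); only the first
  four fields are consumed, offsets are retained but unused by counting, and
  reads are grouped by exact read-name string (no mate folding).

## The synthetic validation harness

`sim_config()` defines the generator. Its defaults are the package's
standard validation condition and were fixed once, up front: 2000 gene models
with lengths uniform on 500–3000 bp (typical transcript lengths), 10
duplicate families of size 2 at 98% within-family identity (at 46 bp reads,
0.98⁴⁶ ≈ 40% of family-derived reads fall in a conserved window and align to
both copies), half the genes expressed, log-normal expression weights with
meanlog 0 and sdlog 1.5 (a realistic ~4 orders of magnitude of dynamic
range), and error-free 46-mer reads drawn with probability proportional to
weight × (length − 45) — molarity times the number of valid start positions —
with uniform start positions on the forward strand.

The *truth* against which estimators are scored is the **intended** expression:
`true_rpkm` is the RPKM of the expected origin count, so it is independent of
sampling noise; realised per-gene origin counts are retained for diagnostics.
Read names encode origin as `read<i>|<gene>|<offset>`, so evaluation needs no
side table. An internal exact-match aligner (a k-mer index of every 46-mer
position, queried by joining read sequences against it) emits every forward-
strand occurrence as Bowtie-format lines, so the whole pipeline runs with no
external binary; real-data users align with an external aligner reporting all
alignments.

What the harness deliberately does **not** emulate: sequencing errors and
quality models (reads are exact substrings, which is what makes the
unique-only baseline provably free of false positives here), reverse-strand
reads, intron/exon structure, paired ends, and non-uniform coverage along the
transcript. Passing validation therefore demonstrates correct handling of
assignment ambiguity — not robustness to base-calling error or alignment
mismatches, which live in the upstream aligner's domain.

## Evaluation metrics

Accuracy is (TP + TN)/n over all genes, truth-positive meaning expression
weight > 0. The false-positive percentage is defined over *called* genes,
100·FP/called (a precision complement; 0 when nothing is called); the
companion rate over truth-negative genes is exposed separately as
`false_positive_rate_pct`. Spearman correlation is computed over **all**
genes with mid-ranks for ties (the tied zeros included), so an estimator is
rewarded for correctly leaving unexpressed genes at zero. MA values are
M = log2(calculated/known), A = log2((calculated + known)/2), computed on
pairs with both sides positive; the dropped count is reported.

## Validation conditions and what they show

The test suite and `scripts/acceptance.R` run the harness at 2000 genes with
300,000 reads (≈150 reads per expressed gene, an adequate-depth regime) and
30,000 reads (≈15 reads per expressed gene, a sparse regime), three seeds
each, 100 bootstrap iterations — sizes chosen so the full validation runs in
about a minute on a single CPU while keeping ≥10 reads of average depth
contrast between regimes. At these conditions the bootstrap estimator's
detection accuracy exceeds 90% at adequate depth, its rank agreement with the
known truth stays above 0.94 even in the sparse regime, and the unique-only
baseline never produces a false positive (an error-free uniquely aligning
read can only originate from its own gene). Tiny instances (≤4 reads, ≤3
locations) are additionally checked against exhaustive enumeration of all
assignment outcomes.

## Known limitations

* The normal model for the bootstrap RPKM distribution is an approximation;
  for genes receiving very few ambiguous reads the distribution is discrete
  and skewed, and the CND p-value is correspondingly approximate.
* An unexpressed exact duplicate of an expressed gene inherits roughly half
  of the shared reads in every iteration, yielding a confident false
  positive; the `unique_reads` column is the intended tie-breaker, and this
  failure mode is visible in the harness whenever a family's members differ
  in truth status.
* RPKM normalises within a sample only; cross-sample comparison inherits
  RPKM's usual compositional caveats.
* Splice-variant discovery is out of scope: gene models are the unit of
  reporting.
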