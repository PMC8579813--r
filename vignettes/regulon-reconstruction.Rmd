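---
title: "Regulon reconstruction by phylogenetic footprinting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulon reconstruction by phylogenetic footprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(regufoot)
```

`regufoot` reconstructs bacterial transcription-factor (TF) regulons by
comparative genomics: it discovers a TF's binding-site motif de novo in the
upstream regions of putatively co-regulated genes, scans related genomes
with the resulting weight matrix, keeps only cross-genome-consistent
targets, infers repression versus activation from site position relative to
the transcription start, and overlays substrate-specific differential
expression.  This vignette explains the underlying models, the parameters
that matter, and what the synthetic benchmark does and does not demonstrate.

## Coordinate conventions

All genomic intervals are 0-based half-open internally; files are read and
written 1-based inclusive (the GFF convention).  Upstream regions and
binding-site hits live in *offset* coordinates relative to a gene's
translation start: offset 0 is the first coding base, negative offsets are
upstream, and a window is `[-L, 0)`.  Minus-strand genes are
reverse-complemented at extraction, so every downstream computation —
scanning, promoter search, mode classification — is strand-agnostic by
construction.

Upstream windows default to 300 bp and stop at the nearest upstream coding
interval.  Stopping avoids planting or scanning inside open reading frames
and matches the intergenic focus of footprint displays; a flag
(`stop_at_coding = FALSE`) disables it for the alternative reading in which
windows run a fixed 300 bp regardless of annotation.  Training sets keep
intergenic regions strictly longer than 50 bp (`min_len`).

Operon structure, where not provided, is approximated by the standard
distance rule: adjacent same-strand genes with an intergenic gap under
100 bp (configurable) form one operon, and scanning anchors at the 5'-most
gene.  This is a heuristic; transcript-level operon maps, when available,
are better and can be supplied as input.

## The motif model

A binding site is modeled as a set of *modeled columns* within a span,
with three intrinsic symmetry modes reflecting how homodimeric and
multimeric bacterial regulators contact DNA:

* **palindrome** — a self-reverse-complementary element, width grid
  20–24 bp.  Column *i* is tied to the complement of column *w + 1 − i*.
* **direct_repeat** — two identical boxes of 7–11 bp whose start-to-start
  periodicity is 21 or 32 bp (two or three helical turns, so both boxes
  present the same face of the helix).  Periodicity is interpreted
  start-to-start; the linker between boxes is not modeled.
* **inverted_repeat_spaced** — two reverse-complementary half-sites
  separated by an unmodeled spacer (default search 20–30 bp); the
  `GGGAC-(27)-GTCCC` layout is the motivating case.

Unmodeled linker/spacer columns score as background everywhere, matching
the `-(27)-` notation of a nonconserved linker.

### ZOOPS expectation-maximization

Discovery assumes each training region carries zero or one site (ZOOPS) on
either strand, with site prior γ (initialized 0.8) and a uniform prior over
positions and strands.  The E-step computes per-region, per-position,
per-strand responsibilities from the current PWM/background odds; the
M-step re-estimates the column probabilities from expected counts and then
*pools tied columns* (complementing where the tie demands it), which is the
exact constrained maximizer, so the EM monotonicity guarantee is preserved.
Two numerical details:

* monotonicity holds only for parameter states inside the symmetric family,
  so the compiled entry point first projects the initial PWM onto the
  symmetry manifold;
* after normalization, each column's partner is written as a bit-exact copy
  rather than a separately rounded normalization, making the symmetry
  invariant exact in floating point, not just to rounding error.

Convergence is declared when the relative log-likelihood change falls below
1e−6 (500 iterations maximum).  Likelihood ratios are accumulated in double
precision with a probability floor of 1e−300 in the log table; no
pseudocounts are added inside EM (the maximum-likelihood update keeps the
monotonicity contract; the reported PWM adds pseudocounts separately, see
below).

### Initialization and restarts

Each of the 20 restarts (default) seeds the PWM from a span-window of the
data itself, smoothed 70/10/10/10 and symmetrized.  A single random window
is an unreliable seed for small training sets (10–20 regions): the chance
that none of 20 windows overlaps a planted site is appreciable, and a
restart that never sees a site converges to a background local optimum.
Each restart therefore screens five candidate windows by their one-step
likelihood and continues only the best — a cheap widening of the basin
coverage that, on the benchmark below, raises exact-position site recovery
from 0.86 to above 0.99 and makes width selection correct in every run,
at roughly unchanged cost (better seeds converge faster).

### Model selection across geometries

Within a geometry, restarts compete on log-likelihood.  Across geometries
(different widths, units, periods, spacers), log-likelihoods are not
comparable, so the selected geometry maximizes the mean per-column
information content of its modeled columns, with exact ties broken toward
the smaller span.  A consequence worth knowing: when a planted palindrome is
*wider* than some grid widths, its interior windows are themselves perfect
palindromes, so the narrower geometry often wins the tie — selection
honors the grid's bounds but does not guarantee recovering an oversize
planted width (the acceptance sweep exploits exactly this cap).

On training sets of pure background the best motif still acquires some
information content by overfitting.  `calibrate_null_ic()` quantifies this:
it runs discovery on simulated null training sets and returns an upper
quantile (default 95th) of the null mean-IC distribution; results below the
calibrated cut are flagged low-confidence.  The cut depends on the geometry
grid and training-set shape, which is why it is a function, not a constant.

## PWM construction and scanning

The reported motif is rebuilt from the discovered sites with Laplace-style
pseudocounts distributed by the background:
`w(b,i) = log2((n(b,i) + α·q(b)) / ((N + α)·q(b)))`, α = 1.  Scores are in
bits (log₂); any base would do since the threshold is learned in the same
units.  For palindromes and spaced inverted repeats the counts are pooled
with their reverse-complement partners, which makes plus- and minus-strand
scores of any window exactly equal — such motifs are scanned on the plus
strand only, avoiding double-counted hits.  Tandem repeats are not
strand-degenerate and are scanned on both strands.

The score threshold θ is the *minimum score over the motif's own training
sites*.  This is deliberately permissive — every training site rescans by
construction (the threshold is computed through the same compiled kernel as
scanning, so the equality is bit-exact) — and relies on the next stage to
remove the false positives it admits.

## Consistency filtering

An operon enters the regulon only when hits occur upstream of its orthologs
in at least `max(quorum_min, ceil(quorum_fraction × n_eligible))` species,
where a species is eligible if it carries both the TF ortholog and the
operon ortholog (defaults: fraction 0.5, minimum 2).  The exact quorum used
by the original footprinting practice is not standardized, so both knobs
are exposed; the defaults are conservative for genus-scale panels of ~8–14
genomes.  Raising θ never adds hits and relaxing the quorum never removes
members (both monotonicity properties are tested).  Single-species scans
cannot be consistency-checked; they are returned in full but flagged
unverified.

## TSS anchoring and mechanism inference

Promoter search assumes the housekeeping σ^A geometry: `TTGACA` (−35) and
`TATAAT` (−10) hexamers, 15–19 bp spacer, and a 4–9 bp gap between the −10
element and the TSS.  The best call minimizes total mismatches (at most 2
per hexamer); ties prefer the canonical layout (gap 7, then spacer 17).
Because a background window of plausible search size often contains a
4-mismatch pair by chance, calls worse than 4 total mismatches are rejected
— `calibrate_promoter_mm()` reproduces this cut as the 5th percentile of the
null best-mismatch distribution rather than treating it as magic.

Mode classification is a pure function of intervals: a site overlapping the
5′ UTR `[tss, 0)` or either promoter hexamer is called **repressor** (it
occludes RNA polymerase or the transcript start); a site entirely upstream
of the −35 element (or of `tss − 35` when no promoter call exists) is
called **activator**; everything else is **ambiguous**, and a missing TSS
gives **unknown**.  Overlap with a promoter hexamer counts as repressor
even by a single base — the rule is the occlusion mechanism, not distance.
Dual-mode regulators are real (the same TF can repress one operon and
activate another), so calls are reported per target; the per-TF aggregate
in the pipeline summary uses an 80 % majority and otherwise reports
"ambiguous".

## Expression overlay

The input is a replicate-averaged gene × condition matrix of log₂
expression; fold changes are differences of stored values.  The
cross-tabulation counts genes strictly above 2 log₂ units per ordered
condition pair, with regulon-member subcounts in parentheses and a closed
moderate band [1.5, 2] tracked separately — the boundary value 2.0 falls in
the moderate band, not the DE set.  Per-regulon concordance asks whether
each member exceeds the DE threshold on *every* expected
inducing-versus-non-inducing pair; with the benchmark effect size (+3 log₂
units) and noise (sd 0.3, so pair noise sd ≈ 0.42), the per-pair pass
probability is ≈ 0.99 and expected concordance ≈ 0.96.  No significance
filter beyond the fold-change threshold is applied.

## The synthetic benchmark

The generator emulates the statistical structure the analysis assumes,
with defaults chosen once as the study conditions:

* 8 pseudo-species, 10 target operons, 200 decoy genes per genome, 300 bp
  regions;
* background GC 0.35 (AT-rich, thermophile-like regulatory regions);
* divergence by independent per-base resampling at rate 0.30 per species
  against a per-base site substitution rate of 0.10 — sites are conserved
  islands, which *is* the footprinting signal.  The 0.30 background rate is
  the package's own choice of a realistic within-genus divergence; the
  no-indel model keeps offsets comparable across species and matches the
  anchor-aligned (right-justified, ungapped) footprint display;
* species 1 is the unmutated reference where TSS are mapped, mirroring the
  role of an anchor genome;
* one site per target region (ZOOPS-consistent); 5′ UTR lengths drawn with
  median 50 bp; repressor/activator geometries realized in configurable
  fractions, with consensus promoter hexamers planted at canonical spacing;
* expression: baseline Normal(8, 1), +3 log₂ on the inducing substrate
  (default xylan of the five-substrate panel), noise sd 0.3.

Toy genomes concatenate `[upstream region][placeholder ORF]` blocks with
alternating strands, so `extract_upstream()` recovers exactly the planted
regions and every stage can be scored against truth files that round-trip
through the package's own input formats.

What passing these benchmarks shows: the estimator recovers planted
geometry, sites, membership, and induction structure under the stated noise
model.  What it does not show: robustness to indels and alignment drift,
non-i.i.d. background (repeats, skews), horizontal transfer, TSS-calling
error, operon mis-annotation, or motif families outside the three symmetry
modes.  Real upstream regions violate all of these to some degree; the
consistency filter absorbs part of that, but results on real genomes should
be read with the usual footprinting caveats.

## Problem sizes and determinism

The shipped tests and the acceptance script run discovery on training sets
of 10–20 regions of 300 bp over full geometry grids with 20 restarts
(seconds per geometry on one core), a 50-training-set recovery benchmark,
and one full 8-genome end-to-end run — sizes chosen to exercise the study
conditions while staying desk-scale.  Every stochastic step derives its
stream from a single integer seed; reruns with the same configuration are
bit-identical, which the suite asserts.

## Known limitations

* No Gibbs sampler and no higher-order background model; 0-order
  backgrounds are estimated from the training regions themselves.
* No gapped multiple alignment: footprint reports are anchor-aligned only.
* No genome-wide FDR for scan hits — the consistency filter is the error
  control, and its quorum is a heuristic.
* Orthology is an input (a table), never inferred.
* The expression stage consumes replicate-averaged log₂ values; count-level
  modeling (normalization, dispersion, significance) is out of scope.
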