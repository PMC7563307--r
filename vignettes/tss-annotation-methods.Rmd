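---
title: "Methods: TSS detection, classification, and validation in tagtss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS detection, classification, and validation in tagtss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagtss)
```

## The problem

Protocols that tag 5'-triphosphate RNA ends (dRNA-seq, tagRNA-seq) mark
genuine transcription initiation events: after alignment, the 5'-most base
of each read from the TSS-tagged library is a vote for a transcription
start site. `tagtss` turns per-base, stranded 5'-end count tracks into an
annotated TSS map for a bacterial genome: detected sites, their class
relative to the coding annotation, 5'UTR structure, re-annotation
candidates, small-RNA candidates, and between-condition statistics.

The package deliberately separates the data model (`genome_io`), the
detector (`tss_detection`), the classifier and downstream analyses
(`tss_annotation`), the statistics (`tss_stats`), and a synthetic-data
generator (`synthetic_data`) whose planted truth set is the package's own
validation surface.

## Detection

For each replicon and strand, replicate 5'-end tracks from one condition
are pooled position-wise (library sizes add). A sliding window of
`window_width` nt (default 5) is evaluated at every position; a window
qualifies when

$$ \text{window count} \times \frac{N_\text{ref}}{N_\text{lib}} >
   \theta $$

with reference library size $N_\text{ref} = 2\,000\,000$, the pooled
library size $N_\text{lib}$, and threshold $\theta = 50$ reads. The
inequality is strict. Overlapping or adjacent qualifying windows are
merged into one maximal run, and each run emits a single TSS at the
coverage-weighted mean of its non-zero positions,

$$ \hat{p} = \operatorname{round}\!\left(
     \frac{\sum_i p_i c_i}{\sum_i c_i} \right), $$

rounded to the nearest integer with round-half-even so ties resolve
deterministically and without directional bias. Merging is essential:
without it a single sharp peak qualifies up to `window_width` overlapping
windows and would emit that many near-duplicate sites. A `top_n` mode
optionally keeps only the strongest calls genome-wide (ties broken by
replicon order then position), emulating tuning the caller to a fixed
number of most highly expressed TSSs.

Because the threshold is applied to normalized counts, scaling all counts
and the library size by a common factor leaves the call set unchanged;
the test suite asserts this exactly, and checks the detector
position-by-position against a brute-force window-enumeration oracle on
random sparse tracks.

Normalization uses the *pooled* library size. Whether per-replicate or
pooled normalization is intended is ambiguous in the underlying rule; the
pooled reading was chosen because detection runs on the pooled track, and
the scale invariance above makes the two readings coincide for equally
sized replicates.

## Classification

Detected TSSs are classified against the CDS annotation by a strict
priority cascade — primary > secondary > internal > antisense > orphan —
so every call gets exactly one class:

* **pTSS** — the strongest call within `p_window` (200) nt upstream of a
  start codon on the sense strand, provided its height is at least
  `dominance_factor` (2) times the runner-up in that window; a lone
  candidate is automatically primary. The window is measured from the
  first base of the start codon and includes it, so a 5'UTR length of 0
  is representable.
* **sTSS** — every other call in such a window. When the dominance rule
  fails, the CDS gets *no* primary TSS and all window calls are
  secondary; this keeps the classes non-overlapping while staying
  faithful to the definition of the primary TSS as the clearly dominant
  start.
* **iTSS** — inside a CDS on the coding strand. A call inside several
  overlapping CDSs is assigned to the one whose 5' end it is closest to.
* **aTSS** — on the non-coding strand of a CDS, or on the non-coding
  strand within `antisense_upstream` (100) nt upstream of its start
  codon (inclusive of the start base).
* **oTSS** — everything else.

A call eligible via several CDSs takes the highest-priority class, per
the cascade: a call upstream of one CDS and inside another is primary or
secondary, never internal.

5'UTR length is the distance from the TSS to the first base of the start
codon (0 when coincident); calls with `utr_length <
leaderless_max_utr` (5 nt) are flagged leaderless. The flag is computed
for primary and secondary TSSs alike; the headline leaderless statistic
is conventionally reported over primary TSSs only.

For internal and antisense TSSs the position along the cognate CDS is
expressed as `relative_position` $=(p - p_{5'})/(L-1)$ in the
translation-sense coordinate system. Antisense TSSs matched through the
100-nt upstream branch lie upstream of the CDS, so their value is
negative; `positional_profile()` bins only $[0, 1]$.

## Re-annotation and orphan triage

A CDS is a start-codon re-annotation candidate when it has no primary
TSS, an internal TSS lies strictly between the annotated and an
externally predicted alternative start (in translation sense), and a
ribosome-binding-site motif precedes the predicted start. The RBS model
is the best match to the consensus `AGGAGG` with at most 2 mismatches
whose last base ends 4–14 nt before the start codon; consensus, mismatch
budget and spacer range are configurable since RBS predictors differ.
Alternative starts outside the CDS or out of frame with the annotated
stop are skipped with a warning rather than silently dropped.

Orphan TSSs are triaged in priority order:

1. **long 5'UTR** — a sense start codon lies `long_utr_range` (200–300)
   nt downstream and every base from the TSS to the start codon has
   coverage of at least `coverage_min` in the untagged-library track
   (the computational analogue of verifying uninterrupted coverage).
   Without a coverage track this check is skipped with a warning.
2. **ORF-associated** — an open reading frame (start codon ATG/GTG/TTG,
   in-frame stop within the replicon, length ≥ `orf_min_length` = 150 nt
   counted start through stop codon inclusive) begins within
   `orf_search_distance` nt downstream on the same strand. The distance
   an ORF may start downstream of the TSS is not fixed by convention;
   the default of 200 nt is configurable. The codon walk is capped at
   9000 nt as a guard against degenerate (stop-free) sequences.
3. **sRNA candidate** — the remainder; these are the interesting
   noncoding-RNA candidates.

Relative isoform expression for genes with alternative TSSs is each
call's share of the summed normalized heights, in percent.

## Statistics

Per-TSS differential expression is a normalized pseudocount log-ratio,

$$ \log_2\mathrm{FC} = \log_2 \frac{(c_B + 0.5)/N_B}{(c_A + 0.5)/N_A}, $$

flagged differential at $|\log_2\mathrm{FC}| > 1$. No count-model
p-value is attached: the per-TSS criterion is deliberately a bare fold
change, and gene-level dispersion modeling is out of scope for this
package (use edgeR/limma on gene counts for that).

Fisher's exact test is implemented from the hypergeometric definition —
the two-sided p-value sums the probabilities of all tables sharing the
observed margins whose probability does not exceed the observed table's
(minimum-likelihood convention, stated explicitly because two-sided
conventions differ) — and Benjamini–Hochberg from the step-up formula.
Both are cross-checked in the tests against `stats::fisher.test` /
`stats::p.adjust` and against an independent enumeration oracle over all
tables with row margins up to 30. Functional-class enrichment runs one
test per class label for a TSS-derived gene set against a labeled
universe (default: all annotated CDSs, with unlabeled genes in class
"S"), with BH correction across labels and significance at adjusted
p < 0.05.

## The synthetic generator and what it validates

`sim_params()` defaults define the package's standing study conditions:

* a 500-kb, two-replicon genome with 220 non-overlapping CDSs (GC 0.61),
  intergenic gaps of 450–1200 nt so that every upstream classification
  window is fully intergenic;
* 200 planted TSSs with class mix p/s/i/a/o = 0.31/0.13/0.26/0.23/0.07,
  the genome-wide proportions typical of bacterial TSS maps;
* lognormal expected pooled peak heights (meanlog = log 600, sdlog =
  0.6) floored at 300 raw reads — i.e. normalized height 100, twice the
  detection threshold at three pooled 2-million-read libraries;
* positional jitter {−1: 0.1, 0: 0.8, +1: 0.1}, emulating the ±1 nt
  wobble of real TSS read starts; recovery tolerance (±3 nt) is set
  accordingly;
* uniform Poisson background of 0.01 reads/nt/strand/replicate;
* triplicate libraries per condition with nominal library size 2e6 (the
  5'-end track is a subset of the sequencing library, which is why the
  nominal rather than the realized total is used for normalization);
* 30% of TSSs at fold change 4 between conditions, and 5% of primary
  TSSs planted leaderless (5'UTR 0–4 nt).

Counts are Poisson per replicate (so pooled counts are Poisson);
optional overdispersion is available as a per-TSS, per-replicate gamma
multiplier but defaults to off, since the detector operates on pooled
counts and no dispersion model is implied by the method.

Placement inverts the classifier's geometry, and that inversion is the
generator's defining contract: with zero background and zero jitter the
classifier must recover 100% of intended classes. Three constructive
details make the contract hold rather than merely usually hold:

* planted TSSs on one strand are at least 15 nt apart, so the detector
  never merges two planted peaks into one run;
* secondary TSSs are planted only on CDSs that also receive a primary,
  at a height ratio drawn from 3–6, so the 2× dominance rule survives
  Poisson sampling with overwhelming probability;
* internal/antisense/orphan positions are rejection-sampled against the
  same window/body/antisense region index the classifier uses, and
  orphans keep more than 300 nt from every CDS.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: processed 5'-monophosphate ends surviving TEX
treatment, rRNA-depletion artifacts, mappability gaps and multi-mapped
reads, operon structure and overlapping genes, condition-dependent
background, or realistic promoter sequence context. The synthetic
validation demonstrates that the implementation is faithful to the
stated rules, not that the rules are optimal for any particular
organism.

## Numerical and design choices

* Internal coordinates are 1-based inclusive (GFF3 convention)
  everywhere; BED/bedGraph conversion happens only at file boundaries,
  and a round-trip property test guards the off-by-one surface.
* Strandless CDS annotations are rejected outright: every
  classification rule is strand-dependent, so a '.' strand has no
  meaningful interpretation here.
* Weighted-mean positions round half-even; `round()`'s banker's
  rounding is relied on deliberately.
* Table-style condition intersections match calls of the same class
  within ±5 nt (one window width) — both conventions (tolerance, and
  whether matching is within class) are configurable.
* Degenerate inputs: an empty track is readable but detection refuses a
  zero library size; a genome with no CDSs classifies every call as an
  orphan; an empty TSS class yields an empty positional profile, not an
  error.
* `diff_tss()` assigns calls detected in only one condition a zero
  count on the missing side; with the 0.5 pseudocount these appear as
  large finite fold changes rather than infinities.

## Problem sizes used in the validation suite

The test suite runs the detector-oracle comparison on 100 random tracks
of up to 10 kb; parameter recovery, the noise-free contract, and
differential recovery on the default 500-kb/200-TSS study; the Fisher
enumeration sweep over all 2×2 tables with row margins ≤ 30; and the
end-to-end determinism check on a 4-Mb genome with six tracks of roughly
two million 5'-end reads each, run twice and compared byte for byte.
These sizes were chosen as the smallest at which each property is
convincing: recovery rates stabilize well below 500 kb, and the 4-Mb run
exercises the same dense code paths as a full bacterial genome.

## Known limitations

* Processed-site (PSS) detection is out of scope; the untagged library
  enters only through the coverage-continuity check in orphan triage.
* The per-TSS fold change has no attached p-value; it is a descriptive
  screen, not a calibrated test.
* The classifier assigns one cognate CDS per call; in dense genomes
  with nested genes, a call genuinely relevant to two genes is reported
  once under the cascade's priority.
* The RBS scan is a consensus-mismatch model, not a trained motif; it
  is meant to rank candidates, not to predict translation efficiency.
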