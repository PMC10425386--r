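---
title: "Classifying Cas9 repair outcomes from amplicon reads"
author: "ampliclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Cas9 repair outcomes from amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclass)
```

## The model

An SpCas9 editing experiment is described by an `experiment_design`: a
reference amplicon, a 20-nt protospacer with an NGG PAM placed uniquely
on either strand, a predicted cut geometry, an optional donor, and a
quantification window. The blunt double-strand break falls 3 nt 5′ of
the PAM, between protospacer positions 17 and 18. The staggered mode
shifts the cut on the protospacer-carrying (non-target) strand one base
towards the PAM-distal side, leaving complementary 1-nt 5′ overhangs
whose base the package reports; this is the geometry that makes
directional dsDNA knock-in possible.

Coordinates follow the R convention: base positions are 1-based, and cut
sites are inter-base integers counting the bases 5′ of the cut (a cut at
`c` separates base `c` from base `c + 1`), which keeps splicing
arithmetic exact. Variants are attributed to editing when they intersect
the inter-base window `[c − w, c + w)`; `w` defaults to 8 bp, a
conventional quantification-window half-width for short-read amplicon
callers — wide enough to catch resected junctions, narrow enough to
exclude most sequencing noise.

Each read is aligned globally (Needleman–Wunsch with affine gaps,
via `Biostrings::pairwiseAlignment`) to the reference and, when an ssODN
donor defines one, to the expected HDR allele. Alignment columns are
collapsed into variant events — insertions, deletions, substitutions —
in reference coordinates, and every indel is left-normalized to its
smallest reference start among sequence-equivalent placements so that
identical edits always share one canonical key. Left shifts never cross
an earlier event; this keeps events non-overlapping and makes the
event → sequence round trip exact, which the test suite checks on every
simulated read.

### The decision cascade

A mapped read is assigned the first matching category:

1. **HDR_KI** — an HDR allele exists, the read's alignment to it has no
   indel inside the insert-expanded window, and every intended
   substitution (PAM-blocking or silent edits carried by the donor arms)
   is present.
2. **NHEJ_KI** — the reference alignment carries exactly one in-window
   indel, an insertion whose sequence matches the donor payload (or its
   reverse complement) at ≥ 90% identity; the better orientation is
   recorded, and an exact tie is treated as ambiguous (no call).
3. **UNMODIFIED** — no in-window indel. Substitution-only reads land
   here: the outcome scheme has no substitution class and substitution
   noise dominates amplicon sequencing, so counting them as edits would
   inflate every denominator.
4. **NHEJ** — a single in-window indel of length ≤ 1 bp.
5. **MH_DEL** — a single in-window deletion of length ≥ 2 bp whose
   junction microhomology is ≥ 2 bp.
6. **OTHER** — everything else: multi-indel reads, long insertions that
   do not match the donor, deletions without microhomology, imperfect
   knock-in junctions.

HDR takes precedence over NHEJ_KI because a read matching the seamless
HDR allele necessarily also contains the payload; seamless,
arm-templated insertion is the operational definition of HDR here.
Imperfect HDR junctions (payload present plus extra in-window indels)
fall through to OTHER rather than HDR_KI, keeping HDR_KI equal to the
precise edit.

The MH-del rule applies two thresholds — deletion length ≥ 2 **and**
junction microhomology ≥ 2 — because a 1-bp deletion is definitionally
NHEJ and single-base junction identity is uninformative. Both thresholds
(`mh_min`, `nhej_indel_max`) are exposed in `classifier_config()`, since
reasonable pipelines differ on whether microhomology alone should
qualify.

### Microhomology length

`mh_length()` measures the junction microhomology of a deletion as the
number of alternative equal-length placements producing the identical
edited sequence: the deletion can shift right `j` bases while
`ref[s + i] == ref[e + i]` for all `i < j` (`s` the first deleted base,
`e` the first base after the segment), and symmetrically left; the total
number of valid single-base shifts is the microhomology. This
continuation form handles repeats shorter than the deletion — deleting
`AC` from `ACACAC` has microhomology 4, matching the placement count —
where a definition bounded by the deleted segment itself would
undercount. The equivalence to the brute-force placement count is the
package's primary invariant, tested on 180,000 random deletions.
Because the measure depends only on the reference and the deletion
interval, upstream left-alignment cannot change it.

### Expected knock-in alleles

* **ssODN** — the homology arms must occur adjacent in the reference
  near the cut (within `arm_search_radius`, default 20 bp); the HDR
  allele is the reference with intended substitutions applied and the
  payload spliced at the arm junction.
* **Blunt dsDNA** — the payload (or its reverse complement) ligated into
  the blunt cut.
* **1-nt 5′-overhang dsDNA** — the donor's top strand is
  `overhang + core`, with the complementary single-base 5′ overhang on
  the bottom strand. An orientation whose overhang pairs the genomic
  overhang ligates seamlessly; the incompatible orientation is modelled
  as fill-in of all single-base overhangs followed by blunt ligation,
  leaving 1-nt anomalies at both junctions. This fill-in model is a
  deliberate simplification: end-processing at incompatible junctions is
  heterogeneous in cells, but any plausible product still contains the
  reverse-complemented payload, which is what orientation calling keys
  on.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `quant_window` | 8 | bp | conventional half-width for cut-site quantification |
| `mh_min` | 2 | bp | single-base junction identity is uninformative |
| `nhej_indel_max` | 1 | bp | ±1 bp indels are the canonical NHEJ footprint |
| `donor_min_identity` | 0.90 | fraction | tolerates sequencing error over a 34-nt payload while rejecting unrelated insertions |
| `mapped_min_score_frac` | 0.60 | fraction of self-score | score floor defining a mapped read |
| `min_mean_qual` | 20 | Phred | standard mean-quality filter |
| match / mismatch / gap open / gap extend | +2 / −2 / −10 / −1 | score | favours one contiguous indel at the cut over scattered gaps |

The mapped-read definition deserves a note: editing fractions are
reported per mapped read, but "mapped" has no universal definition for
global alignment. The package uses a score floor — at least 60% of the
best-matching allele's self-alignment score — as a minimal, declared
proxy; it is a default, not a reconstruction of any particular caller's
behaviour. The quality filter is likewise a declared default and is
skipped for count-table input, which carries no qualities.

## What the simulator emulates — and what it does not

`make_fixture()` builds a random amplicon (default 200 bp) with a
uniquely placed protospacer, an engineered repeat giving the designed
deletion an exact microhomology (verified against `mh_length()` at
construction, with bounded retries), a second engineered 4-bp deletion
with zero microhomology, and optionally a donor.
`simulate_reads()` draws reads i.i.d. from an eight-class mixture of
deterministic templates:

* `unmodified` — the reference;
* `nhej_plus1` / `nhej_minus1` — a 1-bp duplication / deletion at the cut;
* `mh_del` — the engineered microhomology deletion;
* `hdr_ki`, `nhej_ki_fwd`, `nhej_ki_rev` — the expected allele
  sequences (for ssODN donors the NHEJ-capture templates splice the
  payload bluntly at the cut: end joining does not use the arms);
* `other` — the engineered no-microhomology 4-bp deletion, which is
  deterministically rule-6. A multi-indel template of the form "−1 bp
  plus +1 bp a few bases apart" was rejected by design: under affine
  scoring such a net-length-zero pair always aligns better as a handful
  of substitutions, so no optimal aligner could recover it and truth
  labels would be undefined.

Errors are uniform substitutions (default rate 0, up to 0.05); amplicon
short-read error profiles are substitution-dominated, and indel noise
would blur the ground-truth category of a read. Reads span the full
amplicon, emulating merged paired-end reads.

Real data differ in ways the simulator deliberately ignores: PCR bias
and chimeras, position-dependent quality, indel sequencing errors,
partial-span reads, and the full diversity of repair junctions.
Passing simulation tests therefore demonstrates that the classification
logic is correct for reads whose generative category is well-defined —
not that category fractions on arbitrary real libraries are unbiased.

`simulate_long_reads()` emits full-span aligned long reads where a set
fraction carries one fixed deletion segment, exercising the coverage
statistic against its analytic value; it does not model consensus-read
errors or alignment ambiguity.

## Numerical choices and degenerate inputs

* Alignment is deterministic for fixed inputs and scoring; a gap of
  length L costs `open + L · ext`.
* Variant keys encode only in-window, left-normalized indels, so
  out-of-window substitution noise does not split variants; ties in the
  top-variant ranking break lexicographically by key.
* Tabulating zero mapped reads is an error; zero mutated reads yields
  relative fractions of 0 with a flag. An HDR:indel ratio with an empty
  denominator reports `Inf` (or `NA` when HDR is also absent).
* The long-read statistic divides by `Ct`; `Ct = 0` is an error, and
  `(Ct − Cm)/Ct` is the parenthesisation that yields a proportion in
  [0, 1] for spanning reads. Whether partial-span reads count towards
  `Ct` is exposed as `min_span_frac` (default 0: any intersecting read
  counts).
* Fixture construction retries with fresh randomness when an engineered
  constraint collides with the PAM or duplicates the protospacer, and
  fails loudly after a bounded number of attempts.

## Problem sizes

The shipped test-suite and acceptance-script runs use: 1,000 random
200-nt references × deletion lengths 2–10 × 20 positions for the
microhomology oracle; ten 5,000-read fixtures at zero noise; one
20,000-read eight-class mixture at error rate 0.001; 2,000 reads for
orientation purity; and 10,000 long reads for the deletion statistics.
These sizes give three-sigma binomial margins comfortably inside a
±0.01 recovery tolerance while keeping a full run in minutes on one
core.

## Known limitations

* One guide, one cut per amplicon; no base- or prime-editor allele
  models.
* NHEJ-KI typing covers single full-payload integrations; concatemers,
  vector-backbone capture and partial integrations land in OTHER.
* MH_DEL is a proxy for alternative end joining; synthesis-dependent
  variants with templated junction insertions are not subtyped, and
  microhomology-flanked deletions can also arise from NHEJ.
* Substitution-only reads are UNMODIFIED by convention; pipelines that
  count them as edits will report different denominators.
* The staggered-cut overhang strand assignment follows the cited
  single-base 5′-overhang model of SpCas9 cleavage; longer overhangs
  are out of scope.
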