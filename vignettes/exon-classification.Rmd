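---
title: "Classifying constitutive and alternative exons: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying constitutive and alternative exons: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exontype)
```

## The model

A gene model is a set of transcript isoforms, each an ordered chain of
non-overlapping exons on one chromosome and strand; introns are the gaps
between consecutive exons. All internal coordinates are 0-based,
half-open (BED convention); GTF/GFF3 1-based inclusive coordinates are
converted once, at the I/O boundary, so interval arithmetic never deals
with off-by-one cases. Transcripts spanning multiple chromosomes or mixed
strands are rejected rather than repaired, because classification
semantics are undefined for them.

The reference isoform *i0* is the transcript with the maximum exon count,
breaking ties by summed exon length and then by lexicographically
smallest transcript id. The first two criteria are the standard
definition; the third exists only to make selection deterministic.

Boundary vocabulary is strand-aware and follows transcription direction
throughout: an exon's *donor* (5′ splice site) side is its genomic end on
`+` and its genomic start on `-`; the *acceptor* (3′ splice site) side is
the opposite. This is the standard convention — A3SS means the
acceptor-side boundary varies, A5SS the donor-side — and it is what makes
every label and event type invariant under reverse-complementing a locus
(tested as the strand-mirror property).

## Event detection

`detect_events(ref, alt)` works on pure interval relations:

* **ES** — an exon of `ref` lies entirely within one intron of `alt`;
* **IR** — an exon of `alt` exactly spans two or more consecutive exons
  of `ref` plus the intervening intron(s), one event per retained intron;
* **EXONIC_INTRON** — an intron of `alt` lies strictly inside a single
  exon of `ref`;
* **A3SS / A5SS** — two introns share their donor (resp. acceptor)
  boundary but differ at the other end.

A3SS/A5SS comparisons carry one *skipping exclusion*: an intron pair is
ignored when either intron fully contains a complete exon of the other
transcript. Without it, a skipping isoform's long intron would also be
reported as a spurious alt-SS event against both flanking introns of the
reference — the boundary difference is a consequence of skipping, not of
competing splice-site choice. Multiple genuine events per isoform pair
remain allowed.

## Exon classification, scheme 1 (intact units)

The classification units are the distinct exon-coordinate tuples of the
gene: the intact-exon view keeps each observed length form as its own
unit, which also resolves the known representative-sequence ambiguity of
alt-SS exons (both forms are units and both carry the alt-SS label).

Labels are assigned with the following precedence, which matters only for
compound configurations:

1. `CE` — the tuple occurs verbatim in every transcript;
2. `AE_IR_MERGED` — the tuple exactly spans ≥ 2 consecutive exons of some
   transcript (a retained intron, or equivalently the intact form of an
   exonic intron);
3. `AE_CASSETTE` — the tuple lies entirely within an intron of some
   transcript;
4. `AE_ALT3SS` / `AE_ALT5SS` / `AE_ALT_BOTH` — a boundary competes with a
   different splice site (the variable end(s) are recorded).

Alt-SS evidence is *intron-anchored*: a unit's acceptor end varies when
the upstream intron of a transcript containing it competes with an intron
of another transcript that shares the donor boundary but differs at the
acceptor (symmetrically for the donor end). Two exclusions apply. The
skipping exclusion is inherited from event detection. The second is the
*merged-boundary exclusion*: evidence is ignored when the competing
boundary abuts an IR-merged exon of the other transcript. Without it, the
intron chain of a skipping isoform and the intron chain of a retaining
isoform can share an acceptor while differing at the donor purely because
one retains an intron — in the bundled worked example this would
spuriously mark exon 2's donor end as variable, whereas its only genuine
competition is at the acceptor.

Exons whose only alternative partner is an IR-merged unit — the two
flanks of a retained intron, or the two split forms of an exonic intron —
carry no intron-anchored evidence at all. They fall back to a direct
exon-overlap comparison, which records which end differs from the
overlapping (merged) form; the flank abutting the retained intron is thus
reported with its donor or acceptor end variable. This is a deliberate
design choice: such exons are not constitutive (they are absent, as
tuples, from the retaining isoform), and the variable end is the honest
description of how they differ.

Transcription start/end variation is not splicing. With the default
`include_end_variation = FALSE`, a unit whose only variation across
transcripts is at a transcription start (acceptor side of a first exon)
or transcription end (donor side of a last exon) is labelled `CE`. This
deliberately relaxes the strict "CE iff identical in every transcript"
biconditional: the package reads `CE` as *constitutively spliced*.
Setting the flag to `TRUE` restores the broader-sense behaviour in which
those units become alt-SS exons.

## Exon classification, scheme 2 (regions)

Scheme 2 treats exons as dividable. Over the union of exonic bases, each
base's transcript coverage is computed by exact breakpoint arithmetic
(never per-base loops — those are reserved for the test oracles); maximal
abutting runs with coverage equal to the transcript count become `CR`,
runs with partial coverage become `AR`. The output partitions the exonic
union exactly, and a run's reported coverage is the number of transcripts
containing *every* base of the run. The two schemes are mutually
consistent: every base of a `CE` exon lies in a `CR` region, and every
`AR` base lies inside some non-`CE` unit (both tested).

## The exonic-intron duality

An isoform that splices a region out of an internal exon has *more* exons
than the intact isoform. Because *i0* is defined as the isoform with the
maximum exon count, the split isoform is selected as the reference, and
gene-level event detection reports the dual event: intron retention with
the intact isoform as the alternative. The relation between the two
isoforms is identical either way; only the role assignment differs.
The simulator's truth records therefore store the planted ref/alt
orientation explicitly, and the gene-level view is asserted in the tests
as the documented dual. Classification is orientation-free, so the intact
exon is always `AE_IR_MERGED` and the split forms always carry their
variable ends.

## Sequence features: parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| donor window | 3 exonic + 6 intronic | nt | the 9-nt motif recognised at the 5′ SS; a fixed constant |
| acceptor window | 20 intronic + 3 exonic | nt | only the donor window is a stated constant; 23 nt covers the PPT and the terminal `AG`, matching common practice |
| PWM pseudocount α | 1 | counts | Laplace smoothing; avoids −∞ log-odds on held-out windows; α = 0 recovers raw frequencies |
| PWM background | uniform 0.25 | prob. | neutral default; configurable |
| BP consensus | `YTNAY` (DNA for YUNAY) | — | degenerate branch-point motif; `N` in the genome never matches |
| BP search range | 14–350 | nt upstream of 3′ SS | proximal BPs sit 14–50 nt out; distal ones occur up to 350 nt, which bounds the search; candidates beyond 50 nt are flagged `distal` |
| BP tie-break | closest to 3′ SS | — | most branch points are proximal |
| PPT threshold / min length / span / gap | 0.7 / 10 / 50 / 2 | — / nt / nt / nt | the tract is "~20 nt, pyrimidine-rich, ~2 nt from the AG"; the numeric thresholds are package conventions, configurable, not stated constants |
| SRE motifs | the six cluster motifs, as DNA | — | `UCUCU, UGCAUG, UGCU, UGUGU, UUUU, AGGG`; exact matching, overlaps counted |
| boundary-GC window | 25 each side | nt | not a stated constant; configurable |
| symmetry divisor | 3 | — | reading-frame preservation |
| PSI denominator | mean of the two inclusion junctions | reads | keeps inclusion and exclusion on the same per-event scale, so a fully included exon at depth N gives psi = N/(N+0); `min` and `sum` available |
| major/minor cutoff | 0.5 | PSI | the only symmetric choice for an admittedly subjective call; configurable |

Numerical conventions worth knowing:

* Any window containing `N` returns `NA` (a missing-value marker) rather
  than failing — `N` is legal in the genome.
* A pure run of exactly 10 pyrimidines never yields a length-10 PPT under
  the defaults: the run can absorb up to four flanking purines while
  staying at fraction 10/14 ≈ 0.714 ≥ 0.7, so the longest qualifying run
  is 14 nt. The tests freeze the exhaustive-oracle value, not the naive
  hand count.
* Overlapping SRE matches are counted individually; `TGCATGCATG`
  contains `TGCATG` twice (offsets 0 and 4).
* PPT length ties break toward the 3′ splice site; the PWM consensus
  resolves frequency ties to the alphabetically first base.

## What the simulator emulates — and what it does not

`simulate_gene()` builds a reference isoform with configurable exon and
intron length ranges (defaults 90–180 and 250–800 nt: compact,
realistically proportioned loci that keep property suites fast), plus one
alternative isoform per planted event. Events are assigned to distinct,
non-adjacent internal exons, so planted truth labels are single-valued
and exactly recoverable — by design the simulator only plants
unambiguous configurations. Splice-site windows are drawn per position
from the donor/acceptor consensus with probability equal to the
configured strength; reference-isoform sites are planted last, so *i0*'s
`GT`/`AG` dinucleotides are always canonical even when variant windows
overlap them.

Junction counts emulate spliced mapping at the count level: every
reference intron receives `depth` supporting reads; at a cassette exon
the number of included transcripts is a single `Binomial(depth, psi)`
draw, both inclusion junctions receive that coverage, and the remaining
reads support the skip junction. This makes the mean-denominator PSI
estimator unbiased and gives `psi = 1` exactly at full inclusion.

What a green test therefore does **not** establish: robustness to
mapping noise, read-length effects, overlapping genes, unannotated
junctions, compound events on one exon, or expression-level variation
between isoforms — none of which the generator models. FASTQ-level
simulation, BAM processing, and differential splicing across conditions
are out of scope.

## Known limitations

* Classification depends on the transcript set: adding a novel isoform
  may relabel exons (adding a duplicate never does; both are tested).
  Labels are statements about an annotation, not about biology beyond it.
* Compound configurations (one exon participating in several distinct
  events against different isoforms) take the highest-precedence label;
  the per-occurrence sub-forms (simple/multiple/complex) are not
  implemented.
* PSI is computed for cassette exons from the reference isoform's
  junction triplet; alt-SS events would use the two competing junctions
  directly, but a dedicated interface for that is not exposed yet.
* The GFF3 reader handles the flat gene/transcript/exon case (`Parent`
  accepted for the transcript id); deeper feature hierarchies are out of
  scope.
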