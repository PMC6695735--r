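# exontype

Annotation of constitutive and alternative exons in multi-isoform
eukaryotic genes, with the sequence features and inclusion-level
estimates that characterise them.

## The problem

When a gene has several transcript isoforms, every exon is either
**constitutively spliced** (present, with identical coordinates, in every
mature mRNA) or **alternatively spliced**. Tools downstream of a GTF/GFF3
annotation — isoform quantification, splice-site strength analyses,
evolutionary comparisons — routinely need that dichotomy made explicit,
yet it is surprisingly easy to get wrong (alt-3′/5′-SS exons are treated
inconsistently across the literature, intron retention produces merged
exons that fit neither box, and transcription start/end variation is not
splicing at all). `exontype` implements both standard views:

1. **Intact scheme** — every distinct exon-coordinate tuple is one unit,
   labelled `CE`, `AE_CASSETTE`, `AE_ALT3SS`, `AE_ALT5SS`, `AE_ALT_BOTH`,
   or `AE_IR_MERGED`;
2. **Region scheme** — exons are dividable: over the exonic union, maximal
   runs covered by *all* transcripts are constitutive regions (`CR`), runs
   covered by only some are alternative regions (`AR`).

It also detects the underlying events against the reference isoform
*i0* (the isoform with the most exons, then the longest sequence):
exon skipping (**ES**), alternative 3′/5′ splice site (**A3SS**/**A5SS**,
in transcription direction), intron retention (**IR**), and the exonic
intron (**EXONIC_INTRON**).

## Sequence features and inclusion levels

For each exon unit the package computes the diagnostic features of
splicing strength and architecture:

* **Splice-site strength** — position weight matrices over the 9-nt donor
  window (exonic −3..−1 + intronic +1..+6, canonical `GT`/`GC`) and a
  23-nt acceptor window (intronic −20..−1 ending `AG` + exonic +1..+3),
  scored as log-odds bits: `S(w) = Σᵢ log₂ f\[i, wᵢ\] / q\[wᵢ\]`.
* **Branch point** — nearest `YUNAY` consensus match 14–350 nt upstream of
  the 3′ SS (flagged distal beyond 50 nt).
* **Polypyrimidine tract** — longest pyrimidine-rich run (fraction ≥ 0.7,
  length ≥ 10) in the last 50 intronic nt, excluding the `AG` and its 2-nt
  gap.
* **SREs** — overlap-allowed k-mer scanning of splicing regulatory
  elements; the default set is the six cassette-exon cluster motifs
  `UCUCU, UGCAUG, UGCU, UGUGU, UUUU, AGGG` (stored as DNA).
* **Architecture** — exon length, flanking intron lengths,
  intron-to-exon ratio, GC content, boundary GC (±25 nt), and
  reading-frame symmetry (length divisible by 3).
* **PSI** — an alternative exon's inclusion level from junction read
  counts: `psi = I / (I + E)` with `I` the mean of the two
  inclusion-junction counts and `E` the skip-junction count; exons are
  classed major (`psi ≥ 0.5`) or minor.

## Worked example

The bundled four-exon demonstration gene has five isoforms: `i0` (all
exons), `i1` (skips exon 3), `i2` (acceptor of exon 2 shifted), `i3`
(donor of exon 1 shifted), `i4` (retains intron 2).

```r
library(exontype)
wx <- make_worked_example()
gene_events(wx$gene)
#>   gene_id event_type ref_id alt_id chrom strand start end
#> 1   gene1         ES     i0     i1  chrT      +   700 790
#> 2   gene1       A3SS     i0     i2  chrT      +   400 430
#> 3   gene1       A5SS     i0     i3  chrT      +   170 200
#> 4   gene1         IR     i0     i4  chrT      +   500 700
```

One event of each type: exon 3 `[700,790)` is skipped by `i1`; the
competing acceptors of exon 2 differ over `[400,430)`; the competing
donors of exon 1 over `[170,200)`; intron 2 `[500,700)` is retained.

```r
classify_exons_intact(wx$gene)[, c("start","end","label","transcripts")]
#>   start  end        label    transcripts
#> 1   100  170    AE_ALT5SS             i3
#> 2   100  200    AE_ALT5SS    i0,i1,i2,i4
#> 3   400  500    AE_ALT3SS       i0,i1,i3
#> 4   400  790 AE_IR_MERGED             i4
#> 5   430  500    AE_ALT3SS             i2
#> 6   700  790  AE_CASSETTE       i0,i2,i3
#> 7  1000 1100           CE i0,i1,i2,i3,i4
```

Only the last exon is constitutive; both length forms of an alt-SS exon
carry the same label, and `i4`'s merged exon is reported as
`AE_IR_MERGED`. Simulated junction counts at true inclusion 0.7 and depth
1000 recover the inclusion level:

```r
jx <- simulate_junction_counts(wx$gene, psi = 0.7, depth = 1000, seed = 7)
psi_for_gene(wx$gene, jx)[, c("start","end","psi","n_effective","isoform_class")]
#>   start end   psi n_effective isoform_class
#> 1   700 790 0.665        1000         major
```

0.665 is within one binomial standard deviation (0.0145) of the true 0.7,
and the exon is called the major isoform.

## Command line

```sh
inst/cli/exontype annotate --gtf genes.gtf --scheme intact --out exons.bed
inst/cli/exontype segment  --gtf genes.gtf --out regions.bed
inst/cli/exontype events   --gtf genes.gtf --out events.tsv
inst/cli/exontype features --gtf genes.gtf --fasta genome.fa --out feats.tsv
inst/cli/exontype psi      --gtf genes.gtf --junctions sj.tsv --out psi.tsv
inst/cli/exontype simulate --out-prefix sim --seed 1 --events ES,IR
```

`--config file` accepts flat `key: value` or JSON (see
`inst/cli/exontype --config-dump` for the schema); command-line flags
override the config file, which overrides built-ins.

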