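# hervtrace

Integration-site discovery for HERV-K retrotransposition from
ligation-mediated PCR (LM-PCR) junction-sequencing libraries.

## The problem

HERV-K, the youngest human endogenous retrovirus family, can still move:
a completed retrotransposition cycle integrates a new provirus that carries
two diagnostic scars. Integrase duplicates a short host motif — a 5–6 bp
**target-site duplication** (TSD) — on both sides of the provirus, and
reverse transcription regenerates **U3** at the 5′ LTR, so a donor construct
whose 5′ U3 was swapped for a CMV promoter produces integrants with U3 (not
CMV) at the 5′ junction. LM-PCR captures the 3′-LTR/host junction: sheared
DNA is linker-ligated and amplified with one LTR primer and one linker
primer, so read 1 starts inside the LTR, runs through the terminal hexamer
(`CCTACA`/`CCTTCA`) and continues into host DNA.

`hervtrace` is for researchers who need this analysis as tested, reusable
code: it filters read triples on per-position index-read quality
(Phred > 20, strict), trims at the terminal hexamer, maps the host segment
with a deterministic unique-best ungapped k-mer mapper, deduplicates to
molecules keyed by (junction, strand, fragment length), calls sites,
verifies the retrotransposition hallmarks (TSD length, U3-vs-CMV 5′
junction, reporter-intron removal), estimates clone copy numbers, and
classifies loci across samples. A full LM-PCR **simulator** with planted
ground truth makes every stage verifiable end to end.

## The statistics at the core

* **Junction coordinate**: `junction_pos_1based` is the first host base 3′
  of the LTR terminus (provirus orientation); plus-strand proviruses map
  forward from it, minus-strand map reverse ending at it.
* **TSD**: for upstream flank *U* and downstream flank *D*,
  `tsdLength(U, D)` = max { L ≤ 10 : suffix(U, L) = prefix(D, L) }.
* **Clone copy number** of a site = |{ fragment lengths of its molecules }|
  — sister clones shear at different positions, so distinct amplicon
  lengths count clones; collisions only merge, so the estimate is a lower
  bound, exact under collision-free shearing.
* **Relative abundance** of site *i* in a sample = cᵢ / Σⱼ cⱼ, with
  reference and nonreference sites both in the denominator.
* **Classification**: a locus is *reference* if present in the designated
  reference group; *nonreference-universal* if absent there but present in
  every focal sample; *nonreference-specific* if present in all samples of
  exactly one focal group and nowhere else; *excluded* if flagged
  `indel_suspect` (modal-junction read support < 0.8) or `nonunique_flank`
  (50-bp junction flank not unique under exact both-strand search).

## Worked example

```r
library(hervtrace)

co <- simulateCohort(1, chrom_lengths = c(chr1 = 6000L, chr2 = 6000L),
                     n_reference = 2L, n_universal = 1L, n_specific = 1L,
                     copy_reference = c(5L, 8L), copy_universal = c(4L, 6L),
                     copy_specific = c(3L, 4L))
co$library
#> LmpcrLibrary with 69 read triples, 9 planted insertions
#>   samples: control, lineA, lineB
#>   read length: 100 bp; fragment lengths: 165 - 589 bp

res <- runPipeline(co$library, co$genome, groups = co$groups,
                   reference_group = co$reference_group)
res$matrix
#> SiteMatrix: 4 loci x 3 samples
#>   samples: control, lineA, lineB
#>   categories: reference=2, nonreference_universal=1,
#>               nonreference_specific=1, nonreference_partial=0, excluded=0
```

Four planted loci come back as four called loci: the two insertions shared
with the control are classified `reference`, the one shared by the two
derived lines only is `nonreference_universal`, and the lineB-only
insertion is `nonreference_specific`. Per-site detail:

```r
data.frame(sample = mcols(res$sites)$sample_id,
           site = paste0(seqnames(res$sites), ":", start(res$sites),
                         strand(res$sites)),
           molecules = mcols(res$sites)$n_molecules,
           copies = mcols(res$sites)$copy_number,
           rel = round(mcols(res$sites)$rel_abundance, 3))
#>   sample       site molecules copies   rel
#>  control chr1:2877+         5      5 0.385
#>  control chr2:4712+         8      8 0.615
#>    lineA chr1:2877+         7      7 0.368
#>    lineA chr2:2401-         6      6 0.316
#>    lineA chr2:4712+         6      6 0.316
#>    lineB  chr1:727-         4      4 0.174
#>    lineB chr1:2877+         7      7 0.304
#>    lineB chr2:2401-         5      5 0.217
#>    lineB chr2:4712+         7      7 0.304
```

Each called junction equals its planted coordinate and strand; `copies`
equals the planted clone count (all shear lengths here happen to be
distinct), and `rel` sums to 1 within each sample.

The package also ships, under `inst/extdata/`, presence/absence tables of
published nonreference HERV-K loci from two cohorts (HeLa/HeLa-inBLC and
fibroblast/iPSC) plus a known polymorphic-insertion list (K113, K20, K22);
`readSiteTable()` + `classifySites()` + `matchKnown()` reproduce their
universal/specific blocks and footnote matches — see
`tests/testthat/test-acceptance.R`.

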