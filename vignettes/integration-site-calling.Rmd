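---
title: "Calling HERV-K integration sites from LM-PCR junction libraries"
author: "hervtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling HERV-K integration sites from LM-PCR junction libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hervtrace)
```

## The problem

HERV-K is the youngest human endogenous retrovirus family. Its proviruses
are flanked by two long terminal repeats (LTRs), and a completed
retrotransposition cycle leaves two diagnostic scars in the genome: a 5-6 bp
target-site duplication (TSD) created by integrase, and a 5' LTR whose U3
region was regenerated by reverse transcription (so an engineered donor
whose 5' U3 was replaced by a CMV promoter yields integrants carrying U3,
not CMV, at the 5' junction). Ligation-mediated PCR (LM-PCR) captures the
junction between the 3' LTR and host DNA: genomic DNA is sheared by
sonication, linker-ligated, and amplified with one primer in the 3' LTR and
one in the linker, so read 1 of each pair starts inside the LTR, runs
through its terminal hexamer (`CCTACA` or `CCTTCA`) and continues into host
sequence. The host coordinate where the LTR ends is the integration site.

`hervtrace` implements this workflow end to end — demultiplex-quality
gating, junction detection, mapping, deduplication, site calling, hallmark
verification, clonality estimation, and cross-sample classification —
together with a simulator that plants proviruses with known truth so every
stage is testable without external data.

## Pipeline model and assumptions

1. **Index-read gate.** A read triple survives only if *every* position of
   its 8-bp index read has Phred > `min_phred` (default 20). The published
   wording is an inequality ("Phred score of >20"), and we implement it
   strictly: a position at exactly 20 is rejected. This is the conservative
   reading and is pinned by a boundary test.
2. **Junction detection.** R1 is searched for an exact occurrence of a
   terminal hexamer; the *last* occurrence ending within `search_window`
   bases of the read start wins, guarding against the hexamer arising
   earlier inside the LTR tail. No mismatches are tolerated in the motif:
   the original assay's nested primers already guarantee LTR origin, and
   exact matching keeps the behaviour auditable. Everything after the motif
   is the host segment; segments shorter than `min_host_len` (20 bp) are
   rejected. `runPipeline()` defaults `search_window` to the library's LTR
   tail length: with the motif position fixed by primer design, a wider
   window would only admit chance hexamer hits in host sequence, which
   would shift the inferred junction.
3. **Mapping.** A deterministic seed-and-extend mapper over a both-strand
   k-mer index (k = 15): candidates are all placements of the exact first
   k-mer, extended without gaps, keeping placements with at most
   `max_mismatch` (2) substitutions. A read is `unique` iff exactly one
   placement attains the minimal mismatch count, `multi` on ties,
   `unmapped` otherwise; candidates are ordered by chromosome then offset
   so tie-breaking is reproducible. Ungapped alignment is sufficient
   because the simulator's error model is substitution-only; wrapping an
   external aligner is out of scope by design, and the mapper is checked
   against an exhaustive Biostrings mismatch scan.
4. **Coordinate convention.** `junction_pos_1based` is the 1-based
   reference coordinate of the first host base 3' of the LTR terminus, in
   provirus orientation: a plus-strand provirus maps forward starting at
   the junction; a minus-strand provirus maps reverse ending at it. BED
   export converts to 0-based half-open.
5. **Deduplication.** Reads identical in (sample, chromosome, junction,
   strand, fragment length) are PCR duplicates of one molecule. The dedup
   key includes the fragment length deliberately: length-distinct amplicons
   are the abundance unit (below), so collapsing on coordinate alone would
   destroy the copy-number signal. Only uniquely mapped reads enter.
6. **Site calling.** Molecules on one chromosome/strand within
   `cluster_window` (5 bp, single linkage) form a site at the modal
   junction (ties to the smallest coordinate).
7. **QC.** Sites where fewer than `min_modal_fraction` (0.8) of reads agree
   on the modal junction are flagged `indel_suspect`; sites whose 50-bp
   junction flank is not found exactly once in the genome (both strands,
   exact search) are flagged `nonunique_flank`. Both are retained for
   reporting but excluded from classification. The modal-fraction rule is
   an explicit proxy: the original study excluded junctions "with
   deletions or insertions" without stating its criterion, so we chose an
   auditable read-support statistic instead of guessing an alignment
   heuristic.
8. **Clonality.** Sister clones shear at different positions, so the
   number of distinct fragment lengths at a site estimates its clone copy
   number; collisions can only merge lengths, so the estimate is a lower
   bound that is exact when shear lengths are distinct. Relative abundance
   is each site's copy number over the sample's total (reference and
   nonreference sites both in the denominator; the total is per sample,
   not summed across passages). No statistical collision correction is
   applied — plain counting is the published procedure — but
   `siteAbundance(correction=)` provides a hook.
9. **Classification.** Loci are merged across samples within
   `merge_window` (10 bp) and partitioned: `reference` (present in the
   designated reference group), `nonreference_universal` (absent there,
   present in every focal sample), `nonreference_specific` (present in all
   samples of exactly one focal group and nowhere else), `excluded`
   (flagged). Loci present in only part of a group fall back to
   `nonreference_partial`, keeping the partition total. Known-insertion
   matching uses a 100-bp coordinate window, or cytoband-label equality
   for entries without coordinates — "almost identical" coordinates in the
   literature are not quantified, so both windows are configurable.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_phred` | 20 (exclusive) | Phred | published index-quality gate |
| `motifs` | CCTACA, CCTTCA | — | 3'-LTR terminal hexamers of the family |
| `search_window` | LTR tail length | bp | motif position fixed by primer geometry |
| `min_host_len` | 20 | bp | shorter segments seed unreliably (> k) |
| `k` | 15 | bp | unique in a multi-megabase toy genome, robust at 150 kb |
| `max_mismatch` | 2 | subst. | matches the simulator's error scale |
| `cluster_window` | 5 | bp | junctions of one site agree exactly in this model; 5 bp absorbs rare artefacts |
| `min_modal_fraction` | 0.8 | fraction | indel-suspect proxy (see above) |
| `flank_len` | 50 | bp | long enough to be genome-unique, short enough to survive shear |
| `merge_window` | 10 | bp | cross-sample jitter allowance |
| known-match `window` | 100 | bp | unquantified "almost identical" coordinates |

## What the simulator emulates

`simulateLibrary()` plants a compact surrogate provirus (circa 330-390 bp)
with labelled U3/R/U5 segments and an antisense reporter cassette whose
intron is present on the donor plasmid and spliced out after one
retrotransposition cycle. For each insertion it draws one shear length per
clone copy (uniform on 150-600 bp — the real shear profile is not
published, so this is a convention, configurable), builds the amplicon
(LTR tail + host flank to the shear point), and emits R1 from the LTR end,
R2 from the linker end, and an 8-bp index read with a configurable
per-position quality profile (constant Phred 35 by default, so the quality
gate can be exercised explicitly). Substitution errors and PCR duplicates
are applied at configurable rates. Reads are constructed from the
reference flanks at each junction, which is identical to reading the
planted chromosome because the TSD places the same host bases on both
sides of the provirus.

`simulateCohort()` fixes the study conditions used throughout the tests
and the acceptance script: a toy genome of three 50-kb chromosomes; three
samples (a control plus two derived lines); 8 reference loci present in
all samples at 200-300 clone copies, 6 shared nonreference loci in the two
derived lines at 50-80 copies, and 4 specific loci in one line at 5-15
copies, one of them simulated as a direct plasmid integration (CMV 5'
junction, intron retained); TSDs drawn from {5, 6} bp on both strands; PCR
duplicate rate 0.25. This yields roughly 8-9 thousand read triples and
runs in about a minute on one CPU — the scale at which exact,
deterministic verification of every stage is still practical.

Planted positions are rejection-sampled so that loci are at least 2 kb
apart, the TSD is recoverable exactly from the flanks (no chance extension
of the duplicated motif into adjacent host bases), and the first 40 bp of
host sequence past each junction are hexamer-free. The last two conditions
make the planted truth unambiguous: without them a read could be trimmed
at a chance motif or the TSD call could legitimately exceed the planted
length, which are properties of the locus, not errors of the pipeline.

**What the simulator does not model** — and hence what passing tests do
not demonstrate about real data: indel sequencing errors (the mapper is
ungapped by design), base-quality miscalibration, chimeric or
linker-readthrough artefacts, repetitive-element landscapes of a real
genome (the uniqueness filter is exercised only on planted repeats), GC
bias in shearing or PCR, and barcode hopping. The TSD computation needs
both junctions; for 3'-only real data `tsd_len` would remain unset rather
than guessed from one flank.

## Numerical and degenerate-input choices

Ties in the modal junction break to the smallest coordinate; mapper
candidate order is lexicographic (chromosome, offset, strand); empty
inputs return empty, typed results (filters, `callSites`,
`buildSiteMatrix`) while meaningless requests (empty `copyNumber`, zero
abundance denominator, provirus without the reporter cassette) raise
errors. Flanks running off a chromosome end are truncated with a warning.
Malformed index reads are rejected per read with a warning, never a crash.
`tsdLength` compares over the available length when a flank is shorter
than `max_len`. All simulation entry points take a single integer seed and
are fully deterministic in it.

## Worked example

```{r example, eval = FALSE}
co <- simulateCohort(1)
res <- runPipeline(co$library, co$genome,
                   groups = co$groups,
                   reference_group = co$reference_group)
res$matrix
table(siteCategories(res$matrix))
```

On the default study conditions this recovers every planted junction at
its exact coordinate and strand with no false positives, classifies the
loci back into their planted reference/universal/specific classes, and
returns per-sample relative abundances summing to one. The same
computation, plus the published-table classification, is what
`scripts/acceptance.R` re-runs and reports.

## Known limitations

* The mapper is a self-contained toy: ungapped, substitution-only, exact
  seed. It is the right instrument for this simulator, and is
  oracle-checked, but it is not a replacement for a production aligner on
  real reads.
* Copy numbers saturate when clone counts approach the number of distinct
  shear lengths (451 by default); the estimate remains a valid lower
  bound.
* Reference status is operational (presence in a designated control group
  or supplied list); the package ships no human insertion catalogue.
* Cytoband labels are matched as opaque strings; no coordinate-to-band
  computation is attempted.
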