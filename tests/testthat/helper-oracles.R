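# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the package's own code paths.

# exhaustive both-strand mismatch scan via Biostrings; returns all
# placements with <= max_mm substitutions and the unique-best verdict
oracleMap <- function(genome, read, max_mm = 2L) {
  hits <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") Biostrings::DNAString(read)
             else Biostrings::reverseComplement(Biostrings::DNAString(read))
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm)
      if (length(m)) {
        mm <- Biostrings::neditStartingAt(pat, subj,
                                          starting.at = Biostrings::start(m),
                                          with.indels = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start0 = Biostrings::start(m) - 1L,
          strand = strand, mm = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(list(uniqueness = "unmapped", best = NULL))
  all <- do.call(rbind, hits)
  best_mm <- min(all$mm)
  best <- all[all$mm == best_mm, , drop = FALSE]
  best <- best[order(best$chrom, best$start0, best$strand), , drop = FALSE]
  list(uniqueness = if (nrow(best) == 1L) "unique" else "multi",
       best = best, all = all)
}

# brute-force TSD oracle: try every overlap length directly
oracleTsd <- function(up, down, max_len = 10L) {
  best <- 0L
  for (L in seq_len(min(max_len, nchar(up), nchar(down)))) {
    if (substr(up, nchar(up) - L + 1L, nchar(up)) == substr(down, 1L, L))
      best <- L
  }
  best
}

rcChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# minimal read-triple table for filter/trim unit tests
makeReadRows <- function(r1, index_qual, read_id = NULL,
                         fragment_length = NA_integer_) {
  n <- length(r1)
  S4Vectors::DataFrame(
    read_id = if (is.null(read_id)) sprintf("r%03d", seq_len(n)) else read_id,
    sample_id = rep_len("s1", n),
    r1_seq = r1, r1_qual = strrep("I", nchar(r1)),
    r2_seq = r1, r2_qual = strrep("I", nchar(r1)),
    index_seq = strrep("A", nchar(index_qual)),
    index_qual = index_qual,
    fragment_length = rep_len(fragment_length, n))
}

phredStr <- function(scores) intToUtf8(scores + 33L, multiple = FALSE)

# molecule table builder for site-calling/clonality unit tests
makeMolecules <- function(chrom, junction, strand, fragment_length,
                          n_reads = 1L, sample_id = "s1") {
  n <- max(length(chrom), length(junction), length(strand),
           length(fragment_length))
  S4Vectors::DataFrame(
    sample_id = rep_len(sample_id, n),
    chrom = rep_len(chrom, n),
    junction_pos_1based = as.integer(rep_len(junction, n)),
    strand = rep_len(strand, n),
    fragment_length = as.integer(rep_len(fragment_length, n)),
    n_reads = as.integer(rep_len(n_reads, n)),
    read_ids = sprintf("m%03d", seq_len(n)))
}

# a small cohort shared by several heavier tests (cached per session)
smallCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateCohort(
        101, chrom_lengths = c(chr1 = 6000L, chr2 = 6000L),
        n_reference = 2L, n_universal = 1L, n_specific = 1L,
        copy_reference = c(5L, 8L), copy_universal = c(4L, 6L),
        copy_specific = c(3L, 4L))
    cache
  }
})
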