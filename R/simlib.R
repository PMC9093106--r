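#' Generate a random toy reference genome
#'
#' Builds a deterministic toy genome used as the mapping reference. The base
#' composition is uniform over A/C/G/T and homopolymer runs are capped at 30
#' bp so the k-mer index stays well conditioned.
#'
#' @param seed integer seed; the same seed always yields the same genome.
#' @param chrom_lengths named integer vector of chromosome lengths in bp
#'   (each at least 1000).
#' @return a named \code{DNAStringSet}, one entry per chromosome.
#' @examples
#' g <- makeReference(1, c(chr1 = 10000))
#' width(g)
#' @export
makeReference <- function(seed, chrom_lengths) {
  if (length(chrom_lengths) == 0L)
    stop("chrom_lengths must name at least one chromosome")
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)) ||
      any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must have unique non-empty names")
  chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  if (any(is.na(chrom_lengths)) || any(chrom_lengths < 1000L))
    stop("chromosome lengths must be >= 1000 bp")
  seqs <- .withSeed(seed, {
    vapply(chrom_lengths, function(n) {
      repeat {
        s <- .randomDna(n)
        runs <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
        if (max(runs$lengths) <= 30L) return(s)
      }
    }, character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(chrom_lengths)
  out
}

# Fixed segment sequences of the surrogate reporter provirus. The construct
# mirrors the LM-PCR reporter design: a 5' promoter (native U3 after
# retrotransposition, CMV when the plasmid integrated directly), R and U5
# regions, a gag stub, and an antisense reporter cassette whose intron is
# present on the plasmid and absent after one cycle of
# transcription/splicing/reintegration. All segments are hexamer-free except
# the U5 terminus, which carries the diagnostic CCTACA/CCTTCA.
.PROVIRAL_SEGMENTS <- c(
  u3    = "TGGGAAACCAGTCTGAGAACGCGTATTCACCGGTAGCATA",
  cmv   = "GTTGACATTGATTATTGACTAGTTATTAATAGTAATCAAT",
  r     = "GGGAACCGAGGCTAGCTACAACGA",
  u5    = "CATCTGTTGTGTGACTCTGGTAAC",       # terminal hexamer appended
  gag   = paste0("ATGGGACAAACTAAGTCAAAGATTAAGAGCAAGTATGCTTCATACTTGAGCTT",
                 "TATTAAGATTCTGCTGAAGCGAGGAGGA"),
  exon1 = "ATGGCCAAGCCTTTGTCTCAAGAAGAATCC",
  intron = paste0("GTAAGTATCAAGGTTACAAGACAGGTTTAAGGAGACCAATAGAAACTGGGC",
                  "TTGTCGAGAG"),
  exon2 = "ACCGTATTGCAGCAGCATAGGGATGGCAAG"
)

#' Segment sequences of the surrogate reporter provirus
#'
#' Returns the fixed DNA segments from which \code{\link{assembleProvirus}}
#' builds the surrogate provirus: the U3 and CMV promoter tags, the R and U5
#' LTR regions, a gag stub, and the reporter cassette (two exons separated by
#' an intron carried in antisense orientation on the donor construct).
#'
#' @return named character vector of DNA strings.
#' @export
proviralSegments <- function() .PROVIRAL_SEGMENTS

#' Assemble a surrogate provirus sequence
#'
#' Builds a compact (circa 330-390 bp) stand-in for a full provirus with labelled
#' U3/R/U5 LTRs and a reporter cassette. Retrotransposed copies carry U3 at
#' the 5' junction because reverse transcription regenerates U3 from the 3'
#' LTR; copies arising from direct plasmid integration retain the CMV
#' promoter instead. The 3' LTR always terminates in the diagnostic hexamer.
#'
#' @param promoter5 \code{"U3"} (retrotransposed) or \code{"CMV"}
#'   (plasmid-derived) 5' junction sequence.
#' @param intron_present logical; \code{TRUE} keeps the reporter intron (as on
#'   the transfected plasmid), \code{FALSE} yields the spliced form expected
#'   after one retrotransposition cycle.
#' @param terminal_hexamer terminal 3'-LTR hexamer, \code{"CCTACA"} or
#'   \code{"CCTTCA"}.
#' @param segments named character vector of segment sequences
#'   (default \code{\link{proviralSegments}()}).
#' @return a single DNA character string ending in \code{terminal_hexamer}.
#' @examples
#' nchar(assembleProvirus("U3", intron_present = FALSE))
#' @export
assembleProvirus <- function(promoter5 = c("U3", "CMV"),
                             intron_present = TRUE,
                             terminal_hexamer = c("CCTACA", "CCTTCA"),
                             segments = proviralSegments()) {
  promoter5 <- match.arg(promoter5)
  terminal_hexamer <- match.arg(terminal_hexamer)
  u5 <- paste0(segments[["u5"]], terminal_hexamer)
  ltr5_promoter <- if (promoter5 == "U3") segments[["u3"]] else segments[["cmv"]]
  reporter <- paste0(segments[["exon1"]],
                     if (intron_present) segments[["intron"]] else "",
                     segments[["exon2"]])
  paste0(ltr5_promoter, segments[["r"]], u5,     # 5' LTR
         segments[["gag"]], reporter,
         segments[["u3"]], segments[["r"]], u5)  # 3' LTR
}

# default R1 prefix: the distal end of the 3' LTR, ending in the hexamer
.defaultLtrTail <- function(terminal_hexamer = "CCTACA",
                            segments = proviralSegments()) {
  paste0(segments[["u5"]], terminal_hexamer)
}

.validateSpec <- function(spec, genome) {
  need <- c("chrom", "position", "strand", "tsd_len", "copy_count")
  miss <- setdiff(need, names(spec))
  if (length(miss))
    stop("insertion spec is missing fields: ", paste(miss, collapse = ", "))
  if (!spec$chrom %in% names(genome))
    stop("spec chromosome '", spec$chrom, "' not in genome")
  chrlen <- nchar(.chromSeq(genome, spec$chrom))
  if (spec$tsd_len < 0L) stop("tsd_len must be >= 0")
  if (spec$position < 0L || spec$position + spec$tsd_len > chrlen)
    stop("position out of range for chromosome ", spec$chrom)
  if (!spec$strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (spec$copy_count < 1L) stop("copy_count must be >= 1")
  invisible(spec)
}

#' Plant a provirus into a host chromosome with a target-site duplication
#'
#' Models the retroviral integrase mechanism: the \code{tsd_len} host bases at
#' the integration point are duplicated so that they flank the provirus on
#' both sides. A minus-strand insertion places the reverse complement of the
#' provirus. The returned truth record carries the junction coordinate under
#' the package-wide convention: \code{junction_pos_1based} is the 1-based
#' reference coordinate of the first host base 3' of the LTR terminus, read in
#' provirus orientation (plus-strand insertions read forward from the
#' junction; minus-strand insertions read reverse, ending at it).
#'
#' @param genome reference \code{DNAStringSet}.
#' @param spec a list or one-row data.frame with fields \code{chrom},
#'   \code{position} (0-based host offset), \code{strand}, \code{tsd_len},
#'   \code{copy_count}, and optionally \code{sample_id}, \code{promoter5},
#'   \code{intron_present}.
#' @param provirus_seq provirus DNA string; must end in its 3'-LTR terminal
#'   hexamer (\code{CCTACA} or \code{CCTTCA}).
#' @return list with \code{sequence} (the planted chromosome as a
#'   \code{DNAString}) and \code{truth} (one-row \code{DataFrame} with the
#'   spec fields plus \code{junction_pos_1based}).
#' @examples
#' g <- makeReference(1, c(chr1 = 2000))
#' prov <- assembleProvirus("U3", intron_present = FALSE)
#' res <- plantProvirus(g, list(chrom = "chr1", position = 1000L,
#'                              strand = "+", tsd_len = 6L, copy_count = 1L),
#'                      prov)
#' res$truth$junction_pos_1based
#' @export
plantProvirus <- function(genome, spec, provirus_seq) {
  spec <- as.list(spec)
  .validateSpec(spec, genome)
  .assertDna(provirus_seq, "provirus_seq")
  if (!grepl("(CCTACA|CCTTCA)$", provirus_seq))
    stop("provirus_seq must end in its 3'-LTR terminal hexamer")
  host <- .chromSeq(genome, spec$chrom)
  p <- as.integer(spec$position)
  t <- as.integer(spec$tsd_len)
  insert <- if (spec$strand == "+") provirus_seq else .revcomp(provirus_seq)
  left <- substr(host, 1L, p + t)         # host[0 : p+t)
  right <- substr(host, p + 1L, nchar(host))  # host[p : )
  planted <- paste0(left, insert, right)
  junction <- if (spec$strand == "+") p + 1L else p + t
  truth <- S4Vectors::DataFrame(
    sample_id = if (is.null(spec$sample_id)) NA_character_ else spec$sample_id,
    chrom = spec$chrom,
    position = p,
    strand = spec$strand,
    tsd_len = t,
    promoter5 = if (is.null(spec$promoter5)) "U3" else spec$promoter5,
    intron_present = if (is.null(spec$intron_present)) FALSE
                     else spec$intron_present,
    copy_count = as.integer(spec$copy_count),
    junction_pos_1based = as.integer(junction)
  )
  list(sequence = Biostrings::DNAString(planted), truth = truth)
}

#' LM-PCR library simulation parameters
#'
#' @param read_len read length in bp for R1 and R2.
#' @param index_len index-read length (8, per the assay design).
#' @param ltr_tail DNA string forming the start of every R1 (the distal end of
#'   the 3' LTR, ending in CCTACA or CCTTCA), or \code{NULL} to derive it per
#'   insertion from the provirus (sampling both hexamer variants).
#' @param linker_seq ligated linker sequence (assay metadata; linker bases are
#'   not emitted into reads).
#' @param primer_3ltr_outer,primer_3ltr_inner nested LTR primer sequences used
#'   by the assay (metadata only).
#' @param subst_error_rate per-base substitution error probability on R1/R2.
#' @param pcr_dup_rate probability that a molecule is emitted twice
#'   (identical sequence and fragment length).
#' @param shear_range integer length-2 vector; sonication fragment lengths are
#'   drawn uniformly from this range (bp).
#' @param molecules_per_copy sequenced template molecules per clone copy.
#' @param index_qual integer Phred scores, one per index-read position.
#' @param seed integer seed for the simulation stream, or \code{NULL}.
#' @return a validated parameter list.
#' @export
libraryParams <- function(read_len = 100L,
                          index_len = 8L,
                          ltr_tail = NULL,
                          linker_seq = "GTAATACGACTCACTATAGGGC",
                          primer_3ltr_outer = "CCTCCATATGCTGAACGCTGGTT",
                          primer_3ltr_inner = paste0(
                            "AATGATACGGCGACCACCGAGATCTACACCCAAATCTCTCGTCC",
                            "CACCTTACGAGAAACACCCACAGG"),
                          subst_error_rate = 0,
                          pcr_dup_rate = 0,
                          shear_range = c(150L, 600L),
                          molecules_per_copy = 1L,
                          index_qual = rep(35L, 8L),
                          seed = NULL) {
  if (read_len < 30L) stop("read_len must be >= 30 bp")
  if (index_len != length(index_qual))
    stop("index_qual must have one Phred score per index position")
  if (subst_error_rate < 0 || subst_error_rate > 1 ||
      pcr_dup_rate < 0 || pcr_dup_rate > 1)
    stop("rates must lie in [0, 1]")
  shear_range <- as.integer(shear_range)
  if (length(shear_range) != 2L || shear_range[1] > shear_range[2])
    stop("shear_range must be an increasing length-2 integer vector")
  if (read_len > shear_range[1])
    stop("read_len exceeds the shortest fragment length; reads would run ",
         "past the shear point")
  if (!is.null(ltr_tail)) {
    .assertDna(ltr_tail, "ltr_tail")
    if (!grepl("(CCTACA|CCTTCA)$", ltr_tail))
      stop("ltr_tail must end in CCTACA or CCTTCA")
  }
  list(read_len = as.integer(read_len), index_len = as.integer(index_len),
       ltr_tail = ltr_tail, linker_seq = linker_seq,
       primer_3ltr_outer = primer_3ltr_outer,
       primer_3ltr_inner = primer_3ltr_inner,
       subst_error_rate = subst_error_rate, pcr_dup_rate = pcr_dup_rate,
       shear_range = shear_range,
       molecules_per_copy = as.integer(molecules_per_copy),
       index_qual = as.integer(index_qual), seed = seed)
}

.addSubstErrors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  nch <- nchar(seqs)
  nerr <- rbinom(length(seqs), nch, rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(nch[i], nerr[i])
    for (p in pos) chars[p] <- sample(setdiff(.DNA_BASES, chars[p]), 1L)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

# 5'-junction sequence (provirus orientation): 20 bp of host immediately
# upstream of the provirus followed by the first 80 bp of the provirus.
.junction5 <- function(host, p, t, strand, provirus, flank = 20L) {
  up <- if (strand == "+") {
    substr(host, p + t - flank + 1L, p + t)
  } else {
    .revcomp(substr(host, p + 1L, p + flank))
  }
  list(upstream_flank = up,
       junction5_seq = paste0(up, substr(provirus, 1L, 80L)))
}

# host flank 3' of the LTR terminus in provirus orientation, n bases
.hostFlank3 <- function(host, junction, strand, n) {
  if (strand == "+") {
    if (junction + n - 1L > nchar(host))
      stop("fragment runs past the chromosome end")
    substr(host, junction, junction + n - 1L)
  } else {
    if (junction - n < 0L)
      stop("fragment runs past the chromosome start")
    .revcomp(substr(host, junction - n + 1L, junction))
  }
}

#' Simulate an LM-PCR sequencing library
#'
#' For every insertion spec, draws one sonication shear length per sequenced
#' molecule (uniform over \code{shear_range}), forms the amplicon fragment
#' (LTR tail followed by host DNA up to the shear point), and emits a read
#' triple: R1 starts in the 3' LTR, runs through the terminal hexamer into
#' host DNA; R2 reads inward from the linker-proximal (shear) end; the index
#' read carries the per-sample barcode with the configured quality profile.
#' Substitution errors and PCR duplicates are applied at the configured
#' rates. Reads are generated from the reference flanks around each junction,
#' which is equivalent to reading the planted chromosome because the
#' target-site duplication places identical host bases on both sides.
#'
#' @param genome reference \code{DNAStringSet}.
#' @param specs data.frame/DataFrame of insertion specs, one row per planted
#'   insertion per sample: \code{sample_id}, \code{chrom}, \code{position}
#'   (0-based), \code{strand}, \code{tsd_len}, \code{promoter5},
#'   \code{intron_present}, \code{copy_count}.
#' @param params list from \code{\link{libraryParams}}.
#' @return an \code{\linkS4class{LmpcrLibrary}}.
#' @export
simulateLibrary <- function(genome, specs, params = libraryParams()) {
  specs <- as.data.frame(specs)
  if (!nrow(specs)) stop("specs must contain at least one insertion")
  if (is.null(specs$sample_id)) specs$sample_id <- "sample1"
  if (is.null(specs$promoter5)) specs$promoter5 <- "U3"
  if (is.null(specs$intron_present)) specs$intron_present <- FALSE
  for (i in seq_len(nrow(specs))) .validateSpec(as.list(specs[i, ]), genome)

  .withSeed(params$seed, {
    samples <- unique(specs$sample_id)
    barcodes <- setNames(
      vapply(seq_along(samples), function(i) .randomDna(params$index_len),
             character(1)),
      samples)
    iq <- .phredString(params$index_qual)

    read_rows <- vector("list", nrow(specs))
    truth_rows <- vector("list", nrow(specs))
    for (i in seq_len(nrow(specs))) {
      sp <- as.list(specs[i, ])
      hexamer <- if (is.null(params$ltr_tail)) {
        sample(c("CCTACA", "CCTTCA"), 1L)
      } else {
        substr(params$ltr_tail, nchar(params$ltr_tail) - 5L,
               nchar(params$ltr_tail))
      }
      prov <- assembleProvirus(sp$promoter5, sp$intron_present, hexamer)
      tail <- if (is.null(params$ltr_tail)) .defaultLtrTail(hexamer)
              else params$ltr_tail
      tail_len <- nchar(tail)
      host <- .chromSeq(genome, sp$chrom)
      junction <- if (sp$strand == "+") sp$position + 1L
                  else sp$position + sp$tsd_len

      n_mol <- sp$copy_count * params$molecules_per_copy
      shear <- sample(seq(params$shear_range[1], params$shear_range[2]),
                      n_mol, replace = TRUE)
      host_len <- pmax(shear - tail_len, 1L)
      frag <- vapply(host_len, function(n)
        paste0(tail, .hostFlank3(host, junction, sp$strand, n)), character(1))
      r1 <- substr(frag, 1L, params$read_len)
      r2 <- substr(.revcomp(frag), 1L, params$read_len)
      r1 <- .addSubstErrors(r1, params$subst_error_rate)
      r2 <- .addSubstErrors(r2, params$subst_error_rate)

      ids <- sprintf("%s_s%03d_m%05d", sp$sample_id, i, seq_len(n_mol))
      df <- data.frame(
        read_id = ids, sample_id = sp$sample_id,
        r1_seq = r1, r1_qual = strrep(.phredString(35L), nchar(r1)),
        r2_seq = r2, r2_qual = strrep(.phredString(35L), nchar(r2)),
        index_seq = barcodes[[sp$sample_id]], index_qual = iq,
        fragment_length = shear,
        stringsAsFactors = FALSE)
      dup <- runif(n_mol) < params$pcr_dup_rate
      if (any(dup)) {
        ddf <- df[dup, , drop = FALSE]
        ddf$read_id <- paste0(ddf$read_id, "_dup")
        df <- rbind(df, ddf)
      }
      read_rows[[i]] <- df

      j5 <- .junction5(host, sp$position, sp$tsd_len, sp$strand, prov)
      truth_rows[[i]] <- data.frame(
        sample_id = sp$sample_id, chrom = sp$chrom,
        position = as.integer(sp$position), strand = sp$strand,
        tsd_len = as.integer(sp$tsd_len), promoter5 = sp$promoter5,
        intron_present = sp$intron_present,
        copy_count = as.integer(sp$copy_count),
        junction_pos_1based = as.integer(junction),
        terminal_hexamer = hexamer,
        shear_lengths = paste(shear, collapse = ","),
        upstream_flank = j5$upstream_flank,
        junction5_seq = j5$junction5_seq,
        provirus_seq = prov,
        stringsAsFactors = FALSE)
    }
    reads <- S4Vectors::DataFrame(do.call(rbind, read_rows))
    truth <- S4Vectors::DataFrame(do.call(rbind, truth_rows))
    new("LmpcrLibrary", reads = reads, truth = truth, params = params)
  })
}

#' Write a simulated library to FASTQ files and a truth TSV
#'
#' Emits 4-line Phred+33 FASTQ (no /1 /2 read-id suffixes; the mate is
#' carried by file identity) for R1, R2 and the index read, plus a
#' tab-separated truth table.
#'
#' @param lib an \code{\linkS4class{LmpcrLibrary}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of written paths.
#' @export
writeLibrary <- function(lib, dir, prefix = "library") {
  stopifnot(is(lib, "LmpcrLibrary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rd <- libraryReads(lib)
  paths <- c(
    r1 = file.path(dir, paste0(prefix, "_R1.fastq")),
    r2 = file.path(dir, paste0(prefix, "_R2.fastq")),
    i1 = file.path(dir, paste0(prefix, "_I1.fastq")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  .writeFastq <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  .writeFastq(rd$r1_seq, rd$r1_qual, rd$read_id, paths[["r1"]])
  .writeFastq(rd$r2_seq, rd$r2_qual, rd$read_id, paths[["r2"]])
  .writeFastq(rd$index_seq, rd$index_qual, rd$read_id, paths[["i1"]])
  tr <- as.data.frame(libraryTruth(lib))
  write.table(
    tr[, c("sample_id", "chrom", "junction_pos_1based", "strand", "tsd_len",
           "promoter5", "intron_present", "copy_count")],
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read R1/R2/I1 FASTQ files back into a read table
#'
#' Companion reader for \code{\link{writeLibrary}} output (or any 4-line
#' Phred+33 FASTQ triple with matching read order).
#'
#' @param r1,r2,i1 FASTQ file paths.
#' @param sample_id sample label attached to every read.
#' @return a \code{DataFrame} in the \code{\link{libraryReads}} layout
#'   (without \code{fragment_length}, which is simulation geometry).
#' @export
readLibraryFastq <- function(r1, r2, i1, sample_id = "sample1") {
  rd1 <- Biostrings::readDNAStringSet(r1, format = "fastq",
                                      with.qualities = TRUE)
  rd2 <- Biostrings::readDNAStringSet(r2, format = "fastq",
                                      with.qualities = TRUE)
  rdi <- Biostrings::readDNAStringSet(i1, format = "fastq",
                                      with.qualities = TRUE)
  stopifnot(length(rd1) == length(rd2), length(rd1) == length(rdi))
  S4Vectors::DataFrame(
    read_id = names(rd1), sample_id = sample_id,
    r1_seq = unname(as.character(rd1)),
    r1_qual = unname(as.character(S4Vectors::mcols(rd1)$qualities)),
    r2_seq = unname(as.character(rd2)),
    r2_qual = unname(as.character(S4Vectors::mcols(rd2)$qualities)),
    index_seq = unname(as.character(rdi)),
    index_qual = unname(as.character(S4Vectors::mcols(rdi)$qualities)),
    fragment_length = NA_integer_)
}
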