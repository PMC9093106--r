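#' Simulate a multi-sample LM-PCR study with planted ground truth
#'
#' Generates a toy reference genome and a three-sample cohort emulating the
#' study design behind cross-sample integration-site comparisons: a control
#' sample whose insertions define the reference set, plus two derived
#' samples sharing additional nonreference insertions, one of which also
#' carries sample-specific insertions. Reference sites are present in every
#' cell and therefore at high clone copy number; shared nonreference sites
#' are intermediate; specific sites are recent, low-copy events. One
#' specific insertion is simulated as a direct plasmid integration (CMV 5'
#' junction, intron retained); all other insertions are retrotransposed (U3
#' 5' junction, intron spliced out).
#'
#' Planted positions are rejection-sampled so that (i) loci are at least 2 kb
#' apart, (ii) the target-site duplication is recoverable exactly from the
#' flanks (no chance extension of the duplicated motif into neighbouring
#' host bases), and (iii) the first 40 bp of host sequence past each
#' junction are free of the terminal hexamers, so a junction read cannot be
#' mis-trimmed at a chance motif.
#'
#' @param seed integer master seed; the whole cohort is deterministic in it.
#' @param chrom_lengths named chromosome lengths for the toy genome.
#' @param samples length-3 character vector: control sample first, then the
#'   two derived samples.
#' @param n_reference,n_universal,n_specific locus counts per planted class.
#' @param copy_reference,copy_universal,copy_specific integer ranges
#'   (length 2) from which per-sample clone copy counts are drawn.
#' @param params \code{\link{libraryParams}} list for the sequencing layer.
#' @return list with \code{genome}, \code{loci} (per-locus truth),
#'   \code{specs} (per sample-locus insertion specs), \code{library}
#'   (\code{\linkS4class{LmpcrLibrary}}), \code{groups},
#'   \code{reference_group}.
#' @export
simulateCohort <- function(seed,
                           chrom_lengths = c(chr1 = 50000L, chr2 = 50000L,
                                             chr3 = 50000L),
                           samples = c("control", "lineA", "lineB"),
                           n_reference = 8L, n_universal = 6L,
                           n_specific = 4L,
                           copy_reference = c(200L, 300L),
                           copy_universal = c(50L, 80L),
                           copy_specific = c(5L, 15L),
                           params = libraryParams(pcr_dup_rate = 0.25)) {
  stopifnot(length(samples) == 3L)
  genome <- makeReference(seed, chrom_lengths)
  .withSeed(seed, {
    margin <- max(params$shear_range) + 100L
    min_dist <- 2000L
    n_loci <- n_reference + n_universal + n_specific
    taken <- data.frame(chrom = character(0), pos = integer(0))
    loci <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      repeat {
        chrom <- sample(names(chrom_lengths), 1L)
        len <- chrom_lengths[[chrom]]
        p <- sample(seq(margin, len - margin), 1L)
        tsd <- sample(c(5L, 6L), 1L)
        strand <- sample(c("+", "-"), 1L)
        same <- taken$chrom == chrom
        if (any(same) && min(abs(taken$pos[same] - p)) < min_dist) next
        host <- .chromSeq(genome, chrom)
        junction <- if (strand == "+") p + 1L else p + tsd
        up <- if (strand == "+") substr(host, p + tsd - 19L, p + tsd)
              else .revcomp(substr(host, p + 1L, p + 20L))
        down <- junctionFlank(genome, chrom, junction, strand, 40L)
        if (tsdLength(up, substr(down, 1L, 20L)) != tsd) next
        if (grepl("CCTACA|CCTTCA", down)) next
        taken <- rbind(taken, data.frame(chrom = chrom, pos = p))
        loci[[i]] <- data.frame(
          locus_id = sprintf("locus%02d", i), chrom = chrom, position = p,
          strand = strand, tsd_len = tsd, junction_pos_1based = junction,
          stringsAsFactors = FALSE)
        break
      }
    }
    loci <- do.call(rbind, loci)
    loci$class <- rep(c("reference", "universal", "specific"),
                      c(n_reference, n_universal, n_specific))
    loci$promoter5 <- "U3"
    loci$intron_present <- FALSE
    if (n_specific > 0L) {
      # one plasmid-derived integration among the specific sites
      plasmid <- which(loci$class == "specific")[1L]
      loci$promoter5[plasmid] <- "CMV"
      loci$intron_present[plasmid] <- TRUE
    }

    sample_sets <- list(reference = samples,
                        universal = samples[2:3],
                        specific = samples[3])
    copy_range <- list(reference = copy_reference,
                       universal = copy_universal,
                       specific = copy_specific)
    spec_rows <- list()
    for (i in seq_len(nrow(loci))) {
      cls <- loci$class[i]
      for (s in sample_sets[[cls]]) {
        rng <- copy_range[[cls]]
        spec_rows[[length(spec_rows) + 1L]] <- data.frame(
          sample_id = s, locus_id = loci$locus_id[i],
          chrom = loci$chrom[i], position = loci$position[i],
          strand = loci$strand[i], tsd_len = loci$tsd_len[i],
          promoter5 = loci$promoter5[i],
          intron_present = loci$intron_present[i],
          copy_count = sample(seq(rng[1], rng[2]), 1L),
          stringsAsFactors = FALSE)
      }
    }
    specs <- do.call(rbind, spec_rows)
    lib <- simulateLibrary(genome, specs, params)
    groups <- setNames(as.list(samples), samples)
    list(genome = genome, loci = loci, specs = specs, library = lib,
         groups = groups, reference_group = samples[1L])
  })
}

#' Run the full integration-site pipeline on a library
#'
#' Chains the analysis stages: index-read quality gate, LTR terminal-hexamer
#' selection and trimming, unique-best ungapped mapping, molecule
#' deduplication, site calling, junction-integrity and flank-uniqueness QC,
#' distinct-amplicon clonality, and (when \code{groups} is supplied)
#' cross-sample classification.
#'
#' @param lib an \code{\linkS4class{LmpcrLibrary}} (or any object whose
#'   \code{\link{libraryReads}} layout matches).
#' @param genome reference \code{DNAStringSet}.
#' @param min_phred exclusive index-read Phred threshold.
#' @param motifs terminal hexamers searched in R1.
#' @param search_window motif search window; defaults to the library's LTR
#'   tail length, the geometry under which the motif position is known.
#' @param min_host_len minimum trimmed host-segment length.
#' @param k k-mer size of the mapper index.
#' @param max_mismatch mapper substitution tolerance.
#' @param cluster_window junction clustering window (bp).
#' @param min_molecules minimum molecules per called site.
#' @param min_modal_fraction junction-integrity threshold.
#' @param flank_len flank length for the uniqueness filter.
#' @param merge_window cross-sample locus merge window (bp).
#' @param groups,reference_group optional classification design (see
#'   \code{\link{classifySites}}).
#' @param index optional prebuilt \code{KmerIndex} to reuse.
#' @return list with \code{sites} (annotated \code{GRanges}),
#'   \code{molecules}, \code{matrix} (\code{\linkS4class{SiteMatrix}}),
#'   and \code{log} (per-stage counts).
#' @export
runPipeline <- function(lib, genome,
                        min_phred = 20L,
                        motifs = c("CCTACA", "CCTTCA"),
                        search_window = NULL,
                        min_host_len = 20L,
                        k = 15L, max_mismatch = 2L,
                        cluster_window = 5L, min_molecules = 1L,
                        min_modal_fraction = 0.8,
                        flank_len = 50L, merge_window = 10L,
                        groups = NULL, reference_group = NULL,
                        index = NULL) {
  reads <- libraryReads(lib)
  params <- simParams(lib)
  if (is.null(search_window)) {
    tail <- if (!is.null(params$ltr_tail)) params$ltr_tail
            else .defaultLtrTail()
    search_window <- nchar(tail)
  }
  kept <- indexQualityFilter(reads, min_phred)
  jr <- selectAndTrim(kept, motifs, search_window, min_host_len)
  if (is.null(index)) index <- buildKmerIndex(genome, k)
  aln <- mapJunctionReads(jr, index, max_mismatch)
  mols <- deduplicate(aln)
  sites <- callSites(mols, cluster_window, min_molecules)
  sites <- junctionIntegrity(sites, min_modal_fraction)
  if (length(sites)) {
    uniq <- uniquenessFilter(genome, sites, flank_len)
    flags <- S4Vectors::mcols(sites)$flags
    flags[!uniq] <- ifelse(nzchar(flags[!uniq]),
                           paste0(flags[!uniq], ";nonunique_flank"),
                           "nonunique_flank")
    S4Vectors::mcols(sites)$flags <- flags
    sites <- siteAbundance(sites, mols)
  }
  sample_ids <- unique(S4Vectors::mcols(sites)$sample_id)
  sites_by_sample <- setNames(
    lapply(sample_ids, function(s)
      sites[S4Vectors::mcols(sites)$sample_id == s]),
    sample_ids)
  mat <- if (length(sites_by_sample)) {
    buildSiteMatrix(sites_by_sample, merge_window)
  } else NULL
  if (!is.null(mat) && !is.null(groups))
    mat <- classifySites(mat, groups, reference_group)
  log <- list(
    n_input_reads = nrow(reads),
    n_after_index_filter = nrow(kept),
    n_index_discarded = attr(kept, "n_discarded"),
    trim_rejections = attr(jr, "rejections"),
    n_junction_reads = nrow(jr),
    uniqueness = table(aln$uniqueness),
    n_molecules = nrow(mols),
    n_sites = length(sites))
  list(sites = sites, molecules = mols, matrix = mat, log = log)
}
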