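#' Call integration sites from deduplicated molecules
#'
#' Molecules on the same chromosome and strand whose junctions lie within
#' \code{cluster_window} of each other (single-linkage chaining) collapse to
#' one site, reported at the modal junction position (the position carrying
#' the most reads; ties break to the smallest coordinate).
#' \code{modal_support_fraction} is the fraction of the site's reads at the
#' modal position and feeds \code{\link{junctionIntegrity}}.
#'
#' @param molecules \code{DataFrame} from \code{\link{deduplicate}} (a single
#'   sample, or carrying a \code{sample_id} column in which case samples are
#'   processed independently).
#' @param cluster_window junction clustering window in bp.
#' @param min_molecules sites supported by fewer molecules are dropped.
#' @return \code{GRanges} of width-1 junctions with metadata columns
#'   \code{sample_id}, \code{n_molecules}, \code{n_reads},
#'   \code{modal_support_fraction}, \code{flags} (empty string), and
#'   \code{revmap} (an \code{IntegerList} of supporting molecule rows in the
#'   input).
#' @export
callSites <- function(molecules, cluster_window = 5L, min_molecules = 1L) {
  m <- molecules
  empty <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
    sample_id = character(0), n_molecules = integer(0),
    n_reads = integer(0), modal_support_fraction = numeric(0),
    flags = character(0), revmap = IRanges::IntegerList())
  if (!nrow(m)) return(empty)
  sample_id <- if (is.null(m$sample_id)) rep(NA_character_, nrow(m))
               else m$sample_id
  strat <- paste(sample_id, m$chrom, m$strand, sep = "\r")
  cl <- .chainCluster(strat, rep("+", nrow(m)), m$junction_pos_1based,
                      cluster_window)
  groups <- split(seq_len(nrow(m)), cl)
  rows <- lapply(groups, function(ix) {
    reads_at <- tapply(m$n_reads[ix], m$junction_pos_1based[ix], sum)
    pos <- as.integer(names(reads_at))
    best <- max(reads_at)
    modal <- min(pos[reads_at == best])
    list(sample_id = sample_id[ix[1L]], chrom = m$chrom[ix[1L]],
         junction = modal, strand = m$strand[ix[1L]],
         n_molecules = length(ix), n_reads = sum(m$n_reads[ix]),
         msf = best / sum(m$n_reads[ix]), revmap = ix)
  })
  keep <- vapply(rows, function(r) r$n_molecules >= min_molecules, logical(1))
  rows <- rows[keep]
  if (!length(rows)) return(empty)
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(rows, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(start = vapply(rows, `[[`, 0L, "junction"),
                              width = 1L),
    strand = vapply(rows, `[[`, "", "strand"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    sample_id = unname(vapply(rows, `[[`, "", "sample_id")),
    n_molecules = unname(vapply(rows, `[[`, 0L, "n_molecules")),
    n_reads = unname(vapply(rows, `[[`, 0L, "n_reads")),
    modal_support_fraction = unname(vapply(rows, `[[`, 0, "msf")),
    flags = "",
    revmap = IRanges::IntegerList(unname(lapply(rows, `[[`, "revmap"))))
  ord <- order(S4Vectors::mcols(gr)$sample_id,
               as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  gr[ord]
}

#' Target-site duplication length from the two provirus flanks
#'
#' Integrase duplicates a short host motif (5-6 bp for HERV-K) on both sides
#' of the provirus. Given the host sequence immediately 5' of the provirus
#' (its suffix) and immediately 3' (its prefix), both in provirus
#' orientation, returns the largest \code{L <= max_len} for which the
#' upstream suffix equals the downstream prefix, or 0 when none matches.
#'
#' @param upstream_flank host DNA immediately 5' of the provirus.
#' @param downstream_flank host DNA immediately 3' of the provirus.
#' @param max_len longest duplication considered; when a flank is shorter the
#'   comparison is truncated with a warning.
#' @return integer duplication length.
#' @examples
#' tsdLength("TTTTGATCCA", "GATCCAAGTT")  # 6
#' @export
tsdLength <- function(upstream_flank, downstream_flank, max_len = 10L) {
  .assertDna(upstream_flank, "upstream_flank")
  .assertDna(downstream_flank, "downstream_flank")
  avail <- min(nchar(upstream_flank), nchar(downstream_flank))
  if (avail < max_len) {
    warning("flank shorter than max_len; comparing over ", avail, " bases")
    max_len <- avail
  }
  nu <- nchar(upstream_flank)
  for (L in seq(max_len, 1L)) {
    if (substr(upstream_flank, nu - L + 1L, nu) ==
        substr(downstream_flank, 1L, L))
      return(as.integer(L))
  }
  0L
}

#' Classify the 5' junction as U3 or CMV
#'
#' Reverse transcription regenerates U3 at the 5' LTR, so a U3 5' junction
#' evidences retrotransposition whereas a retained CMV promoter indicates
#' direct plasmid integration. The call is \code{"U3"} when the U3 tag is
#' found and the CMV tag is not, \code{"CMV"} for the converse, and
#' \code{"ambiguous"} when both or neither are found (e.g. a junction
#' truncated before any tag).
#'
#' @param five_prime_junction_seq DNA spanning the host/provirus 5' junction.
#' @param u3_tag,cmv_tag diagnostic tag sequences (defaults: the package's
#'   surrogate-provirus promoter segments).
#' @return \code{"U3"}, \code{"CMV"} or \code{"ambiguous"}.
#' @export
promoter5Check <- function(five_prime_junction_seq,
                           u3_tag = proviralSegments()[["u3"]],
                           cmv_tag = proviralSegments()[["cmv"]]) {
  .assertDna(five_prime_junction_seq, "five_prime_junction_seq")
  if (!nzchar(u3_tag) || !nzchar(cmv_tag) || u3_tag == cmv_tag)
    stop("u3_tag and cmv_tag must be non-empty and distinguishable")
  has_u3 <- grepl(u3_tag, five_prime_junction_seq, fixed = TRUE)
  has_cmv <- grepl(cmv_tag, five_prime_junction_seq, fixed = TRUE)
  if (has_u3 && !has_cmv) "U3"
  else if (has_cmv && !has_u3) "CMV"
  else "ambiguous"
}

#' Test whether the reporter intron was spliced out of a provirus
#'
#' The reporter cassette only becomes functional after transcription,
#' splicing and reintegration, so an integrated copy lacking the intron but
#' retaining both exons evidences a completed retrotransposition cycle.
#'
#' @param provirus_seq integrated provirus DNA.
#' @param intron_seq the reporter intron.
#' @param exon_seqs character vector of exon segments that must both be
#'   present (otherwise the sequence is not a reporter provirus and an error
#'   is raised).
#' @return \code{TRUE} if the intron is absent (spliced), \code{FALSE} if it
#'   is still present.
#' @export
intronRemoved <- function(provirus_seq,
                          intron_seq = proviralSegments()[["intron"]],
                          exon_seqs = proviralSegments()[c("exon1", "exon2")]) {
  .assertDna(provirus_seq, "provirus_seq")
  if (!all(vapply(exon_seqs, grepl, logical(1), x = provirus_seq,
                  fixed = TRUE)))
    stop("provirus lacks the reporter cassette exons")
  !grepl(intron_seq, provirus_seq, fixed = TRUE)
}

#' Flag sites whose junction support suggests an indel or artefact
#'
#' Sites where fewer than \code{min_modal_fraction} of the reads agree on the
#' modal junction position are flagged \code{indel_suspect}. Flagged sites
#' are retained (for reporting) but excluded from downstream cross-sample
#' classification. A site exactly at the threshold passes.
#'
#' @param sites \code{GRanges} from \code{\link{callSites}}.
#' @param min_modal_fraction minimum modal-read fraction to pass.
#' @return \code{sites} with an added logical \code{integrity_pass} column
#'   and \code{indel_suspect} appended to \code{flags} on failures.
#' @export
junctionIntegrity <- function(sites, min_modal_fraction = 0.8) {
  msf <- S4Vectors::mcols(sites)$modal_support_fraction
  pass <- msf >= min_modal_fraction
  S4Vectors::mcols(sites)$integrity_pass <- pass
  flags <- S4Vectors::mcols(sites)$flags
  if (is.null(flags)) flags <- rep("", length(sites))
  flags[!pass] <- ifelse(nzchar(flags[!pass]),
                         paste0(flags[!pass], ";indel_suspect"),
                         "indel_suspect")
  S4Vectors::mcols(sites)$flags <- flags
  sites
}

#' Reference host flank 3' of a junction, in provirus orientation
#'
#' Extracts the \code{len} reference bases that a junction read would enter
#' after the LTR terminus: forward from the junction on plus-strand sites,
#' reverse-complemented ending at the junction on minus-strand sites. Used
#' as the downstream flank for \code{\link{tsdLength}}.
#'
#' @param genome reference \code{DNAStringSet}.
#' @param chrom chromosome name.
#' @param junction 1-based junction coordinate.
#' @param strand \code{"+"} or \code{"-"}.
#' @param len flank length in bp (shortened with a warning at chromosome
#'   ends).
#' @return DNA character string.
#' @export
junctionFlank <- function(genome, chrom, junction, strand, len = 20L) {
  host <- .chromSeq(genome, chrom)
  n <- nchar(host)
  if (junction < 1L || junction > n)
    stop("junction outside chromosome bounds")
  if (strand == "-") {
    start <- junction - len + 1L
    if (start < 1L) {
      warning("flank truncated at chromosome start")
      start <- 1L
    }
    .revcomp(substr(host, start, junction))
  } else {
    end <- junction + len - 1L
    if (end > n) {
      warning("flank truncated at chromosome end")
      end <- n
    }
    substr(host, junction, end)
  }
}
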