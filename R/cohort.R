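#' Merge per-sample integration sites into a loci-by-sample matrix
#'
#' Junctions from different samples lying within \code{merge_window} on the
#' same chromosome and strand (single-linkage) are treated as one locus,
#' reported at the minimum member coordinate. Presence and distinct-amplicon
#' copy numbers are tabulated per sample.
#'
#' @param sites_by_sample named list of \code{GRanges} (one per sample,
#'   typically from \code{\link{callSites}}/\code{\link{siteAbundance}};
#'   \code{flags} and \code{cytoband} metadata columns are propagated).
#' @param merge_window cross-sample merge window in bp.
#' @return a \code{\linkS4class{SiteMatrix}}.
#' @export
buildSiteMatrix <- function(sites_by_sample, merge_window = 10L) {
  samples <- names(sites_by_sample)
  if (is.null(samples) || any(!nzchar(samples)))
    stop("sites_by_sample must be a named list")
  rows <- list()
  for (s in samples) {
    gr <- sites_by_sample[[s]]
    if (!length(gr)) next
    mc <- S4Vectors::mcols(gr)
    rows[[s]] <- data.frame(
      sample = s,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      pos = GenomicRanges::start(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      copies = if (!is.null(mc$copy_number)) mc$copy_number
               else rep(1L, length(gr)),
      flags = if (!is.null(mc$flags)) mc$flags else rep("", length(gr)),
      cytoband = if (!is.null(mc$cytoband)) mc$cytoband
                 else rep(NA_character_, length(gr)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(present = matrix(logical(0), 0, length(samples),
                                     dimnames = list(NULL, samples)),
                    copies = matrix(integer(0), 0, length(samples),
                                    dimnames = list(NULL, samples))),
      rowRanges = GenomicRanges::GRanges())
    return(new("SiteMatrix", se))
  }
  all <- do.call(rbind, rows)
  cl <- .chainCluster(all$chrom, all$strand, all$pos, merge_window)
  loci <- lapply(split(seq_len(nrow(all)), cl), function(ix) {
    fl <- unique(unlist(strsplit(all$flags[ix], ";", fixed = TRUE)))
    fl <- fl[nzchar(fl)]
    cb <- all$cytoband[ix]
    list(chrom = all$chrom[ix[1L]], pos = min(all$pos[ix]),
         strand = all$strand[ix[1L]],
         flags = paste(sort(fl), collapse = ";"),
         cytoband = if (any(!is.na(cb))) cb[!is.na(cb)][1L]
                    else NA_character_,
         members = ix)
  })
  ord <- order(vapply(loci, `[[`, "", "chrom"),
               vapply(loci, `[[`, 0L, "pos"),
               vapply(loci, `[[`, "", "strand"))
  loci <- loci[ord]
  n <- length(loci)
  present <- matrix(FALSE, n, length(samples),
                    dimnames = list(NULL, samples))
  copies <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  for (i in seq_len(n)) {
    ix <- loci[[i]]$members
    for (j in ix) {
      s <- all$sample[j]
      present[i, s] <- TRUE
      copies[i, s] <- copies[i, s] + all$copies[j]
    }
  }
  rr <- GenomicRanges::GRanges(
    seqnames = vapply(loci, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(start = vapply(loci, `[[`, 0L, "pos"),
                              width = 1L),
    strand = vapply(loci, `[[`, "", "strand"))
  S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
    flags = vapply(loci, `[[`, "", "flags"),
    cytoband = vapply(loci, `[[`, "", "cytoband"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(present = present, copies = copies), rowRanges = rr)
  new("SiteMatrix", se)
}

#' Classify loci into reference / nonreference-universal / specific sets
#'
#' Mirrors the cross-sample tabulation used to separate database (reference)
#' insertions from new ones: a locus present in any sample of the designated
#' reference group is \code{reference}; a locus absent from the reference
#' group but present in every focal sample is \code{nonreference_universal};
#' a locus absent everywhere except a single focal group, and present in all
#' of that group's samples, is \code{nonreference_specific} (with the group
#' recorded as witness). Loci carrying integrity or uniqueness flags are
#' \code{excluded} before any counting. Loci matching none of these patterns
#' (present in only part of a group) fall back to
#' \code{nonreference_partial}.
#'
#' @param matrix a \code{\linkS4class{SiteMatrix}}.
#' @param groups named list mapping group name to the character vector of its
#'   sample (column) names.
#' @param reference_group name of the group defining reference status.
#' @return the matrix with \code{category} (factor) and \code{group_witness}
#'   columns added to \code{rowData}.
#' @export
classifySites <- function(matrix, groups, reference_group) {
  stopifnot(is(matrix, "SiteMatrix"))
  if (!reference_group %in% names(groups))
    stop("reference_group must name an entry of groups")
  all_samples <- unique(unlist(groups))
  missing <- setdiff(all_samples, colnames(matrix))
  if (length(missing))
    stop("samples not in matrix: ", paste(missing, collapse = ", "))
  present <- assay(matrix, "present")
  ref_samples <- groups[[reference_group]]
  focal_groups <- setdiff(names(groups), reference_group)
  focal_samples <- unique(unlist(groups[focal_groups]))
  levels <- c("reference", "nonreference_universal", "nonreference_specific",
              "nonreference_partial", "excluded")
  category <- character(nrow(matrix))
  witness <- rep(NA_character_, nrow(matrix))
  flags <- rowData(matrix)$flags
  if (is.null(flags)) flags <- rep("", nrow(matrix))
  for (i in seq_len(nrow(matrix))) {
    pr <- present[i, , drop = TRUE]
    if (!any(pr[all_samples]))
      stop("locus ", i, " is present in no sample")
    if (nzchar(flags[i])) {
      category[i] <- "excluded"
    } else if (any(pr[ref_samples])) {
      category[i] <- "reference"
    } else if (all(pr[focal_samples])) {
      category[i] <- "nonreference_universal"
    } else {
      hit <- vapply(focal_groups, function(g) {
        inside <- groups[[g]]
        all(pr[inside]) && !any(pr[setdiff(all_samples, inside)])
      }, logical(1))
      if (sum(hit) == 1L) {
        category[i] <- "nonreference_specific"
        witness[i] <- focal_groups[hit]
      } else {
        category[i] <- "nonreference_partial"
      }
    }
  }
  rowData(matrix)$category <- factor(category, levels = levels)
  rowData(matrix)$group_witness <- witness
  matrix
}

#' Count classified loci
#'
#' @param matrix a classified \code{\linkS4class{SiteMatrix}}.
#' @param category category to count (one of the classification levels), or
#'   \code{NULL} with \code{predicate}.
#' @param group optional witness group restriction (for
#'   \code{nonreference_specific}).
#' @param predicate optional function taking the \code{rowData} DataFrame and
#'   returning a logical vector; overrides \code{category}/\code{group}.
#' @return integer count.
#' @export
countCategory <- function(matrix, category = NULL, group = NULL,
                          predicate = NULL) {
  stopifnot(is(matrix, "SiteMatrix"))
  rd <- rowData(matrix)
  if (!is.null(predicate)) return(sum(predicate(rd)))
  if (is.null(rd$category)) stop("run classifySites() first")
  hit <- !is.na(rd$category) & rd$category == category
  if (!is.null(group)) hit <- hit & !is.na(rd$group_witness) &
    rd$group_witness == group
  sum(hit)
}

#' Exclude loci whose junction flank is not unique in the genome
#'
#' Extracts the \code{flank_len} host bases a junction read enters
#' (\code{\link{junctionFlank}}) and exact-searches both strands of the
#' genome; the locus passes only if exactly one hit is found (its own).
#' Repetitive flanks or flanks that no longer match the reference exactly
#' therefore fail, mirroring the strict 100 \%-identity, single-hit
#' exclusion applied before classification.
#'
#' @param genome reference \code{DNAStringSet}.
#' @param sites \code{GRanges} of junctions (width 1).
#' @param flank_len flank length in bp.
#' @return logical vector, \code{TRUE} when the flank is unique.
#' @export
uniquenessFilter <- function(genome, sites, flank_len = 50L) {
  if (!length(sites)) return(logical(0))
  vapply(seq_along(sites), function(i) {
    strand <- as.character(GenomicRanges::strand(sites[i]))
    if (strand == "*") strand <- "+"
    flank <- junctionFlank(genome,
                           as.character(GenomicRanges::seqnames(sites[i])),
                           GenomicRanges::start(sites[i]), strand, flank_len)
    fwd <- sum(Biostrings::vcountPattern(flank, genome))
    rev <- sum(Biostrings::vcountPattern(.revcomp(flank), genome))
    (fwd + rev) == 1L
  }, logical(1))
}

#' Match loci against a list of known polymorphic insertions
#'
#' A locus matches a known insertion when their coordinates lie within
#' \code{window} bp on the same chromosome, or -- for known entries without a
#' coordinate -- when the cytoband labels are equal.
#'
#' @param loci a \code{\linkS4class{SiteMatrix}} or \code{GRanges} (an
#'   optional \code{cytoband} metadata column enables label matching).
#' @param known data.frame with columns \code{name}, \code{cytoband},
#'   \code{chrom}, \code{pos} (\code{pos} may be \code{NA}); see
#'   \code{\link{readKnownInsertions}}.
#' @param window coordinate tolerance in bp.
#' @return \code{DataFrame} of matched pairs: \code{locus_index},
#'   \code{locus_chrom}, \code{locus_pos}, \code{cytoband},
#'   \code{known_name}, \code{distance} (\code{NA} for cytoband-only
#'   matches).
#' @export
matchKnown <- function(loci, known, window = 100L) {
  gr <- if (is(loci, "SiteMatrix")) rowRanges(loci) else loci
  out <- S4Vectors::DataFrame(
    locus_index = integer(0), locus_chrom = character(0),
    locus_pos = integer(0), cytoband = character(0),
    known_name = character(0), distance = integer(0))
  if (!length(gr) || !nrow(known)) return(out)
  if (anyDuplicated(known$name)) stop("known insertion names must be unique")
  cyto <- S4Vectors::mcols(gr)$cytoband
  if (is.null(cyto)) cyto <- rep(NA_character_, length(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr)
  rows <- list()
  for (k in seq_len(nrow(known))) {
    if (!is.na(known$pos[k]) && !is.na(known$chrom[k])) {
      hit <- which(chrom == known$chrom[k] &
                     abs(pos - known$pos[k]) <= window)
      dist <- abs(pos[hit] - known$pos[k])
    } else {
      hit <- which(!is.na(cyto) & cyto == known$cytoband[k])
      dist <- rep(NA_integer_, length(hit))
    }
    if (length(hit))
      rows[[length(rows) + 1L]] <- S4Vectors::DataFrame(
        locus_index = hit, locus_chrom = chrom[hit],
        locus_pos = pos[hit], cytoband = cyto[hit],
        known_name = known$name[k], distance = as.integer(dist))
  }
  if (length(rows)) out <- do.call(rbind, rows)
  out
}

#' Read a presence/absence site table into a SiteMatrix
#'
#' Reads a TSV with columns \code{locus} (cytoband label), \code{chrom},
#' \code{pos}, followed by one 0/1 presence column per sample, such as the
#' tables of published nonreference HERV-K loci shipped in
#' \code{inst/extdata}.
#'
#' @param path TSV path.
#' @return a \code{\linkS4class{SiteMatrix}} (strand \code{*}, copies equal
#'   to presence).
#' @export
readSiteTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("locus", "chrom", "pos")
  if (!all(need %in% colnames(df)))
    stop("site table must have columns locus, chrom, pos")
  sample_cols <- setdiff(colnames(df), need)
  if (!length(sample_cols)) stop("site table has no sample columns")
  ord <- order(df$chrom, df$pos)
  df <- df[ord, , drop = FALSE]
  present <- as.matrix(df[, sample_cols, drop = FALSE]) > 0
  copies <- matrix(as.integer(present), nrow(df),
                   dimnames = list(NULL, sample_cols))
  rr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$pos, width = 1L),
                               strand = "*")
  S4Vectors::mcols(rr) <- S4Vectors::DataFrame(flags = "",
                                               cytoband = df$locus)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(present = present, copies = copies), rowRanges = rr)
  new("SiteMatrix", se)
}

#' Read a known-insertion list
#'
#' @param path TSV with columns \code{name}, \code{cytoband}, \code{chrom},
#'   \code{pos} (coordinate optional, blank/NA allowed).
#' @return data.frame with unique names.
#' @export
readKnownInsertions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  need <- c("name", "cytoband", "chrom", "pos")
  if (!all(need %in% colnames(df)))
    stop("known-insertion table must have columns name, cytoband, chrom, pos")
  if (anyDuplicated(df$name)) stop("known insertion names must be unique")
  df$pos <- as.integer(df$pos)
  df
}

#' Export integration sites as BED
#'
#' Writes width-1 junction sites in BED format (0-based half-open), with
#' \code{name} set to \code{sample:siteNN} and \code{score} to the molecule
#' count.
#'
#' @param sites \code{GRanges} from \code{\link{callSites}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSitesBed <- function(sites, path) {
  mc <- S4Vectors::mcols(sites)
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    start = GenomicRanges::start(sites) - 1L,
    end = GenomicRanges::start(sites),
    name = sprintf("%s:site%02d",
                   ifelse(is.na(mc$sample_id), "sample", mc$sample_id),
                   seq_along(sites)),
    score = mc$n_molecules,
    strand = as.character(GenomicRanges::strand(sites)))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
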