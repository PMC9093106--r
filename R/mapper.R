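#' Build a both-strand k-mer index of a reference genome
#'
#' Indexes every k-mer of the genome on both strands. Forward entries record
#' the 0-based offset of the k-mer on the chromosome; minus-strand entries
#' are keyed by the reverse complement of the forward k-mer at the same
#' offset. The index backs the deterministic seed-and-extend mapper
#' (\code{\link{mapRead}}).
#'
#' @param genome named \code{DNAStringSet}.
#' @param k k-mer size (>= 8, and no longer than the shortest chromosome).
#' @return a \code{KmerIndex} object (opaque list).
#' @export
buildKmerIndex <- function(genome, k = 15L) {
  k <- as.integer(k)
  if (is.na(k) || k < 8L) stop("k must be an integer >= 8")
  if (!length(genome)) stop("genome is empty")
  widths <- nchar(as.character(genome))
  if (any(widths < k)) stop("k exceeds the shortest chromosome length")

  kmer_list <- vector("list", length(genome))
  meta <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    s <- as.character(genome[[ci]])
    n <- nchar(s)
    starts <- seq_len(n - k + 1L)
    kf <- substring(s, starts, starts + k - 1L)
    kr <- .revcomp(kf)
    kmer_list[[ci]] <- c(kf, kr)
    meta[[ci]] <- list(chrom = rep.int(ci, 2L * length(starts)),
                       off = rep.int(starts - 1L, 2L),
                       strand = rep(c("+", "-"), each = length(starts)))
  }
  kmers <- unlist(kmer_list, use.names = FALSE)
  chrom <- unlist(lapply(meta, `[[`, "chrom"), use.names = FALSE)
  off <- unlist(lapply(meta, `[[`, "off"), use.names = FALSE)
  strand <- unlist(lapply(meta, `[[`, "strand"), use.names = FALSE)
  sp <- split(seq_along(kmers), kmers)
  env <- list2env(sp, hash = TRUE, size = length(sp))
  structure(list(k = k, env = env, chrom = chrom, off = off, strand = strand,
                 chrom_names = names(genome),
                 seqs = setNames(as.character(genome), names(genome)),
                 widths = setNames(widths, names(genome))),
            class = "KmerIndex")
}

#' @export
print.KmerIndex <- function(x, ...) {
  cat("KmerIndex: k =", x$k, "over", length(x$chrom_names),
      "chromosome(s) (", sum(x$widths), "bp )\n")
  invisible(x)
}

#' Map a host segment with a deterministic unique-best contract
#'
#' Seeds on the first k-mer of the segment (covering both strands through the
#' both-strand index), extends each candidate placement without gaps, and
#' counts mismatches over the full segment. Placements with more than
#' \code{max_mismatch} mismatches are dropped. The call is \code{unique} iff
#' exactly one placement attains the minimal mismatch count, \code{multi} if
#' two or more tie, and \code{unmapped} if no placement survives. Candidates
#' are ordered by chromosome name, then offset, then strand, so tie-breaking
#' is reproducible. A placement with a mismatch inside the seed k-mer is by
#' construction not found (seed matching is exact).
#'
#' @param index a \code{KmerIndex} from \code{\link{buildKmerIndex}}.
#' @param host_seq DNA string to map.
#' @param max_mismatch maximum tolerated substitutions.
#' @return list with \code{chrom}, \code{start0} (0-based), \code{strand},
#'   \code{mismatches}, \code{uniqueness} (\code{"unique"}, \code{"multi"}
#'   or \code{"unmapped"}).
#' @export
mapRead <- function(index, host_seq, max_mismatch = 2L) {
  stopifnot(inherits(index, "KmerIndex"))
  unmapped <- list(chrom = NA_character_, start0 = NA_integer_,
                   strand = NA_character_, mismatches = NA_integer_,
                   uniqueness = "unmapped")
  L <- nchar(host_seq)
  if (L < index$k) return(unmapped)
  seed <- substr(host_seq, 1L, index$k)
  rows <- index$env[[seed]]
  if (is.null(rows)) return(unmapped)

  cand_chrom <- index$chrom[rows]
  cand_strand <- index$strand[rows]
  cand_off <- index$off[rows]
  # seed on minus strand: the read's first k bases sit at the right-hand end
  # of the reverse-complemented alignment
  start0 <- ifelse(cand_strand == "+", cand_off, cand_off + index$k - L)
  widths <- index$widths[cand_chrom]
  ok <- start0 >= 0L & (start0 + L) <= widths
  if (!any(ok)) return(unmapped)
  cand_chrom <- cand_chrom[ok]
  cand_strand <- cand_strand[ok]
  start0 <- start0[ok]

  key <- paste(cand_chrom, start0, cand_strand)
  first <- !duplicated(key)
  cand_chrom <- cand_chrom[first]
  cand_strand <- cand_strand[first]
  start0 <- start0[first]

  rc <- NULL
  mm <- integer(length(start0))
  for (i in seq_along(start0)) {
    ref <- substr(index$seqs[[cand_chrom[i]]], start0[i] + 1L, start0[i] + L)
    if (cand_strand[i] == "+") {
      mm[i] <- .hamming(ref, host_seq)
    } else {
      if (is.null(rc)) rc <- .revcomp(host_seq)
      mm[i] <- .hamming(ref, rc)
    }
  }
  ok <- mm <= max_mismatch
  if (!any(ok)) return(unmapped)
  chrom_name <- index$chrom_names[cand_chrom[ok]]
  start0 <- start0[ok]
  strand <- cand_strand[ok]
  mm <- mm[ok]
  ord <- order(chrom_name, start0, strand)
  chrom_name <- chrom_name[ord]; start0 <- start0[ord]
  strand <- strand[ord]; mm <- mm[ord]
  best <- which(mm == min(mm))
  uniqueness <- if (length(best) == 1L) "unique" else "multi"
  b <- best[1L]
  list(chrom = chrom_name[b], start0 = as.integer(start0[b]),
       strand = strand[b], mismatches = as.integer(mm[b]),
       uniqueness = uniqueness)
}

#' Map a table of junction reads
#'
#' Vectorised wrapper around \code{\link{mapRead}}: distinct host segments
#' are mapped once and results joined back, and the junction coordinate is
#' derived from each alignment (plus strand: alignment start; minus strand:
#' alignment end, both 1-based).
#'
#' @param junction_reads output of \code{\link{selectAndTrim}}.
#' @param index a \code{KmerIndex}.
#' @param max_mismatch maximum tolerated substitutions.
#' @return the input with appended columns \code{chrom}, \code{start0},
#'   \code{strand}, \code{mismatches}, \code{uniqueness},
#'   \code{junction_pos_1based}.
#' @export
mapJunctionReads <- function(junction_reads, index, max_mismatch = 2L) {
  jr <- junction_reads
  useq <- unique(jr$host_seq)
  hits <- lapply(useq, function(s) mapRead(index, s, max_mismatch))
  idx <- match(jr$host_seq, useq)
  get <- function(field, mode) {
    vapply(hits, `[[`, vector(mode, 1L), field)[idx]
  }
  jr$chrom <- get("chrom", "character")
  jr$start0 <- get("start0", "integer")
  jr$strand <- get("strand", "character")
  jr$mismatches <- get("mismatches", "integer")
  jr$uniqueness <- get("uniqueness", "character")
  host_len <- nchar(jr$host_seq)
  jr$junction_pos_1based <- ifelse(jr$strand == "+", jr$start0 + 1L,
                                   jr$start0 + host_len)
  jr$junction_pos_1based <- as.integer(jr$junction_pos_1based)
  jr
}

#' Collapse aligned reads into deduplicated molecules
#'
#' Reads with identical (sample, chromosome, junction, strand, fragment
#' length) are PCR duplicates of one sequenced molecule and collapse to a
#' single record; amplicons of different shear length remain distinct
#' molecules, the unit on which clone copy numbers are counted. Only
#' uniquely aligned reads contribute; multi-mapping and unmapped reads are
#' discarded. The operation is idempotent.
#'
#' @param alignments output of \code{\link{mapJunctionReads}} (the
#'   \code{uniqueness} filter is applied internally).
#' @return \code{DataFrame} of molecules sorted by (sample, chrom, junction):
#'   \code{sample_id}, \code{chrom}, \code{junction_pos_1based},
#'   \code{strand}, \code{fragment_length}, \code{n_reads},
#'   \code{read_ids} (comma-joined).
#' @export
deduplicate <- function(alignments) {
  al <- alignments
  if (nrow(al) && !is.null(al$uniqueness))
    al <- al[al$uniqueness == "unique", , drop = FALSE]
  if (!nrow(al)) {
    return(S4Vectors::DataFrame(
      sample_id = character(0), chrom = character(0),
      junction_pos_1based = integer(0), strand = character(0),
      fragment_length = integer(0), n_reads = integer(0),
      read_ids = character(0)))
  }
  sample_id <- if (is.null(al$sample_id)) rep(NA_character_, nrow(al))
               else al$sample_id
  # accept our own output as input (idempotence)
  n_reads_in <- if (is.null(al$n_reads)) rep(1L, nrow(al)) else al$n_reads
  ids_in <- if (!is.null(al$read_ids)) al$read_ids else al$read_id
  key <- paste(sample_id, al$chrom, al$junction_pos_1based, al$strand,
               al$fragment_length, sep = "\r")
  groups <- split(seq_len(nrow(al)), key)
  rows <- lapply(groups, function(ix) {
    i <- ix[1L]
    data.frame(sample_id = sample_id[i], chrom = al$chrom[i],
               junction_pos_1based = al$junction_pos_1based[i],
               strand = al$strand[i],
               fragment_length = al$fragment_length[i],
               n_reads = sum(n_reads_in[ix]),
               read_ids = paste(ids_in[ix], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$chrom, out$junction_pos_1based,
                   out$strand, out$fragment_length), , drop = FALSE]
  rownames(out) <- NULL
  S4Vectors::DataFrame(out)
}
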