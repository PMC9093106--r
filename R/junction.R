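#' Filter read triples on per-position index-read quality
#'
#' Reproduces the demultiplexing quality gate: a read triple is kept only if
#' every position of its 8-bp index read has a Phred score strictly greater
#' than \code{min_phred} (the threshold itself is rejected). Index reads
#' whose length differs from \code{index_len} are rejected with a warning
#' rather than an error. Input order is preserved and the discard count is
#' attached as the \code{"n_discarded"} attribute.
#'
#' @param reads \code{DataFrame}/data.frame with at least \code{index_qual}
#'   (Phred+33 string) per row, e.g. from \code{\link{libraryReads}}.
#' @param min_phred exclusive Phred threshold (default 20: scores of 21 and
#'   above pass).
#' @param index_len expected index-read length.
#' @return the kept subset of \code{reads}, with attributes
#'   \code{n_discarded} (quality failures) and \code{n_malformed}
#'   (length failures).
#' @export
indexQualityFilter <- function(reads, min_phred = 20L, index_len = 8L) {
  if (nrow(reads) == 0L) {
    out <- reads
    attr(out, "n_discarded") <- 0L
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  quals <- reads$index_qual
  ok_len <- nchar(quals) == index_len
  if (any(!ok_len))
    warning(sum(!ok_len), " read(s) rejected: index read not length ",
            index_len)
  pass <- ok_len & vapply(quals, function(q) all(.phred(q) > min_phred),
                          logical(1))
  out <- reads[pass, , drop = FALSE]
  attr(out, "n_discarded") <- sum(ok_len & !pass)
  attr(out, "n_malformed") <- sum(!ok_len)
  out
}

#' Select LTR-junction reads and trim to the host segment
#'
#' Scans each R1 for the terminal 3'-LTR hexamer (\code{CCTACA} or
#' \code{CCTTCA} by default). Matching is exact; the \emph{last} occurrence
#' ending within \code{search_window} bases of the read start is used, which
#' guards against the hexamer arising earlier inside the LTR tail. The bases
#' strictly after the motif form the host segment. Reads with no motif, or
#' with a host segment shorter than \code{min_host_len}, are rejected;
#' per-category rejection counts are attached as the \code{"rejections"}
#' attribute.
#'
#' @param reads read table (as from \code{\link{indexQualityFilter}}).
#' @param motifs character vector of terminal hexamers (each 6 bp, ACGT).
#' @param search_window the motif must end within this many bases of the R1
#'   start. Match it to the expected LTR-tail length of the library when
#'   known; chance hexamer occurrences in host sequence beyond the tail
#'   otherwise shift the inferred junction.
#' @param min_host_len minimum retained host-segment length (bp).
#' @return \code{DataFrame} of junction reads: \code{read_id},
#'   \code{sample_id}, \code{host_seq}, \code{motif_used},
#'   \code{fragment_length}.
#' @export
selectAndTrim <- function(reads, motifs = c("CCTACA", "CCTTCA"),
                          search_window = 60L, min_host_len = 20L) {
  if (!length(motifs) || any(nchar(motifs) != 6L) || !all(.isDna(motifs)))
    stop("motifs must be non-empty 6-bp ACGT hexamers")
  n <- nrow(reads)
  rejections <- c(no_motif = 0L, short_host = 0L)
  if (n == 0L) {
    out <- S4Vectors::DataFrame(read_id = character(0),
                                sample_id = character(0),
                                host_seq = character(0),
                                motif_used = character(0),
                                fragment_length = integer(0))
    attr(out, "rejections") <- rejections
    return(out)
  }
  r1 <- reads$r1_seq
  # last exact occurrence of any motif ending within the window
  motif_end <- rep(NA_integer_, n)
  motif_used <- rep(NA_character_, n)
  for (m in motifs) {
    starts <- gregexpr(m, r1, fixed = TRUE)
    ends <- lapply(starts, function(s) {
      s <- s[s > 0L]
      e <- s + 5L
      e[e <= search_window]
    })
    last_end <- vapply(ends, function(e)
      if (length(e)) max(e) else NA_integer_, integer(1))
    better <- !is.na(last_end) & (is.na(motif_end) | last_end > motif_end)
    motif_end[better] <- last_end[better]
    motif_used[better] <- m
  }
  host <- ifelse(is.na(motif_end), NA_character_,
                 substr(r1, motif_end + 1L, nchar(r1)))
  keep_motif <- !is.na(motif_end)
  keep <- keep_motif & !is.na(host) & nchar(host) >= min_host_len
  rejections["no_motif"] <- sum(!keep_motif)
  rejections["short_host"] <- sum(keep_motif & !keep)
  out <- S4Vectors::DataFrame(
    read_id = reads$read_id[keep],
    sample_id = if (is.null(reads$sample_id)) NA_character_
                else reads$sample_id[keep],
    host_seq = host[keep],
    motif_used = motif_used[keep],
    fragment_length = if (is.null(reads$fragment_length)) NA_integer_
                      else reads$fragment_length[keep])
  attr(out, "rejections") <- rejections
  out
}
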