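# Small shared helpers. None are exported.

.DNA_BASES <- c("A", "C", "G", "T")

.isDna <- function(x) grepl("^[ACGT]+$", x)

.assertDna <- function(x, what = "sequence") {
  if (length(x) == 0L || any(is.na(x)) || !all(.isDna(x)))
    stop(what, " must be non-empty and contain only A/C/G/T", call. = FALSE)
  invisible(x)
}

# vectorised reverse complement on plain character vectors
.revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 decoding; returns integer vector for a single quality string
.phred <- function(qual) utf8ToInt(qual) - 33L

.phredString <- function(scores) intToUtf8(scores + 33L, multiple = FALSE)

.hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# run body under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards so simulation calls do not perturb user code
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.randomDna <- function(n) {
  paste(sample(.DNA_BASES, n, replace = TRUE), collapse = "")
}

# single-linkage chaining of 1D positions within `window`, stratified by
# chrom and strand; returns an integer cluster id per input element
.chainCluster <- function(chrom, strand, pos, window) {
  n <- length(pos)
  if (n == 0L) return(integer(0))
  ord <- order(chrom, strand, pos)
  cl <- integer(n)
  cur <- 0L
  last_chrom <- NA_character_
  last_strand <- NA_character_
  last_pos <- NA_integer_
  for (i in ord) {
    new_cluster <- is.na(last_pos) ||
      chrom[i] != last_chrom || strand[i] != last_strand ||
      (pos[i] - last_pos) > window
    if (new_cluster) cur <- cur + 1L
    cl[i] <- cur
    last_chrom <- chrom[i]
    last_strand <- strand[i]
    last_pos <- pos[i]
  }
  cl
}

.chromSeq <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not in genome", call. = FALSE)
  as.character(genome[[chrom]])
}
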