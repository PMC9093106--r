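test_that("makeReference is deterministic, seed-sensitive and well-formed", {
  g1 <- makeReference(1, c(chr1 = 10000L))
  g2 <- makeReference(1, c(chr1 = 10000L))
  g3 <- makeReference(2, c(chr1 = 10000L))
  expect_identical(as.character(g1), as.character(g2))
  expect_false(as.character(g1[[1]]) == as.character(g3[[1]]))
  expect_equal(unname(width(g1)), 10000L)
  s <- as.character(g1[[1]])
  expect_match(s, "^[ACGT]+$")
  runs <- rle(strsplit(s, "")[[1]])
  expect_lte(max(runs$lengths), 30L)
  expect_error(makeReference(1, integer(0)), "at least one")
  expect_error(makeReference(1, c(chr1 = 0L)), ">= 1000")
  expect_error(makeReference(1, c(chr1 = -5L)), ">= 1000")
})

test_that("plantProvirus duplicates the target site around the provirus", {
  g <- makeReference(5, c(chr1 = 4000L))
  host <- as.character(g[[1]])
  prov <- assembleProvirus("U3", intron_present = FALSE)
  p <- 1500L

  for (t in c(0L, 5L, 6L)) {
    res <- plantProvirus(g, list(chrom = "chr1", position = p, strand = "+",
                                 tsd_len = t, copy_count = 1L), prov)
    # string-level oracle: hand-built concatenation
    expected <- paste0(substr(host, 1, p + t), prov,
                       substr(host, p + 1, nchar(host)))
    expect_identical(as.character(res$sequence), expected)
    expect_identical(res$truth$junction_pos_1based, p + 1L)
    if (t > 0) {
      tsd <- substr(host, p + 1, p + t)
      planted <- as.character(res$sequence)
      expect_identical(substr(planted, p + 1, p + t), tsd)
      expect_identical(substr(planted, p + t + nchar(prov) + 1,
                              p + 2 * t + nchar(prov)), tsd)
    }
  }

  resm <- plantProvirus(g, list(chrom = "chr1", position = p, strand = "-",
                                tsd_len = 6L, copy_count = 1L), prov)
  expectedm <- paste0(substr(host, 1, p + 6L), rcChar(prov),
                      substr(host, p + 1, nchar(host)))
  expect_identical(as.character(resm$sequence), expectedm)
  expect_identical(resm$truth$junction_pos_1based, p + 6L)

  expect_error(plantProvirus(g, list(chrom = "chr1", position = 5000L,
                                     strand = "+", tsd_len = 6L,
                                     copy_count = 1L), prov),
               "out of range")
  expect_error(plantProvirus(g, list(chrom = "chr1", position = p,
                                     strand = "+", tsd_len = 6L,
                                     copy_count = 1L), "ACGTNACGT"),
               "A/C/G/T")
  expect_error(plantProvirus(g, list(chrom = "chr1", position = p,
                                     strand = "+", tsd_len = 6L,
                                     copy_count = 1L), "ACGTACGT"),
               "terminal hexamer")
})

test_that("planting round-trip recovers every TSD length 0..10", {
  g <- makeReference(11, c(chr1 = 8000L))
  host <- as.character(g[[1]])
  prov <- assembleProvirus("U3", intron_present = FALSE)
  np <- nchar(prov)
  for (t in 0:10) {
    # choose a position where the duplication cannot extend by chance
    p <- 1000L
    repeat {
      up <- substr(host, p + t - 19L, p + t)
      down <- substr(host, p + 1L, p + 20L)
      if (oracleTsd(up, down) == t) break
      p <- p + 17L
    }
    res <- plantProvirus(g, list(chrom = "chr1", position = p, strand = "+",
                                 tsd_len = t, copy_count = 1L), prov)
    planted <- as.character(res$sequence)
    up_fl <- substr(planted, p + t - 19L, p + t)
    down_fl <- substr(planted, p + t + np + 1L, p + t + np + 20L)
    expect_identical(tsdLength(up_fl, down_fl), t)
  }
})

test_that("planting commutes with reverse complementation", {
  g <- makeReference(13, c(chr1 = 3000L))
  n <- 3000L
  prov <- assembleProvirus("U3", intron_present = FALSE)
  grc <- Biostrings::reverseComplement(g)
  names(grc) <- names(g)
  for (t in c(0L, 5L, 6L)) {
    p <- 1200L
    fwd <- plantProvirus(g, list(chrom = "chr1", position = p, strand = "+",
                                 tsd_len = t, copy_count = 1L), prov)
    mir <- plantProvirus(grc, list(chrom = "chr1", position = n - p - t,
                                   strand = "-", tsd_len = t,
                                   copy_count = 1L), prov)
    expect_identical(as.character(mir$sequence),
                     rcChar(as.character(fwd$sequence)))
  }
})

test_that("simulateLibrary emits one read triple per molecule with the
           correct junction geometry", {
  g <- makeReference(21, c(chr1 = 5000L))
  host <- as.character(g[[1]])
  spec <- data.frame(sample_id = "s1", chrom = "chr1", position = 2000L,
                     strand = "+", tsd_len = 6L, promoter5 = "U3",
                     intron_present = FALSE, copy_count = 3L)
  params <- libraryParams(seed = 3,
                          ltr_tail = paste0(proviralSegments()[["u5"]],
                                            "CCTACA"))
  lib <- simulateLibrary(g, spec, params)
  rd <- libraryReads(lib)
  expect_equal(nrow(rd), 3L)
  tail <- params$ltr_tail
  for (i in seq_len(3)) {
    r1 <- rd$r1_seq[i]
    expect_identical(substr(r1, 1, nchar(tail)), tail)
    host_part <- substr(r1, nchar(tail) + 1L, nchar(r1))
    # oracle: direct slice of the reference downstream of the junction
    expect_identical(host_part,
                     substr(host, 2001L, 2000L + nchar(host_part)))
  }
  tr <- libraryTruth(lib)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$junction_pos_1based, 2001L)
  shears <- as.integer(strsplit(tr$shear_lengths, ",")[[1]])
  expect_identical(sort(shears), sort(rd$fragment_length))
})

test_that("PCR duplicate emission and truth completeness", {
  g <- makeReference(22, c(chr1 = 5000L))
  specs <- data.frame(sample_id = c("s1", "s1"), chrom = "chr1",
                      position = c(1500L, 3200L), strand = c("+", "-"),
                      tsd_len = c(5L, 6L), promoter5 = "U3",
                      intron_present = FALSE, copy_count = c(2L, 4L))
  lib <- simulateLibrary(g, specs, libraryParams(seed = 4, pcr_dup_rate = 1))
  rd <- libraryReads(lib)
  # every molecule appears exactly twice, with identical R1 and length
  expect_equal(nrow(rd), 2L * (2L + 4L))
  dups <- rd[grepl("_dup$", rd$read_id), ]
  orig <- rd[!grepl("_dup$", rd$read_id), ]
  expect_equal(nrow(libraryTruth(lib)), nrow(specs))
  expect_equal(nrow(orig), sum(specs$copy_count))
  m <- match(paste0(orig$read_id, "_dup"), dups$read_id)
  expect_false(anyNA(m))
  expect_identical(orig$r1_seq, dups$r1_seq[m])
  expect_identical(orig$fragment_length, dups$fragment_length[m])
})

test_that("5' junctions carry the promoter class planted by the simulator", {
  g <- makeReference(23, c(chr1 = 5000L))
  specs <- data.frame(sample_id = "s1", chrom = "chr1",
                      position = c(1500L, 3200L), strand = "+",
                      tsd_len = 6L, promoter5 = c("U3", "CMV"),
                      intron_present = c(FALSE, TRUE), copy_count = 1L)
  lib <- simulateLibrary(g, specs, libraryParams(seed = 5))
  tr <- libraryTruth(lib)
  segs <- proviralSegments()
  expect_true(grepl(segs[["u3"]], tr$junction5_seq[1], fixed = TRUE))
  expect_false(grepl(segs[["cmv"]], tr$junction5_seq[1], fixed = TRUE))
  expect_true(grepl(segs[["cmv"]], tr$junction5_seq[2], fixed = TRUE))
  expect_false(grepl(segs[["u3"]], tr$junction5_seq[2], fixed = TRUE))
  expect_true(grepl(segs[["intron"]], tr$provirus_seq[2], fixed = TRUE))
  expect_false(grepl(segs[["intron"]], tr$provirus_seq[1], fixed = TRUE))
})

test_that("library parameter validation rejects impossible geometries", {
  expect_error(libraryParams(read_len = 200L, shear_range = c(150L, 600L)),
               "shortest fragment")
  expect_error(libraryParams(subst_error_rate = 1.5), "rates")
  expect_error(libraryParams(ltr_tail = "ACGTACGT"), "CCTACA or CCTTCA")
  expect_error(libraryParams(index_qual = rep(35L, 6L)), "index_qual")
})

test_that("FASTQ output round-trips through Biostrings", {
  co <- smallCohort()
  dir <- tempfile("lib")
  paths <- writeLibrary(co$library, dir)
  expect_true(all(file.exists(paths)))
  rd0 <- libraryReads(co$library)
  rd <- readLibraryFastq(paths[["r1"]], paths[["r2"]], paths[["i1"]])
  expect_identical(rd$read_id, rd0$read_id)
  expect_identical(rd$r1_seq, rd0$r1_seq)
  expect_identical(rd$r2_qual, rd0$r2_qual)
  expect_identical(rd$index_seq, rd0$index_seq)
  truth <- read.delim(paths[["truth"]])
  expect_equal(nrow(truth), nrow(libraryTruth(co$library)))
})
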