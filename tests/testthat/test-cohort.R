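makeSites <- function(chrom, pos, strand = "+", copy = 1L, flags = "",
                      sample_id = "s") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    sample_id = sample_id, copy_number = as.integer(rep_len(copy,
                                                            length(gr))),
    flags = rep_len(flags, length(gr)))
  gr
}

test_that("buildSiteMatrix merges nearby junctions across samples", {
  m <- buildSiteMatrix(list(A = makeSites("chr1", 1000L),
                            B = makeSites("chr1", 1003L)),
                       merge_window = 10L)
  expect_equal(nrow(m), 1L)
  expect_true(all(SummarizedExperiment::assay(m, "present")[1, ]))
  expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(m)),
               1000L)

  m2 <- buildSiteMatrix(list(A = makeSites("chr1", c(1000L, 1050L))),
                        merge_window = 10L)
  expect_equal(nrow(m2), 2L)

  m3 <- buildSiteMatrix(setNames(list(), character(0)))
  expect_equal(nrow(m3), 0L)
})

test_that("classifySites partitions loci and is invariant to sample and
           locus order", {
  sites <- list(
    ctrl = makeSites("chr1", c(1000L, 5000L)),
    a = makeSites("chr1", c(1000L, 9000L, 13000L)),
    b = makeSites("chr1", c(1000L, 9000L, 17000L, 21000L)))
  groups <- list(ctrl = "ctrl", a = "a", b = "b")
  m <- classifySites(buildSiteMatrix(sites), groups, "ctrl")
  cats <- as.character(siteCategories(m))
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(m))
  expect_identical(cats[pos == 1000], "reference")
  expect_identical(cats[pos == 5000], "reference")
  expect_identical(cats[pos == 9000], "nonreference_universal")
  expect_identical(cats[pos == 13000], "nonreference_specific")
  expect_identical(SummarizedExperiment::rowData(m)$group_witness[
    pos == 13000], "a")
  expect_identical(cats[pos == 17000], "nonreference_specific")
  expect_identical(cats[pos == 21000], "nonreference_specific")
  # total partition
  total <- sum(vapply(levels(siteCategories(m)), function(l)
    countCategory(m, l), integer(1)))
  expect_equal(total, nrow(m))
  # permutation symmetry
  m2 <- classifySites(buildSiteMatrix(rev(sites)), rev(groups), "ctrl")
  pos2 <- GenomicRanges::start(SummarizedExperiment::rowRanges(m2))
  expect_identical(as.character(siteCategories(m2))[order(pos2)],
                   cats[order(pos)])
})

test_that("flagged loci are excluded from classification", {
  sites <- list(ctrl = makeSites("chr1", 1000L),
                a = makeSites("chr1", c(1000L, 9000L),
                              flags = c("", "indel_suspect")))
  m <- classifySites(buildSiteMatrix(sites),
                     list(ctrl = "ctrl", a = "a"), "ctrl")
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(m))
  expect_identical(as.character(siteCategories(m))[pos == 9000], "excluded")
  expect_equal(countCategory(m, "excluded"), 1L)
})

test_that("countCategory supports predicates and degenerate cases", {
  sites <- list(ctrl = makeSites("chr1", 1000L),
                a = makeSites("chr1", c(1000L, 9000L)))
  m <- classifySites(buildSiteMatrix(sites),
                     list(ctrl = "ctrl", a = "a"), "ctrl")
  expect_equal(countCategory(m, predicate = function(rd) rep(FALSE,
                                                             nrow(rd))), 0L)
  expect_equal(countCategory(m, predicate = function(rd) rep(TRUE,
                                                             nrow(rd))),
               nrow(m))
})

test_that("uniquenessFilter passes unique flanks and fails repeats and
           mutated flanks", {
  g <- makeReference(61, c(chr1 = 8000L))
  s <- as.character(g[[1]])
  # plant an exact repeat of the 60-mer at 3001 after position 7000
  dup <- substr(s, 3001, 3060)
  s2 <- paste0(substr(s, 1, 7000), dup, substr(s, 7061, 8000))
  g2 <- Biostrings::DNAStringSet(c(chr1 = s2))

  unique_site <- GenomicRanges::GRanges("chr1",
                                        IRanges::IRanges(1000L, width = 1L),
                                        strand = "+")
  rep_site <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(3001L, width = 1L),
                                     strand = "+")
  expect_true(uniquenessFilter(g2, unique_site, flank_len = 50L))
  expect_false(uniquenessFilter(g2, rep_site, flank_len = 50L))

  # a flank that mismatches the reference (identity < 100%) finds no hit
  mut <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000L, width = 1L),
                                strand = "+")
  g3 <- g
  chars <- strsplit(s, "")[[1]]
  chars[1020] <- setdiff(c("A", "C", "G", "T"), chars[1020])[1]
  g3[[1]] <- Biostrings::DNAString(paste(chars, collapse = ""))
  flank <- junctionFlank(g, "chr1", 1000L, "+", 50L)
  hits <- sum(Biostrings::vcountPattern(flank, g3)) +
    sum(Biostrings::vcountPattern(rcChar(flank), g3))
  expect_equal(hits, 0L)
})

test_that("matchKnown matches by coordinate within the window or by
           cytoband label", {
  loci <- GenomicRanges::GRanges(c("chr12", "chr19"),
                                 IRanges::IRanges(c(43919900L, 21658739L),
                                                  width = 1L))
  S4Vectors::mcols(loci)$cytoband <- c("12q12", "19p12")
  known <- data.frame(name = c("K20", "K113", "K99"),
                      cytoband = c("12q12", "19p12", "5q11"),
                      chrom = c("chr12", NA, "chr5"),
                      pos = c(43919854L, NA, 100000L))
  hits <- matchKnown(loci, known, window = 100L)
  expect_setequal(hits$known_name, c("K20", "K113"))
  expect_equal(hits$distance[hits$known_name == "K20"], 46L)
  expect_true(is.na(hits$distance[hits$known_name == "K113"]))
  # beyond the window: no coordinate match
  expect_equal(nrow(matchKnown(loci, known, window = 10L)), 1L)
  expect_equal(nrow(matchKnown(loci, known[0, ])), 0L)
  expect_error(matchKnown(loci, data.frame(name = c("K1", "K1"),
                                           cytoband = NA, chrom = NA,
                                           pos = NA)), "unique")
})

test_that("readSiteTable and readKnownInsertions validate their input", {
  path <- system.file("extdata", "hela_cohort_sites.tsv",
                      package = "hervtrace")
  m <- readSiteTable(path)
  expect_s4_class(m, "SiteMatrix")
  expect_equal(nrow(m), 15L)
  expect_setequal(colnames(m), c("HeLa", "HeLa_inBLC", "fibroblast"))
  bad <- tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", bad)
  expect_error(readSiteTable(bad), "locus")
  known <- readKnownInsertions(system.file("extdata",
                                           "known_hervk_insertions.tsv",
                                           package = "hervtrace"))
  expect_equal(nrow(known), 3L)
  expect_true(is.na(known$pos[known$name == "K113"]))
})
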