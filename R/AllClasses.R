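#' Simulated LM-PCR sequencing library with ground truth
#'
#' Container for a simulated ligation-mediated PCR library: one row per
#' sequenced read triple (R1, R2 and the 8-bp index read, each with Phred+33
#' qualities), the per-insertion truth table, and the simulation parameters.
#' Created by \code{\link{simulateLibrary}}; written to R1/R2/I1 FASTQ plus a
#' truth TSV by \code{\link{writeLibrary}}.
#'
#' @slot reads \code{DataFrame} with columns \code{read_id}, \code{sample_id},
#'   \code{r1_seq}, \code{r1_qual}, \code{r2_seq}, \code{r2_qual},
#'   \code{index_seq}, \code{index_qual}, \code{fragment_length}.
#' @slot truth \code{DataFrame}, one row per planted insertion per sample
#'   (sample, locus, strand, TSD length, 5' promoter class, clone copy count,
#'   shear lengths, 5'-junction sequence).
#' @slot params \code{list} of simulation parameters
#'   (see \code{\link{libraryParams}}).
#'
#' @aliases LmpcrLibrary-class
#' @exportClass LmpcrLibrary
setClass("LmpcrLibrary",
  slots = c(reads = "DataFrame", truth = "DataFrame", params = "list")
)

setValidity("LmpcrLibrary", function(object) {
  rd <- object@reads
  need <- c("read_id", "sample_id", "r1_seq", "r1_qual", "r2_seq", "r2_qual",
            "index_seq", "index_qual", "fragment_length")
  missing_cols <- setdiff(need, colnames(rd))
  if (length(missing_cols))
    return(paste("reads is missing columns:",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(rd)) {
    for (mate in c("r1", "r2", "index")) {
      s <- rd[[paste0(mate, "_seq")]]
      q <- rd[[paste0(mate, "_qual")]]
      if (!all(nchar(s) == nchar(q)))
        return(paste0(mate, " sequence and quality lengths differ"))
      if (any(vapply(q, function(x) any(utf8ToInt(x) < 33L), logical(1))))
        return(paste0(mate, " qualities are not valid Phred+33"))
    }
  }
  TRUE
})

#' @describeIn LmpcrLibrary read table accessor
#' @param object,x an \code{LmpcrLibrary}
#' @export
setGeneric("libraryReads", function(object) standardGeneric("libraryReads"))

#' @describeIn LmpcrLibrary truth table accessor
#' @export
setGeneric("libraryTruth", function(object) standardGeneric("libraryTruth"))

#' @describeIn LmpcrLibrary simulation parameter accessor
#' @export
setGeneric("simParams", function(object) standardGeneric("simParams"))

setMethod("libraryReads", "LmpcrLibrary", function(object) object@reads)
setMethod("libraryTruth", "LmpcrLibrary", function(object) object@truth)
setMethod("simParams", "LmpcrLibrary", function(object) object@params)

setMethod("show", "LmpcrLibrary", function(object) {
  rd <- object@reads
  cat("LmpcrLibrary with", nrow(rd), "read triples,",
      nrow(object@truth), "planted insertions\n")
  if (nrow(rd)) {
    cat("  samples:", paste(unique(rd$sample_id), collapse = ", "), "\n")
    cat("  read length:", object@params$read_len,
        "bp; fragment lengths:", min(rd$fragment_length), "-",
        max(rd$fragment_length), "bp\n")
  }
  invisible(NULL)
})

#' Loci-by-sample integration-site matrix
#'
#' A \code{RangedSummarizedExperiment} whose rows are merged integration-site
#' loci (width-1 junction coordinates) and whose columns are samples, with a
#' logical \code{present} assay and an integer \code{copies} assay
#' (distinct-amplicon copy numbers; 1 for presence-only inputs).
#' \code{\link{classifySites}} adds a \code{category} column to
#' \code{rowData}.
#'
#' @aliases SiteMatrix-class
#' @exportClass SiteMatrix
setClass("SiteMatrix", contains = "RangedSummarizedExperiment")

setValidity("SiteMatrix", function(object) {
  an <- assayNames(object)
  if (!all(c("present", "copies") %in% an))
    return("assays must include 'present' and 'copies'")
  if (nrow(object)) {
    if (!is.logical(assay(object, "present")))
      return("'present' assay must be logical")
    if (!is.numeric(assay(object, "copies")))
      return("'copies' assay must be numeric")
  }
  TRUE
})

#' @describeIn SiteMatrix per-locus classification accessor (factor, or NULL
#'   before \code{\link{classifySites}} has been run)
#' @param object a \code{SiteMatrix}
#' @export
setGeneric("siteCategories", function(object) standardGeneric("siteCategories"))

setMethod("siteCategories", "SiteMatrix", function(object) {
  rowData(object)$category
})

setMethod("show", "SiteMatrix", function(object) {
  cat("SiteMatrix:", nrow(object), "loci x", ncol(object), "samples\n")
  if (nrow(object)) {
    cat("  samples:", paste(colnames(object), collapse = ", "), "\n")
    cls <- rowData(object)$category
    if (!is.null(cls)) {
      tab <- table(cls)
      cat("  categories:",
          paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                collapse = ", "), "\n")
    }
  }
  invisible(NULL)
})
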