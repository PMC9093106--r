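#' Clone copy number by distinct-amplicon counting
#'
#' Sister clones carrying the same integration site shear at different
#' positions, so the number of distinct amplicon (fragment) lengths observed
#' at a site estimates its clone copy number. Length collisions can only
#' merge molecules, so the estimate never exceeds the true copy count.
#'
#' @param fragment_lengths integer vector of deduplicated molecule fragment
#'   lengths belonging to one site (must be non-empty).
#' @return integer count of distinct lengths.
#' @examples
#' copyNumber(c(200, 200, 350, 410))  # 3
#' @export
copyNumber <- function(fragment_lengths) {
  if (!length(fragment_lengths) || any(is.na(fragment_lengths)))
    stop("fragment_lengths must be a non-empty vector without NAs")
  length(unique(fragment_lengths))
}

#' Relative abundance of sites from copy numbers
#'
#' @param copy_numbers numeric vector of per-site copy numbers for one
#'   sample (reference and nonreference sites both belong in the
#'   denominator).
#' @return numeric vector of fractions summing to 1.
#' @examples
#' relativeAbundance(c(A = 1, B = 3))
#' @export
relativeAbundance <- function(copy_numbers) {
  if (!length(copy_numbers)) stop("no sites supplied")
  total <- sum(copy_numbers)
  if (total <= 0) stop("total copy number is zero")
  copy_numbers / total
}

#' Per-site copy numbers and relative abundances
#'
#' Annotates called sites with their distinct-amplicon copy number and, per
#' sample, the ratio of each site's copy number to the sample's total copy
#' number. An optional \code{correction} hook can post-process the raw
#' distinct-length counts (e.g. a collision correction); the default is the
#' identity, matching plain counting.
#'
#' @param sites \code{GRanges} from \code{\link{callSites}} (with
#'   \code{revmap}).
#' @param molecules the molecule table the sites were called from.
#' @param correction function applied to the vector of raw copy numbers.
#' @return \code{sites} with added \code{copy_number} and
#'   \code{rel_abundance} metadata columns.
#' @export
siteAbundance <- function(sites, molecules, correction = identity) {
  if (!length(sites)) {
    S4Vectors::mcols(sites)$copy_number <- integer(0)
    S4Vectors::mcols(sites)$rel_abundance <- numeric(0)
    return(sites)
  }
  revmap <- S4Vectors::mcols(sites)$revmap
  cn <- vapply(seq_along(sites), function(i)
    copyNumber(molecules$fragment_length[revmap[[i]]]), integer(1))
  cn <- correction(cn)
  S4Vectors::mcols(sites)$copy_number <- cn
  sample_id <- S4Vectors::mcols(sites)$sample_id
  if (is.null(sample_id)) sample_id <- rep("sample", length(sites))
  rel <- numeric(length(sites))
  for (s in unique(sample_id)) {
    ix <- sample_id == s
    rel[ix] <- relativeAbundance(cn[ix])
  }
  S4Vectors::mcols(sites)$rel_abundance <- rel
  sites
}
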