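#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' MatchParams: thresholds governing when two SV calls are the same event
#'
#' Two calls match when their sequence similarity and size similarity both
#' reach the configured minima, their start positions are within
#' \code{maxDist} base pairs, and (optionally) their SV types agree.
#' \code{strict = TRUE} switches the similarity comparisons from
#' \code{>=} to \code{>}; replicate-concordance classification uses the
#' strict form ("over 70\%"), cross-sample collapsing the non-strict form
#' ("95\% or greater").
#'
#' @slot seqSimMin minimum sequence similarity, fraction in [0, 1].
#' @slot sizeSimMin minimum size similarity, fraction in [0, 1].
#' @slot maxDist maximum start-position distance in bp.
#' @slot requireSameType logical; must SV types agree?
#' @slot strict logical; use strict inequalities for the similarity gates?
#' @export
setClass("MatchParams",
  representation(seqSimMin = "numeric", sizeSimMin = "numeric",
                 maxDist = "numeric", requireSameType = "logical",
                 strict = "logical"),
  prototype(seqSimMin = 0.95, sizeSimMin = 0.95, maxDist = 1000,
            requireSameType = TRUE, strict = FALSE))

setValidity("MatchParams", function(object) {
  msg <- character(0)
  if (object@seqSimMin < 0 || object@seqSimMin > 1)
    msg <- c(msg, "seqSimMin must be in [0, 1]")
  if (object@sizeSimMin < 0 || object@sizeSimMin > 1)
    msg <- c(msg, "sizeSimMin must be in [0, 1]")
  if (object@maxDist < 0) msg <- c(msg, "maxDist must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct match parameters
#'
#' @param seqSimMin,sizeSimMin similarity thresholds in [0, 1].
#' @param maxDist maximum start distance in bp.
#' @param requireSameType require equal SV types.
#' @param strict use strict (\code{>}) similarity comparisons.
#' @return a \linkS4class{MatchParams} object.
#' @export
#' @examples
#' matchParams()                      # collapse defaults: 0.95/0.95/1000 bp
#' matchParams(0.70, 0.70, strict = TRUE)  # replicate-concordance form
matchParams <- function(seqSimMin = 0.95, sizeSimMin = 0.95, maxDist = 1000,
                        requireSameType = TRUE, strict = FALSE) {
  new("MatchParams", seqSimMin = seqSimMin, sizeSimMin = sizeSimMin,
      maxDist = as.numeric(maxDist), requireSameType = requireSameType,
      strict = strict)
}

#' SVCallSet: a set of sequence-resolved structural-variant calls
#'
#' Wraps a \link[GenomicRanges]{GRanges} whose ranges are the reference
#' spans of the calls (1-based inclusive, so an insertion occupies its single
#' anchor base) with metadata columns \code{recordID}, \code{sampleID},
#' \code{ref}, \code{alt}, \code{svtype}, \code{svlen}, \code{qual},
#' \code{filter} and \code{genotype}. The exchange format used throughout the
#' package is the 0-based half-open table returned by \code{\link{callTable}};
#' the class enforces the record-level invariants (alleles over A/C/G/T/N,
#' svlen >= 50, type-consistent allele length differences, span = ref length).
#'
#' @slot calls a \code{GRanges} of calls as described above.
#' @export
setClass("SVCallSet", representation(calls = "GRanges"))

setValidity("SVCallSet", function(object) {
  gr <- object@calls
  mc <- S4Vectors::mcols(gr)
  need <- c("recordID", "sampleID", "ref", "alt", "svtype", "svlen",
            "qual", "filter", "genotype")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing call columns:", paste(miss, collapse = ", ")))
  if (length(gr) == 0L) return(TRUE)
  msg <- character(0)
  if (any(grepl("[^ACGTN]", mc$ref)) || any(grepl("[^ACGTN]", mc$alt)))
    msg <- c(msg, "alleles must use only A,C,G,T,N")
  if (!all(mc$svtype %in% SV_TYPES))
    msg <- c(msg, "svtype must be DEL, INS or INV")
  if (!all(mc$genotype %in% GT_LEVELS))
    msg <- c(msg, "genotype must be hom_ref/het/hom_alt/missing")
  if (any(mc$svlen < 50))
    msg <- c(msg, "svlen must be >= 50 for retained records")
  if (any(mc$qual < 0)) msg <- c(msg, "qual must be >= 0")
  if (!all(GenomicRanges::width(gr) == nchar(mc$ref)))
    msg <- c(msg, "reference span must equal ref allele length")
  dd <- nchar(mc$ref) - nchar(mc$alt)
  if (any(mc$svtype == "DEL" & dd < 50))
    msg <- c(msg, "DEL requires len(ref) - len(alt) >= 50")
  if (any(mc$svtype == "INS" & -dd < 50))
    msg <- c(msg, "INS requires len(alt) - len(ref) >= 50")
  if (any(mc$svtype == "INV" & (nchar(mc$ref) < 50 | nchar(mc$alt) < 50)))
    msg <- c(msg, "INV requires both alleles >= 50 bp")
  if (length(msg)) msg else TRUE
})

#' Construct an SVCallSet from a call table
#'
#' @param table data.frame with columns \code{record_id}, \code{sample_id},
#'   \code{chrom}, \code{start} (0-based), \code{end} (0-based exclusive),
#'   \code{ref}, \code{alt}, \code{svtype}, \code{svlen}, \code{qual},
#'   \code{filter}, \code{genotype}.
#' @return an \linkS4class{SVCallSet}.
#' @export
SVCallSet <- function(table = emptyCallTable()) {
  stopifnot(is.data.frame(table))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(table$chrom),
    ranges = IRanges::IRanges(start = table$start + 1L,
                              end = as.integer(table$end)),
    recordID = as.character(table$record_id),
    sampleID = as.character(table$sample_id),
    ref = as.character(table$ref), alt = as.character(table$alt),
    svtype = as.character(table$svtype), svlen = as.integer(table$svlen),
    qual = as.numeric(table$qual), filter = as.character(table$filter),
    genotype = as.character(table$genotype))
  new("SVCallSet", calls = gr)
}

#' An empty call table with the canonical columns
#' @return zero-row data.frame in the package's call-table layout.
#' @export
emptyCallTable <- function() {
  data.frame(record_id = character(0), sample_id = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             ref = character(0), alt = character(0), svtype = character(0),
             svlen = integer(0), qual = numeric(0), filter = character(0),
             genotype = character(0), stringsAsFactors = FALSE)
}

#' CohortCallset: collapsed cohort sites with a dosage matrix
#'
#' Extends \link[SummarizedExperiment]{RangedSummarizedExperiment}: rows are
#' collapsed SV sites (ranges = reference spans; rowData carries
#' \code{siteID}, \code{svtype}, \code{svlen}, \code{ref}, \code{alt},
#' \code{qual}, \code{ac}, \code{af}, \code{n_called}), columns are samples
#' (colData = sample metadata), and the single assay \code{dosage} holds
#' alternate-allele dosages 0/1/2 with \code{NA} for missing genotypes.
#' Validity enforces af = ac / (2 x non-missing samples) per site.
#'
#' @export
setClass("CohortCallset", contains = "RangedSummarizedExperiment")

setValidity("CohortCallset", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (!all(d[!is.na(d)] %in% 0:2)) return("dosages must be 0, 1, 2 or NA")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("siteID", "svtype", "svlen", "ac", "af")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    return(paste("missing rowData columns:", paste(miss, collapse = ", ")))
  if (nrow(d)) {
    ac <- rowSums(d, na.rm = TRUE)
    nc <- rowSums(!is.na(d))
    af <- ifelse(nc > 0, ac / (2 * nc), NA_real_)
    if (!isTRUE(all.equal(unname(ac), as.numeric(rd$ac))))
      return("rowData ac inconsistent with dosage matrix")
    ok <- is.na(af) | abs(af - rd$af) < 1e-12
    if (!all(ok)) return("rowData af != ac / (2 * non-missing)")
  }
  TRUE
})
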