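#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("callTable", "SVCallSet", function(x) {
  gr <- x@calls
  mc <- S4Vectors::mcols(gr)
  data.frame(record_id = mc$recordID, sample_id = mc$sampleID,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             ref = mc$ref, alt = mc$alt, svtype = mc$svtype,
             svlen = mc$svlen, qual = mc$qual, filter = mc$filter,
             genotype = mc$genotype, stringsAsFactors = FALSE,
             row.names = NULL)
})

#' @rdname accessors
#' @export
setMethod("nCalls", "SVCallSet", function(x) length(x@calls))

setMethod("show", "SVCallSet", function(object) {
  tab <- callTable(object)
  cat(sprintf("SVCallSet with %d call(s)\n", nrow(tab)))
  if (nrow(tab)) {
    cat(sprintf("  samples: %d  chroms: %d\n",
                length(unique(tab$sample_id)), length(unique(tab$chrom))))
    tt <- table(factor(tab$svtype, levels = SV_TYPES))
    cat(sprintf("  DEL: %d  INS: %d  INV: %d\n", tt["DEL"], tt["INS"], tt["INV"]))
    cat(sprintf("  svlen: %d-%d bp  qual: %.1f-%.1f\n",
                min(tab$svlen), max(tab$svlen), min(tab$qual), max(tab$qual)))
  }
  invisible(NULL)
})

#' @rdname accessors
#' @export
setMethod("dosageMatrix", "CohortCallset", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("siteAF", "CohortCallset", function(x) {
  af <- SummarizedExperiment::rowData(x)$af
  names(af) <- SummarizedExperiment::rowData(x)$siteID
  af
})

#' @rdname accessors
#' @export
setMethod("siteAC", "CohortCallset", function(x) {
  ac <- SummarizedExperiment::rowData(x)$ac
  names(ac) <- SummarizedExperiment::rowData(x)$siteID
  ac
})

#' @rdname accessors
#' @export
setMethod("sampleMeta", "CohortCallset", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

setMethod("show", "CohortCallset", function(object) {
  cat(sprintf("CohortCallset: %d site(s) x %d sample(s)\n",
              nrow(object), ncol(object)))
  rd <- SummarizedExperiment::rowData(object)
  if (nrow(object)) {
    tt <- table(factor(rd$svtype, levels = SV_TYPES))
    cat(sprintf("  DEL: %d  INS: %d  INV: %d  singletons: %d\n",
                tt["DEL"], tt["INS"], tt["INV"], sum(rd$ac == 1)))
  }
  invisible(NULL)
})

setMethod("show", "MatchParams", function(object) {
  cat(sprintf(
    "MatchParams: seqSim %s %.2f, sizeSim %s %.2f, dist <= %d bp, sameType = %s\n",
    if (object@strict) ">" else ">=", object@seqSimMin,
    if (object@strict) ">" else ">=", object@sizeSimMin,
    as.integer(object@maxDist), object@requireSameType))
  invisible(NULL)
})
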