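#' @include AllClasses.R
NULL

#' Accessors for SV call sets and cohort callsets
#'
#' \code{callTable} returns the 0-based half-open call table of an
#' \linkS4class{SVCallSet}; \code{nCalls} its record count.
#' \code{dosageMatrix}, \code{siteAF}, \code{siteAC} and \code{sampleMeta}
#' expose the dosage assay, per-site alternate allele frequencies / counts
#' and the sample metadata of a \linkS4class{CohortCallset}.
#'
#' @param x an \linkS4class{SVCallSet} or \linkS4class{CohortCallset}.
#' @return \code{callTable}: data.frame; \code{nCalls}: integer;
#'   \code{dosageMatrix}: sites x samples integer matrix; \code{siteAF},
#'   \code{siteAC}: numeric vectors; \code{sampleMeta}: data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("callTable", function(x) standardGeneric("callTable"))

#' @rdname accessors
#' @export
setGeneric("nCalls", function(x) standardGeneric("nCalls"))

#' @rdname accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname accessors
#' @export
setGeneric("siteAF", function(x) standardGeneric("siteAF"))

#' @rdname accessors
#' @export
setGeneric("siteAC", function(x) standardGeneric("siteAC"))

#' @rdname accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))
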