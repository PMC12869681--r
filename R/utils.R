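#' @importFrom Biostrings DNAString reverseComplement
#' @importFrom methods new validObject is as
#' @importFrom stats pchisq pnorm qnorm pbinom p.adjust cor cor.test mad
#'   median rbinom rnorm runif rbeta binomial glm.fit kruskal.test dbeta
#'   qlogis plogis setNames sd var quantile rmultinom
#' @importFrom utils adist head
NULL

SV_TYPES <- c("DEL", "INS", "INV")
GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#'
#' Thin character-vector wrapper around Biostrings' reverse complement,
#' accepting A/C/G/T/N.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' reverseComplementSeq("ACGTN")
reverseComplementSeq <- function(x) {
  vapply(x, function(s) {
    as.character(reverseComplement(DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

## Levenshtein distance between two allele strings (C implementation in utils).
editDistance <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  as.integer(adist(a, b)[1L, 1L])
}

assertNucleotides <- function(x, what = "allele") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-nucleotide characters (allowed: A,C,G,T,N): %s",
                 what, x[which(bad)[1L]]), call. = FALSE)
  }
  invisible(TRUE)
}

## The sequence content compared between two calls: the deleted bases for a
## DEL, the inserted bases for an INS (leading shared base stripped in both
## cases), the full ALT for an INV.
variantSeq <- function(ref, alt, svtype) {
  switch(svtype,
    DEL = substring(ref, 2L),
    INS = substring(alt, 2L),
    INV = alt,
    alt)
}

clipP <- function(p) pmin(pmax(p, 1e-300), 1 - 1e-16)
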