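#' Infer the structural-variant type from resolved alleles
#'
#' An event is an inversion when both alleles are at least 50 bp and the
#' sequence similarity between the reference allele and the reverse
#' complement of the alternate allele reaches \code{invSimThreshold}
#' (default 80\%). The inversion rule takes precedence; otherwise the signed
#' allele-length difference classifies the event as a deletion or insertion
#' when it is at least 50 bp, and anything else is \code{UNRESOLVED}.
#'
#' @param ref,alt nonempty nucleotide strings (A/C/G/T/N).
#' @param invSimThreshold minimum reference vs reverse-complement(alt)
#'   similarity for an inversion call.
#' @return one of \code{"DEL"}, \code{"INS"}, \code{"INV"},
#'   \code{"UNRESOLVED"}.
#' @export
#' @examples
#' s <- strrep("ACGTT", 12)
#' inferSVType(s, reverseComplementSeq(s))   # INV
#' inferSVType("A", paste0("A", strrep("T", 119)))  # INS
inferSVType <- function(ref, alt, invSimThreshold = 0.80) {
  stopifnot(nchar(ref) > 0, nchar(alt) > 0)
  assertNucleotides(ref, "ref"); assertNucleotides(alt, "alt")
  if (nchar(ref) >= 50 && nchar(alt) >= 50 &&
      seqSimilarity(ref, reverseComplementSeq(alt)) >= invSimThreshold)
    return("INV")
  d <- nchar(ref) - nchar(alt)
  if (d >= 50) return("DEL")
  if (-d >= 50) return("INS")
  "UNRESOLVED"
}

decodeGT <- function(gt) {
  al <- strsplit(sub(":.*", "", gt), "[/|]")
  vapply(al, function(a) {
    if (length(a) == 0L || any(a == ".") || any(is.na(a))) return("missing")
    n <- sum(a != "0")
    c("hom_ref", "het", "hom_alt")[n + 1L]
  }, character(1))
}

#' Read per-sample SV calls from a VCF file
#'
#' Parses a single-sample VCF with sequence-resolved REF/ALT alleles,
#' keeping only records with FILTER \code{PASS} and an inferred SV length of
#' at least \code{minLen} (default 50 bp). Multi-allelic records are split
#' into one record per ALT before filtering; symbolic or breakend ALTs
#' (\code{<DEL>}, \code{]}...) are skipped with a warning since sequence
#' resolution is required. VCF 1-based POS is converted to the internal
#' 0-based half-open convention and GT is decoded to
#' hom_ref/het/hom_alt/missing. Record order is preserved.
#'
#' @param path path to a VCF file.
#' @param minLen minimum SV length in bp.
#' @param sampleID sample identifier; defaults to the VCF sample column name.
#' @return an \linkS4class{SVCallSet}.
#' @export
readSVVcf <- function(path, minLen = 50, sampleID = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  checkVcfLines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = FALSE)
  if (is.null(fix) || nrow(as.matrix(fix)) == 0L) {
    out <- SVCallSet()
    attr(out, "n_symbolic_skipped") <- 0L
    return(out)
  }
  fix <- matrix(as.matrix(fix), ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  gtmat <- v@gt
  if (is.null(gtmat) || ncol(gtmat) < 2L)
    stop("VCF must carry one sample column with GT")
  vcfSample <- colnames(gtmat)[2L]
  sampleID <- sampleID %||% vcfSample
  gtRaw <- gtmat[, 2L]

  rows <- list(); nSymbolic <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    ref <- toupper(fix[i, "REF"])
    gts <- decodeGTMulti(gtRaw[i], length(alts))
    for (k in seq_along(alts)) {
      alt <- toupper(alts[k])
      if (grepl("[<>]|\\[|\\]", alt)) { nSymbolic <- nSymbolic + 1L; next }
      if (fix[i, "FILTER"] != "PASS") next
      svtype <- inferSVType(ref, alt)
      if (svtype == "UNRESOLVED") next
      svlen <- if (svtype == "INV") nchar(ref) else abs(nchar(ref) - nchar(alt))
      if (svlen < minLen) next
      pos1 <- as.integer(fix[i, "POS"])
      id <- fix[i, "ID"]
      if (is.na(id) || id == ".")
        id <- sprintf("%s_%s_%d_%d", sampleID, fix[i, "CHROM"], pos1, k)
      qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = id, sample_id = sampleID, chrom = fix[i, "CHROM"],
        start = pos1 - 1L, end = pos1 - 1L + nchar(ref),
        ref = ref, alt = alt, svtype = svtype, svlen = as.integer(svlen),
        qual = if (is.na(qual)) 0 else qual, filter = fix[i, "FILTER"],
        genotype = gts[k], stringsAsFactors = FALSE)
    }
  }
  if (nSymbolic > 0L)
    warning(sprintf("%d symbolic/breakend ALT allele(s) skipped in %s",
                    nSymbolic, basename(path)))
  tab <- if (length(rows)) do.call(rbind, rows) else emptyCallTable()
  out <- SVCallSet(tab)
  validObject(out)
  attr(out, "n_symbolic_skipped") <- nSymbolic
  out
}

## genotype of each split ALT allele: count occurrences of its allele index
decodeGTMulti <- function(gt, nAlt) {
  a <- strsplit(sub(":.*", "", gt), "[/|]")[[1L]]
  vapply(seq_len(nAlt), function(k) {
    if (length(a) == 0L || any(a == ".") || any(is.na(a))) return("missing")
    n <- sum(a == as.character(k))
    c("hom_ref", "het", "hom_alt")[n + 1L]
  }, character(1))
}

## light structural check so malformed lines fail with a line number
## (the heavy parse is delegated to vcfR)
checkVcfLines <- function(path) {
  ln <- readLines(path, warn = FALSE)
  body <- which(!startsWith(ln, "#") & nzchar(ln))
  for (i in body) {
    f <- strsplit(ln[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L || is.na(suppressWarnings(as.integer(f[2L]))))
      stop(sprintf("malformed VCF line %d in %s", i, basename(path)),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Write SV calls to a VCF file
#'
#' Serializes an \linkS4class{SVCallSet} (or call table) as plain-text
#' VCF 4.2 with INFO keys SVTYPE, SVLEN and END and a single GT sample
#' column. Coordinates are re-converted to 1-based POS; END is the 1-based
#' inclusive reference-span end. \code{readSVVcf(writeSVVcf(x))} is the
#' identity for PASS records of at least 50 bp.
#'
#' @param x an \linkS4class{SVCallSet} or call table, sorted by
#'   (chrom, start); unsorted input is an error.
#' @param path output path.
#' @param sampleID sample column name; defaults to the records' sample id.
#' @return \code{path}, invisibly.
#' @export
writeSVVcf <- function(x, path, sampleID = NULL) {
  tab <- if (is(x, "SVCallSet")) callTable(x) else x
  if (nrow(tab)) {
    o <- order(tab$chrom, tab$start)
    if (!identical(o, seq_len(nrow(tab))))
      stop("records must be sorted by (chrom, start)")
    sampleID <- sampleID %||% tab$sample_id[1L]
  } else sampleID <- sampleID %||% "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svcohort",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Reference span end\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sampleID))
  gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
          missing = "./.")[tab$genotype]
  lines <- character(0)
  if (nrow(tab)) {
    signedLen <- ifelse(tab$svtype == "DEL", -tab$svlen, tab$svlen)
    lines <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\tSVTYPE=%s;SVLEN=%d;END=%d\tGT\t%s",
                     tab$chrom, tab$start + 1L, tab$record_id, tab$ref, tab$alt,
                     format(tab$qual, digits = 15, trim = TRUE, scientific = FALSE),
                     tab$filter, tab$svtype, signedLen, tab$end, gt)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
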