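siteQueryRanges <- function(rd) {
  ## DEL/INV are annotated by their full reference span; an INS only by the
  ## single anchor base at which it is reported
  start1 <- ifelse(rd$svtype == "INS", rd$start + 1L, rd$start + 1L)
  end1 <- ifelse(rd$svtype == "INS", rd$start + 1L, rd$end)
  GenomicRanges::GRanges(rd$chrom,
                         IRanges::IRanges(start = start1, end = end1))
}

rowDataFrame <- function(callset) {
  rd <- as.data.frame(SummarizedExperiment::rowData(callset))
  gr <- SummarizedExperiment::rowRanges(callset)
  rd$chrom <- as.character(GenomicRanges::seqnames(gr))
  rd$start <- GenomicRanges::start(gr) - 1L
  rd$end <- GenomicRanges::end(gr)
  rd
}

#' Intersect cohort sites with a known-SV catalog
#'
#' DEL/INV sites match a same-type catalog entry when their reciprocal
#' overlap (intersection over the longer span) reaches
#' \code{delInvRecipOverlap}; INS sites match a catalog INS when the anchor
#' distance is at most \code{insMaxDist} and the size similarity reaches
#' \code{insSizeSim} (relaxed because catalog insertion lengths are often
#' approximate). A site is known when matched in at least one catalog.
#'
#' @param callset a \linkS4class{CohortCallset}.
#' @param catalog data.frame: \code{source}, \code{chrom}, \code{start}
#'   (0-based), \code{end}, \code{svtype}, optional \code{svlen}, optional
#'   \code{af}.
#' @param delInvRecipOverlap reciprocal-overlap threshold for DEL/INV.
#' @param insMaxDist,insSizeSim INS matching parameters.
#' @return data.frame per site: \code{site_id}, \code{known},
#'   \code{sources} (comma-separated), \code{matched_af} (AF of the best
#'   match, NA if none/absent).
#' @export
intersectCatalog <- function(callset, catalog, delInvRecipOverlap = 0.5,
                             insMaxDist = 1000, insSizeSim = 0.5) {
  rd <- rowDataFrame(callset)
  if (is.null(catalog$svlen)) catalog$svlen <- catalog$end - catalog$start
  if (is.null(catalog$af)) catalog$af <- NA_real_
  known <- logical(nrow(rd)); sources <- character(nrow(rd))
  matchedAF <- rep(NA_real_, nrow(rd))
  for (i in seq_len(nrow(rd))) {
    cand <- catalog[catalog$chrom == rd$chrom[i] &
                      catalog$svtype == rd$svtype[i], , drop = FALSE]
    if (!nrow(cand)) next
    if (rd$svtype[i] %in% c("DEL", "INV")) {
      inter <- pmax(0, pmin(rd$end[i], cand$end) - pmax(rd$start[i], cand$start))
      longer <- pmax(rd$end[i] - rd$start[i], cand$end - cand$start)
      score <- inter / longer
      hit <- score >= delInvRecipOverlap
    } else {
      dist <- abs(cand$start - rd$start[i])
      ssim <- pmin(rd$svlen[i], cand$svlen) / pmax(rd$svlen[i], cand$svlen)
      score <- -dist
      hit <- dist <= insMaxDist & ssim >= insSizeSim
    }
    if (any(hit)) {
      known[i] <- TRUE
      sources[i] <- paste(sort(unique(cand$source[hit])), collapse = ",")
      best <- which(hit)[which.max(score[hit])]
      matchedAF[i] <- cand$af[best]
    }
  }
  data.frame(site_id = rd$siteID, known = known, sources = sources,
             matched_af = matchedAF, stringsAsFactors = FALSE)
}

#' Allele-frequency concordance with a catalog
#'
#' Squared Pearson correlation between cohort and catalog allele
#' frequencies over matched common sites (cohort AF at or above
#' \code{minAF}, catalog AF present), with the two-sided p-value for zero
#' correlation.
#'
#' @param cohortAF,catalogAF paired numeric AF vectors (matched sites).
#' @param minAF cohort common-site threshold (default 0.01).
#' @return list: \code{r2}, \code{p}, \code{n}.
#' @export
afConcordance <- function(cohortAF, catalogAF, minAF = 0.01) {
  keep <- !is.na(catalogAF) & !is.na(cohortAF) & cohortAF >= minAF
  x <- cohortAF[keep]; y <- catalogAF[keep]
  if (length(x) < 3) stop("need at least 3 matched common sites")
  ct <- cor.test(x, y, method = "pearson")
  list(r2 = unname(ct$estimate^2), p = ct$p.value, n = length(x))
}

#' Read gene models from a GFF3 file
#'
#' Imports a GFF3 of one representative transcript per gene and returns the
#' flat interval table used by \code{\link{annotateGenes}}: one row per
#' feature with \code{gene_id}, \code{feature} (gene, exon, cds, utr5,
#' utr3), and 0-based half-open coordinates.
#'
#' @param path GFF3 file path.
#' @return data.frame: \code{gene_id}, \code{feature}, \code{chrom},
#'   \code{start}, \code{end}.
#' @export
readGeneModels <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read GFF3 gene models")
  gr <- rtracklayer::import(path, format = "gff3")
  typeMap <- c(gene = "gene", exon = "exon", CDS = "cds",
               five_prime_UTR = "utr5", three_prime_UTR = "utr3")
  keep <- as.character(gr$type) %in% names(typeMap)
  gr <- gr[keep]
  gid <- gr$gene_id %||% gr$ID
  if (is.null(gid)) gid <- gr$Parent
  data.frame(gene_id = as.character(gid),
             feature = unname(typeMap[as.character(gr$type)]),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Annotate cohort sites against gene models
#'
#' Classifies each site as \code{gene_overlap} (reference span — anchor
#' base for insertions — intersects a gene body), \code{proximal_5kb}
#' (nearest gene within \code{proximity} bp but no overlap) or
#' \code{intergenic}; the classes are mutually exclusive and exhaustive.
#' For overlapping sites all intersected feature types are listed, with
#' \code{intron} added when part of the within-gene overlap is not covered
#' by the gene's exons.
#'
#' @param callset a \linkS4class{CohortCallset}.
#' @param geneModels interval table as from \code{\link{readGeneModels}}.
#' @param proximity proximity window in bp (default 5000).
#' @return data.frame per site: \code{site_id}, \code{class},
#'   \code{features} (comma-separated), \code{gene_ids} (comma-separated).
#' @export
annotateGenes <- function(callset, geneModels, proximity = 5000) {
  rd <- rowDataFrame(callset)
  gm <- geneModels
  bodies <- gm[gm$feature == "gene", , drop = FALSE]
  cls <- character(nrow(rd)); feats <- character(nrow(rd))
  gids <- character(nrow(rd))
  qs <- ifelse(rd$svtype == "INS", rd$start, rd$start)
  qe <- ifelse(rd$svtype == "INS", rd$start + 1L, rd$end)
  for (i in seq_len(nrow(rd))) {
    bi <- bodies$chrom == rd$chrom[i] & bodies$start < qe[i] &
      bodies$end > qs[i]
    if (any(bi)) {
      cls[i] <- "gene_overlap"
      genes <- bodies$gene_id[bi]
      gids[i] <- paste(sort(unique(genes)), collapse = ",")
      ff <- character(0)
      for (g in unique(genes)) {
        sub <- gm[gm$gene_id == g & gm$chrom == rd$chrom[i], , drop = FALSE]
        ov <- sub$feature[sub$start < qe[i] & sub$end > qs[i] &
                            sub$feature != "gene"]
        ff <- c(ff, ov)
        ## intron: some of the overlap with the gene body is not exonic
        body <- sub[sub$feature == "gene", , drop = FALSE]
        inS <- max(qs[i], body$start[1L]); inE <- min(qe[i], body$end[1L])
        ex <- sub[sub$feature == "exon", , drop = FALSE]
        covered <- 0L
        if (nrow(ex))
          covered <- sum(pmax(0L, pmin(inE, ex$end) - pmax(inS, ex$start)))
        if (covered < inE - inS) ff <- c(ff, "intron")
      }
      feats[i] <- paste(sort(unique(ff)), collapse = ",")
    } else {
      near <- bodies[bodies$chrom == rd$chrom[i], , drop = FALSE]
      d <- if (nrow(near)) {
        min(pmax(near$start - qe[i], qs[i] - near$end))
      } else Inf
      cls[i] <- if (d <= proximity) "proximal_5kb" else "intergenic"
      if (cls[i] == "proximal_5kb") {
        nb <- near[pmax(near$start - qe[i], qs[i] - near$end) <= proximity, ]
        gids[i] <- paste(sort(unique(nb$gene_id)), collapse = ",")
      }
    }
  }
  data.frame(site_id = rd$siteID, class = cls, features = feats,
             gene_ids = gids, stringsAsFactors = FALSE)
}

#' Candidate-gene report of common gene-body SVs
#'
#' Filters to sites with AF at or above \code{minAF} whose features include
#' at least one non-intron feature of a listed gene.
#'
#' @param callset a \linkS4class{CohortCallset}.
#' @param annotations output of \code{\link{annotateGenes}}.
#' @param geneList nonempty character vector of genes of interest.
#' @param minAF common-variant threshold (default 0.01).
#' @param excludeIntronicOnly drop sites whose only gene feature is intron.
#' @return data.frame: \code{gene}, \code{site_id}, \code{svtype},
#'   \code{svlen}, \code{af}.
#' @export
candidateGeneReport <- function(callset, annotations, geneList,
                                minAF = 0.01, excludeIntronicOnly = TRUE) {
  stopifnot(length(geneList) > 0)
  rd <- rowDataFrame(callset)
  ann <- annotations[match(rd$siteID, annotations$site_id), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(rd))) {
    if (is.na(rd$af[i]) || rd$af[i] < minAF) next
    if (ann$class[i] != "gene_overlap") next
    ff <- strsplit(ann$features[i], ",", fixed = TRUE)[[1L]]
    if (excludeIntronicOnly && all(ff == "intron")) next
    genes <- intersect(strsplit(ann$gene_ids[i], ",", fixed = TRUE)[[1L]],
                       geneList)
    for (g in genes)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, site_id = rd$siteID[i], svtype = rd$svtype[i],
        svlen = rd$svlen[i], af = rd$af[i], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene = character(0), site_id = character(0),
                      svtype = character(0), svlen = integer(0),
                      af = numeric(0)))
  do.call(rbind, rows)
}
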