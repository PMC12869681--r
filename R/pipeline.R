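#' Default pipeline parameters
#'
#' Every stage threshold with its default: 50 bp minimum length and PASS at
#' ingestion, 0.80 inversion similarity, strict 0.70 replicate-concordance
#' similarity, quality score 50, 0.95/0.95 within 1000 bp for collapsing,
#' 2\% sample-outlier fraction, MAF 1\% + Bonferroni HWE + r2 0.1 pruning
#' for PCA, MAF 0.5\% for single-variant tests, r2 0.4 tag-LD scan, 5 kbp
#' gene proximity, MAF 1\% / cMAC 10 for rare-variant sets, and reporting
#' thresholds 1e-7 (gene Bonferroni) / 1e-5 (suggestive).
#'
#' @param ... named overrides.
#' @return named list of parameters.
#' @export
pipelineParams <- function(...) {
  p <- list(minLen = 50, invSim = 0.80, repSim = 0.70, qualMin = 50,
            calibrateQual = TRUE, collapseSeqSim = 0.95,
            collapseSizeSim = 0.95, collapseMaxDist = 1000,
            outlierFraction = 0.02, studyAlpha = 0.05, readLength = NULL,
            pcaMafMin = 0.01, pcaPruneR2 = 0.1, nPCs = 5,
            assocMafMin = 0.005, tagR2Min = 0.4, proximity = 5000,
            rareMafMax = 0.01, cmacMin = 10, geneBonf = 1e-7,
            suggestive = 1e-5, weightMode = "beta")
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

## map a position/type-keyed raw score table onto collapsed site ids
matchScoreTable <- function(callset, rawScores, maxDist = 1000) {
  rd <- rowDataFrame(callset)
  rows <- list()
  for (i in seq_len(nrow(rd))) {
    hit <- rawScores$chrom == rd$chrom[i] &
      rawScores$svtype == rd$svtype[i] &
      abs(rawScores$start - rd$start[i]) <= maxDist
    if (!any(hit)) next
    sub <- rawScores[hit, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      sv_id = rd$siteID[i], gene_id = sub$gene_id, score = sub$score,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sv_id = character(0), gene_id = character(0),
                      score = numeric(0)))
  do.call(rbind, rows)
}

covariateMatrix <- function(meta, scores, nPCs) {
  X <- cbind(intercept = 1,
             sex_male = as.numeric(meta$sex == "male"),
             pcr_free = as.numeric(meta$pcr_free))
  cen <- as.factor(meta$center)
  if (nlevels(cen) > 1)
    X <- cbind(X, stats::model.matrix(~cen)[, -1, drop = FALSE])
  if (!is.null(scores)) {
    k <- min(nPCs, ncol(scores))
    X <- cbind(X, scores[, seq_len(k), drop = FALSE])
  }
  ## drop constant non-intercept columns (a stratified subgroup may have
  ## only one centre or one sex)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) var(v) > 0))
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
}

#' Run the full SV cohort pipeline on a fixture bundle
#'
#' Executes the stages in order: VCF ingestion, replicate-concordance QC
#' and quality-threshold calibration, the quality filter, sample/study
#' outlier QC, replicate reduction and cohort collapsing, catalog and gene
#' annotation, PCA with the PC-vs-batch screen, per-ancestry single-variant
#' association with Stouffer meta-analysis, the tag-SNP LD scan with
#' conditional tests, and per-ancestry gene-based rare-variant tests with
#' BH FDR. Writes stage outputs and a manifest of per-stage counts and
#' output-file MD5 hashes to \code{outDir}; reruns on identical inputs
#' produce identical manifests.
#'
#' @param bundleDir a fixture bundle directory
#'   (\code{\link{writeFixtureBundle}} layout).
#' @param outDir output directory (created; overwritten when rerun).
#' @param params a \code{\link{pipelineParams}} list.
#' @return the manifest list, invisibly; also written as
#'   \code{manifest.json}.
#' @export
runPipeline <- function(bundleDir, outDir, params = pipelineParams()) {
  for (f in c("meta.tsv", "genes.gff3", "catalog.tsv"))
    if (!file.exists(file.path(bundleDir, f)))
      stop("missing pipeline input: ", f)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(params = params, stages = list())
  meta <- utils::read.delim(file.path(bundleDir, "meta.tsv"),
                            stringsAsFactors = FALSE)
  meta$sample_id <- as.character(meta$sample_id)

  ## ingest
  vcfs <- sort(list.files(file.path(bundleDir, "vcf"), full.names = TRUE,
                          pattern = "\\.vcf$"))
  if (!length(vcfs)) stop("missing pipeline input: vcf/")
  callsets <- lapply(vcfs, readSVVcf, minLen = params$minLen)
  calls <- do.call(rbind, lapply(callsets, callTable))
  manifest$stages$ingest <- list(n_files = length(vcfs),
                                 n_records = nrow(calls))

  ## replicate QC + quality threshold
  qualMin <- params$qualMin
  dupInds <- names(which(table(meta$individual_id) > 1))
  pairReports <- list()
  if (params$calibrateQual && length(dupInds)) {
    for (ind in dupInds) {
      sids <- meta$sample_id[meta$individual_id == ind]
      for (a in seq_along(sids)) for (b in seq_along(sids)) {
        if (b <= a) next
        pairReports[[length(pairReports) + 1L]] <- classifyReplicateCalls(
          calls[calls$sample_id == sids[a], , drop = FALSE],
          calls[calls$sample_id == sids[b], , drop = FALSE],
          simMin = params$repSim, maxDist = params$collapseMaxDist)
      }
    }
    consQ <- unlist(lapply(pairReports, `[[`, "consistent_quals"))
    incQ <- unlist(lapply(pairReports, `[[`, "inconsistent_quals"))
    if (length(consQ) && length(incQ))
      qualMin <- calibrateQualityThreshold(consQ, incQ)$threshold
  }
  manifest$stages$replicate_qc <- list(
    n_pairs = length(pairReports), qual_threshold = qualMin,
    n_consistent = sum(vapply(pairReports, `[[`, numeric(1), "n_consistent")),
    n_inconsistent = sum(vapply(pairReports, `[[`, numeric(1),
                                "n_inconsistent")))

  qf <- applyQualityFilter(calls, t = qualMin)
  manifest$stages$quality_filter <- list(
    raw = nrow(calls), removed = qf$removed_count,
    retained = nrow(qf$passed))
  calls <- qf$passed

  ## sample/study QC
  counts <- sampleTypeCounts(calls)
  dropped <- character(0)
  if (nrow(counts) >= 50) {
    flagged <- detectOutlierSamples(counts, params$outlierFraction)
    badStudies <- flagOutlierStudies(flagged, meta, params$studyAlpha)
    dropped <- meta$sample_id[meta$study %in% badStudies]
    meta <- meta[!meta$sample_id %in% dropped, , drop = FALSE]
    calls <- calls[!calls$sample_id %in% dropped, , drop = FALSE]
    manifest$stages$sample_qc <- list(
      n_flagged = length(flagged), studies_dropped = as.character(badStudies),
      samples_dropped = length(dropped))
  } else {
    manifest$stages$sample_qc <- list(skipped = "fewer than 50 samples")
  }

  ## one sample per individual: keep the highest call count
  counts <- sampleTypeCounts(calls)
  tot <- counts$n_del + counts$n_ins + counts$n_inv
  names(tot) <- counts$sample_id
  keep <- vapply(split(meta$sample_id, meta$individual_id), function(s) {
    s[order(-tot[s], s)][1L]
  }, character(1))
  meta <- meta[meta$sample_id %in% keep, , drop = FALSE]
  calls <- calls[calls$sample_id %in% keep, , drop = FALSE]

  ## collapse + cohort
  mp <- matchParams(params$collapseSeqSim, params$collapseSizeSim,
                    params$collapseMaxDist)
  cohort <- buildCohort(calls, meta, mp, readLength = params$readLength)
  manifest$stages$cohort <- list(n_sites = nrow(cohort),
                                 n_samples = ncol(cohort),
                                 composition = typeComposition(cohort))
  writeTsv(cbind(rowDataFrame(cohort)), file.path(outDir, "sites.tsv"))
  writeTsv(as.data.frame(dosageMatrix(cohort)),
           file.path(outDir, "dosage.tsv"), rowNames = TRUE)

  ## annotation
  geneModels <- readGeneModels(file.path(bundleDir, "genes.gff3"))
  catalog <- utils::read.delim(file.path(bundleDir, "catalog.tsv"),
                               stringsAsFactors = FALSE)
  known <- intersectCatalog(cohort, catalog)
  conc <- tryCatch(
    afConcordance(siteAF(cohort), known$matched_af),
    error = function(e) list(r2 = NA_real_, p = NA_real_, n = 0))
  ann <- annotateGenes(cohort, geneModels, proximity = params$proximity)
  manifest$stages$annotate <- list(
    frac_known = mean(known$known), af_concordance_r2 = conc$r2,
    class_counts = as.list(table(ann$class)))
  writeTsv(merge(known, ann, by = "site_id"),
           file.path(outDir, "annotation.tsv"))

  ## PCA + batch screen
  pca <- tryCatch(svPCA(cohort, mafMin = params$pcaMafMin,
                        K = max(params$nPCs, 2),
                        pruneR2 = params$pcaPruneR2),
                  error = function(e) NULL)
  if (!is.null(pca)) {
    screen <- tryCatch(pcBatchScreen(pca$scores, sampleMeta(cohort)$center),
                       error = function(e) NULL)
    manifest$stages$pca <- list(
      n_sites_used = length(pca$kept_sites),
      var_explained = round(pca$var_explained, 4),
      separated_pcs = if (!is.null(screen))
        screen$pc[screen$separated] else character(0))
  } else manifest$stages$pca <- list(skipped = "no sites after filters")

  ## single-variant association per ancestry + meta
  sm <- sampleMeta(cohort)
  y <- as.numeric(sm$status == "case")
  D <- dosageMatrix(cohort)
  assocTabs <- list()
  for (anc in sort(unique(sm$ancestry))) {
    sel <- sm$ancestry == anc
    if (sum(sel) < 20 || length(unique(y[sel])) < 2) next
    Danc <- D[, sel, drop = FALSE]
    af <- rowMeans(Danc, na.rm = TRUE) / 2
    maf <- pmin(af, 1 - af)
    testable <- which(maf > params$assocMafMin)
    if (!length(testable)) next
    Xa <- covariateMatrix(sm[sel, ], if (!is.null(pca))
      pca$scores[sel, , drop = FALSE] else NULL, params$nPCs)
    res <- lapply(testable, function(i) {
      r <- tryCatch(
        logisticAssoc(y[sel], as.numeric(Danc[i, ]), Xa,
                      siteID = rownames(D)[i]),
        error = function(e) NULL)
      r
    })
    res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
    if (is.null(res) || !nrow(res)) next
    res$ancestry <- anc
    res$bonferroni <- bonferroniThreshold(nrow(res))
    assocTabs[[anc]] <- res
  }
  assoc <- if (length(assocTabs)) do.call(rbind, assocTabs) else NULL
  metaRows <- NULL
  if (length(assocTabs) >= 2) {
    allSites <- unique(unlist(lapply(assocTabs, `[[`, "site_id")))
    rows <- list()
    for (s in allSites) {
      zs <- c(); ns <- c()
      for (anc in names(assocTabs)) {
        r <- assocTabs[[anc]]
        i <- match(s, r$site_id)
        if (!is.na(i) && is.finite(r$z[i])) {
          zs <- c(zs, r$z[i]); ns <- c(ns, r$n[i])
        }
      }
      if (length(zs) >= 2) {
        mres <- stoufferMeta(zs, ns)
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = s, n_groups = length(zs), z_meta = mres$z_meta,
          p_meta = mres$p_meta, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) metaRows <- do.call(rbind, rows)
  }
  manifest$stages$assoc_single <- list(
    n_tested = if (is.null(assoc)) 0 else nrow(assoc),
    n_meta = if (is.null(metaRows)) 0 else nrow(metaRows))
  if (!is.null(assoc)) writeTsv(assoc, file.path(outDir, "assoc_single.tsv"))
  if (!is.null(metaRows)) writeTsv(metaRows, file.path(outDir, "assoc_meta.tsv"))

  ## tag-SNP LD scan + conditional tests
  tagPath <- file.path(bundleDir, "tagsnp.tsv")
  if (file.exists(tagPath)) {
    tg <- utils::read.delim(tagPath, stringsAsFactors = FALSE)
    snp <- tg$snp_dosage[match(colnames(D), tg$sample_id)]
    ok <- !is.na(snp)
    svd <- t(D[, ok, drop = FALSE])
    scan <- tagLDScan(svd, matrix(snp[ok], ncol = 1,
                                  dimnames = list(NULL, "tagSNP")),
                      r2Min = params$tagR2Min)
    cond <- NULL
    if (nrow(scan)) {
      Xc <- covariateMatrix(sm[ok, ], if (!is.null(pca))
        pca$scores[ok, , drop = FALSE] else NULL, params$nPCs)
      cond <- do.call(rbind, lapply(scan$sv, function(s) {
        tryCatch(conditionalAssoc(y[ok], as.numeric(D[s, ok]), Xc,
                                  gCond = snp[ok], siteID = s),
                 error = function(e)
                   data.frame(site_id = s, n = sum(ok), beta = NA, se = NA,
                              or_ = NA, ci_low = NA, ci_high = NA, z = NA,
                              p = NA, method = "collinear"))
      }))
    }
    manifest$stages$tag_ld <- list(n_pairs = nrow(scan),
                                   max_r2 = if (nrow(scan)) max(scan$r2) else NA)
    if (nrow(scan)) writeTsv(scan, file.path(outDir, "tag_ld.tsv"))
    if (!is.null(cond)) writeTsv(cond, file.path(outDir, "tag_conditional.tsv"))
  }

  ## gene-based rare-variant tests
  scorePath <- file.path(bundleDir, "pathogenicity.tsv")
  geneTab <- NULL
  if (file.exists(scorePath)) {
    rawScores <- utils::read.delim(scorePath, stringsAsFactors = FALSE)
    scoreTable <- matchScoreTable(cohort, rawScores)
    svCls <- suppressWarnings(classifySV(cohort, geneModels, scoreTable))
    rows <- list()
    for (anc in sort(unique(sm$ancestry))) {
      sel <- sm$ancestry == anc
      if (sum(sel) < 20 || length(unique(y[sel])) < 2) next
      svd <- t(D[, sel, drop = FALSE])
      sets <- buildVariantSets(svd, svCls, mafMax = params$rareMafMax,
                               cmacMin = params$cmacMin,
                               weightMode = params$weightMode)
      if (!length(sets)) next
      Xa <- covariateMatrix(sm[sel, ], if (!is.null(pca))
        pca$scores[sel, , drop = FALSE] else NULL, params$nPCs)
      null <- fitNullLogistic(y[sel], Xa)
      for (vs in sets) {
        r <- smmatE(vs, null = null)
        rows[[length(rows) + 1L]] <- data.frame(
          ancestry = anc, gene = vs@geneID, category = vs@category,
          n_variants = ncol(vs@G), cmac = vs@cmac, p = r$p,
          p_burden = r$p_burden, p_adj = r$p_adj, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      geneTab <- do.call(rbind, rows)
      for (anc in unique(geneTab$ancestry)) {
        i <- geneTab$ancestry == anc
        geneTab$q[i] <- bhFDR(geneTab$p[i])
      }
      writeTsv(geneTab, file.path(outDir, "assoc_gene.tsv"))
    }
  }
  manifest$stages$assoc_gene <- list(
    n_sets = if (is.null(geneTab)) 0 else nrow(geneTab),
    n_suggestive = if (is.null(geneTab)) 0 else
      sum(geneTab$p < params$suggestive))

  outFiles <- sort(list.files(outDir, pattern = "\\.tsv$"))
  manifest$outputs <- as.list(tools::md5sum(file.path(outDir, outFiles)))
  names(manifest$outputs) <- outFiles
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE,
                       dataframe = "columns")
  invisible(manifest)
}

writeTsv <- function(df, path, rowNames = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = rowNames)
  invisible(path)
}
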