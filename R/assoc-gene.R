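CODING_CATEGORIES <- c("pLoF", "missense", "disruptive_missense",
                       "pLoF_plus_disruptive", "synonymous")
NONCODING_CATEGORIES <- c("promoter_cage", "enhancer_cage", "promoter_dhs",
                          "enhancer_dhs", "utr", "upstream", "downstream",
                          "ncRNA")

#' VariantSet: one gene/category rare-variant aggregate
#'
#' Members are rare variants (SNVs/INDELs and/or pathogenic SVs) of one
#' gene and functional category, with aligned dosage columns, per-variant
#' MAF and test weights. The cumulative minor allele count (cMAC) is the
#' sum of member minor-allele counts; sets below the cMAC floor are
#' excluded from testing upstream.
#'
#' @slot geneID gene identifier.
#' @slot category functional category label.
#' @slot variantIDs member variant ids.
#' @slot G samples x members dosage matrix.
#' @slot maf per-member minor allele frequency.
#' @slot weights per-member test weights.
#' @slot isSV logical per member.
#' @slot cmac cumulative minor allele count.
#' @export
setClass("VariantSet",
  representation(geneID = "character", category = "character",
                 variantIDs = "character", G = "matrix", maf = "numeric",
                 weights = "numeric", isSV = "logical", cmac = "numeric"))

setValidity("VariantSet", function(object) {
  m <- ncol(object@G)
  if (length(object@variantIDs) != m || length(object@maf) != m ||
      length(object@weights) != m || length(object@isSV) != m)
    return("member vectors must match the dosage columns")
  if (any(object@maf >= 0.5)) return("member MAF must be the minor frequency")
  cm <- sum(colSums(object@G, na.rm = TRUE))
  if (!isTRUE(all.equal(cm, object@cmac)))
    return("cmac inconsistent with dosages")
  TRUE
})

setMethod("show", "VariantSet", function(object) {
  cat(sprintf("VariantSet %s / %s: %d member(s) (%d SV), cMAC %g\n",
              object@geneID, object@category, ncol(object@G),
              sum(object@isSV), object@cmac))
  invisible(NULL)
})

variantWeights <- function(maf, mode = c("beta", "maf")) {
  mode <- match.arg(mode)
  if (mode == "beta") dbeta(maf, 1, 25) else maf
}

#' Classify SVs as coding/noncoding and pathogenic/benign
#'
#' An SV is coding for a gene when its reference span overlaps at least
#' 1 bp of that gene's exons (representative transcript). Coding SVs are
#' scored against their overlapped genes; noncoding SVs against genes
#' within \code{noncodingWindow} (default 1 Mb) of the SV. Scores come
#' from a per-(SV, gene) pathogenicity table in [0, 1]; a score of at
#' least 0.5 is pathogenic. SV/gene pairs absent from the table are benign
#' with a warning.
#'
#' @param callset a \linkS4class{CohortCallset}.
#' @param geneModels interval table as from \code{\link{readGeneModels}}.
#' @param scoreTable data.frame: \code{sv_id}, \code{gene_id},
#'   \code{score}.
#' @param noncodingWindow search window for noncoding SV-gene pairs in bp.
#' @return data.frame, one row per (SV, gene): \code{sv_id},
#'   \code{gene_id}, \code{score}, \code{is_pathogenic}, \code{is_coding}.
#' @export
classifySV <- function(callset, geneModels, scoreTable,
                       noncodingWindow = 1e6) {
  rd <- rowDataFrame(callset)
  ex <- geneModels[geneModels$feature == "exon", , drop = FALSE]
  bodies <- geneModels[geneModels$feature == "gene", , drop = FALSE]
  rows <- list(); nMissing <- 0L
  for (i in seq_len(nrow(rd))) {
    qs <- rd$start[i]; qe <- rd$end[i]
    exHit <- unique(ex$gene_id[ex$chrom == rd$chrom[i] & ex$start < qe &
                                 ex$end > qs])
    isCoding <- length(exHit) > 0
    genes <- if (isCoding) exHit else {
      bi <- bodies$chrom == rd$chrom[i] &
        bodies$start < qe + noncodingWindow &
        bodies$end > qs - noncodingWindow
      unique(bodies$gene_id[bi])
    }
    for (g in genes) {
      sc <- scoreTable$score[scoreTable$sv_id == rd$siteID[i] &
                               scoreTable$gene_id == g]
      if (!length(sc)) { nMissing <- nMissing + 1L; sc <- 0 }
      rows[[length(rows) + 1L]] <- data.frame(
        sv_id = rd$siteID[i], gene_id = g, score = sc[1L],
        is_pathogenic = sc[1L] >= 0.5, is_coding = isCoding,
        stringsAsFactors = FALSE)
    }
  }
  if (nMissing > 0L)
    warning(sprintf("%d SV-gene pair(s) absent from the score table; treated as benign", nMissing))
  if (!length(rows))
    return(data.frame(sv_id = character(0), gene_id = character(0),
                      score = numeric(0), is_pathogenic = logical(0),
                      is_coding = logical(0)))
  do.call(rbind, rows)
}

#' Build gene/category rare-variant sets
#'
#' Per (gene, category): rare (MAF below \code{mafMax}) SNVs/INDELs of the
#' category plus rare pathogenic SVs of the matching coding/noncoding type
#' (combined mode), or pathogenic SVs alone grouped into per-gene
#' \code{coding}/\code{noncoding} sets (sv-only mode, the primary
#' analysis). Sets with cMAC below \code{cmacMin} are dropped.
#'
#' @param svDosage samples x SVs dosage matrix (columns named by sv id).
#' @param svCalls output of \code{\link{classifySV}}.
#' @param snvDosage optional samples x SNVs dosage matrix for combined
#'   mode.
#' @param snvTable optional data.frame: \code{variant_id}, \code{gene_id},
#'   \code{category}.
#' @param mode \code{"sv-only"} or \code{"combined"}.
#' @param mafMax rare-variant MAF ceiling (default 0.01).
#' @param cmacMin minimum cumulative minor allele count (default 10).
#' @param weightMode \code{"beta"} (Beta(1,25)(MAF)) or \code{"maf"}.
#' @return list of \linkS4class{VariantSet}s.
#' @export
buildVariantSets <- function(svDosage, svCalls, snvDosage = NULL,
                             snvTable = NULL, mode = c("sv-only", "combined"),
                             mafMax = 0.01, cmacMin = 10,
                             weightMode = c("beta", "maf")) {
  mode <- match.arg(mode); weightMode <- match.arg(weightMode)
  svDosage <- as.matrix(svDosage)
  svAF <- colMeans(svDosage, na.rm = TRUE) / 2
  svMAF <- pmin(svAF, 1 - svAF)
  path <- svCalls[svCalls$is_pathogenic, , drop = FALSE]
  path <- path[path$sv_id %in% colnames(svDosage)[svMAF < mafMax], ,
               drop = FALSE]
  sets <- list()
  addSet <- function(gene, category, ids, isSV) {
    mats <- lapply(seq_along(ids), function(k) {
      if (isSV[k]) svDosage[, ids[k]] else snvDosage[, ids[k]]
    })
    G <- do.call(cbind, mats)
    colnames(G) <- ids
    G[is.na(G)] <- 0L
    af <- colMeans(G) / 2
    maf <- pmin(af, 1 - af)
    cm <- sum(colSums(G))
    if (cm < cmacMin) return(invisible(NULL))
    vs <- new("VariantSet", geneID = gene, category = category,
              variantIDs = ids, G = G, maf = unname(maf),
              weights = unname(variantWeights(pmax(maf, 1e-8), weightMode)),
              isSV = isSV, cmac = cm)
    sets[[length(sets) + 1L]] <<- vs
    invisible(NULL)
  }
  if (mode == "sv-only") {
    for (gene in sort(unique(path$gene_id))) {
      for (cd in c(TRUE, FALSE)) {
        ids <- unique(path$sv_id[path$gene_id == gene & path$is_coding == cd])
        if (!length(ids)) next
        addSet(gene, if (cd) "coding" else "noncoding", ids,
               rep(TRUE, length(ids)))
      }
    }
  } else {
    if (is.null(snvDosage) || is.null(snvTable))
      stop("combined mode requires snvDosage and snvTable")
    snvDosage <- as.matrix(snvDosage)
    snvAF <- colMeans(snvDosage, na.rm = TRUE) / 2
    snvMAF <- pmin(snvAF, 1 - snvAF)
    rare <- colnames(snvDosage)[snvMAF < mafMax]
    snvTable <- snvTable[snvTable$variant_id %in% rare, , drop = FALSE]
    for (gene in sort(unique(c(snvTable$gene_id, path$gene_id)))) {
      cats <- sort(unique(snvTable$category[snvTable$gene_id == gene]))
      for (cat in cats) {
        snvIDs <- snvTable$variant_id[snvTable$gene_id == gene &
                                        snvTable$category == cat]
        coding <- cat %in% CODING_CATEGORIES
        svIDs <- unique(path$sv_id[path$gene_id == gene &
                                     path$is_coding == coding])
        ids <- c(snvIDs, svIDs)
        addSet(gene, cat, ids,
               c(rep(FALSE, length(snvIDs)), rep(TRUE, length(svIDs))))
      }
    }
  }
  sets
}

#' Weighted burden score test
#'
#' Collapses the set to a per-sample weighted dosage sum and score-tests it
#' in the covariate-only null logistic model (1 df chi-square).
#'
#' @param set a \linkS4class{VariantSet} (cMAC-filtered upstream).
#' @param y,X case flags and covariate matrix (with intercept); ignored
#'   when \code{null} is supplied.
#' @param null optional prefit \code{\link{fitNullLogistic}} result.
#' @return list: \code{stat}, \code{p}, \code{flag} (\code{"constant"}
#'   when the burden does not vary, with p = 1).
#' @export
burdenTest <- function(set, y = NULL, X = NULL, null = NULL) {
  null <- null %||% fitNullLogistic(y, X)
  b <- drop(set@G %*% set@weights)
  if (var(b) == 0)
    return(list(stat = 0, p = 1, flag = "constant"))
  st <- scoreTest(null, b)
  list(stat = st$z^2, p = pchisq(st$z^2, df = 1, lower.tail = FALSE),
       flag = NA_character_)
}

## Liu et al. moment-matching p for Q ~ sum(lambda_k chi2_1)
liuP <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-10 * max(lambda, 1)]
  if (!length(lambda)) return(1)
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3)
  c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  muX <- l + d; sigmaX <- sqrt(2) * a
  tstar <- (q - muQ) / sigmaQ
  pchisq(tstar * sigmaX + muX, df = l, ncp = d, lower.tail = FALSE)
}

## projected covariance of weighted genotypes under the null:
## Gw' (W - W X (X'WX)^-1 X'W) Gw
projectedCov <- function(null, Gw) {
  WG <- Gw * null$w
  XtWG <- crossprod(null$X, WG)
  crossprod(Gw, WG) - crossprod(XtWG, null$XtWXinv %*% XtWG)
}

#' Variance-component (SKAT-type) score test
#'
#' Q is the weighted sum of squared per-variant null-model scores; its
#' null distribution, a mixture of 1-df chi-squares with weights equal to
#' the eigenvalues of the projected weighted-genotype covariance, is
#' evaluated by four-moment (Liu-type) matching.
#'
#' @inheritParams burdenTest
#' @return list: \code{Q}, \code{p}, \code{lambda}, \code{flag}
#'   (\code{"degenerate"} with p = 1 at rank 0).
#' @export
skatTest <- function(set, y = NULL, X = NULL, null = NULL) {
  null <- null %||% fitNullLogistic(y, X)
  Gw <- sweep(set@G, 2, set@weights, "*")
  S <- drop(crossprod(Gw, null$y - null$fitted))
  Q <- sum(S^2)
  V <- projectedCov(null, Gw)
  lambda <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-10 * max(lambda, 1)]
  if (!length(lambda))
    return(list(Q = Q, p = 1, lambda = numeric(0), flag = "degenerate"))
  list(Q = Q, p = min(1, liuP(Q, lambda)), lambda = lambda,
       flag = NA_character_)
}

#' Hybrid burden + adjusted SKAT test
#'
#' Combines the burden score test with a SKAT test on burden-adjusted
#' genotypes (the weighted genotype columns orthogonalized against the
#' burden vector in the null-model metric) via Fisher's method on the two
#' p-values (chi-square, 4 df). Efficient against both concerted and
#' heterogeneous rare-variant effect profiles.
#'
#' @inheritParams burdenTest
#' @return list: \code{p}, \code{p_burden}, \code{p_adj}, \code{flag}.
#' @export
smmatE <- function(set, y = NULL, X = NULL, null = NULL) {
  null <- null %||% fitNullLogistic(y, X)
  bt <- burdenTest(set, null = null)
  Gw <- sweep(set@G, 2, set@weights, "*")
  b <- rowSums(Gw)
  if (var(b) == 0) {
    sk <- skatTest(set, null = null)
    return(list(p = sk$p, p_burden = bt$p, p_adj = sk$p, flag = "constant"))
  }
  Pb <- b * null$w -
    null$X %*% (null$XtWXinv %*% crossprod(null$X, null$w * b))
  bPb <- sum(b * Pb)
  bPG <- drop(crossprod(Pb, Gw))
  Gadj <- Gw - outer(b, bPG / bPb)
  Sadj <- drop(crossprod(Gadj, null$y - null$fitted))
  Qadj <- sum(Sadj^2)
  Vadj <- projectedCov(null, Gadj)
  lambda <- eigen(Vadj, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-8 * max(lambda, 1)]
  pAdj <- if (!length(lambda)) 1 else min(1, liuP(Qadj, lambda))
  fisher <- -2 * (log(clipP(bt$p)) + log(clipP(pAdj)))
  p <- pchisq(fisher, df = 4, lower.tail = FALSE)
  list(p = p, p_burden = bt$p, p_adj = pAdj,
       flag = if (!length(lambda)) "burden_only" else NA_character_)
}

#' SNV-conditioned test of the SV members
#'
#' Appends the weighted SNV/INDEL burden of a gene to the covariates and
#' reruns the hybrid test on the SV-only set, asking whether the SV signal
#' survives adjustment for the small-variant aggregate.
#'
#' @param svSet,snvSet nonempty \linkS4class{VariantSet}s for one gene.
#' @param y,X case flags and covariates.
#' @return list as \code{\link{smmatE}}.
#' @export
conditionalSetTest <- function(svSet, snvSet, y, X = NULL) {
  if (ncol(svSet@G) == 0 || ncol(snvSet@G) == 0)
    stop("both variant sets must be nonempty")
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  snvBurden <- drop(snvSet@G %*% snvSet@weights)
  X2 <- cbind(as.matrix(X), snv_burden = snvBurden)
  if (qr(X2)$rank < ncol(X2))
    stop("SNV burden is collinear with the covariates")
  smmatE(svSet, y, X2)
}

#' Benjamini-Hochberg q-values
#'
#' @param p p-values in (0, 1].
#' @return step-up adjusted q-values (monotone in sorted order).
#' @export
bhFDR <- function(p) p.adjust(p, method = "BH")

#' Directionless Stouffer combination of gene-based p-values
#'
#' One-sided Stouffer on z = qnorm(1 - p) with sqrt(n) weights (set tests
#' carry no direction). Degenerate p at 0 or 1 is clipped to machine
#' bounds with a warning.
#'
#' @param p per-group p-values (>= 2 groups).
#' @param n per-group sample sizes.
#' @return combined p-value.
#' @export
metaGene <- function(p, n) {
  stopifnot(length(p) == length(n))
  if (length(p) < 2) stop("need at least 2 groups")
  if (any(p <= 0 | p >= 1)) {
    warning("p-values at 0 or 1 clipped to machine bounds")
    p <- clipP(p)
  }
  z <- qnorm(1 - p)
  zm <- sum(sqrt(n) * z) / sqrt(sum(n))
  pnorm(zm, lower.tail = FALSE)
}
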