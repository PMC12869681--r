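#' Per-sample passing call counts by SV type
#'
#' @param x combined call table or \linkS4class{SVCallSet} covering many
#'   samples.
#' @return data.frame: \code{sample_id}, \code{n_del}, \code{n_ins},
#'   \code{n_inv}.
#' @export
sampleTypeCounts <- function(x) {
  tab <- if (is(x, "SVCallSet")) callTable(x) else x
  ids <- sort(unique(tab$sample_id))
  tt <- table(factor(tab$sample_id, levels = ids),
              factor(tab$svtype, levels = SV_TYPES))
  data.frame(sample_id = ids, n_del = as.integer(tt[, "DEL"]),
             n_ins = as.integer(tt[, "INS"]), n_inv = as.integer(tt[, "INV"]),
             stringsAsFactors = FALSE)
}

#' Cohort SV type composition
#'
#' @param svtypes character vector of SV types (or a call table /
#'   \linkS4class{CohortCallset}, whose svtype column is used).
#' @return data.frame with per-type \code{n} and \code{pct} (percent of
#'   total, 2 decimals).
#' @export
typeComposition <- function(svtypes) {
  if (is(svtypes, "CohortCallset"))
    svtypes <- SummarizedExperiment::rowData(svtypes)$svtype
  if (is.data.frame(svtypes)) svtypes <- svtypes$svtype
  n <- as.integer(table(factor(svtypes, levels = SV_TYPES)))
  data.frame(svtype = SV_TYPES, n = n,
             pct = round(100 * n / sum(n), 2), stringsAsFactors = FALSE)
}

#' Flag outlier samples by per-type call counts
#'
#' Computes a robust Mahalanobis distance of log1p-transformed (DEL, INS,
#' INV) counts, centring on column medians with a rank-based covariance
#' (Spearman correlation mapped to the Pearson scale via 2 sin(pi rho / 6),
#' scaled by column MADs), and flags the ceiling(fraction x n) largest
#' distances. Fully deterministic; ties are broken by sample id order.
#'
#' @param counts data.frame from \code{\link{sampleTypeCounts}}; at least
#'   50 samples are required for a stable covariance.
#' @param fraction fraction of samples to flag (default 0.02).
#' @return character vector of flagged sample ids.
#' @export
detectOutlierSamples <- function(counts, fraction = 0.02) {
  n <- nrow(counts)
  if (n < 50) stop("at least 50 samples are required")
  if (fraction <= 0) return(character(0))
  X <- log1p(as.matrix(counts[, c("n_del", "n_ins", "n_inv")]))
  ctr <- apply(X, 2, median)
  scl <- apply(X, 2, mad)
  rho <- suppressWarnings(cor(X, method = "spearman"))
  rho[!is.finite(rho)] <- 0; diag(rho) <- 1
  R <- 2 * sin(pi * rho / 6)
  scl[scl == 0 | !is.finite(scl)] <- 1e-8
  Sigma <- diag(scl) %*% R %*% diag(scl)
  Sinv <- tryCatch(solve(Sigma), error = function(e) MASS::ginv(Sigma))
  Xc <- sweep(X, 2, ctr)
  d2 <- rowSums((Xc %*% Sinv) * Xc)
  k <- ceiling(fraction * n)
  ord <- order(-d2, counts$sample_id)
  counts$sample_id[ord[seq_len(k)]]
}

#' Identify studies with a concentration of outlier samples
#'
#' Per study, a one-sided binomial tail test of the observed outlier count
#' against the global outlier rate; studies with a Benjamini-Hochberg
#' adjusted q below \code{alpha} AND at least two outliers are returned.
#' All samples of the returned studies are intended to be dropped
#' downstream.
#'
#' @param flagged character vector of flagged sample ids.
#' @param meta sample metadata with \code{sample_id} and \code{study}.
#' @param alpha BH-adjusted significance level.
#' @return character vector of study names to drop (possibly empty); the
#'   per-study table is attached as attribute \code{"table"}.
#' @export
flagOutlierStudies <- function(flagged, meta, alpha = 0.05) {
  if (!all(flagged %in% meta$sample_id))
    stop("every flagged sample must appear in the metadata")
  studies <- sort(unique(meta$study))
  globalRate <- length(flagged) / nrow(meta)
  nS <- vapply(studies, function(s) sum(meta$study == s), numeric(1))
  kS <- vapply(studies, function(s)
    sum(meta$sample_id[meta$study == s] %in% flagged), numeric(1))
  p <- pbinom(kS - 1, nS, globalRate, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  tab <- data.frame(study = studies, n = nS, n_outliers = kS, p = p, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- studies[q < alpha & kS >= 2]
  attr(out, "table") <- tab
  out
}

#' Build a cohort callset from per-sample calls
#'
#' Pools quality- and sample-filtered per-sample records, collapses them
#' into sites with \code{\link{collapseCalls}}, and assigns per-sample
#' dosages from each sample's member record (0 when the sample carries no
#' record at the site; NA for an explicit missing genotype). If a sample
#' contributes two records to one cluster the higher-quality genotype wins
#' with a warning. Per-site allele counts and frequencies use non-missing
#' samples in the denominator.
#'
#' @param x pooled call table or \linkS4class{SVCallSet}, or a list of
#'   per-sample \linkS4class{SVCallSet}s.
#' @param meta sample metadata (one row per retained sample; replicates
#'   already reduced to one sample per individual).
#' @param p \linkS4class{MatchParams} for collapsing.
#' @param readLength optional read-length restriction: samples whose
#'   metadata read_length differs are excluded.
#' @return a \linkS4class{CohortCallset}.
#' @export
buildCohort <- function(x, meta, p = matchParams(), readLength = NULL) {
  if (is.list(x) && !is.data.frame(x) && !is(x, "SVCallSet"))
    x <- do.call(rbind, lapply(x, function(s)
      if (is(s, "SVCallSet")) callTable(s) else s))
  tab <- if (is(x, "SVCallSet")) callTable(x) else x
  if (!is.null(readLength)) meta <- meta[meta$read_length == readLength, ,
                                         drop = FALSE]
  keepSamples <- meta$sample_id
  tab <- tab[tab$sample_id %in% keepSamples, , drop = FALSE]
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  col <- collapseCalls(tab, p)
  sites <- col$sites
  nSite <- nrow(sites); nSamp <- length(keepSamples)
  dosage <- matrix(0L, nrow = nSite, ncol = nSamp,
                   dimnames = list(sites$site_id, keepSamples))
  if (nSite) {
    gtDose <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, missing = NA_integer_)
    siteOf <- setNames(col$cluster_map$site_id, col$cluster_map$record_id)
    dup <- 0L
    ord <- order(tab$qual)  # ascending: the later (higher-qual) write wins
    for (r in ord) {
      s <- siteOf[[tab$record_id[r]]]
      j <- tab$sample_id[r]
      cur <- dosage[s, j]
      if (!is.na(cur) && cur != 0L) dup <- dup + 1L
      dosage[s, j] <- gtDose[[tab$genotype[r]]]
    }
    if (dup > 0L)
      warning(sprintf("%d cluster(s) had two records from one sample; kept the higher-quality genotype", dup))
  }
  ac <- rowSums(dosage, na.rm = TRUE)
  nCalled <- rowSums(!is.na(dosage))
  af <- ifelse(nCalled > 0, ac / (2 * nCalled), NA_real_)
  rr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end),
    siteID = sites$site_id, svtype = sites$svtype, svlen = sites$svlen,
    ref = sites$ref, alt = sites$alt, qual = sites$qual,
    ac = unname(ac), af = unname(af), n_called = unname(nCalled))
  cd <- S4Vectors::DataFrame(meta[match(keepSamples, meta$sample_id), ,
                                  drop = FALSE], row.names = keepSamples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = rr, colData = cd)
  out <- as(se, "CohortCallset")
  validObject(out)
  out
}

SIZE_BIN_BREAKS <- c(50, 100, 300, 1000, 2500, 5000, Inf)
SIZE_BIN_LABELS <- c("50-100", "100-300", "300-1000", "1000-2500",
                     "2500-5000", ">5000")
AF_BIN_BREAKS <- c(0, 1e-4, 1e-3, 1e-2, 1e-1, 0.5, 1)
AF_BIN_LABELS <- c("(0,1e-4]", "(1e-4,1e-3]", "(1e-3,0.01]", "(0.01,0.1]",
                   "(0.1,0.5]", "(0.5,1]")

#' Site-frequency and singleton summaries of a cohort callset
#'
#' Tabulates per-type counts over log-scaled allele-frequency bins and
#' size bins (50-100, 100-300, 300-1000, 1000-2500, 2500-5000, >5000 bp;
#' left-closed, right-open), singleton proportions (allele count 1) per
#' type and per size bin, and the fraction of sites with AF < 1\%.
#'
#' @param callset a nonempty \linkS4class{CohortCallset}.
#' @return list: \code{af_bins}, \code{singleton_by_type},
#'   \code{singleton_by_size}, \code{frac_af_lt_01},
#'   \code{type_composition}.
#' @export
sfsSummary <- function(callset) {
  rd <- as.data.frame(SummarizedExperiment::rowData(callset))
  if (!nrow(rd)) stop("empty callset")
  type <- factor(rd$svtype, levels = SV_TYPES)
  afBin <- cut(rd$af, AF_BIN_BREAKS, labels = AF_BIN_LABELS,
               include.lowest = FALSE, right = TRUE)
  sizeBin <- cut(rd$svlen, SIZE_BIN_BREAKS, labels = SIZE_BIN_LABELS,
                 right = FALSE, include.lowest = TRUE)
  singleton <- rd$ac == 1
  afTab <- as.data.frame.matrix(table(afBin, type))
  afTab <- cbind(af_bin = rownames(afTab), afTab, row.names = NULL)
  singType <- data.frame(
    svtype = SV_TYPES,
    n = as.integer(table(type)),
    singleton_prop = vapply(SV_TYPES, function(tp) {
      idx <- type == tp
      if (!any(idx)) NA_real_ else mean(singleton[idx])
    }, numeric(1)), row.names = NULL)
  singSize <- data.frame(
    size_bin = SIZE_BIN_LABELS,
    n = as.integer(table(sizeBin)),
    singleton_prop = vapply(SIZE_BIN_LABELS, function(b) {
      idx <- sizeBin == b
      if (!any(idx)) NA_real_ else mean(singleton[idx])
    }, numeric(1)), row.names = NULL)
  list(af_bins = afTab, singleton_by_type = singType,
       singleton_by_size = singSize,
       frac_af_lt_01 = mean(rd$af < 0.01, na.rm = TRUE),
       type_composition = typeComposition(rd$svtype))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the allele count and sample size, the
#' p-value is the probability mass of all heterozygote counts no more
#' probable than the observed one under the random-mating (hypergeometric-
#' type) null.
#'
#' @param nHomRef,nHet,nHomAlt non-negative genotype counts, sum > 0.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' hweExact(100, 0, 0)   # monomorphic: 1
hweExact <- function(nHomRef, nHet, nHomAlt) {
  if (any(c(nHomRef, nHet, nHomAlt) < 0)) stop("counts must be >= 0")
  n <- nHomRef + nHet + nHomAlt
  if (n == 0) stop("sum of counts must be > 0")
  nAlt <- 2 * nHomAlt + nHet
  nRare <- min(nAlt, 2 * n - nAlt)
  if (nRare == 0) return(1.0)
  hs <- seq.int(nRare %% 2, nRare, by = 2)
  logp <- vapply(hs, function(h) {
    homRare <- (nRare - h) / 2
    homCommon <- n - h - homRare
    if (homCommon < 0) return(-Inf)
    lgamma(n + 1) - lgamma(homRare + 1) - lgamma(h + 1) -
      lgamma(homCommon + 1) + h * log(2) +
      lgamma(nRare + 1) + lgamma(2 * n - nRare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- which(hs == nHet)
  if (!length(obs)) stop("inconsistent genotype counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-10)]))
}
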