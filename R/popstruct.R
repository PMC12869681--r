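#' Two-locus linkage disequilibrium by composite EM
#'
#' Maximum-likelihood haplotype frequencies for two unphased biallelic loci
#' from dosage vectors, resolving double-heterozygote phase by EM on the
#' 3 x 3 genotype table. Returns D, D' and r-squared computed from the
#' converged frequencies (alt alleles of both loci define the "AB"
#' haplotype).
#'
#' @param g1,g2 dosage vectors in \{0, 1, 2\} (NA pairs dropped); both loci
#'   must be polymorphic.
#' @param tol convergence tolerance on haplotype-frequency change.
#' @param maxIter maximum EM iterations.
#' @return list: \code{hap_freqs} (AB, Ab, aB, ab), \code{D},
#'   \code{D_prime}, \code{r2}, \code{n_iter}.
#' @export
emLD <- function(g1, g2, tol = 1e-8, maxIter = 1000) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  if (n == 0) stop("no complete dosage pairs")
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("both loci must be polymorphic (r2 undefined otherwise)")
  cnt <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  ## fixed haplotype contributions from the eight unambiguous cells
  fixAB <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]
  fixAb <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1]
  fixaB <- 2 * cnt[1, 3] + cnt[2, 3] + cnt[1, 2]
  fixab <- 2 * cnt[1, 1] + cnt[2, 1] + cnt[1, 2]
  nDH <- cnt[2, 2]
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  it <- 0L
  repeat {
    it <- it + 1L
    den <- f["AB"] * f["ab"] + f["Ab"] * f["aB"]
    w <- if (den > 0) unname(f["AB"] * f["ab"] / den) else 0.5
    newF <- c(fixAB + nDH * w, fixAb + nDH * (1 - w),
              fixaB + nDH * (1 - w), fixab + nDH * w) / (2 * n)
    names(newF) <- names(f)
    delta <- max(abs(newF - f))
    f <- newF
    if (delta < tol || it >= maxIter) break
  }
  D <- unname(f["AB"] - pA * pB)
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(hap_freqs = f, D = D,
       D_prime = if (dmax > 0) D / dmax else 0,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
       n_iter = it)
}

imputeMean <- function(X) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  X
}

pairR2 <- function(x, y) {
  r <- suppressWarnings(cor(x, y))
  if (is.na(r)) 0 else r^2
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of \code{window} sites (advanced by \code{step}), any
#' remaining pair with genotype-correlation r-squared above \code{r2Max}
#' loses its lower-MAF member (ties: the higher column index is removed),
#' until no within-window pair exceeds the threshold.
#'
#' @param X samples x sites dosage matrix (missing values mean-imputed).
#' @param r2Max maximum tolerated pairwise r-squared (default 0.1).
#' @param window,step window size and stride in sites.
#' @return sorted integer vector of kept site (column) indices.
#' @export
ldPrune <- function(X, r2Max = 0.1, window = 50, step = 5) {
  X <- imputeMean(X)
  m <- ncol(X)
  if (m <= 1) return(seq_len(m))
  maf <- pmin(colMeans(X) / 2, 1 - colMeans(X) / 2)
  kept <- rep(TRUE, m)
  pos <- 1L
  while (pos <= m) {
    win <- which(kept)
    win <- win[win >= pos & win < pos + window]
    if (length(win) > 1) {
      repeat {
        removed <- FALSE
        for (a in seq_along(win)) {
          if (removed) break
          for (b in seq_along(win)) {
            if (b <= a) next
            i <- win[a]; j <- win[b]
            if (!kept[i] || !kept[j]) next
            if (pairR2(X[, i], X[, j]) > r2Max) {
              drop <- if (maf[i] < maf[j]) i
                      else if (maf[j] < maf[i]) j
                      else max(i, j)
              kept[drop] <- FALSE
              removed <- TRUE
              break
            }
          }
        }
        win <- win[kept[win]]
        if (!removed || length(win) < 2) break
      }
    }
    pos <- pos + step
  }
  which(kept)
}

#' Genotype principal component analysis with MAF/HWE/LD filters
#'
#' Filters sites to minor allele frequency above \code{mafMin} and exact
#' Hardy-Weinberg p above the Bonferroni-corrected level (0.05 / number of
#' MAF-passing sites unless \code{hweAlpha} is given), LD-prunes the
#' survivors, centres each dosage column at 2p and scales by
#' sqrt(2p(1 - p)) (missing values imputed to the mean), and takes the
#' truncated SVD. Component signs are fixed so the largest-magnitude
#' loading of each component is positive.
#'
#' @param x a \linkS4class{CohortCallset} or a samples x sites dosage
#'   matrix.
#' @param mafMin MAF filter (strict, \code{maf > mafMin}); 0 disables.
#' @param hweAlpha HWE significance level; NULL for the Bonferroni default.
#' @param K number of components.
#' @param pruneR2 LD-pruning threshold; NA disables pruning.
#' @return list: \code{scores} (samples x K, zero column means),
#'   \code{loadings} (sites x K), \code{var_explained} (non-increasing),
#'   \code{kept_sites} (column indices into the input site order).
#' @export
svPCA <- function(x, mafMin = 0.01, hweAlpha = NULL, K = 10, pruneR2 = 0.1) {
  X <- if (is(x, "CohortCallset")) t(dosageMatrix(x)) else x
  n <- nrow(X); m <- ncol(X)
  af <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- if (mafMin > 0) maf > mafMin else rep(TRUE, m)
  if (is.null(hweAlpha)) hweAlpha <- 0.05 / max(1, sum(keep))
  if (hweAlpha > 0 && any(keep)) {
    hweP <- vapply(which(keep), function(j) {
      g <- X[, j]
      hweExact(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
               sum(g == 2, na.rm = TRUE))
    }, numeric(1))
    keep[which(keep)] <- hweP > hweAlpha
  }
  idx <- which(keep)
  if (length(idx) && !is.na(pruneR2))
    idx <- idx[ldPrune(X[, idx, drop = FALSE], r2Max = pruneR2)]
  if (!length(idx)) stop("no sites remain after MAF/HWE/LD filters")
  K <- min(K, n - 1L, length(idx))
  Z <- imputeMean(X[, idx, drop = FALSE])
  p <- colMeans(Z) / 2
  sdv <- sqrt(pmax(2 * p * (1 - p), 1e-12))
  Z <- sweep(sweep(Z, 2, 2 * p), 2, sdv, "/")
  sv <- svd(Z, nu = K, nv = K)
  d <- sv$d[seq_len(K)]
  scores <- sv$u %*% diag(d, K, K)
  loadings <- sv$v
  for (k in seq_len(K)) {
    top <- which.max(abs(loadings[, k]))
    if (loadings[top, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  tot <- sum(sv$d^2)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(K))
  rownames(scores) <- rownames(X)
  list(scores = scores, loadings = loadings,
       var_explained = if (tot > 0) d^2 / tot else rep(0, K),
       kept_sites = idx)
}

#' Screen principal components for batch association
#'
#' Per component: a Kruskal-Wallis rank test of scores across batch levels
#' and a complete-separation flag, true when the score ranges of any two
#' batches are disjoint (the signature of a technical artifact axis that
#' must not enter association models as a covariate proxy for ancestry).
#'
#' @param scores samples x K score matrix.
#' @param batch batch labels (at least two levels).
#' @return data.frame: \code{pc}, \code{p}, \code{separated}.
#' @export
pcBatchScreen <- function(scores, batch) {
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) stop("need at least 2 batch levels")
  K <- ncol(scores)
  p <- numeric(K); sep <- logical(K)
  for (k in seq_len(K)) {
    s <- scores[, k]
    p[k] <- kruskal.test(s, batch)$p.value
    rng <- tapply(s, batch, range)
    lv <- levels(batch)
    for (a in seq_along(lv)) for (b in seq_along(lv)) {
      if (b <= a) next
      if (rng[[a]][2] < rng[[b]][1] || rng[[b]][2] < rng[[a]][1])
        sep[k] <- TRUE
    }
  }
  data.frame(pc = colnames(scores) %||% paste0("PC", seq_len(K)),
             p = p, separated = sep, stringsAsFactors = FALSE)
}
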