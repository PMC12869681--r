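#' Fit the covariate-only null logistic model
#'
#' @param y 0/1 case flags.
#' @param X covariate matrix including an intercept column.
#' @return list: \code{fitted} (null probabilities), \code{X}, \code{w}
#'   (IRLS weights mu(1-mu)), \code{XtWXinv}.
#' @export
fitNullLogistic <- function(y, X) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("collinear covariate matrix")
  fit <- glm.fit(X, y, family = binomial())
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  XtWX <- crossprod(X, X * w)
  list(fitted = mu, X = X, w = w, XtWXinv = solve(XtWX), y = y)
}

## score test of a single predictor (or burden) in the null model
scoreTest <- function(null, g) {
  r <- null$y - null$fitted
  U <- sum(g * r)
  XtWg <- crossprod(null$X, null$w * g)
  V <- sum(null$w * g^2) - drop(crossprod(XtWg, null$XtWXinv %*% XtWg))
  if (V <= 0) return(list(z = 0, p = 1, U = U, V = V))
  z <- U / sqrt(V)
  list(z = z, p = 2 * pnorm(-abs(z)), U = U, V = V)
}

#' Single-variant logistic case-control association
#'
#' Maximum-likelihood logistic regression of case status on allele dosage
#' with covariate adjustment (iteratively reweighted least squares), giving
#' the per-allele log-odds, Wald z and two-sided p. Under quasi-complete
#' separation (non-convergence or a diverging estimate) the p-value falls
#' back to the score test in the null model and the result is flagged
#' (\code{method = "score"}).
#'
#' @param y 0/1 case flags.
#' @param g dosage vector; a constant vector is an error.
#' @param X covariate matrix including an intercept (default
#'   intercept-only). A covariate matrix that is itself rank-deficient, or
#'   that absorbs \code{g} completely, is an error.
#' @param siteID optional label.
#' @param group optional per-sample group labels (e.g. ancestry); per-group
#'   alternate allele frequencies are reported as \code{af_<group>} columns.
#' @return one-row data.frame: \code{site_id}, \code{n}, \code{beta},
#'   \code{se}, \code{or_}, \code{ci_low}, \code{ci_high} (exp(beta +/-
#'   1.96 se)), \code{z}, \code{p}, \code{method}.
#' @export
logisticAssoc <- function(y, g, X = NULL, siteID = NA_character_,
                          group = NULL) {
  n <- length(y)
  stopifnot(all(y %in% 0:1))
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(c) all(c == c[1L]))))
    stop("X must include an intercept column")
  if (var(g) == 0) stop("constant dosage vector")
  if (qr(X)$rank < ncol(X)) stop("collinear covariate matrix")
  Xg <- cbind(X, g = g)
  if (qr(Xg)$rank < ncol(Xg))
    stop("dosage is collinear with the covariates")
  fit <- suppressWarnings(glm.fit(Xg, y, family = binomial(),
                                  control = list(epsilon = 1e-10, maxit = 50)))
  k <- ncol(Xg)
  beta <- fit$coefficients[k]
  mu <- fit$fitted.values
  W <- mu * (1 - mu)
  cov <- tryCatch(solve(crossprod(Xg, Xg * W)), error = function(e) NULL)
  se <- if (is.null(cov)) Inf else sqrt(cov[k, k])
  separated <- !fit$converged || !is.finite(beta) || abs(beta) > 15 ||
    !is.finite(se) || se > 100
  if (separated) {
    null <- fitNullLogistic(y, X)
    st <- scoreTest(null, g)
    res <- data.frame(site_id = siteID, n = n, beta = NA_real_,
                      se = NA_real_, or_ = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, z = st$z, p = st$p,
                      method = "score", stringsAsFactors = FALSE)
  } else {
    z <- beta / se
    res <- data.frame(site_id = siteID, n = n, beta = unname(beta),
                      se = se, or_ = exp(unname(beta)),
                      ci_low = exp(beta - 1.96 * se),
                      ci_high = exp(beta + 1.96 * se),
                      z = unname(z), p = 2 * pnorm(-abs(z)),
                      method = "wald", stringsAsFactors = FALSE)
  }
  if (!is.null(group)) {
    for (gv in sort(unique(as.character(group))))
      res[[paste0("af_", gv)]] <- mean(g[group == gv], na.rm = TRUE) / 2
  }
  res
}

#' Conditional single-variant association
#'
#' \code{\link{logisticAssoc}} with the conditioning variant's dosage
#' appended to the covariates, reporting the adjusted test of \code{g}.
#' Perfect LD between \code{g} and \code{gCond} is a collinearity error.
#'
#' @inheritParams logisticAssoc
#' @param gCond dosage of the conditioning variant.
#' @return as \code{\link{logisticAssoc}}.
#' @export
conditionalAssoc <- function(y, g, X = NULL, gCond, siteID = NA_character_,
                             group = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  logisticAssoc(y, g, cbind(as.matrix(X), cond = gCond), siteID = siteID,
                group = group)
}

#' Scan SVs for linkage disequilibrium with tag SNPs
#'
#' Computes EM-based r-squared for every (SV, SNP) pair on the same
#' chromosome and reports pairs with r-squared strictly above
#' \code{r2Min}.
#'
#' @param svDosage samples x SVs dosage matrix (column names = SV ids).
#' @param snpDosage samples x SNPs dosage matrix (column names = SNP ids).
#' @param svChrom,snpChrom chromosome labels per column; by default a
#'   single shared chromosome is assumed.
#' @param r2Min strict r-squared threshold (default 0.4).
#' @return data.frame: \code{sv}, \code{snp}, \code{r2}, \code{D},
#'   \code{D_prime}.
#' @export
tagLDScan <- function(svDosage, snpDosage, svChrom = NULL, snpChrom = NULL,
                      r2Min = 0.4) {
  svDosage <- as.matrix(svDosage); snpDosage <- as.matrix(snpDosage)
  svChrom <- svChrom %||% rep("chr1", ncol(svDosage))
  snpChrom <- snpChrom %||% rep("chr1", ncol(snpDosage))
  rows <- list()
  for (i in seq_len(ncol(svDosage))) for (j in seq_len(ncol(snpDosage))) {
    if (svChrom[i] != snpChrom[j]) next
    ld <- tryCatch(emLD(svDosage[, i], snpDosage[, j]),
                   error = function(e) NULL)
    if (is.null(ld) || ld$r2 <= r2Min) next
    rows[[length(rows) + 1L]] <- data.frame(
      sv = colnames(svDosage)[i] %||% as.character(i),
      snp = colnames(snpDosage)[j] %||% as.character(j),
      r2 = ld$r2, D = ld$D, D_prime = ld$D_prime, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sv = character(0), snp = character(0), r2 = numeric(0),
                      D = numeric(0), D_prime = numeric(0)))
  do.call(rbind, rows)
}

#' Haplotype placement of an SV relative to a risk allele
#'
#' Orients the two-locus disequilibrium coefficient D to the SV alternate
#' allele and the SNP risk allele: positive D with |D'| above
#' \code{dPrimeMin} places the SV on the risk haplotype, negative D on the
#' opposite haplotype; anything weaker is ambiguous.
#'
#' @param svDosage SV alternate-allele dosages.
#' @param riskDosage SNP risk-allele dosages.
#' @param dPrimeMin minimum |D'| for a verdict (default 0.5).
#' @return \code{"same_haplotype"}, \code{"opposite_haplotype"} or
#'   \code{"ambiguous"}.
#' @export
haplotypePhase <- function(svDosage, riskDosage, dPrimeMin = 0.5) {
  ld <- emLD(svDosage, riskDosage)
  if (ld$D > 0 && abs(ld$D_prime) > dPrimeMin) "same_haplotype"
  else if (ld$D < 0 && abs(ld$D_prime) > dPrimeMin) "opposite_haplotype"
  else "ambiguous"
}

#' Bonferroni-corrected significance threshold
#'
#' @param m number of tests (>= 1).
#' @param alpha family-wise level (default 0.05).
#' @return alpha / m.
#' @export
#' @examples
#' signif(bonferroniThreshold(14656), 2)  # 3.4e-06
bonferroniThreshold <- function(m, alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Sample-size weighted Stouffer meta-analysis
#'
#' Combines per-group signed z-statistics as
#' z_meta = sum(sqrt(n_i) z_i) / sqrt(sum(n_i)) with a two-sided p.
#'
#' @param z per-group signed z-statistics (finite).
#' @param n per-group sample sizes.
#' @return list: \code{z_meta}, \code{p_meta}.
#' @export
stoufferMeta <- function(z, n) {
  stopifnot(length(z) == length(n), all(is.finite(z)), all(n > 0))
  if (length(z) < 2) {
    warning("single group: meta-analysis is an identity passthrough")
    return(list(z_meta = z, p_meta = 2 * pnorm(-abs(z))))
  }
  zm <- sum(sqrt(n) * z) / sqrt(sum(n))
  list(z_meta = zm, p_meta = 2 * pnorm(-abs(zm)))
}
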