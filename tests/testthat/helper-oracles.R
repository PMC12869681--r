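# Independent oracles used to validate the package's algorithms. Each is a
# direct, naive implementation kept deliberately separate from the code paths
# it checks.

## Levenshtein distance by full dynamic programming (pure R)
edOracle <- function(a, b) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  m <- length(A); n <- length(B)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  d <- matrix(0L, m + 1L, n + 1L)
  d[, 1L] <- 0:m; d[1L, ] <- 0:n
  for (i in seq_len(m)) for (j in seq_len(n))
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + (A[i] != B[j]))
  d[m + 1L, n + 1L]
}

## exhaustive one-to-one assignment over matching candidate pairs,
## maximizing (number of matches, then total sequence similarity)
assignmentOracle <- function(cand) {
  best <- list(count = -1, sim = -Inf, pairs = NULL)
  recurse <- function(rows, usedA, usedB, pairs, sim) {
    if (!length(rows)) {
      if (length(pairs) > best$count ||
          (length(pairs) == best$count && sim > best$sim + 1e-12))
        best <<- list(count = length(pairs), sim = sim, pairs = pairs)
      return(invisible(NULL))
    }
    r <- rows[1L]; rest <- rows[-1L]
    recurse(rest, usedA, usedB, pairs, sim)  # skip this candidate
    a <- cand$id_a[r]; b <- cand$id_b[r]
    if (!(a %in% usedA) && !(b %in% usedB))
      recurse(rest, c(usedA, a), c(usedB, b), c(pairs, r),
              sim + cand$pct_seq_similarity[r])
    invisible(NULL)
  }
  recurse(seq_len(nrow(cand)), character(0), character(0), integer(0), 0)
  best
}

## exact HWE p by explicit enumeration of genotype configurations with the
## observed sample size and allele count (probabilities from first
## principles via choose())
hweOracle <- function(nHomRef, nHet, nHomAlt) {
  n <- nHomRef + nHet + nHomAlt
  nAlt <- 2 * nHomAlt + nHet
  if (nAlt == 0 || nAlt == 2 * n) return(1.0)
  configs <- list(); probs <- numeric(0)
  for (h in 0:n) {
    homAlt2 <- (nAlt - h) / 2
    if (homAlt2 < 0 || homAlt2 != round(homAlt2)) next
    homRef2 <- n - h - homAlt2
    if (homRef2 < 0) next
    pr <- choose(n, homRef2) * choose(n - homRef2, h) * 2^h
    configs[[length(configs) + 1L]] <- h
    probs <- c(probs, pr)
  }
  probs <- probs / sum(probs)
  obs <- which(unlist(configs) == nHet)
  sum(probs[probs <= probs[obs] * (1 + 1e-10)])
}

## all-pairs interval overlap scan (0-based half-open)
overlapOracle <- function(qs, qe, ss, se) {
  outer(seq_along(qs), seq_along(ss),
        Vectorize(function(i, j) qs[i] < se[j] && qe[i] > ss[j]))
}

## Monte-Carlo p for Q ~ sum(lambda_k chi2_1)
mixtureMCOracle <- function(q, lambda, nDraw = 1e5, seed = 99) {
  set.seed(seed)
  draws <- colSums(matrix(stats::rchisq(length(lambda) * nDraw, df = 1),
                          nrow = length(lambda)) * lambda)
  mean(draws >= q)
}

## direct haplotype-frequency LD when phase is unambiguous
directLDOracle <- function(hap1, hap2) {
  ## hap1/hap2: 0/1 alleles per chromosome (length 2n)
  pA <- mean(hap1); pB <- mean(hap2)
  pAB <- mean(hap1 == 1 & hap2 == 1)
  D <- pAB - pA * pB
  list(D = D, r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

randomSeqStr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## construct a one-row call table
makeRec <- function(id, sample = "S1", chrom = "chr1", start = 1000,
                    svtype = "DEL", svlen = 100, qual = 60,
                    genotype = "het", ref = NULL, alt = NULL) {
  if (is.null(ref) || is.null(alt)) {
    anchor <- "A"
    if (svtype == "DEL") {
      ref <- paste0(anchor, randomSeqStr(svlen)); alt <- anchor
    } else if (svtype == "INS") {
      ref <- anchor; alt <- paste0(anchor, randomSeqStr(svlen))
    } else {
      ref <- randomSeqStr(svlen); alt <- reverseComplementSeq(ref)
    }
  }
  data.frame(record_id = id, sample_id = sample, chrom = chrom,
             start = start, end = start + nchar(ref), ref = ref, alt = alt,
             svtype = svtype, svlen = svlen, qual = qual, filter = "PASS",
             genotype = genotype, stringsAsFactors = FALSE)
}
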