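#' Sequence similarity between two allele strings
#'
#' Defined as 1 - editdistance(a, b) / max(nchar(a), nchar(b)): symmetric,
#' bounded in [0, 1], 1 for identical strings and, by convention, 1 when
#' both strings are empty. N participates as an ordinary (mismatching)
#' symbol.
#'
#' @param a,b nucleotide strings (may be empty).
#' @return similarity fraction in [0, 1].
#' @export
#' @examples
#' seqSimilarity("AAAA", "AAAT")  # 0.75
seqSimilarity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L && lb == 0L) return(1.0)
  if (a == b) return(1.0)  # avoids the DP on identical alleles
  1 - editDistance(a, b) / max(la, lb)
}

#' Size similarity between two SV lengths
#'
#' The min/max length ratio: symmetric, in (0, 1], and 1 iff equal.
#'
#' @param lenA,lenB positive lengths in bp.
#' @return fraction in (0, 1].
#' @export
#' @examples
#' sizeSimilarity(50, 100)  # 0.5
sizeSimilarity <- function(lenA, lenB) {
  if (any(c(lenA, lenB) <= 0)) stop("lengths must be > 0")
  pmin(lenA, lenB) / pmax(lenA, lenB)
}

## similarity gate honouring the strict flag
passGate <- function(value, minimum, strict) {
  if (strict) value > minimum else value >= minimum
}

#' Compare two SV calls
#'
#' Computes the sequence similarity (over the event sequences: deleted bases
#' for DELs, inserted bases for INSs, the alternate allele for INVs), the
#' size similarity of the SV lengths, and the start-position distance, and
#' applies the match rule of \code{p}: both similarities at/above their
#' minima, distance within \code{maxDist}, and equal types when required.
#' Calls on different chromosomes never match.
#'
#' @param a,b single-row call tables (or single-call
#'   \linkS4class{SVCallSet}s).
#' @param p a \linkS4class{MatchParams}.
#' @return one-row data.frame: \code{id_a}, \code{id_b},
#'   \code{pct_seq_similarity}, \code{pct_size_similarity}, \code{dist},
#'   \code{is_match}.
#' @export
matchPair <- function(a, b, p = matchParams()) {
  if (is(a, "SVCallSet")) a <- callTable(a)
  if (is(b, "SVCallSet")) b <- callTable(b)
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  seqSim <- seqSimilarity(variantSeq(a$ref, a$alt, a$svtype),
                          variantSeq(b$ref, b$alt, b$svtype))
  sizeSim <- sizeSimilarity(a$svlen, b$svlen)
  dist <- abs(a$start - b$start)
  isMatch <- a$chrom == b$chrom &&
    passGate(seqSim, p@seqSimMin, p@strict) &&
    passGate(sizeSim, p@sizeSimMin, p@strict) &&
    dist <= p@maxDist &&
    (!p@requireSameType || a$svtype == b$svtype)
  data.frame(id_a = a$record_id, id_b = b$record_id,
             pct_seq_similarity = seqSim, pct_size_similarity = sizeSim,
             dist = as.integer(dist), is_match = isMatch,
             stringsAsFactors = FALSE)
}

## all candidate pairwise comparisons between two call tables
## (same chromosome, start distance within maxDist)
candidateMatches <- function(A, B, p) {
  out <- list()
  for (chr in intersect(unique(A$chrom), unique(B$chrom))) {
    ai <- which(A$chrom == chr); bi <- which(B$chrom == chr)
    for (i in ai) {
      near <- bi[abs(B$start[bi] - A$start[i]) <= p@maxDist]
      for (j in near) {
        m <- matchPair(A[i, , drop = FALSE], B[j, , drop = FALSE], p)
        m$row_a <- i; m$row_b <- j
        out[[length(out) + 1L]] <- m
      }
    }
  }
  if (!length(out)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      pct_seq_similarity = numeric(0),
                      pct_size_similarity = numeric(0), dist = integer(0),
                      is_match = logical(0), row_a = integer(0),
                      row_b = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Match two call sets one-to-one
#'
#' Greedy one-to-one assignment over candidate pairs (same chromosome,
#' within \code{maxDist}) that satisfy the match rule, processed in
#' deterministic order: descending sequence similarity, descending size
#' similarity, ascending distance, then lexicographic record ids. Each
#' record participates in at most one match; unmatched records are reported.
#'
#' @param A,B \linkS4class{SVCallSet}s or call tables.
#' @param p a \linkS4class{MatchParams}.
#' @return list with \code{matches} (data.frame of accepted pairs),
#'   \code{unmatched_a}, \code{unmatched_b} (record id vectors).
#' @export
matchCallsets <- function(A, B, p = matchParams()) {
  if (is(A, "SVCallSet")) A <- callTable(A)
  if (is(B, "SVCallSet")) B <- callTable(B)
  cand <- candidateMatches(A, B, p)
  cand <- cand[cand$is_match, , drop = FALSE]
  ord <- order(-cand$pct_seq_similarity, -cand$pct_size_similarity,
               cand$dist, cand$id_a, cand$id_b)
  cand <- cand[ord, , drop = FALSE]
  usedA <- rep(FALSE, nrow(A)); usedB <- rep(FALSE, nrow(B))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$row_a[r]; j <- cand$row_b[r]
    if (!usedA[i] && !usedB[j]) { keep[r] <- TRUE; usedA[i] <- usedB[j] <- TRUE }
  }
  matches <- cand[keep, setdiff(colnames(cand), c("row_a", "row_b")),
                  drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       unmatched_a = A$record_id[!usedA],
       unmatched_b = B$record_id[!usedB])
}

#' Collapse a multi-sample call list into cohort sites
#'
#' Greedy star clustering in the "keep max qual" sense: records are
#' processed in descending quality (ties: ascending chrom, start, record
#' id); each record either joins the best-matching existing seed (per
#' \code{p}, comparing against the seed itself, never chaining) or founds a
#' new site. The surviving representative of each site is its seed, hence
#' the maximal-quality member.
#'
#' @param x \linkS4class{SVCallSet} or call table sorted by (chrom, start);
#'   unsorted input is an error.
#' @param p a \linkS4class{MatchParams}; cohort collapsing uses the
#'   defaults (both similarities >= 0.95 within 1000 bp, same type).
#' @return list with \code{sites} (call table of seed records, sorted by
#'   chrom/start, with a \code{site_id} column) and \code{cluster_map}
#'   (data.frame record_id -> site_id covering every input record).
#' @export
collapseCalls <- function(x, p = matchParams()) {
  tab <- if (is(x, "SVCallSet")) callTable(x) else x
  if (nrow(tab) == 0L)
    return(list(sites = cbind(emptyCallTable(), site_id = character(0)),
                cluster_map = data.frame(record_id = character(0),
                                         site_id = character(0))))
  if (!identical(order(tab$chrom, tab$start), seq_len(nrow(tab))))
    stop("records must be sorted by (chrom, start)")
  n <- nrow(tab)
  ord <- order(-tab$qual, tab$chrom, tab$start, tab$record_id)
  ## precomputed per-record vectors for the hot loop
  vseq <- vapply(seq_len(n), function(i)
    variantSeq(tab$ref[i], tab$alt[i], tab$svtype[i]), character(1))
  chrom <- tab$chrom; start <- tab$start
  svtype <- tab$svtype; svlen <- tab$svlen
  isSeed <- logical(n)
  assign <- integer(n)
  for (i in ord) {
    cand <- which(isSeed & chrom == chrom[i] &
                    abs(start - start[i]) <= p@maxDist)
    if (p@requireSameType && length(cand))
      cand <- cand[svtype[cand] == svtype[i]]
    best <- 0L; bestKey <- NULL
    for (s in cand) {
      sizeSim <- sizeSimilarity(svlen[i], svlen[s])
      if (!passGate(sizeSim, p@sizeSimMin, p@strict)) next
      ## edit distance is at least the length difference, so the
      ## similarity can never exceed this bound: skip the DP when the
      ## gate is already lost
      li <- nchar(vseq[i]); ls <- nchar(vseq[s])
      if (max(li, ls) > 0 &&
          !passGate(1 - abs(li - ls) / max(li, ls), p@seqSimMin, p@strict))
        next
      seqSim <- seqSimilarity(vseq[i], vseq[s])
      if (!passGate(seqSim, p@seqSimMin, p@strict)) next
      key <- c(seqSim, sizeSim, -abs(start[i] - start[s]))
      if (is.null(bestKey) || lexGreater(key, bestKey)) {
        best <- s; bestKey <- key
      }
    }
    if (best > 0L) assign[i] <- best
    else { isSeed[i] <- TRUE; assign[i] <- i }
  }
  seedRows <- which(isSeed)
  sites <- tab[sort(seedRows), , drop = FALSE]
  siteID <- sprintf("site_%s_%d_%s", sites$chrom, sites$start, sites$svtype)
  if (anyDuplicated(siteID))
    siteID <- make.unique(siteID, sep = "_")
  sites$site_id <- siteID
  rownames(sites) <- NULL
  lookup <- setNames(siteID, as.character(sort(seedRows)))
  clusterMap <- data.frame(record_id = tab$record_id,
                           site_id = unname(lookup[as.character(assign)]),
                           stringsAsFactors = FALSE)
  list(sites = sites, cluster_map = clusterMap)
}

lexGreater <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] > b[k]) return(TRUE)
    if (a[k] < b[k]) return(FALSE)
  }
  FALSE
}
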