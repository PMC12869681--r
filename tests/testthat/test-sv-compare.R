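test_that("sequence similarity agrees with the DP edit-distance oracle", {
  expect_identical(seqSimilarity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_identical(seqSimilarity("AAAA", "AAAT"), 0.75)
  expect_identical(seqSimilarity("ACGT", ""), 0.0)
  expect_identical(seqSimilarity("", ""), 1.0)
  set.seed(21)
  for (i in 1:20) {
    a <- randomSeqStr(sample(1:40, 1)); b <- randomSeqStr(sample(1:40, 1))
    expect_equal(seqSimilarity(a, b),
                 1 - edOracle(a, b) / max(nchar(a), nchar(b)))
    expect_identical(seqSimilarity(a, b), seqSimilarity(b, a))
    expect_gte(seqSimilarity(a, b), 0); expect_lte(seqSimilarity(a, b), 1)
  }
})

test_that("size similarity is the min/max ratio", {
  expect_identical(sizeSimilarity(100, 100), 1.0)
  expect_identical(sizeSimilarity(50, 100), 0.5)
  expect_identical(sizeSimilarity(96, 100), 0.96)  # passes the 0.95 gate
  expect_gte(sizeSimilarity(96, 100), 0.95)
  expect_error(sizeSimilarity(0, 10), "> 0")
})

test_that("pair matching applies distance, type and similarity gates", {
  set.seed(22)
  a <- makeRec("a", start = 1000, svtype = "DEL", svlen = 100)
  ident <- a; ident$record_id <- "b"
  m <- matchPair(a, ident, matchParams(0.95, 0.95, 1000, TRUE))
  expect_true(m$is_match)
  expect_identical(m$pct_seq_similarity, 1.0)
  far <- ident; far$start <- 2500; far$end <- far$end + 1500
  expect_false(matchPair(a, far, matchParams(0.95, 0.95, 1000, TRUE))$is_match)
  ins <- makeRec("c", start = 1000, svtype = "INS", svlen = 100)
  expect_false(matchPair(a, ins, matchParams(0, 0, 1000, TRUE))$is_match)
  otherChrom <- ident; otherChrom$chrom <- "chr2"
  expect_false(matchPair(a, otherChrom, matchParams())$is_match)
})

test_that("callset matching is one-to-one and prefers higher similarity", {
  set.seed(23)
  x <- makeRec("x", start = 1000, svtype = "DEL", svlen = 100)
  ## y1 almost identical; y2 a worse but still acceptable partner
  y1 <- x; y1$record_id <- "y1"
  y1$ref <- paste0(substr(x$ref, 1, 99), "TT"); y1$end <- y1$start + 101
  y2 <- x; y2$record_id <- "y2"
  y2$ref <- paste0(substr(x$ref, 1, 93), strrep("T", 8))
  m <- matchCallsets(x, rbind(y1, y2), matchParams(0.9, 0.9, 1000, TRUE))
  expect_identical(m$matches$id_b, "y1")
  expect_identical(m$unmatched_b, "y2")
  ## identity: everything matches itself at similarity 1
  A <- rbind(makeRec("r1", start = 1000), makeRec("r2", start = 4000))
  self <- matchCallsets(A, A, matchParams())
  expect_identical(nrow(self$matches), 2L)
  expect_true(all(self$matches$pct_seq_similarity == 1))
  ## disjoint chromosomes
  B <- A; B$chrom <- "chr9"
  expect_identical(nrow(matchCallsets(A, B, matchParams())$matches), 0L)
})

test_that("greedy matching equals the exhaustive assignment oracle", {
  set.seed(24)
  p <- matchParams(0.90, 0.90, 1000, TRUE)
  for (rep in 1:8) {
    ## jittered copies of distinct events, plus noise records
    nA <- sample(2:5, 1)
    A <- do.call(rbind, lapply(seq_len(nA), function(i)
      makeRec(sprintf("a%d", i), start = i * 4000,
              svlen = sample(60:120, 1))))
    B <- A
    B$record_id <- sub("a", "b", B$record_id)
    B$start <- B$start + sample(-20:20, nA, replace = TRUE)
    B$end <- B$start + nchar(B$ref)
    drop <- runif(nA) < 0.3
    B <- B[!drop, , drop = FALSE]
    got <- matchCallsets(A, B, p)
    cand <- svcohort:::candidateMatches(A, B, p)
    cand <- cand[cand$is_match, , drop = FALSE]
    oracle <- assignmentOracle(cand)
    expect_identical(nrow(got$matches), oracle$count)
    expect_equal(sum(got$matches$pct_seq_similarity), oracle$sim,
                 tolerance = 1e-9)
  }
})

test_that("collapsing keeps the max-qual representative", {
  set.seed(25)
  base <- makeRec("q30", start = 1000, svlen = 100, qual = 30)
  r2 <- base; r2$record_id <- "q50"; r2$sample_id <- "S2"; r2$qual <- 50
  r3 <- base; r3$record_id <- "q90"; r3$sample_id <- "S3"; r3$qual <- 90
  col <- collapseCalls(rbind(base, r2, r3))
  expect_identical(nrow(col$sites), 1L)
  expect_identical(col$sites$qual, 90)
  expect_identical(col$sites$record_id, "q90")
  expect_identical(unique(col$cluster_map$site_id), col$sites$site_id)
})

test_that("collapsing separates dissimilar events and passes singletons through", {
  set.seed(26)
  a <- makeRec("a", start = 1000, svlen = 100)
  ## ~90% sequence similarity: below the 0.95 merge bar
  b <- a; b$record_id <- "b"; b$sample_id <- "S2"
  b$ref <- paste0(substr(a$ref, 1, 90), randomSeqStr(11))
  expect_lt(seqSimilarity(substring(a$ref, 2), substring(b$ref, 2)), 0.95)
  col <- collapseCalls(rbind(a, b))
  expect_identical(nrow(col$sites), 2L)
  single <- collapseCalls(makeRec("solo", start = 500))
  expect_identical(nrow(single$sites), 1L)
  expect_identical(single$cluster_map$record_id, "solo")
  expect_error(collapseCalls(rbind(b, a)[c(1, 2), ][order(c(2, 1)), ]),
               NA)  # sorted input fine
  unsorted <- rbind(a, b); unsorted$start <- c(2000, 1000)
  unsorted$end <- unsorted$start + nchar(unsorted$ref)
  expect_error(collapseCalls(unsorted), "sorted")
})

test_that("collapse is idempotent and surviving seeds are mutually unmergeable", {
  set.seed(27)
  p <- matchParams()
  recs <- list()
  for (i in 1:6) {
    base <- makeRec(sprintf("s%d_0", i), start = i * 5000,
                    svlen = sample(60:200, 1),
                    qual = round(runif(1, 10, 99), 1))
    recs[[length(recs) + 1L]] <- base
    for (k in 1:2) {
      cp <- base
      cp$record_id <- sprintf("s%d_%d", i, k)
      cp$sample_id <- sprintf("S%d", k + 1)
      cp$qual <- round(runif(1, 10, 99), 1)
      cp$start <- cp$start + sample(-30:30, 1)
      cp$end <- cp$start + nchar(cp$ref)
      recs[[length(recs) + 1L]] <- cp
    }
  }
  tab <- do.call(rbind, recs)
  tab <- tab[order(tab$chrom, tab$start), ]
  col <- collapseCalls(tab, p)
  expect_identical(nrow(col$sites), 6L)
  ## idempotence
  again <- collapseCalls(col$sites[, names(tab)], p)
  expect_identical(again$sites[, names(tab)], col$sites[, names(tab)])
  ## exclusion: no pair of surviving same-type sites still matches
  s <- col$sites
  for (i in seq_len(nrow(s))) for (j in seq_len(nrow(s))) {
    if (j <= i) next
    expect_false(matchPair(s[i, ], s[j, ], p)$is_match)
  }
})
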