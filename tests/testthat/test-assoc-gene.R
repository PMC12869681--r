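mkSet <- function(G, weights = rep(1, ncol(G)), gene = "G1",
                  category = "coding") {
  G <- as.matrix(G)
  ids <- sprintf("v%d", seq_len(ncol(G)))
  colnames(G) <- ids
  af <- if (ncol(G)) colMeans(G) / 2 else numeric(0)
  new("VariantSet", geneID = gene, category = category,
      variantIDs = ids, G = G, maf = pmin(af, 1 - af),
      weights = weights, isSV = rep(TRUE, ncol(G)),
      cmac = sum(colSums(G)))
}

test_that("SV classification follows exon overlap, score cut and distance window", {
  set.seed(81)
  gm <- data.frame(gene_id = c("GA", "GB"),
                   feature = "gene", chrom = "chr1",
                   start = c(10000, 3e6), end = c(20000, 3e6 + 2e4))
  gm <- rbind(gm,
              data.frame(gene_id = c("GA", "GB"), feature = "exon",
                         chrom = "chr1", start = c(10000, 3e6),
                         end = c(10500, 3e6 + 500)))
  ## 1 bp exon overlap -> coding; far intergenic SV -> noncoding for GA only
  ## if within 1 Mb
  exonTouch <- makeRec("e", start = 10499, svtype = "DEL", svlen = 100)
  nearGA <- makeRec("n", start = 900000, svtype = "DEL", svlen = 100)
  beyond <- makeRec("b", start = 10000 + 1.3e6, svtype = "DEL", svlen = 100)
  ids <- c("S1")
  meta <- data.frame(sample_id = "S1", individual_id = "I1")
  cc <- buildCohort(rbind(exonTouch, nearGA, beyond)[order(c(1, 2, 3)), ],
                    meta)
  rd <- svcohort:::rowDataFrame(cc)
  sid <- function(st) rd$siteID[rd$start == st]
  scores <- data.frame(sv_id = c(sid(10499), sid(900000)),
                       gene_id = "GA", score = c(0.50, 0.49))
  calls <- suppressWarnings(classifySV(cc, gm, scores))
  e <- calls[calls$sv_id == sid(10499) & calls$gene_id == "GA", ]
  expect_true(e$is_coding)
  expect_true(e$is_pathogenic)  # score exactly 0.5 is pathogenic
  nGA <- calls[calls$sv_id == sid(900000) & calls$gene_id == "GA", ]
  expect_false(nGA$is_coding)
  expect_false(nGA$is_pathogenic)
  ## beyond 1 Mb from GA: no (sv, GA) call
  expect_false(any(calls$sv_id == sid(10000 + 1.3e6) &
                     calls$gene_id == "GA"))
})

test_that("set construction enforces MAF and cMAC gates", {
  set.seed(82)
  n <- 600
  ## three rare pathogenic SVs in one gene, one common SV excluded
  D <- cbind(sv1 = rbinom(n, 1, 0.004), sv2 = rbinom(n, 1, 0.005),
             sv3 = rbinom(n, 1, 0.004), svCommon = rbinom(n, 2, 0.3))
  calls <- data.frame(sv_id = colnames(D), gene_id = "G1",
                      score = 0.9, is_pathogenic = TRUE, is_coding = TRUE)
  sets <- buildVariantSets(D, calls, cmacMin = 5)
  expect_identical(length(sets), 1L)
  expect_false("svCommon" %in% sets[[1]]@variantIDs)
  expect_gte(sets[[1]]@cmac, 5)
  ## a set below the cMAC floor is dropped
  tiny <- cbind(sv1 = c(1, rep(0, n - 1)))
  setsTiny <- buildVariantSets(tiny, calls[1, ], cmacMin = 10)
  expect_identical(length(setsTiny), 0L)
  ## combined mode unions SNVs and matching-type SVs
  snvD <- cbind(snv1 = rbinom(n, 1, 0.004), snv2 = rbinom(n, 1, 0.004))
  snvTab <- data.frame(variant_id = c("snv1", "snv2"), gene_id = "G1",
                       category = "pLoF")
  comb <- buildVariantSets(D, calls, snvD, snvTab, mode = "combined",
                           cmacMin = 5)
  expect_identical(length(comb), 1L)
  expect_setequal(comb[[1]]@variantIDs, c("snv1", "snv2", "sv1", "sv2", "sv3"))
})

test_that("burden, SKAT and single-variant score tests agree on singleton sets", {
  set.seed(83)
  n <- 1000
  g <- rbinom(n, 1, 0.02)
  y <- rbinom(n, 1, 0.5)
  X <- matrix(1, n, 1)
  null <- fitNullLogistic(y, X)
  vs <- mkSet(matrix(g, ncol = 1))
  st <- svcohort:::scoreTest(null, g)
  pSingle <- pchisq(st$z^2, 1, lower.tail = FALSE)
  expect_equal(burdenTest(vs, null = null)$p, pSingle, tolerance = 1e-8)
  expect_equal(skatTest(vs, null = null)$p, pSingle, tolerance = 1e-8)
  sm <- smmatE(vs, null = null)
  expect_gt(sm$p, 0); expect_lte(sm$p, 1)
})

test_that("moment-matched SKAT p agrees with the Monte-Carlo mixture oracle", {
  set.seed(84)
  n <- 800
  for (rep in 1:4) {
    G <- matrix(rbinom(n * 5, 1, runif(5, 0.005, 0.02)), n, 5, byrow = TRUE)
    if (any(colSums(G) == 0)) G[1, colSums(G) == 0] <- 1
    y <- rbinom(n, 1, 0.5)
    null <- fitNullLogistic(y, matrix(1, n, 1))
    vs <- mkSet(G)
    sk <- skatTest(vs, null = null)
    pMC <- mixtureMCOracle(sk$Q, sk$lambda, nDraw = 1e5, seed = rep)
    if (pMC > 0.005)  # MC resolution limit
      expect_equal(sk$p, pMC, tolerance = 0.1)  # 10% relative
  }
})

test_that("null p-values of the hybrid test are uniform", {
  set.seed(85)
  n <- 600
  y <- rbinom(n, 1, 0.5)
  null <- fitNullLogistic(y, matrix(1, n, 1))
  ps <- replicate(400, {
    G <- matrix(rbinom(n * 4, 1, 0.01), n, 4)
    if (any(colSums(G) == 0)) return(NA_real_)
    smmatE(mkSet(G), null = null)$p
  })
  ps <- ps[!is.na(ps)]
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("a concerted burden signal favors the hybrid over SKAT alone", {
  set.seed(86)
  n <- 1200
  wins <- replicate(60, {
    G <- matrix(rbinom(n * 5, 1, 0.01), n, 5)
    risk <- rowSums(G)
    y <- rbinom(n, 1, plogis(-0.1 + 0.9 * risk))
    if (any(colSums(G) == 0)) return(NA)
    null <- fitNullLogistic(y, matrix(1, n, 1))
    vs <- mkSet(G)
    smmatE(vs, null = null)$p <= skatTest(vs, null = null)$p
  })
  expect_gte(mean(wins, na.rm = TRUE), 0.8)
})

test_that("zero-dosage members do not change the statistics", {
  set.seed(87)
  n <- 500
  G <- matrix(rbinom(n * 3, 1, 0.02), n, 3)
  if (any(colSums(G) == 0)) G[1, colSums(G) == 0] <- 1
  y <- rbinom(n, 1, 0.5)
  null <- fitNullLogistic(y, matrix(1, n, 1))
  Gz <- cbind(G, 0)
  expect_equal(smmatE(mkSet(Gz), null = null)$p,
               smmatE(mkSet(G), null = null)$p, tolerance = 1e-10)
  expect_equal(burdenTest(mkSet(Gz), null = null)$p,
               burdenTest(mkSet(G), null = null)$p, tolerance = 1e-10)
})

test_that("conditional set test separates independent from LD-mediated SV signal", {
  set.seed(88)
  n <- 2500
  ## SV with a real effect, SNVs null
  svG <- matrix(rbinom(n * 3, 1, 0.01), n, 3)
  snvG <- matrix(rbinom(n * 4, 1, 0.01), n, 4)
  y <- rbinom(n, 1, plogis(-0.1 + 1.5 * rowSums(svG)))
  if (all(colSums(svG) > 0) && all(colSums(snvG) > 0)) {
    pAdj <- conditionalSetTest(mkSet(svG), mkSet(snvG), y)$p
    expect_lt(pAdj, 0.05)
  }
  ## SV signal entirely mediated: SVs are a copy of causal SNV burden carriers
  snvG2 <- matrix(rbinom(n * 2, 1, 0.02), n, 2)
  svG2 <- snvG2[, 1, drop = FALSE]  # SV tags the causal SNV perfectly
  y2 <- rbinom(n, 1, plogis(-0.1 + 1.5 * rowSums(snvG2)))
  if (all(colSums(svG2) > 0)) {
    pm <- tryCatch(conditionalSetTest(mkSet(svG2), mkSet(snvG2), y2)$p,
                   error = function(e) NA_real_)
    pu <- smmatE(mkSet(svG2), y2, matrix(1, n, 1))$p
    if (!is.na(pm)) expect_gt(pm, pu)
  }
  expect_error(conditionalSetTest(mkSet(svG[, 0, drop = FALSE]),
                                  mkSet(snvG), y), "nonempty")
})

test_that("BH q-values and the gene-level Stouffer combination follow their formulas", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFDR(0.2), 0.2)
  expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
  ## equal p, equal n: closed form
  p <- 0.01; n <- c(400, 400)
  z <- qnorm(1 - p)
  expected <- pnorm(sum(sqrt(n) * z) / sqrt(sum(n)), lower.tail = FALSE)
  expect_equal(metaGene(c(p, p), n), expected, tolerance = 1e-12)
  ## a near-null group dilutes a strong one
  expect_gt(metaGene(c(1e-6, 0.97), c(500, 500)), 1e-6)
  expect_warning(metaGene(c(0.01, 1), c(100, 100)), "clipped")
  expect_error(metaGene(0.05, 100), "2 groups")
})
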