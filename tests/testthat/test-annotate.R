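mkCohort <- function(recs, nSamples = 1) {
  ids <- unique(recs$sample_id)
  meta <- data.frame(sample_id = ids,
                     individual_id = paste0("I", seq_along(ids)))
  buildCohort(recs[order(recs$chrom, recs$start), ], meta)
}

test_that("catalog intersection applies reciprocal-overlap and INS rules", {
  set.seed(51)
  del <- makeRec("d", start = 1000, svtype = "DEL", svlen = 100)
  ins <- makeRec("i", start = 9000, svtype = "INS", svlen = 80)
  cc <- mkCohort(rbind(del, ins))
  rd <- svcohort:::rowDataFrame(cc)
  dRow <- rd[rd$svtype == "DEL", ]; iRow <- rd[rd$svtype == "INS", ]
  catalog <- data.frame(
    source = "CAT",
    chrom = "chr1",
    start = c(dRow$start, iRow$start + 200),
    end = c(dRow$end, iRow$start + 200 + 1),
    svtype = c("DEL", "INS"), svlen = c(101, 85),
    af = c(0.2, 0.1), stringsAsFactors = FALSE)
  hit <- intersectCatalog(cc, catalog)
  expect_true(all(hit$known))
  expect_equal(hit$matched_af[match(dRow$siteID, hit$site_id)], 0.2)
  ## 40% reciprocal overlap < 0.5 threshold: novel
  catalog40 <- catalog[1, ]
  catalog40$start <- dRow$start + 61  # overlap 40 of 101 bp
  catalog40$end <- catalog40$start + 101
  expect_false(intersectCatalog(cc, catalog40)$known[
    match(dRow$siteID, hit$site_id)])
  ## INS farther than 1000 bp: novel
  catalogFar <- catalog[2, ]
  catalogFar$start <- iRow$start + 1500; catalogFar$end <- catalogFar$start + 1
  expect_false(any(intersectCatalog(cc, catalogFar)$known))
})

test_that("catalog intersection is translation invariant and oracle-consistent", {
  set.seed(52)
  recs <- do.call(rbind, lapply(1:6, function(i)
    makeRec(sprintf("d%d", i), start = i * 5000, svtype = "DEL",
            svlen = sample(60:300, 1))))
  cc <- mkCohort(recs)
  rd <- svcohort:::rowDataFrame(cc)
  catalog <- data.frame(source = "CAT", chrom = "chr1",
                        start = rd$start[1:3] - 10, end = rd$end[1:3] - 10,
                        svtype = "DEL", af = 0.1)
  hit1 <- intersectCatalog(cc, catalog)
  ## all-pairs overlap oracle agrees on which sites touch the catalog
  ov <- overlapOracle(rd$start, rd$end, catalog$start, catalog$end)
  expect_setequal(hit1$site_id[hit1$known],
                  rd$siteID[rowSums(ov) > 0])
  ## translate everything by a constant: verdicts unchanged
  shift <- 70000L
  recsT <- recs; recsT$start <- recsT$start + shift
  recsT$end <- recsT$end + shift
  ccT <- mkCohort(recsT)
  catalogT <- catalog; catalogT$start <- catalogT$start + shift
  catalogT$end <- catalogT$end + shift
  expect_identical(intersectCatalog(ccT, catalogT)$known, hit1$known)
})

test_that("AF concordance is exact on duplicated frequencies and attenuates under noise", {
  set.seed(53)
  af <- runif(500, 0.02, 0.6)
  expect_equal(afConcordance(af, af)$r2, 1.0)
  noisy <- pmin(1, pmax(0, af + rnorm(500, 0, 0.05)))
  r2 <- afConcordance(af, noisy)$r2
  expected <- var(af) / (var(af) + 0.0025)
  expect_equal(r2, expected, tolerance = 0.08)
  ## independent AF vectors: no concordance
  expect_lt(afConcordance(af, sample(af))$r2, 0.05)
  expect_error(afConcordance(af[1:2], af[1:2]), "at least 3")
})

test_that("gene annotation classes are exclusive, exhaustive and correct", {
  set.seed(54)
  gm <- data.frame(
    gene_id = "G1",
    feature = c("gene", "exon", "exon", "cds", "utr3"),
    chrom = "chr1",
    start = c(50000, 50000, 58000, 50200, 59800),
    end = c(60000, 51000, 60000, 51000, 60000))
  ## DEL spanning the first exon-intron junction
  junction <- makeRec("j", start = 50900, svtype = "DEL", svlen = 300)
  ## SV 4999 bp upstream of the gene, no overlap
  upstream <- makeRec("u", start = 50000 - 5000 - 151, svtype = "DEL",
                      svlen = 150)
  ## INS anchored in the intron (would span into the exon if laid out)
  insIntron <- makeRec("ii", start = 52000, svtype = "INS", svlen = 9000)
  ## far away
  far <- makeRec("f", start = 200000, svtype = "DEL", svlen = 100)
  cc <- mkCohort(rbind(upstream, junction, insIntron, far))
  ann <- annotateGenes(cc, gm)
  rd <- svcohort:::rowDataFrame(cc)
  get <- function(st) ann[match(rd$siteID[rd$start == st], ann$site_id), ]
  j <- get(50900)
  expect_identical(j$class, "gene_overlap")
  expect_true(all(c("exon", "intron", "cds") %in%
                    strsplit(j$features, ",")[[1]]))
  u <- get(50000 - 5000 - 151)
  expect_identical(u$class, "proximal_5kb")
  ii <- get(52000)
  expect_identical(ii$class, "gene_overlap")
  expect_identical(ii$features, "intron")  # anchor base only
  expect_identical(get(200000)$class, "intergenic")
  expect_setequal(unique(ann$class),
                  c("gene_overlap", "proximal_5kb", "intergenic"))
})

test_that("candidate-gene report applies AF and non-intronic filters", {
  set.seed(55)
  gm <- data.frame(gene_id = "APOE4LIKE",
                   feature = c("gene", "exon", "utr3"),
                   chrom = "chr1",
                   start = c(10000, 10000, 11500),
                   end = c(12000, 10500, 12000))
  utrHit <- makeRec("c1", sample = "S1", start = 11600, svtype = "DEL",
                    svlen = 100, genotype = "hom_alt")
  intronOnly <- makeRec("c2", sample = "S1", start = 10700, svtype = "DEL",
                        svlen = 60, genotype = "hom_alt")
  cc <- mkCohort(rbind(utrHit, intronOnly))
  ann <- annotateGenes(cc, gm)
  rep1 <- candidateGeneReport(cc, ann, "APOE4LIKE", minAF = 0.01)
  expect_identical(nrow(rep1), 1L)
  expect_identical(rep1$gene, "APOE4LIKE")
  expect_identical(rep1$svtype, "DEL")
  ## intron-only site enters only when the exclusion is lifted
  rep2 <- candidateGeneReport(cc, ann, "APOE4LIKE",
                              excludeIntronicOnly = FALSE)
  expect_identical(nrow(rep2), 2L)
  ## rare site excluded: simulate af below threshold via minAF above 1
  rep3 <- candidateGeneReport(cc, ann, "APOE4LIKE", minAF = 1.1)
  expect_identical(nrow(rep3), 0L)
})
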