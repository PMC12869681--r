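test_that("planted count outliers are recovered", {
  set.seed(41)
  n <- 500
  base <- cbind(rpois(n, 400), rpois(n, 300), rpois(n, 20))
  shifted <- sample(n, 10)
  base[shifted, ] <- base[shifted, ] + matrix(rep(c(900, 700, 60), each = 10),
                                              ncol = 3)
  counts <- data.frame(sample_id = sprintf("S%03d", 1:n),
                       n_del = base[, 1], n_ins = base[, 2],
                       n_inv = base[, 3])
  flagged <- detectOutlierSamples(counts, fraction = 0.02)
  expect_identical(length(flagged), 10L)
  expect_setequal(flagged, counts$sample_id[shifted])
  expect_identical(detectOutlierSamples(counts, fraction = 0), character(0))
  expect_error(detectOutlierSamples(counts[1:40, ]), "at least 50")
})

test_that("identical samples are flagged deterministically by id order", {
  counts <- data.frame(sample_id = sprintf("S%03d", 1:100),
                       n_del = 100, n_ins = 80, n_inv = 5)
  f1 <- detectOutlierSamples(counts, 0.02)
  expect_identical(f1, c("S001", "S002"))
  expect_identical(detectOutlierSamples(counts, 0.02), f1)
})

test_that("outlier-concentrated studies are flagged by binomial enrichment", {
  meta <- data.frame(
    sample_id = sprintf("S%03d", 1:500),
    study = c(rep("BAD", 10), sample(paste0("ST", 1:10), 490, replace = TRUE)))
  ## all 10 BAD samples flagged at a 2% global rate
  flagged <- meta$sample_id[1:10]
  hit <- flagOutlierStudies(flagged, meta)
  expect_identical(as.character(hit), "BAD")
  ## oracle: binomial tail at the global rate
  tab <- attr(hit, "table")
  expect_equal(tab$p[tab$study == "BAD"],
               pbinom(9, 10, 10 / 500, lower.tail = FALSE), tolerance = 1e-12)
  expect_identical(length(flagOutlierStudies(character(0), meta)), 0L)
})

test_that("uniformly spread outliers rarely implicate a study", {
  set.seed(42)
  meta <- data.frame(sample_id = sprintf("S%04d", 1:1000),
                     study = rep(paste0("ST", 1:20), each = 50))
  hits <- replicate(50, {
    flagged <- sample(meta$sample_id, 20)  # the global 2% rate
    length(flagOutlierStudies(flagged, meta))
  })
  expect_lt(mean(hits > 0), 0.3)
})

test_that("cohort construction counts alleles correctly", {
  set.seed(43)
  base <- makeRec("r1", sample = "S1", start = 1000, svlen = 100,
                  genotype = "het")
  r2 <- base; r2$record_id <- "r2"; r2$sample_id <- "S2"
  r3 <- base; r3$record_id <- "r3"; r3$sample_id <- "S3"
  r3$genotype <- "hom_alt"
  meta <- data.frame(sample_id = c("S1", "S2", "S3"),
                     individual_id = c("I1", "I2", "I3"),
                     read_length = c(150L, 150L, 150L))
  cc <- buildCohort(rbind(base, r2, r3), meta)
  expect_identical(nrow(cc), 1L)
  expect_equal(unname(siteAF(cc)), 4 / 6)
  expect_equal(unname(siteAC(cc)), 4)
  ## singleton
  solo <- makeRec("s", sample = "S1", start = 8000, genotype = "het")
  cc2 <- buildCohort(rbind(base, r2, r3, solo), meta)
  expect_equal(sort(unname(siteAC(cc2))), c(1, 4))
  ## read-length restriction drops mixed-length samples
  meta$read_length <- c(150L, 100L, 150L)
  cc3 <- buildCohort(rbind(base, r2, r3), meta, readLength = 150)
  expect_identical(ncol(cc3), 2L)
  expect_equal(unname(siteAF(cc3)), 3 / 4)
})

test_that("allele frequencies are invariant to sample order", {
  set.seed(44)
  co <- simulateCohort(simConfig(nPerPop = c(10, 10), nSites = 25,
                                 falseCallRate = 0), seed = 4)
  meta <- co$meta
  cc1 <- buildCohort(co$calls, meta)
  cc2 <- buildCohort(co$calls, meta[rev(seq_len(nrow(meta))), ])
  expect_equal(sort(unname(siteAF(cc1))), sort(unname(siteAF(cc2))))
})

test_that("SFS summary bins conserve counts and obey the bin conventions", {
  set.seed(45)
  co <- simulateCohort(simConfig(nPerPop = c(25, 25), nSites = 60,
                                 falseCallRate = 0), seed = 6)
  cc <- buildCohort(co$calls, co$meta)
  s <- sfsSummary(cc)
  expect_identical(sum(unlist(s$af_bins[, -1])), nrow(cc))
  expect_identical(sum(s$singleton_by_type$n), nrow(cc))
  ## size bins are left-closed right-open: 299 and 301 differ, 300 sits right
  expect_identical(as.character(cut(c(299, 300, 301), c(50, 100, 300, 1000),
                                    right = FALSE)),
                   c("[100,300)", "[300,1e+03)", "[300,1e+03)"))
  ## all-singleton degenerate case
  solo <- rbind(makeRec("a", sample = "S1", start = 1000, genotype = "het"),
                makeRec("b", sample = "S1", start = 8000, svtype = "INS",
                        genotype = "het"))
  meta <- data.frame(sample_id = "S1", individual_id = "I1")
  sSolo <- sfsSummary(buildCohort(solo, meta))
  expect_true(all(na.omit(sSolo$singleton_by_type$singleton_prop) == 1))
})

test_that("exact HWE test matches the enumeration oracle for all n <= 20", {
  expect_identical(hweExact(100, 0, 0), 1.0)
  for (n in c(3, 7, 12, 20)) {
    for (nAlt in 1:n) {  # enumerate allele counts, scan het configs
      for (h in seq.int(nAlt %% 2, min(nAlt, n), by = 2)) {
        homAlt <- (nAlt - h) / 2
        homRef <- n - h - homAlt
        if (homRef < 0) next
        expect_equal(hweExact(homRef, h, homAlt), hweOracle(homRef, h, homAlt),
                     tolerance = 1e-12)
      }
    }
  }
  expect_lt(hweExact(0, 100, 0), 1e-6)
  expect_error(hweExact(-1, 0, 3), ">= 0")
})

test_that("HWE type-I rate is nominal under HWE-compliant genotypes", {
  set.seed(46)
  pvals <- replicate(2000, {
    p <- runif(1, 0.1, 0.5)
    g <- rbinom(120, 2, p)
    hweExact(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  rate <- mean(pvals < 0.05)
  ## exact-test conservatism keeps the rate at or below nominal
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 2000) + 0.005)
})
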