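randomBases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutateSeq <- function(s, rate) {
  if (rate <= 0 || nchar(s) == 0) return(s)
  ch <- strsplit(s, "")[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

#' Simulation configuration
#'
#' Returns the generator configuration with defaults emulating the study's
#' data structure: a Balding-Nichols two-population cohort, an SV type mix
#' of 55.8\% deletions / 41.8\% insertions / 2.4\% inversions, a size
#' distribution dominated by 50-100 bp events with an ALU-like mode near
#' 300 bp, true-call quality scores centred at 70 and false-call scores at
#' 30 (sd 10 each, so a threshold of 50 separates them), 5\% replicate
#' dropout and small breakpoint jitter. Every stochastic choice is fully
#' determined by (config, seed). Override any field by name.
#'
#' @param ... named overrides of the defaults.
#' @return a config list (class \code{svcohort_sim_config}).
#' @export
simConfig <- function(...) {
  cfg <- list(
    ancestries = c("AFR", "EUR"),
    nPerPop = c(150, 150),
    fst = c(0.1, 0.1),
    nSites = 250,
    afBeta = c(0.2, 2),
    typeMix = c(DEL = 0.5578, INS = 0.4178, INV = 0.0244),
    sizeAluWeight = 0.25,  # fraction of events at the ~300 bp mode
    sizeSmallWeight = 0.45,  # fraction in the 50-100 bp band
    caseFraction = 0.5,
    causalEffects = data.frame(site = integer(0), or = numeric(0)),
    sexEffect = 0.2,
    centerEffect = 0.1,
    replicateIndividuals = 10,
    replicateDropout = 0.05,
    breakpointJitterSD = 3,
    seqErrorRate = 0.005,
    falseCallRate = 0.1,
    qualTrue = c(mean = 70, sd = 10),
    qualFalse = c(mean = 30, sd = 10),
    tagLoci = list(),
    nStudies = 6,
    nGenes = 15,
    catalogFraction = 0.35,
    catalogAFNoiseSD = 0,
    chrom = "chr1",
    siteSpacing = 15000)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (length(cfg$nPerPop) != length(cfg$ancestries) ||
      length(cfg$fst) != length(cfg$ancestries))
    stop("nPerPop and fst must match ancestries")
  if (any(unlist(cfg[c("replicateDropout", "seqErrorRate", "caseFraction")]) < 0) ||
      cfg$caseFraction > 1)
    stop("fractions must lie in [0, 1]")
  if (nrow(cfg$causalEffects) && any(cfg$causalEffects$or <= 0))
    stop("odds ratios must be > 0")
  class(cfg) <- "svcohort_sim_config"
  cfg
}

drawSize <- function(n, cfg) {
  u <- runif(n)
  sz <- integer(n)
  small <- u < cfg$sizeSmallWeight
  alu <- !small & u < cfg$sizeSmallWeight + cfg$sizeAluWeight
  body <- !small & !alu
  sz[small] <- as.integer(round(runif(sum(small), 50, 100)))
  sz[alu] <- pmax(50L, as.integer(round(rnorm(sum(alu), 300, 30))))
  sz[body] <- as.integer(round(exp(runif(sum(body), log(100), log(8000)))))
  sz
}

drawQual <- function(n, spec) pmax(0, rnorm(n, spec[["mean"]], spec[["sd"]]))

makeGeneModels <- function(cfg, regionEnd) {
  rows <- list()
  span <- regionEnd - 1000
  for (g in seq_len(cfg$nGenes)) {
    gs <- round(1000 + (g - 1) * span / cfg$nGenes)
    glen <- 30000
    ge <- gs + glen
    gid <- sprintf("GENE%02d", g)
    ex <- rbind(c(gs, gs + 2000), c(gs + 14000, gs + 16000),
                c(ge - 2000, ge))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid,
      feature = c("gene", "exon", "exon", "exon", "utr5", "cds", "cds",
                  "cds", "utr3"),
      chrom = cfg$chrom,
      start = c(gs, ex[, 1], gs, gs + 200, ex[2, 1], ex[3, 1], ge - 200),
      end = c(ge, ex[, 2], gs + 200, ex[1, 2], ex[2, 2], ge - 200, ge),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

siteAlleles <- function(svtype, svlen, motif) {
  anchor <- sample(c("A", "C", "G", "T"), 1)
  if (svtype == "DEL") {
    list(ref = paste0(anchor, randomBases(svlen)), alt = anchor)
  } else if (svtype == "INS") {
    ins <- substr(strrep(motif, ceiling(svlen / nchar(motif)) + 1),
                  1, svlen)
    ins <- mutateSeq(ins, 0.05)
    list(ref = anchor, alt = paste0(anchor, ins))
  } else {
    s <- randomBases(svlen)
    list(ref = s, alt = reverseComplementSeq(s))
  }
}

#' Simulate Balding-Nichols genotypes only
#'
#' The genotype layer of \code{\link{simulateCohort}} without sequence
#' realization: ancestral AFs from the configured Beta distribution,
#' per-population AFs from Balding-Nichols, Hardy-Weinberg genotypes
#' within population. Used directly when only a dosage matrix is needed
#' (e.g. to validate PCA at many sites).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param seed integer seed.
#' @return list: \code{genotypes} (sites x samples), \code{popAF},
#'   \code{baseAF}, \code{pop} (population index per sample).
#' @export
simulateGenotypes <- function(cfg = simConfig(), seed = 1) {
  set.seed(seed)
  nPop <- length(cfg$ancestries)
  nSamp <- sum(cfg$nPerPop)
  pop <- rep(seq_len(nPop), cfg$nPerPop)
  p0 <- rbeta(cfg$nSites, cfg$afBeta[1], cfg$afBeta[2])
  popAF <- matrix(0, cfg$nSites, nPop,
                  dimnames = list(NULL, cfg$ancestries))
  for (k in seq_len(nPop)) {
    F <- cfg$fst[k]
    popAF[, k] <- if (F <= 0) p0 else
      rbeta(cfg$nSites, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
  }
  G <- matrix(0L, cfg$nSites, nSamp,
              dimnames = list(sprintf("truth_site_%03d", seq_len(cfg$nSites)),
                              sprintf("S%04d", seq_len(nSamp))))
  for (k in seq_len(nPop)) {
    cols <- which(pop == k)
    G[, cols] <- matrix(rbinom(cfg$nSites * length(cols), 2,
                               rep(popAF[, k], length(cols))),
                        nrow = cfg$nSites)
  }
  list(genotypes = G, popAF = popAF, baseAF = p0, pop = pop)
}

#' Simulate a structured SV cohort with full ground truth
#'
#' Draws per-site ancestral allele frequencies from the configured Beta
#' distribution, per-population frequencies from the Balding-Nichols model
#' Beta(p(1-F)/F, (1-p)(1-F)/F), and Hardy-Weinberg genotypes within each
#' population. Sites are sequence-realized (deletions remove a simulated
#' reference substring, insertions carry a motif-seeded sequence,
#' inversions a reverse-complemented substring) and spaced so that
#' distinct sites never co-collapse. Carrier samples emit one call per
#' site with quality from the true-call distribution and small breakpoint
#' jitter; false calls are injected at the configured per-sample rate with
#' quality from the false-call distribution. Case status follows a
#' logistic model with the configured per-site odds ratios plus sex and
#' sequencing-centre effects, with the intercept tuned to the target case
#' fraction.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param seed integer seed; everything is reproducible from (cfg, seed).
#' @return list: \code{calls} (combined call table, true and false calls),
#'   \code{meta} (sample metadata), \code{truth} (true genotype matrix
#'   sites x samples, site table with per-population AFs and causal
#'   effects, per-call truth labels), \code{geneModels}, \code{config}.
#' @export
simulateCohort <- function(cfg = simConfig(), seed = 1) {
  set.seed(seed)
  nPop <- length(cfg$ancestries)
  nSamp <- sum(cfg$nPerPop)
  pop <- rep(seq_len(nPop), cfg$nPerPop)
  sampleIDs <- sprintf("S%04d", seq_len(nSamp))
  motif <- randomBases(300)

  ## sites
  types <- sample(names(cfg$typeMix), cfg$nSites, replace = TRUE,
                  prob = cfg$typeMix)
  sizes <- drawSize(cfg$nSites, cfg)
  starts <- 10000 + (seq_len(cfg$nSites) - 1L) * cfg$siteSpacing
  p0 <- rbeta(cfg$nSites, cfg$afBeta[1], cfg$afBeta[2])
  popAF <- matrix(0, cfg$nSites, nPop,
                  dimnames = list(NULL, cfg$ancestries))
  for (k in seq_len(nPop)) {
    F <- cfg$fst[k]
    popAF[, k] <- if (F <= 0) p0 else
      rbeta(cfg$nSites, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
  }
  alleles <- lapply(seq_len(cfg$nSites), function(i)
    siteAlleles(types[i], sizes[i], motif))
  siteIDs <- sprintf("truth_site_%03d", seq_len(cfg$nSites))
  refLen <- vapply(alleles, function(a) nchar(a$ref), numeric(1))

  ## genotypes
  G <- matrix(0L, cfg$nSites, nSamp, dimnames = list(siteIDs, sampleIDs))
  for (k in seq_len(nPop)) {
    cols <- which(pop == k)
    for (i in seq_len(cfg$nSites))
      G[i, cols] <- rbinom(length(cols), 2, popAF[i, k])
  }

  ## metadata
  sex <- sample(c("male", "female"), nSamp, replace = TRUE)
  center <- sample(c("C1", "C2"), nSamp, replace = TRUE)
  meta <- data.frame(
    sample_id = sampleIDs,
    individual_id = sprintf("I%04d", seq_len(nSamp)),
    study = sprintf("STUDY%02d", sample.int(cfg$nStudies, nSamp, replace = TRUE)),
    read_length = 150L,
    center = center,
    pcr_free = sample(c(TRUE, FALSE), nSamp, replace = TRUE, prob = c(0.7, 0.3)),
    sex = sex,
    ancestry = cfg$ancestries[pop],
    stringsAsFactors = FALSE)

  ## phenotype
  eta <- rep(0, nSamp)
  if (nrow(cfg$causalEffects)) {
    for (r in seq_len(nrow(cfg$causalEffects))) {
      i <- cfg$causalEffects$site[r]
      eta <- eta + log(cfg$causalEffects$or[r]) * G[i, ]
    }
  }
  eta <- eta + cfg$sexEffect * (sex == "male") +
    cfg$centerEffect * (center == "C2")
  b0 <- qlogis(cfg$caseFraction) - mean(eta)
  meta$status <- ifelse(rbinom(nSamp, 1, plogis(b0 + eta)) == 1,
                        "case", "control")

  ## calls (vectorized per sample)
  refAll <- vapply(alleles, `[[`, character(1), "ref")
  altAll <- vapply(alleles, `[[`, character(1), "alt")
  rows <- list(); truthLab <- list()
  for (j in seq_len(nSamp)) {
    carriers <- which(G[, j] > 0)
    nTrue <- length(carriers)
    if (nTrue) {
      jit <- as.integer(round(rnorm(nTrue, 0, cfg$breakpointJitterSD)))
      st <- starts[carriers] + jit
      rid <- sprintf("%s_t%03d", sampleIDs[j], carriers)
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = rid, sample_id = sampleIDs[j], chrom = cfg$chrom,
        start = st, end = st + nchar(refAll[carriers]),
        ref = refAll[carriers], alt = altAll[carriers],
        svtype = types[carriers], svlen = sizes[carriers],
        qual = drawQual(nTrue, cfg$qualTrue), filter = "PASS",
        genotype = ifelse(G[carriers, j] == 2L, "hom_alt", "het"),
        stringsAsFactors = FALSE)
      truthLab[[length(truthLab) + 1L]] <- data.frame(
        record_id = rid, true_call = TRUE, site = siteIDs[carriers],
        stringsAsFactors = FALSE)
    }
    nFalse <- rbinom(1, max(nTrue, 1), cfg$falseCallRate)
    if (nFalse > 0) {
      tp <- sample(names(cfg$typeMix), nFalse, replace = TRUE,
                   prob = cfg$typeMix)
      sz <- drawSize(nFalse, cfg)
      al <- lapply(seq_len(nFalse), function(f)
        siteAlleles(tp[f], sz[f], motif))
      fr <- vapply(al, `[[`, character(1), "ref")
      fa <- vapply(al, `[[`, character(1), "alt")
      st <- 10000 + cfg$nSites * cfg$siteSpacing +
        as.integer(round(runif(nFalse, 0, cfg$nSites * cfg$siteSpacing)))
      rid <- sprintf("%s_f%03d", sampleIDs[j], seq_len(nFalse))
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = rid, sample_id = sampleIDs[j], chrom = cfg$chrom,
        start = st, end = st + nchar(fr), ref = fr, alt = fa, svtype = tp,
        svlen = sz, qual = drawQual(nFalse, cfg$qualFalse), filter = "PASS",
        genotype = "het", stringsAsFactors = FALSE)
      truthLab[[length(truthLab) + 1L]] <- data.frame(
        record_id = rid, true_call = FALSE, site = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  calls <- calls[order(calls$chrom, calls$start, calls$record_id), ]
  rownames(calls) <- NULL
  siteTab <- data.frame(site_id = siteIDs, chrom = cfg$chrom,
                        start = starts, end = starts + refLen,
                        svtype = types, svlen = sizes, base_af = p0,
                        stringsAsFactors = FALSE)
  siteTab <- cbind(siteTab, popAF)
  siteTab$causal_or <- 1
  if (nrow(cfg$causalEffects))
    siteTab$causal_or[cfg$causalEffects$site] <- cfg$causalEffects$or
  regionEnd <- 10000 + 2 * cfg$nSites * cfg$siteSpacing
  list(calls = calls, meta = meta,
       truth = list(genotypes = G, sites = siteTab,
                    call_labels = do.call(rbind, truthLab),
                    alleles = alleles),
       geneModels = makeGeneModels(cfg, regionEnd),
       config = cfg, seed = seed)
}

#' Simulate technical replicates with injected call errors
#'
#' For the first \code{replicateIndividuals} individuals of a simulated
#' cohort, emits a second sample: every true call is duplicated, dropped
#' with probability \code{replicateDropout}, its breakpoint jittered by
#' Normal(0, \code{breakpointJitterSD}), its event sequence mutated at
#' \code{seqErrorRate} per base and its quality redrawn from the true-call
#' distribution; false calls are injected at \code{falseCallRate} with
#' false-call quality.
#'
#' @param cohort output of \code{\link{simulateCohort}}.
#' @param seed integer seed.
#' @return list: \code{calls} (replicate call table), \code{meta}
#'   (replicate sample rows, sharing individual ids with the originals),
#'   \code{labels} (per-call truth).
#' @export
simulateReplicates <- function(cohort, seed = 1) {
  cfg <- cohort$config
  set.seed(seed + 1000003L)
  origIDs <- cohort$meta$sample_id[seq_len(min(cfg$replicateIndividuals,
                                               nrow(cohort$meta)))]
  labTrue <- cohort$truth$call_labels
  rows <- list(); labels <- list(); metaRows <- list()
  for (sid in origIDs) {
    repID <- paste0(sid, "R")
    own <- cohort$calls[cohort$calls$sample_id == sid, , drop = FALSE]
    own <- own[labTrue$true_call[match(own$record_id, labTrue$record_id)], ,
               drop = FALSE]
    k <- 0L
    for (r in seq_len(nrow(own))) {
      if (runif(1) < cfg$replicateDropout) next
      k <- k + 1L
      rec <- own[r, ]
      jit <- as.integer(round(rnorm(1, 0, cfg$breakpointJitterSD)))
      rec$start <- rec$start + jit
      if (rec$svtype == "DEL") {
        rec$ref <- paste0(substr(rec$ref, 1, 1),
                          mutateSeq(substring(rec$ref, 2), cfg$seqErrorRate))
      } else if (rec$svtype == "INS") {
        rec$alt <- paste0(substr(rec$alt, 1, 1),
                          mutateSeq(substring(rec$alt, 2), cfg$seqErrorRate))
      } else {
        rec$alt <- mutateSeq(rec$alt, cfg$seqErrorRate)
      }
      rec$end <- rec$start + nchar(rec$ref)
      rec$record_id <- sprintf("%s_t%03d", repID, k)
      rec$sample_id <- repID
      rec$qual <- drawQual(1, cfg$qualTrue)
      rows[[length(rows) + 1L]] <- rec
      labels[[length(labels) + 1L]] <- data.frame(
        record_id = rec$record_id, true_call = TRUE,
        source_record = own$record_id[r])
    }
    nFalse <- rbinom(1, max(nrow(own), 1), cfg$falseCallRate)
    if (nFalse > 0) for (f in seq_len(nFalse)) {
      tp <- sample(names(cfg$typeMix), 1, prob = cfg$typeMix)
      sz <- drawSize(1, cfg)
      al <- siteAlleles(tp, sz, randomBases(300))
      st <- 10000 + cfg$nSites * cfg$siteSpacing +
        as.integer(round(runif(1, 0, cfg$nSites * cfg$siteSpacing)))
      rid <- sprintf("%s_f%03d", repID, f)
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = rid, sample_id = repID, chrom = cfg$chrom, start = st,
        end = st + nchar(al$ref), ref = al$ref, alt = al$alt, svtype = tp,
        svlen = sz, qual = drawQual(1, cfg$qualFalse), filter = "PASS",
        genotype = "het", stringsAsFactors = FALSE)
      labels[[length(labels) + 1L]] <- data.frame(
        record_id = rid, true_call = FALSE, source_record = NA_character_)
    }
    m <- cohort$meta[cohort$meta$sample_id == sid, , drop = FALSE]
    m$sample_id <- repID
    metaRows[[length(metaRows) + 1L]] <- m
  }
  calls <- if (length(rows)) do.call(rbind, rows) else emptyCallTable()
  calls <- calls[order(calls$chrom, calls$start, calls$record_id), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls,
       meta = if (length(metaRows)) do.call(rbind, metaRows) else NULL,
       labels = if (length(labels)) do.call(rbind, labels) else NULL)
}

#' Simulate an SV in target LD with a tag SNP
#'
#' Constructs two-locus haplotype frequencies whose population r-squared
#' equals the target, with the SV alternate allele placed on the risk
#' (\code{orientation = "risk"}) or non-risk haplotype background, then
#' draws 2n haplotypes and pairs them into unphased dosages. An infeasible
#' target (D-squared beyond the allele-frequency bound) is an error naming
#' the maximum attainable r-squared.
#'
#' @param targetR2 target r-squared in [0, 1].
#' @param n number of diploid samples.
#' @param afSV,afSNP alternate/risk allele frequencies.
#' @param orientation \code{"risk"} or \code{"nonrisk"}.
#' @param seed integer seed.
#' @return list: \code{sv} and \code{snp} dosage vectors, \code{truth}
#'   (target and haplotype-level realized r-squared, haplotype counts).
#' @export
simulateTaggedLocus <- function(targetR2, n, afSV = 0.3, afSNP = 0.3,
                                orientation = c("risk", "nonrisk"),
                                seed = 1) {
  orientation <- match.arg(orientation)
  set.seed(seed + 2000003L)
  pA <- afSV; pB <- afSNP
  sgn <- if (orientation == "risk") 1 else -1
  D <- sgn * sqrt(targetR2 * pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (sgn > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (abs(D) > dmax + 1e-12) {
    r2max <- dmax^2 / (pA * (1 - pA) * pB * (1 - pB))
    stop(sprintf("target r2 %.3f infeasible for AFs (%.3f, %.3f); maximum attainable r2 is %.3f",
                 targetR2, afSV, afSNP, r2max))
  }
  f <- c(AB = pA * pB + D, Ab = pA * (1 - pB) - D,
         aB = (1 - pA) * pB - D, ab = (1 - pA) * (1 - pB) + D)
  f <- pmax(f, 0); f <- f / sum(f)
  haps <- rmultinom(1, 2 * n, f)[, 1]
  hapAlleles <- cbind(sv = c(1, 1, 0, 0), snp = c(1, 0, 1, 0))
  hapSeq <- rep(seq_len(4), haps)
  hapSeq <- sample(hapSeq)  # random pairing into diploids
  h1 <- hapSeq[seq_len(n)]; h2 <- hapSeq[n + seq_len(n)]
  sv <- hapAlleles[h1, "sv"] + hapAlleles[h2, "sv"]
  snp <- hapAlleles[h1, "snp"] + hapAlleles[h2, "snp"]
  fr <- haps / sum(haps)
  pAr <- fr[1] + fr[2]; pBr <- fr[1] + fr[3]
  Dr <- fr[1] - pAr * pBr
  r2r <- if (pAr %in% c(0, 1) || pBr %in% c(0, 1)) NA_real_ else
    Dr^2 / (pAr * (1 - pAr) * pBr * (1 - pBr))
  list(sv = sv, snp = snp,
       truth = list(target_r2 = targetR2, realized_r2 = unname(r2r),
                    hap_counts = haps, hap_freqs = f, D = D))
}

#' Write a self-describing fixture bundle
#'
#' Emits the complete set of pipeline inputs for a simulated cohort:
#' per-sample VCFs (including replicates when given), the sample metadata
#' TSV, gene models as GFF3, a known-SV catalog TSV (a configured fraction
#' of the true sites with truth-derived AFs plus optional noise), a
#' pathogenicity score table, optional tag-SNP dosages, and the truth JSON
#' with the embedded configuration.
#'
#' @param cohort output of \code{\link{simulateCohort}}.
#' @param dir output directory.
#' @param replicates optional output of \code{\link{simulateReplicates}}.
#' @param tagged optional output of \code{\link{simulateTaggedLocus}}.
#' @param force overwrite an existing directory.
#' @return \code{dir}, invisibly.
#' @export
writeFixtureBundle <- function(cohort, dir, replicates = NULL,
                               tagged = NULL, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory exists; use force = TRUE")
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  allCalls <- cohort$calls
  meta <- cohort$meta
  if (!is.null(replicates) && nrow(replicates$calls)) {
    allCalls <- rbind(allCalls, replicates$calls)
    meta <- rbind(meta, replicates$meta)
  }
  for (sid in meta$sample_id) {
    tab <- allCalls[allCalls$sample_id == sid, , drop = FALSE]
    tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
    writeSVVcf(tab, file.path(dir, "vcf", paste0(sid, ".vcf")),
               sampleID = sid)
  }
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  writeGFF3(cohort$geneModels, file.path(dir, "genes.gff3"))

  ## catalog: a fraction of true sites, truth-derived pooled AF +/- noise
  st <- cohort$truth$sites
  G <- cohort$truth$genotypes
  pooledAF <- rowMeans(G) / 2
  nCat <- round(cfg$catalogFraction * nrow(st))
  idx <- sort(sample.int(nrow(st), nCat))
  catalog <- data.frame(
    chrom = st$chrom[idx], start = st$start[idx], end = st$end[idx],
    svtype = st$svtype[idx], svlen = st$svlen[idx],
    af = pmin(1, pmax(0, pooledAF[idx] +
                        rnorm(nCat, 0, cfg$catalogAFNoiseSD))),
    source = "SIMCAT", stringsAsFactors = FALSE)
  write.table(catalog, file.path(dir, "catalog.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  ## pathogenicity scores keyed by true site position/type
  gm <- cohort$geneModels
  bodies <- gm[gm$feature == "gene", ]
  ex <- gm[gm$feature == "exon", ]
  rows <- list()
  for (i in seq_len(nrow(st))) {
    hit <- bodies$gene_id[bodies$start < st$end[i] + 1e6 &
                            bodies$end > st$start[i] - 1e6]
    for (g in hit)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = st$chrom[i], start = st$start[i], svtype = st$svtype[i],
        gene_id = g, score = round(runif(1), 3), stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  write.table(scores, file.path(dir, "pathogenicity.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  if (!is.null(tagged)) {
    tg <- data.frame(sample_id = cohort$meta$sample_id,
                     snp_dosage = tagged$snp, stringsAsFactors = FALSE)
    write.table(tg, file.path(dir, "tagsnp.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  truth <- list(config = unclass(cfg), seed = cohort$seed,
                genotypes = cohort$truth$genotypes,
                sites = cohort$truth$sites,
                call_labels = cohort$truth$call_labels)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.data.frame, logical(1))],
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

writeGFF3 <- function(gm, path) {
  typeMap <- c(gene = "gene", exon = "exon", cds = "CDS",
               utr5 = "five_prime_UTR", utr3 = "three_prime_UTR")
  lines <- c("##gff-version 3",
             sprintf("%s\tsvcohort_sim\t%s\t%d\t%d\t.\t+\t.\tID=%s;gene_id=%s",
                     gm$chrom, typeMap[gm$feature], gm$start + 1L, gm$end,
                     paste0(gm$gene_id, "_", gm$feature,
                            seq_len(nrow(gm))), gm$gene_id))
  writeLines(lines, path)
  invisible(path)
}
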