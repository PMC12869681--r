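#' Classify calls between technical replicates as consistent/inconsistent
#'
#' Matches the two call sets one-to-one; matched pairs with BOTH sequence
#' and size similarity strictly above \code{simMin} (default 0.70) are
#' consistent, everything else — below-threshold pairs and unmatched calls
#' on either side — is inconsistent. Every call of both call sets is counted
#' exactly once, so 2 x n_consistent + n_inconsistent equals the total call
#' count.
#'
#' @param a,b \linkS4class{SVCallSet}s from two sequencing runs of the same
#'   individual; an error is raised when \code{meta} shows different
#'   individuals.
#' @param simMin strict lower bound for both similarities.
#' @param maxDist candidate-pair distance in bp.
#' @param meta optional sample metadata data.frame with \code{sample_id} and
#'   \code{individual_id}, used to verify the pair.
#' @return list (replicate report): \code{pair_id}, \code{n_consistent},
#'   \code{n_inconsistent}, \code{consistent_quals},
#'   \code{inconsistent_quals}, \code{frac_highsim} (fraction of consistent
#'   matches with both similarities >= 0.95).
#' @export
classifyReplicateCalls <- function(a, b, simMin = 0.70, maxDist = 1000,
                                   meta = NULL) {
  ta <- if (is(a, "SVCallSet")) callTable(a) else a
  tb <- if (is(b, "SVCallSet")) callTable(b) else b
  if (!is.null(meta)) {
    ia <- meta$individual_id[match(ta$sample_id[1L], meta$sample_id)]
    ib <- meta$individual_id[match(tb$sample_id[1L], meta$sample_id)]
    if (!isTRUE(ia == ib))
      stop("replicate call sets must come from the same individual")
  }
  p <- matchParams(simMin, simMin, maxDist, requireSameType = TRUE,
                   strict = TRUE)
  mm <- matchCallsets(ta, tb, p)
  m <- mm$matches
  consQ <- c(ta$qual[match(m$id_a, ta$record_id)],
             tb$qual[match(m$id_b, tb$record_id)])
  inconsQ <- c(ta$qual[ta$record_id %in% mm$unmatched_a],
               tb$qual[tb$record_id %in% mm$unmatched_b])
  fracHigh <- if (nrow(m)) {
    mean(m$pct_seq_similarity >= 0.95 & m$pct_size_similarity >= 0.95)
  } else NA_real_
  list(pair_id = paste(ta$sample_id[1L] %||% "a", tb$sample_id[1L] %||% "b",
                       sep = "|"),
       n_consistent = nrow(m),
       n_inconsistent = length(mm$unmatched_a) + length(mm$unmatched_b),
       consistent_quals = consQ,
       inconsistent_quals = inconsQ,
       frac_highsim = fracHigh)
}

#' Calibrate the cohort quality-score threshold from replicate concordance
#'
#' Scans an integer grid of candidate thresholds t and returns the one
#' maximizing Youden's J(t) = P(consistent qual >= t) - P(inconsistent
#' qual >= t), i.e. the score that best segregates consistent from
#' inconsistent calls. Ties go to the smallest t. A Kolmogorov-Smirnov
#' mode (\code{method = "ks"}) maximizes the absolute ECDF gap instead.
#'
#' @param consistentQuals,inconsistentQuals nonempty numeric score vectors.
#' @param gridStep grid spacing of candidate thresholds.
#' @param method "youden" (default) or "ks".
#' @return list: \code{threshold}, \code{J} (criterion value at the
#'   optimum), \code{grid}, \code{J_grid}.
#' @export
calibrateQualityThreshold <- function(consistentQuals, inconsistentQuals,
                                      gridStep = 1, method = c("youden", "ks")) {
  method <- match.arg(method)
  if (!length(consistentQuals) || !length(inconsistentQuals))
    stop("both quality-score lists must be nonempty")
  rng <- range(c(consistentQuals, inconsistentQuals))
  grid <- seq(floor(rng[1L]), ceiling(rng[2L]) + gridStep, by = gridStep)
  sensC <- vapply(grid, function(t) mean(consistentQuals >= t), numeric(1))
  sensI <- vapply(grid, function(t) mean(inconsistentQuals >= t), numeric(1))
  J <- if (method == "youden") sensC - sensI else abs(sensC - sensI)
  best <- which.max(J)  # which.max takes the first (smallest t) on ties
  list(threshold = grid[best], J = J[best], grid = grid, J_grid = J)
}

#' Apply the minimum quality-score filter
#'
#' Retains records with \code{qual >= t} (default 50) and reports the
#' removed count, so that raw = retained + removed always holds.
#'
#' @param x \linkS4class{SVCallSet} or call table.
#' @param t minimum quality score.
#' @return list: \code{passed} (same class as input), \code{removed_count}.
#' @export
applyQualityFilter <- function(x, t = 50) {
  tab <- if (is(x, "SVCallSet")) callTable(x) else x
  keep <- tab$qual >= t
  passed <- tab[keep, , drop = FALSE]
  rownames(passed) <- NULL
  if (is(x, "SVCallSet")) passed <- SVCallSet(passed)
  list(passed = passed, removed_count = sum(!keep))
}
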