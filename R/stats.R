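# Significance machinery: chi-squared goodness of fit, G-test, chi-squared
# homogeneity across timepoints, and the per-region summary assembly.
# Cells with small expected counts are pooled deterministically
# left-to-right before testing.

# Pool adjacent cells left-to-right until every pooled expected count is
# >= minExpected; a trailing short pool is merged backwards. Returns
# list(observed, expected).
.poolCells <- function(observed, expected, minExpected = 5) {
  n <- length(observed)
  grp <- integer(n)
  g <- 1L; acc <- 0
  for (i in seq_len(n)) {
    grp[i] <- g
    acc <- acc + expected[i]
    if (acc >= minExpected && i < n) { g <- g + 1L; acc <- 0 }
  }
  if (acc < minExpected && g > 1L) grp[grp == g] <- g - 1L
  list(observed = as.numeric(tapply(observed, grp, sum)),
       expected = as.numeric(tapply(expected, grp, sum)))
}

#' Chi-squared goodness of fit
#'
#' Pearson X2 of observed counts against expected weights (rescaled to
#' the observed total), `df = ncells - 1`, upper-tail p-value. Cells
#' with expected < `minExpected` are pooled with their neighbours
#' (deterministic, left-to-right); with fewer than 2 cells after pooling
#' the result is missing.
#'
#' @param observed non-negative counts.
#' @param expected positive weights (any scale).
#' @param pool pool small-expected cells first (default TRUE).
#' @param minExpected pooling threshold (default 5).
#' @return `list(statistic, df, p_value)`.
#' @export
chisqGof <- function(observed, expected, pool = TRUE, minExpected = 5) {
  keep <- expected > 0
  observed <- observed[keep]; expected <- expected[keep]
  if (length(observed) < 2L)
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  expected <- expected * sum(observed) / sum(expected)
  if (pool) {
    p <- .poolCells(observed, expected, minExpected)
    observed <- p$observed; expected <- p$expected
  }
  if (length(observed) < 2L)
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' G-test goodness of fit
#'
#' Likelihood-ratio statistic `G = 2 * sum(O * ln(O / E))` over cells
#' with `O > 0`, against the chi-squared upper tail with
#' `df = ncells - 1`. Pooling as in [chisqGof()].
#'
#' @inheritParams chisqGof
#' @return `list(statistic, df, p_value)`.
#' @export
gTest <- function(observed, expected, pool = TRUE, minExpected = 5) {
  keep <- expected > 0
  observed <- observed[keep]; expected <- expected[keep]
  if (length(observed) < 2L)
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  expected <- expected * sum(observed) / sum(expected)
  if (pool) {
    p <- .poolCells(observed, expected, minExpected)
    observed <- p$observed; expected <- p$expected
  }
  if (length(observed) < 2L)
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  pos <- observed > 0
  stat <- 2 * sum(observed[pos] * log(observed[pos] / expected[pos]))
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Chi-squared homogeneity of two timepoint distributions
#'
#' Standard 2 x k contingency chi-squared comparing two count vectors
#' over the same positions (`df = k - 1` after pooling columns whose
#' expected cells fall below `minExpected`). A timepoint with zero total
#' gives a missing result.
#'
#' @param counts0,counts48 count vectors over the same positions.
#' @param pool,minExpected as in [chisqGof()].
#' @return `list(statistic, df, p_value)`.
#' @export
chisqHomogeneity <- function(counts0, counts48, pool = TRUE,
                             minExpected = 5) {
  .check(length(counts0) == length(counts48), "count vectors differ in length")
  n0 <- sum(counts0); n48 <- sum(counts48)
  if (n0 == 0 || n48 == 0)
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  colTot <- counts0 + counts48
  keep <- colTot > 0
  counts0 <- counts0[keep]; counts48 <- counts48[keep]; colTot <- colTot[keep]
  if (pool) {
    # pool on the smaller row's expected counts so all cells clear the bar
    minRowFrac <- min(n0, n48) / (n0 + n48)
    p <- .poolCells(counts0 + counts48, colTot * minRowFrac, minExpected)
    grpSizes <- p$observed  # pooled column totals
    # recover pooled rows by applying the same grouping
    g <- .poolCells(counts0, colTot * minRowFrac, minExpected)
    counts0 <- g$observed
    counts48 <- grpSizes - counts0
    colTot <- grpSizes
  }
  k <- length(colTot)
  if (k < 2L)
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  tot <- n0 + n48
  e0 <- colTot * n0 / tot
  e48 <- colTot * n48 / tot
  stat <- sum((counts0 - e0)^2 / e0) + sum((counts48 - e48)^2 / e48)
  df <- k - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' G-test of independence for a contingency table
#'
#' `G = 2 * sum(O * ln(O / E))` with `E` from the usual row/column
#' margins, `df = (r - 1)(c - 1)`. Used for region-vs-reference
#' timepoint redistribution calls.
#'
#' @param tab contingency matrix of counts.
#' @return `list(statistic, df, p_value)`.
#' @export
gTestIndependence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pos <- tab > 0
  stat <- 2 * sum(tab[pos] * log(tab[pos] / e[pos]))
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Poisson likelihood-ratio test of a single observed count
#'
#' Tests one observed count against a known expectation via the G
#' statistic `2 * (O * ln(O / E) - (O - E))` on 1 df. Used for
#' per-dipyrimidine significance calls where only one cell exists.
#'
#' @param observed observed count.
#' @param expected expected count (> 0).
#' @return `list(statistic, df, p_value)`.
#' @export
poissonGTest <- function(observed, expected) {
  if (is.na(expected) || expected <= 0)
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  stat <- if (observed > 0)
    2 * (observed * log(observed / expected) - (observed - expected))
  else 2 * expected
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Per-region observed-vs-expected summary
#'
#' Emits one row per region comparing an observed per-offset profile to
#' an expected one: summed counts, `log2(observed / expected)` (the
#' expected sum rescaled to the observed total first), a significance
#' call, a `significant` flag at P < 0.05 (uncorrected, matching the
#' raw-P convention) and a Benjamini-Hochberg column across the emitted
#' rows. Significance tests the *level* of the region against the
#' expectation: the chosen statistic on the two-cell partition
#' (inside region, rest of window), df = 1, so a uniform excess over a
#' region is detected even though its internal shape matches.
#'
#' @param observed,expected per-offset vectors (length 2001).
#' @param config an [analysisConfig()].
#' @param test `"gtest"` (default) or `"chi2"`.
#' @param metric label copied into the output.
#' @param motifId label copied into the output.
#' @return `data.frame` with one row per region.
#' @export
summarizeRegions <- function(observed, expected, config = analysisConfig(),
                             test = c("gtest", "chi2"), metric = "mutations",
                             motifId = "") {
  test <- match.arg(test)
  expected <- expected * sum(observed) / sum(expected)
  rows <- lapply(c("motif", "tfbs", "dhs_flank", "flank"), function(region) {
    idx <- regionIndices(config, region)
    oSum <- sum(observed[idx]); eSum <- sum(expected[idx])
    oCells <- c(oSum, sum(observed) - oSum)
    eCells <- c(eSum, sum(expected) - eSum)
    tst <- if (test == "gtest") gTest(oCells, eCells, pool = FALSE)
      else chisqGof(oCells, eCells, pool = FALSE)
    data.frame(motif_id = motifId, region = region, metric = metric,
               observed_sum = oSum, expected_sum = eSum,
               log2_ratio = if (oSum > 0 && eSum > 0) log2(oSum / eSum)
                 else NA_real_,
               statistic = tst$statistic, p_value = tst$p_value,
               test = test, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out$fdr_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
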