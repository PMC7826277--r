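# Relative repair from two-timepoint fixed-depth CPD maps, damage-vs-naked
# summaries, 48h damage prediction, and the damage/mutation correlation.

#' Relative repair profile from two CPD timepoints
#'
#' Both tracks are normalised (by their window totals, or by supplied
#' genome-wide totals) and subtracted per offset:
#' `repair = rel0 - rel48`. With fixed-depth maps only this
#' redistribution is identifiable; under window scope the repair profile
#' sums to zero by construction.
#'
#' @param cpd0,cpd48 per-offset count vectors of the two timepoints.
#' @param scope `"window"` (normalise by window totals) or `"genome"`.
#' @param genomeTotals numeric(2) `c(total0, total48)` when
#'   `scope = "genome"`.
#' @return `data.frame(offset, rel0, rel48, repair)`.
#' @export
relativeRepairProfile <- function(cpd0, cpd48,
                                  scope = c("window", "genome"),
                                  genomeTotals = NULL) {
  scope <- match.arg(scope)
  .check(length(cpd0) == length(cpd48), "tracks differ in length")
  if (scope == "window") {
    t0 <- sum(cpd0); t48 <- sum(cpd48)
  } else {
    .check(!is.null(genomeTotals) && length(genomeTotals) == 2L,
           "genome scope needs genomeTotals = c(total0, total48)")
    t0 <- genomeTotals[1]; t48 <- genomeTotals[2]
  }
  .check(t0 > 0 && t48 > 0, "zero CPD total at a timepoint")
  hw <- (length(cpd0) - 1L) %/% 2L
  rel0 <- cpd0 / t0
  rel48 <- cpd48 / t48
  data.frame(offset = seq.int(-hw, hw), rel0 = rel0, rel48 = rel48,
             repair = rel0 - rel48)
}

#' Observed vs naked-DNA damage summary per region
#'
#' Window-normalises the 0h and naked-DNA CPD profiles and summarises
#' each region as `log2(sum observed fractions / sum naked fractions)`
#' with a significance call on the region's level against the
#' naked-derived expectation (two-cell in-region/rest-of-window
#' partition of the observed counts, expected from the naked fractions
#' scaled to the observed total; df = 1).
#'
#' @param cpd0,naked per-offset count vectors.
#' @param config an [analysisConfig()].
#' @param test `"gtest"` (default, as used for region deviation calls)
#'   or `"chi2"`.
#' @return `data.frame` with one row per region: sums, `log2_ratio`,
#'   `statistic`, `p_value`, `test`.
#' @export
damageVsNakedSummary <- function(cpd0, naked, config = analysisConfig(),
                                 test = c("gtest", "chi2")) {
  test <- match.arg(test)
  obs <- normalizeWindowTrack(cpd0, "cpd_0h")
  exp <- normalizeWindowTrack(naked, "cpd_naked")
  out <- lapply(c("motif", "tfbs", "dhs_flank", "flank"), function(region) {
    idx <- regionIndices(config, region)
    oSum <- sum(obs[idx]); eSum <- sum(exp[idx])
    if (eSum == 0)
      return(data.frame(region = region, observed_sum = oSum,
                        expected_sum = eSum, log2_ratio = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        test = test))
    oCells <- c(sum(cpd0[idx]), sum(cpd0) - sum(cpd0[idx]))
    eCells <- c(eSum, 1 - eSum) * sum(cpd0)
    tst <- if (test == "gtest")
      gTest(oCells, eCells, pool = FALSE)
    else chisqGof(oCells, eCells, pool = FALSE)
    data.frame(region = region, observed_sum = oSum, expected_sum = eSum,
               log2_ratio = if (oSum > 0) log2(oSum / eSum) else NA_real_,
               statistic = tst$statistic, p_value = tst$p_value, test = test)
  })
  do.call(rbind, out)
}

#' Region repair relative to a reference region
#'
#' Summarises a relative-repair profile as
#' `log2(mean repair in region / mean repair in reference)` per region,
#' using means so regions of different widths are comparable. Regions
#' with non-positive mean repair are reported as missing (log
#' undefined); a non-positive reference mean is an error. When the raw
#' 0h/48h count profiles are supplied, each region also gets a G-test of
#' independence on the 2 x 2 table (region vs reference x timepoint),
#' testing whether CPDs redistributed between the region and the
#' reference.
#'
#' @param repairProfile output of [relativeRepairProfile()].
#' @param config an [analysisConfig()].
#' @param reference `"flank"` or `"dhs_flank"`.
#' @param cpd0,cpd48 optional per-offset count vectors for the
#'   significance test.
#' @return `data.frame` with one row per non-reference region.
#' @export
regionRepairRatio <- function(repairProfile, config = analysisConfig(),
                              reference = c("flank", "dhs_flank"),
                              cpd0 = NULL, cpd48 = NULL) {
  reference <- match.arg(reference)
  refIdx <- regionIndices(config, reference)
  refMean <- mean(repairProfile$repair[refIdx])
  .check(refMean > 0, "reference region '%s' has non-positive mean repair",
         reference)
  regions <- setdiff(c("motif", "tfbs", "dhs_flank", "flank"), reference)
  out <- lapply(regions, function(region) {
    idx <- regionIndices(config, region)
    m <- mean(repairProfile$repair[idx])
    ratio <- if (m > 0) log2(m / refMean) else NA_real_
    stat <- p <- NA_real_
    if (!is.null(cpd0) && !is.null(cpd48)) {
      tab <- rbind(c(sum(cpd0[idx]), sum(cpd0[refIdx])),
                   c(sum(cpd48[idx]), sum(cpd48[refIdx])))
      tst <- gTestIndependence(tab)
      stat <- tst$statistic; p <- tst$p_value
    }
    data.frame(region = region, reference = reference, mean_repair = m,
               reference_mean_repair = refMean, log2_ratio = ratio,
               statistic = stat, p_value = p)
  })
  do.call(rbind, out)
}

#' Predict the 48h CPD distribution of an independent 0h map
#'
#' Learns the per-offset 0h-to-48h redistribution from a reference
#' dataset (`f_i = rel(ref48)_i / rel(ref0)_i`) and applies it to an
#' independently measured 0h profile:
#' `predicted_i = rel(target0)_i * f_i`, renormalised to sum 1. All
#' three inputs enter only through their normalised shapes, so the
#' prediction is invariant to rescaling any input. Zero reference cells
#' are tamed by add-`pseudo` smoothing of both reference tracks
#' (applied only when needed so that the identity cases
#' `target0 = ref0` and `ref48 = ref0` are reproduced exactly);
#' `smoothBw > 1` additionally applies a moving-average to `f`.
#'
#' @param target0 per-offset 0h counts to project forward.
#' @param ref0,ref48 reference per-offset counts at 0h and 48h.
#' @param pseudo pseudocount added to the reference tracks when `ref0`
#'   has zero cells where `target0` is positive (default 0.5).
#' @param smoothBw moving-average bandwidth for the redistribution
#'   factor (default 1 = off).
#' @return Numeric per-offset predicted 48h fractions (sum 1).
#' @export
predictCpds48h <- function(target0, ref0, ref48, pseudo = 0.5,
                           smoothBw = 1L) {
  .check(length(target0) == length(ref0) && length(ref0) == length(ref48),
         "tracks differ in length")
  .check(sum(target0) > 0 && sum(ref0) > 0 && sum(ref48) > 0,
         "zero CPD total")
  .check(any(target0 > 0 & ref0 > 0),
         "no overlap between target 0h support and reference 0h support")
  if (any(ref0 == 0 & target0 > 0)) {
    ref0 <- ref0 + pseudo
    ref48 <- ref48 + pseudo
  }
  f <- (ref48 / sum(ref48)) / (ref0 / sum(ref0))
  f[!is.finite(f)] <- 0
  f <- .movingAverage(f, smoothBw)
  pred <- (target0 / sum(target0)) * f
  .check(sum(pred) > 0, "prediction degenerated to zero")
  pred / sum(pred)
}

#' Correlate damage with mutation rate across motifs
#'
#' For each stack, computes `x = log2(mean TFBS fraction / mean flank
#' fraction)` of the mutation profile and `y` likewise for the chosen
#' CPD track (a per-offset count vector per motif, e.g. observed 0h or
#' predicted 48h), and returns the Pearson correlation over motifs.
#' Motifs with zero flank signal in either profile are excluded with a
#' warning.
#'
#' @param stacks list of [WindowStack]s with mutations tracks.
#' @param cpdProfiles named list (per motif) of per-offset CPD vectors.
#' @param config an [analysisConfig()].
#' @return `list(r, n, data)` where `data` has one row per motif used.
#' @export
correlateDamageMutation <- function(stacks, cpdProfiles,
                                    config = analysisConfig()) {
  tfbsIdx <- regionIndices(config, "tfbs")
  flankIdx <- regionIndices(config, "flank")
  rows <- lapply(stacks, function(st) {
    mut <- stackProfile(st, "mutations")
    cpd <- cpdProfiles[[st@motifId]]
    if (is.null(cpd)) return(NULL)
    mf <- mean(mut[flankIdx]); cf <- mean(cpd[flankIdx])
    if (mf == 0 || cf == 0) {
      warning(sprintf("motif %s excluded: zero flank signal", st@motifId))
      return(NULL)
    }
    data.frame(motif_id = st@motifId,
               x = log2(mean(mut[tfbsIdx]) / mf),
               y = log2(mean(cpd[tfbsIdx]) / cf))
  })
  data <- do.call(rbind, rows)
  .check(!is.null(data) && nrow(data) >= 3L,
         "need at least 3 motifs with usable signal")
  list(r = stats::cor(data$x, data$y), n = nrow(data), data = data)
}
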