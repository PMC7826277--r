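# Conserved dipyrimidine selection, tetranucleotide-matched flank
# sampling and the within-motif repair comparison.

# Independent enumeration of the consensus dipyrimidines in motif
# coordinates: pairs read on the motif strand and its complement.
consensusDipyrs <- function(consensus = DEFAULT_CONSENSUS) {
  b <- strsplit(consensus, "")[[1]]
  out <- list()
  for (i in seq_len(length(b) - 1)) {
    o <- i - 11L                       # offset of the 5'-most base
    pair <- paste0(b[i], b[i + 1])
    if (grepl("^[CT][CT]$", pair))
      out[[length(out) + 1L]] <- data.frame(offset = o, strand = "+",
                                            type = pair)
    if (grepl("^[AG][AG]$", pair)) {
      comp <- chartr("AG", "TC", pair)
      rc <- paste0(substr(comp, 2, 2), substr(comp, 1, 1))
      out[[length(out) + 1L]] <- data.frame(offset = o, strand = "-",
                                            type = rc)
    }
  }
  do.call(rbind, out)
}

test_that("consensus-only stacks report exactly the consensus dipyrimidines", {
  stk <- smallStack()
  sites <- conservedDipyrimidines(stk)
  expect_true(all(sites$conservation == 1))
  truth <- consensusDipyrs()
  expect_equal(sites[order(sites$offset, sites$strand),
                     c("offset", "strand", "type")],
               truth[order(truth$offset, truth$strand), ],
               ignore_attr = TRUE)
})

test_that("conservation threshold requires one specific type at 50%", {
  # windows carry TT (49%) or TC (51%) at the same motif offsets
  cfg <- analysisConfig()
  w <- 2L * cfg$halfWidth + 1L + 4L
  # alternating A/C background carries no dipyrimidine on either strand;
  # offsets -1,0 sit at string positions 1002..1003 (margin 2)
  mkSeq <- function(mid) {
    chars <- rep(c("A", "C"), length.out = w)
    # phase shift after the pair keeps purines and pyrimidines alternating
    chars[1004:w] <- rep(c("A", "C"), length.out = w - 1003L)
    chars[1002:1003] <- strsplit(mid, "")[[1]]
    paste(chars, collapse = "")
  }
  seqTT <- mkSeq("TT"); seqTC <- mkSeq("TC")
  stk <- syntheticStack(100L)
  stk@seqs <- Biostrings::DNAStringSet(c(rep(seqTT, 49), rep(seqTC, 51)))
  sites <- conservedDipyrimidines(stk, minConservation = 0.5)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$type, "TC")
  expect_equal(sites$conservation, 0.51)
  none <- conservedDipyrimidines(stk, minConservation = 0.52)
  expect_equal(nrow(none), 0L)
})

test_that("percent over expected follows its definition", {
  expect_equal(percentOverExpected(15, 10), 50)
  expect_equal(percentOverExpected(10, 10), 0)
  expect_equal(percentOverExpected(0, 4), -100)
  expect_true(is.na(percentOverExpected(3, 0)))
})

test_that("matched sampling is exact under uniform flank tracks", {
  stk <- smallStack()
  n <- nSites(stk)
  # uniform mutation track: every offset of every window holds 1 event
  stk@tracks$mutations <- denseTrack(n, rep(1, 2001))
  one <- Matrix::Matrix(1, n, 2001, sparse = TRUE)
  stk@tracks$cpd_0h <- list(plus = one, minus = one)
  site <- conservedDipyrimidines(stk)
  site <- site[site$offset == -8 & site$strand == "+", ]
  drawn <- drawMatchedSamples(stk, site, nIter = 10L, seed = 5)
  expect_equal(drawn$nSkipped, 0L)
  # every draw lands on a flank pair worth exactly 2 mutation counts
  ev <- evaluateDraws(stk, drawn, "mutations")
  expect_equal(ev$expected, 2 * n)
  expect_equal(ev$perIter, rep(2 * n, 10L))
  # CPD tracks read the strand-specific pair anchor: worth exactly 1
  ev2 <- evaluateDraws(stk, drawn, "cpd_0h")
  expect_equal(ev2$expected, n)
  # observed counterpart sums both bases over carriers
  expect_equal(siteObserved(stk, site, "mutations"), 2 * n)
  expect_equal(siteObserved(stk, site, "cpd_0h"), n)
})

test_that("draws are reproducible per seed and stable across seeds", {
  stk <- smallStack()
  site <- conservedDipyrimidines(stk)
  site <- site[site$offset == -8 & site$strand == "+", ]
  d1 <- drawMatchedSamples(stk, site, nIter = 50L, seed = 5)
  d2 <- drawMatchedSamples(stk, site, nIter = 50L, seed = 5)
  expect_identical(d1$draws, d2$draws)
  e1 <- evaluateDraws(stk, d1, "cpd_0h")
  e3 <- evaluateDraws(stk, drawMatchedSamples(stk, site, nIter = 50L,
                                              seed = 31), "cpd_0h")
  sem <- stats::sd(e1$perIter) / sqrt(length(e1$perIter))
  expect_lt(abs(e1$expected - e3$expected), 6 * sem + 1e-9)
})

test_that("within-motif repair difference matches hand arithmetic", {
  stk <- smallStack()
  n <- nSites(stk)
  mask <- as.character(regionMask(analysisConfig()))
  motifCols <- which(mask == "motif")
  flankCols <- which(mask == "flank")
  # site loses 20% of normalised CPDs, flanks lose 60% -> +40 pp
  row0 <- rep(0, 2001); row0[motifCols] <- 5; row0[flankCols] <- 5
  row48 <- rep(0, 2001); row48[motifCols] <- 4; row48[flankCols] <- 2
  zero <- Matrix::Matrix(0, n, 2001, sparse = TRUE)
  stk@tracks$cpd_0h <- list(plus = denseTrack(n, row0), minus = denseTrack(n, row0))
  stk@tracks$cpd_48h <- list(plus = denseTrack(n, row48), minus = denseTrack(n, row48))
  site <- conservedDipyrimidines(stk)
  site <- site[site$offset == -8 & site$strand == "+", ]
  drawn <- drawMatchedSamples(stk, site, nIter = 5L, seed = 2)
  res <- withinMotifRepair(stk, site, genomeTotals = c(1, 1), drawn)
  expect_equal(res$site_percent_change, -20)
  expect_equal(res$flank_percent_change, -60)
  expect_equal(res$pp_diff, 40)

  # identical decay at site and flanks -> 0 pp
  stk@tracks$cpd_48h <- list(plus = denseTrack(n, row0 * 0.5),
                             minus = denseTrack(n, row0 * 0.5))
  res0 <- withinMotifRepair(stk, site, genomeTotals = c(1, 1), drawn)
  expect_equal(res0$pp_diff, 0)
})

test_that("the full summary covers sites, tracks and seeds", {
  stk <- smallStack()
  st <- smallStudy()
  gt <- list(cpd_0h = sum(S4Vectors::mcols(st$maps[["0h"]])$count),
             cpd_48h = sum(S4Vectors::mcols(st$maps[["48h"]])$count))
  wm <- withinMotifSummary(stk, tracks = c("mutations", "cpd_0h"),
                           nIter = 20L, seed = 3, genomeTotals = gt)
  expect_true(all(wm$conservation >= 0.5))
  expect_setequal(unique(wm$track), c("mutations", "cpd_0h"))
  # the planted 2x spike at (-8, +) stands out on the CPD track
  spike <- wm[wm$offset == -8 & wm$strand == "+" & wm$track == "cpd_0h", ]
  expect_gt(spike$percent_over_expected, 50)
  expect_lt(spike$p_value, 0.05)
  # repair differences hover around the planted contrast
  expect_true(all(is.finite(wm$repair_pp_diff)))
  # identical call reproduces identical numbers
  wm2 <- withinMotifSummary(stk, tracks = c("mutations", "cpd_0h"),
                            nIter = 20L, seed = 3, genomeTotals = gt)
  expect_identical(wm, wm2)
})
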