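# Window geometry, strand-aware event mapping, motif filters and window
# normalisation.

test_that("region mask partitions the window with the published widths", {
  cfg <- analysisConfig()
  mask <- regionMask(cfg)
  off <- stackOffsets(syntheticStack(1L))
  expect_length(mask, 2001L)
  expect_equal(sum(mask == "motif"), 21L)
  expect_equal(sum(mask == "tfbs"), 101L - 21L)
  expect_length(regionIndices(cfg, "tfbs"), 101L)        # contains motif
  expect_equal(sum(mask == "dhs_flank"), 400L)
  expect_equal(sum(mask == "flank"), 1500L)
  expect_equal(as.character(mask[off == 0]), "motif")
  expect_equal(as.character(mask[off %in% c(-250, 51)]),
               c("dhs_flank", "dhs_flank"))
  expect_equal(as.character(mask[off %in% c(-251, 251)]),
               c("flank", "flank"))
  expect_error(analysisConfig(flankWidth = 700), "inconsistent")
})

test_that("window extraction bounds-checks and flags orientation", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 2500)))  # 10 kb
  mkSites <- function(centers, strand = "+") {
    gr <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(centers - 10, width = 21),
                                 strand = strand)
    S4Vectors::mcols(gr)$center <- centers
    S4Vectors::mcols(gr)$active <- TRUE
    gr
  }
  st <- buildWindowStack(mkSites(5000), g, motifId = "m")
  expect_equal(nSites(st), 1L)
  expect_equal(GenomicRanges::start(st@windows), 4000L)
  expect_equal(GenomicRanges::end(st@windows), 6000L)

  st2 <- buildWindowStack(mkSites(c(500, 5000)), g, motifId = "m")
  expect_equal(nSites(st2), 1L)          # near-edge window discarded
  expect_equal(st2@nDiscarded, 1L)

  st3 <- buildWindowStack(mkSites(5000, "-"), g, motifId = "m")
  expect_equal(S4Vectors::mcols(st3@windows)$siteStrand, "-")
  # oriented sequence is the reverse complement of the plus window
  expect_equal(as.character(st3@seqs[[1]]),
               as.character(Biostrings::reverseComplement(st@seqs[[1]])))
})

test_that("point events map to strand-aware offsets (involution)", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 2500)))
  mkSites <- function(strand) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4990, width = 21),
                                 strand = strand)
    S4Vectors::mcols(gr)$center <- 5000L
    S4Vectors::mcols(gr)$active <- TRUE
    gr
  }
  ev <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(5000, 5007), width = 1))
  S4Vectors::mcols(ev)$sample <- c("s", "s")
  plus <- mapEvents(buildWindowStack(mkSites("+"), g, motifId = "m"), ev)
  minus <- mapEvents(buildWindowStack(mkSites("-"), g, motifId = "m"), ev)
  off <- stackOffsets(plus)
  expect_equal(which(stackProfile(plus, "mutations") > 0),
               which(off %in% c(0, 7)))
  expect_equal(which(stackProfile(minus, "mutations") > 0),
               which(off %in% c(0, -7)))
  # inverting orientation twice restores the profile exactly
  expect_equal(rev(stackProfile(minus, "mutations")),
               stackProfile(plus, "mutations"))
})

test_that("CPD records keep strand and pair anchoring under orientation", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 2500)))
  mkStack <- function(strand) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4990, width = 21),
                                 strand = strand)
    S4Vectors::mcols(gr)$center <- 5000L
    S4Vectors::mcols(gr)$active <- TRUE
    buildWindowStack(gr, g, motifId = "m")
  }
  cp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5006, width = 1),
                               strand = "+")
  S4Vectors::mcols(cp)$count <- 4
  S4Vectors::mcols(cp)$timepoint <- "0h"
  plus <- mapEvents(mkStack("+"), cp)
  minus <- mapEvents(mkStack("-"), cp)
  off <- stackOffsets(plus)
  # plus window: pair occupies offsets (6,7) on the + strand
  expect_equal(which(as.matrix(plus@tracks$cpd_0h$plus[1, , drop = FALSE])
                     > 0), which(off == 6))
  expect_equal(sum(plus@tracks$cpd_0h$minus), 0)
  # minus window: same dimer maps to pair start -7 on the - strand
  expect_equal(which(as.matrix(minus@tracks$cpd_0h$minus[1, , drop = FALSE])
                     > 0), which(off == -7))
  expect_equal(sum(minus@tracks$cpd_0h$plus), 0)
  expect_equal(sum(stackProfile(plus, "cpd_0h")), 4)
})

test_that("motif filters apply the site-count and median thresholds", {
  cfg <- analysisConfig()
  mk <- function(n, colCounts) {
    st <- syntheticStack(n)
    # all counts in the first window: exact integer column sums
    st@tracks$mutations <- Matrix::sparseMatrix(
      i = rep(1L, sum(colCounts > 0)), j = which(colCounts > 0),
      x = colCounts[colCounts > 0], dims = c(n, 2001L))
    st
  }
  # 4999 sites, plenty of mutations -> excluded for site count
  s1 <- mk(4999L, rep(5000, 2001))
  # 5000 sites, median exactly 2 -> retained
  s2 <- mk(5000L, rep(2, 2001))
  # 6000 sites, 1001 offsets at 1 mutation, 1000 at 5 -> median 1, excluded
  s3 <- mk(6000L, c(rep(1, 1001), rep(5, 1000)))
  s3@motifId <- "FIX3"
  res <- filterMotifs(list(s1, s2, s3), cfg)
  expect_equal(res$report$kept, c(FALSE, TRUE, FALSE))
  expect_equal(res$report$reason, c("site count", "", "median mutations"))
  expect_equal(res$report$median_mutations[3], 1)
  expect_length(res$kept, 1L)
})

test_that("window normalisation yields fractions summing to one", {
  expect_equal(normalizeWindowTrack(rep(3, 2001)), rep(1 / 2001, 2001))
  delta <- c(rep(0, 1000), 7, rep(0, 1000))
  expect_equal(normalizeWindowTrack(delta)[1001], 1)
  x <- runif(2001)
  expect_equal(sum(normalizeWindowTrack(x)), 1, tolerance = 1e-12)
  expect_error(normalizeWindowTrack(rep(0, 2001), "cpd"), "zero total")
})

test_that("stacked event totals are conserved", {
  stk <- smallStack()
  st <- smallStudy()
  # every 0h record falling fully inside some window is counted there
  prof <- stackProfile(stk, "cpd_0h")
  cp <- st$maps[["0h"]]
  hw <- 1000L
  centers <- S4Vectors::mcols(stk@windows)$center
  inWin <- IRanges::overlapsAny(
    GenomicRanges::resize(cp, 2L, fix = "start", ignore.strand = TRUE),
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(centers - hw, centers + hw)),
    type = "within", ignore.strand = TRUE)
  expect_equal(sum(prof), sum(S4Vectors::mcols(cp)$count[inWin]))
})
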