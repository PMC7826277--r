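# The synthetic study generator: determinism, planted-truth structure,
# and recovery of the planted parameters by the analysis stages.

test_that("genome generation respects composition and seed", {
  g <- simulateGenome(1e5, gc = 0.5, seed = 4)
  f <- Biostrings::alphabetFrequency(g[[1]])[c("C", "G")]
  expect_lt(abs(sum(f) / 1e5 - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_identical(as.character(simulateGenome(5000, seed = 8)[[1]]),
                   as.character(simulateGenome(5000, seed = 8)[[1]]))
  at <- simulateGenome(2000, gc = 0, seed = 1)
  expect_equal(sum(Biostrings::alphabetFrequency(at[[1]])[c("C", "G")]), 0)
})

test_that("implanted sites are recovered by scan + DHS classification", {
  g <- simulateGenome(200000L, seed = 14)
  imp <- implantSites(g, nActive = 60L, nInactive = 20L, spacing = 2100L,
                      seed = 15)
  pwm <- buildPWM(syntheticMotif(), background = genomeBackground(imp$genome))
  hits <- scanMotif(imp$genome, imp$peaks, pwm, 0.85)
  expect_equal(sort(S4Vectors::mcols(hits)$center),
               sort(S4Vectors::mcols(imp$sites)$center))
  hits <- classifyActivity(hits, list(imp$dhs1, imp$dhs2))
  truthActive <- sort(S4Vectors::mcols(imp$sites)$center[
    S4Vectors::mcols(imp$sites)$active])
  expect_equal(sort(S4Vectors::mcols(hits)$center[
    S4Vectors::mcols(hits)$active]), truthActive)
  # spacing >= window length keeps windows disjoint
  centers <- sort(S4Vectors::mcols(imp$sites)$center)
  expect_true(all(diff(centers) >= 2001L))
  expect_error(implantSites(simulateGenome(5000, seed = 1), nActive = 10),
               "longer genome")
})

test_that("CPD maps place counts only at genomic dipyrimidines", {
  st <- smallStudy()
  inv <- dipyrimidineInventory(st$genome)
  key <- paste(inv$pos, inv$strand)
  for (tp in names(st$maps)) {
    m <- st$maps[[tp]]
    expect_true(all(paste(GenomicRanges::start(m),
                          as.character(GenomicRanges::strand(m))) %in% key))
    expect_true(all(S4Vectors::mcols(m)$count > 0))
  }
})

test_that("uniform survival yields a null repair profile", {
  g <- simulateGenome(150000L, seed = 31)
  imp <- implantSites(g, nActive = 60L, nInactive = 0L, seed = 32)
  cpd <- simulateCpdMaps(imp$genome, imp$sites, depthPerWindow = 5000,
                         survival = c(motif = 1, tfbs = 1, dhs_flank = 1,
                                      flank = 1),
                         spike = NULL, timepoints = c("0h", "48h"),
                         seed = 33)
  stk <- buildWindowStack(imp$sites, imp$genome)
  stk <- mapEvents(stk, cpd$maps[["0h"]], "cpd_0h")
  stk <- mapEvents(stk, cpd$maps[["48h"]], "cpd_48h")
  p0 <- stackProfile(stk, "cpd_0h"); p48 <- stackProfile(stk, "cpd_48h")
  rp <- relativeRepairProfile(p0, p48)
  expect_equal(sum(rp$repair), 0, tolerance = 1e-12)
  phat <- (p0 + p48) / (sum(p0) + sum(p48))
  se <- sqrt(phat * (1 - phat)) * sqrt(1 / sum(p0) + 1 / sum(p48))
  expect_true(all(abs(rp$repair) < 4 * se + 1e-12))
})

test_that("no planted damage multiplier means no damage-vs-naked signal", {
  g <- simulateGenome(150000L, seed = 41)
  imp <- implantSites(g, nActive = 60L, nInactive = 0L, seed = 42)
  cpd <- simulateCpdMaps(imp$genome, imp$sites, depthPerWindow = 5000,
                         spike = NULL, damageMotif = 1,
                         timepoints = c("naked", "0h"), seed = 43)
  stk <- buildWindowStack(imp$sites, imp$genome)
  stk <- mapEvents(stk, cpd$maps[["0h"]], "cpd_0h")
  stk <- mapEvents(stk, cpd$maps[["naked"]], "cpd_naked")
  s <- damageVsNakedSummary(stackProfile(stk, "cpd_0h"),
                            stackProfile(stk, "cpd_naked"))
  expect_true(all(abs(s$log2_ratio) < 0.15))
})

test_that("cohort generator honours the C>T fraction and scales linearly", {
  st <- smallStudy()
  res <- filterCohort(st$mutations)
  expect_true(all(res$report$kept))
  expect_true(all(abs(res$report$fraction - 0.9) < 0.05))

  low <- simulateMutationCohort(st$genome, st$intensities, nSamples = 4L,
                                mutsPerSample = 400L, ctFraction = 0.5,
                                seed = 3)
  resLow <- filterCohort(low)
  expect_false(any(resLow$report$kept))

  # doubling the per-sample count doubles totals exactly
  a <- simulateMutationCohort(st$genome, st$intensities, nSamples = 3L,
                              mutsPerSample = 200L, seed = 5)
  b <- simulateMutationCohort(st$genome, st$intensities, nSamples = 3L,
                              mutsPerSample = 400L, seed = 5)
  expect_equal(length(b), 2L * length(a))
})

test_that("mutations concentrate where damage survives repair", {
  st <- smallStudy()
  # per-dipyrimidine mutation weight follows the surviving intensity:
  # compare mutation counts at high- vs low-survival regions
  coh <- filterCohort(st$mutations)$muts
  stk <- smallStack()
  prof <- stackProfile(stk, "mutations")
  cfg <- analysisConfig()
  motifRate <- mean(prof[regionIndices(cfg, "motif")])
  flankRate <- mean(prof[regionIndices(cfg, "flank")])
  # motif survival 0.8 vs flank 0.4 (plus the damage spike) -> enrichment
  expect_gt(motifRate / flankRate, 1.3)
})

test_that("every generator output is reproducible from the seed", {
  a <- simulateStudy(seed = 77, nActive = 40L, nInactive = 10L,
                     depthPerWindow = 500, backgroundWeight = 2,
                     nSamples = 3L, mutsPerSample = 100L)
  b <- simulateStudy(seed = 77, nActive = 40L, nInactive = 10L,
                     depthPerWindow = 500, backgroundWeight = 2,
                     nSamples = 3L, mutsPerSample = 100L)
  expect_identical(as.character(a$genome[[1]]), as.character(b$genome[[1]]))
  expect_identical(S4Vectors::mcols(a$sites)$center,
                   S4Vectors::mcols(b$sites)$center)
  for (tp in names(a$maps)) {
    expect_identical(GenomicRanges::start(a$maps[[tp]]),
                     GenomicRanges::start(b$maps[[tp]]))
    expect_identical(S4Vectors::mcols(a$maps[[tp]])$count,
                     S4Vectors::mcols(b$maps[[tp]])$count)
  }
  expect_identical(GenomicRanges::start(a$mutations),
                   GenomicRanges::start(b$mutations))
})

test_that("panel truth drives the expected correlation structure", {
  p <- simulatePanel(nMotifs = 10L, sitesPerMotif = 100L,
                     depthPerWindow = 1500, mutsPerSample = 1500L,
                     nSamples = 10L, seed = 63)
  expect_equal(nrow(p$truth), 10L)
  cc <- panelCorrelationContrast(p)
  expect_gt(cc$r48, cc$r0)
  expect_gt(cc$r48, 0.6)
})
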