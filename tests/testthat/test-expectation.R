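# Cohort filtering, the k-mer substitution model and the analytic
# expected-mutation profile.

mkMuts <- function(sample, chrom, pos, ref, alt) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  S4Vectors::mcols(gr)$sample <- sample
  S4Vectors::mcols(gr)$ref <- ref
  S4Vectors::mcols(gr)$alt <- alt
  gr
}

test_that("cohort filter applies the 70% C>T threshold per sample", {
  n1 <- 100
  mu <- mkMuts(rep(c("a", "b"), each = n1), "chr1",
               c(seq_len(n1), seq_len(n1) + 200),
               c(rep("C", 70), rep("A", 30), rep("C", 69), rep("A", 31)),
               c(rep("T", 70), rep("G", 30), rep("T", 69), rep("G", 31)))
  res <- filterCohort(mu)
  expect_equal(res$report$kept, c(TRUE, FALSE))
  expect_equal(res$report$fraction, c(0.70, 0.69))
  expect_length(res$muts, 70L)          # only sample a's C>T records
  expect_true(all(S4Vectors::mcols(res$muts)$sample == "a"))

  # G>A counts as C>T on the opposite strand and is retained
  mu2 <- mkMuts(rep("c", 10), "chr1", 1:10,
                c(rep("G", 8), "A", "T"), c(rep("A", 8), "C", "G"))
  res2 <- filterCohort(mu2)
  expect_true(res2$report$kept)
  expect_length(res2$muts, 8L)
})

test_that("trinucleotide model matches hand enumeration", {
  g <- Biostrings::DNAStringSet(c(chr1 = "TCGTCGTCG"))
  # mutations at two of the three TCG centers (1-based positions 2, 5)
  mu <- mkMuts(c("s", "s"), "chr1", c(2, 5), c("C", "C"), c("T", "T"))
  m <- fitSubstitutionModel(mu, g, 3)
  expect_equal(unname(m@genomeCounts["TCG"]), 3)
  expect_equal(unname(m@prob["TCG"]), 2 / 3)
  # exact rational identity prob * genome_count = mutation_count
  expect_equal(m@prob * m@genomeCounts, m@mutationCounts)
  # no mutations -> all-zero model
  m0 <- fitSubstitutionModel(mu[0], g, 3)
  expect_true(all(m0@prob == 0))
})

test_that("model is invariant under reverse complementing the data", {
  st <- smallStudy()
  coh <- filterCohort(st$mutations)$muts
  m1 <- fitSubstitutionModel(coh, st$genome, 3)
  # reverse-complement genome and mirror the mutations
  len <- Biostrings::width(st$genome)[1]
  rcg <- Biostrings::DNAStringSet(stats::setNames(as.character(
    Biostrings::reverseComplement(st$genome[[1]])), "chr1"))
  flip <- c(A = "T", C = "G", G = "C", T = "A")
  rcmu <- mkMuts(S4Vectors::mcols(coh)$sample, "chr1",
                 len - GenomicRanges::start(coh) + 1L,
                 unname(flip[S4Vectors::mcols(coh)$ref]),
                 unname(flip[S4Vectors::mcols(coh)$alt]))
  m2 <- fitSubstitutionModel(rcmu, rcg, 3)
  expect_equal(m1@prob, m2@prob)
  expect_equal(m1@genomeCounts, m2@genomeCounts)
})

test_that("uniform mutations over C sites give flat C-centered rates", {
  g <- simulateGenome(200000L, gc = 0.5, seed = 7)
  chars <- strsplit(as.character(g[[1]]), "")[[1]]
  # all genomic cytosines: plus-strand C sites plus minus-strand ones (G)
  cg <- which(chars %in% c("C", "G"))
  cg <- cg[cg > 2 & cg < length(chars) - 1]
  set.seed(11)
  pick <- sample(cg, 1e5, replace = TRUE)
  ref <- chars[pick]
  mu <- mkMuts(rep("s", length(pick)), "chr1", pick,
               ref, ifelse(ref == "C", "T", "A"))
  m <- fitSubstitutionModel(mu, g, 3)
  cpos <- cg
  cKmers <- names(m@prob)[substr(names(m@prob), 2, 2) == "C"]
  p <- m@prob[cKmers]
  # binomial sampling error around the common rate
  rate <- 1e5 / length(cpos)
  se <- sqrt(rate / m@genomeCounts[cKmers])
  expect_true(all(abs(p - rate) < 4 * se))
  # T-centered k-mers are untouched
  expect_true(all(m@prob[substr(names(m@prob), 2, 2) == "T"] == 0))
})

test_that("expected profile is exact in the uniform-context case", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("T", 12000)))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5990, width = 21),
                               strand = "+")
  S4Vectors::mcols(gr)$center <- 6000L
  S4Vectors::mcols(gr)$active <- TRUE
  stk <- buildWindowStack(gr, g, motifId = "m")
  ev <- mkMuts(rep("s", 4), "chr1", c(5100, 6000, 6500, 6900),
               rep("T", 4), rep("C", 4))
  stk <- mapEvents(stk, ev)
  m <- fitSubstitutionModel(ev, g, 3)     # only TTT, constant rate
  stk <- expectedProfile(stk, m)
  expect_equal(expectedMutations(stk), rep(4 / 2001, 2001))
})

test_that("expectation conserves each window's observed total", {
  stk <- smallStack()
  st <- smallStudy()
  model <- fitSubstitutionModel(filterCohort(st$mutations)$muts,
                                st$genome, 3)
  stk <- expectedProfile(stk, model)
  expect_equal(sum(expectedMutations(stk)),
               sum(stackProfile(stk, "mutations")), tolerance = 1e-9)
  # per-window: single-window stacks conserve exactly
  for (i in c(1L, 5L, 17L)) {
    sub <- st$sites[S4Vectors::mcols(st$sites)$active][i]
    s1 <- buildWindowStack(sub, st$genome, motifId = "w")
    s1 <- mapEvents(s1, filterCohort(st$mutations)$muts)
    s1 <- expectedProfile(s1, model)
    expect_equal(sum(expectedMutations(s1)),
                 sum(stackProfile(s1, "mutations")), tolerance = 1e-9)
  }
})

test_that("pentanucleotide mode fits and redistributes consistently", {
  st <- smallStudy()
  coh <- filterCohort(st$mutations)$muts
  m5 <- fitSubstitutionModel(coh, st$genome, 5)
  expect_equal(m5@k, 5L)
  expect_equal(sum(m5@mutationCounts), length(coh))
  stk <- expectedProfile(smallStack(), m5)
  expect_equal(sum(expectedMutations(stk)),
               sum(stackProfile(stk, "mutations")), tolerance = 1e-9)
})

test_that("inactive-site background scales shape onto the active total", {
  st <- smallStudy()
  cfg <- analysisConfig()
  coh <- filterCohort(st$mutations)$muts
  act <- smallStack()
  inact <- buildWindowStack(
    st$sites[!S4Vectors::mcols(st$sites)$active], st$genome, cfg,
    motifId = "SYN1", activeOnly = FALSE)
  inact <- mapEvents(inact, coh)
  bg <- inactiveBackgroundProfile(act, inact)
  expect_equal(sum(bg), sum(stackProfile(act, "mutations")))
  prof <- stackProfile(inact, "mutations")
  i <- which(prof > 0)[1:2]
  expect_equal(bg[i[1]] / bg[i[2]], prof[i[1]] / prof[i[2]])
  # identical stacks give expected == observed
  self <- inactiveBackgroundProfile(act, act)
  expect_equal(self, stackProfile(act, "mutations"))
})
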