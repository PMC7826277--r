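# Shared fixtures, built in code and memoised for the session.

.fixtureEnv <- new.env(parent = emptyenv())

# Small complete synthetic study (120 active / 30 inactive sites).
smallStudy <- function() {
  if (is.null(.fixtureEnv$study))
    .fixtureEnv$study <- simulateStudy(
      seed = 42, nActive = 120L, nInactive = 30L, depthPerWindow = 2000,
      backgroundWeight = 5, nSamples = 8L, mutsPerSample = 400L)
  .fixtureEnv$study
}

# Stack over the small study's active sites with all tracks mapped.
smallStack <- function() {
  if (is.null(.fixtureEnv$stack)) {
    st <- smallStudy()
    cfg <- analysisConfig()
    stk <- buildWindowStack(st$sites, st$genome, cfg)
    coh <- filterCohort(st$mutations)
    stk <- mapEvents(stk, coh$muts, "mutations")
    for (tp in names(st$maps))
      stk <- mapEvents(stk, st$maps[[tp]], paste0("cpd_", tp))
    .fixtureEnv$stack <- stk
  }
  .fixtureEnv$stack
}

# A WindowStack built directly (no genome walk): n identical windows of
# the given sequence (width 2005), with empty tracks. For filter and
# geometry fixtures.
syntheticStack <- function(n, seqChar = NULL, config = analysisConfig()) {
  w <- 2L * config$halfWidth + 1L + 4L
  if (is.null(seqChar))
    seqChar <- paste(rep("A", w), collapse = "")
  stopifnot(nchar(seqChar) == w)
  windows <- GenomicRanges::GRanges("chrX",
    IRanges::IRanges(seq_len(n) * 10000L, width = 2L * config$halfWidth + 1L))
  S4Vectors::mcols(windows)$center <-
    GenomicRanges::start(windows) + config$halfWidth
  S4Vectors::mcols(windows)$siteStrand <- rep("+", n)
  methods::new("WindowStack", motifId = "FIX", config = unclass(config),
               windows = windows,
               seqs = Biostrings::DNAStringSet(rep(seqChar, n)),
               tracks = list(), expected = numeric(0), nDiscarded = 0L,
               cache = new.env(parent = emptyenv()))
}

# Dense per-offset track -> sparse matrix with identical rows.
denseTrack <- function(n, rowValues) {
  Matrix::Matrix(matrix(rowValues, nrow = n, ncol = length(rowValues),
                        byrow = TRUE), sparse = TRUE)
}

tmpFile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
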