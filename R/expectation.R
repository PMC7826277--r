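# Background mutation model: UV-cohort filtering, the pyrimidine-centered
# k-mer substitution model, and per-offset expected mutation counts.

# TRUE where a record is a C>T substitution on either strand.
.isCT <- function(ref, alt) (ref == "C" & alt == "T") | (ref == "G" & alt == "A")

#' Filter a cohort to UV-dominated samples
#'
#' Keeps samples whose C>T fraction (counting G>A as C>T on the opposite
#' strand) is at least `minFraction`, and within kept samples keeps only
#' the C>T / G>A records. Samples with zero mutations are excluded with
#' reason `"empty"`.
#'
#' @param muts mutations `GRanges` from [readMutations()].
#' @param minFraction per-sample C>T fraction threshold (default 0.70).
#' @return `list(muts = <filtered GRanges>, report = <data.frame>)`; the
#'   report has one row per sample with total, C>T count, fraction and
#'   the kept flag.
#' @export
filterCohort <- function(muts, minFraction = 0.70) {
  mc <- S4Vectors::mcols(muts)
  ct <- .isCT(mc$ref, mc$alt)
  samples <- unique(mc$sample)
  tot <- table(factor(mc$sample, levels = samples))
  ctn <- table(factor(mc$sample[ct], levels = samples))
  frac <- as.numeric(ctn) / pmax(as.numeric(tot), 1L)
  kept <- as.numeric(tot) > 0L & frac >= minFraction
  report <- data.frame(sample = samples, total = as.numeric(tot),
                       c_to_t = as.numeric(ctn), fraction = frac,
                       kept = kept,
                       reason = ifelse(as.numeric(tot) == 0L, "empty",
                                       ifelse(kept, "", "C>T fraction")),
                       stringsAsFactors = FALSE)
  keepRec <- mc$sample %in% samples[kept] & ct
  list(muts = muts[keepRec], report = report)
}

#' Fit the k-mer substitution background model
#'
#' Every mutation contributes to the pyrimidine-centered k-mer of its
#' mutated base (G>A records are counted through the reverse
#' complement). Genome occurrences are counted once per genomic
#' position, on the pyrimidine-bearing strand; contexts containing N are
#' excluded. The mutability of a k-mer is its mutation count divided by
#' its occurrence count.
#'
#' @param muts a C>T-only cohort (e.g. `filterCohort(...)$muts`).
#' @param genome `DNAStringSet`.
#' @param k context size, 3 or 5.
#' @return A [SubstitutionModel].
#' @export
fitSubstitutionModel <- function(muts, genome, k = 3L) {
  k <- as.integer(k)
  .check(k %in% c(3L, 5L), "k must be 3 or 5")
  flank <- (k - 1L) %/% 2L
  kmers <- .allKmers(k)
  rc <- .revcompKmers(kmers)
  center <- substr(kmers, flank + 1L, flank + 1L)
  isPyr <- center %in% c("C", "T")
  # genome occurrences, folded onto the pyrimidine-bearing strand
  fwd <- colSums(Biostrings::oligonucleotideFrequency(genome, width = k))
  gcount <- fwd[kmers] + fwd[rc]
  gcount <- stats::setNames(as.numeric(gcount), kmers)[isPyr]
  # mutation contexts
  mcount <- stats::setNames(numeric(sum(isPyr)), kmers[isPyr])
  if (length(muts)) {
    pos <- GenomicRanges::start(muts)
    chrom <- as.character(GenomicRanges::seqnames(muts))
    chrLen <- stats::setNames(Biostrings::width(genome), names(genome))
    inside <- pos - flank >= 1L & pos + flank <= chrLen[chrom]
    if (any(!inside))
      warning(sprintf("%d mutations too close to a chromosome end ignored",
                      sum(!inside)))
    ctxGr <- GenomicRanges::GRanges(chrom[inside],
                                    IRanges::IRanges(pos[inside] - flank,
                                                     pos[inside] + flank))
    ctx <- as.character(.getSeqs(genome, ctxGr))
    mid <- substr(ctx, flank + 1L, flank + 1L)
    pur <- mid %in% c("A", "G")
    ctx[pur] <- .revcompKmers(ctx[pur])
    ctx <- ctx[!grepl("N", ctx, fixed = TRUE)]
    tb <- table(ctx)
    mcount[names(tb)] <- as.numeric(tb)
  }
  zero <- gcount == 0 & mcount > 0
  .check(!any(zero),
         "k-mers with mutations but no genome occurrences: %s",
         paste(head(names(mcount)[zero], 5L), collapse = ","))
  prob <- ifelse(gcount > 0, mcount / gcount, 0)
  new("SubstitutionModel", k = k, prob = prob, genomeCounts = gcount,
      mutationCounts = mcount)
}

# Mutability lookup over all 4^k k-mer codes: purine-centered codes get
# the mutability of their reverse complement.
.probLookup <- function(model) {
  k <- model@k
  kmers <- .allKmers(k)
  lut <- stats::setNames(numeric(length(kmers)), kmers)
  lut[names(model@prob)] <- model@prob
  rcNames <- .revcompKmers(names(model@prob))
  lut[rcNames] <- model@prob
  unname(lut)
}

# Per-window per-offset mutability matrix (n x 2001); NA contexts -> 0.
.windowMutability <- function(stack, model) {
  hw <- stack@config$halfWidth
  margin <- 2L
  codes <- .stackCodes(stack)
  centerCols <- seq_len(2L * hw + 1L) + margin
  kc <- .kmerCodes(codes, centerCols, model@k)
  lut <- .probLookup(model)
  p <- matrix(0, nrow = nrow(kc), ncol = ncol(kc))
  ok <- !is.na(kc)
  p[ok] <- lut[kc[ok]]
  p
}

#' Per-offset expected mutation counts for a stack
#'
#' For each window with `m` observed mutations, the expected contribution
#' to offset `i` is `m * p_i / sum_j p_j`, where `p_j` is the model
#' mutability of the pyrimidine-centered k-mer at offset `j` of that
#' window (0 for N contexts). This is the analytic expectation of
#' redistributing each window's mutations by context, conditioned on the
#' per-window total: per window, the expected counts sum exactly to the
#' observed count.
#'
#' @param stack a [WindowStack] with a mutations track.
#' @param model a [SubstitutionModel].
#' @return The stack with the `expected` slot filled (length 2001).
#' @export
expectedProfile <- function(stack, model) {
  p <- .windowMutability(stack, model)
  m <- windowMutationCounts(stack)
  rs <- rowSums(p)
  .check(!any(m > 0 & rs == 0),
         "window with observed mutations but all-zero context mutability")
  scale <- ifelse(rs > 0, m / rs, 0)
  stack@expected <- colSums(p * scale)
  stack
}

#' @rdname expectedProfile
#' @export
expectedMutations <- function(stack) stack@expected

#' Monte-Carlo expected profile
#'
#' Seeded Monte-Carlo counterpart of [expectedProfile()]: each window's
#' observed mutations are redistributed `nIter` times over the offsets
#' according to the per-offset mutability, and the per-offset mean is
#' returned. Used to verify the analytic expectation.
#'
#' @param stack,model as in [expectedProfile()].
#' @param nIter randomisation count.
#' @param seed RNG seed.
#' @return Numeric per-offset mean counts (length 2001).
#' @export
mcExpectedProfile <- function(stack, model, nIter = 1000L, seed = 1L) {
  p <- .windowMutability(stack, model)
  m <- windowMutationCounts(stack)
  ncols <- ncol(p)
  set.seed(seed)
  acc <- numeric(ncols)
  for (w in which(m > 0)) {
    pw <- p[w, ]
    draws <- sample.int(ncols, size = m[w] * nIter, replace = TRUE,
                        prob = pw)
    acc <- acc + tabulate(draws, nbins = ncols)
  }
  acc / nIter
}

#' Inactive-site background profile
#'
#' Alternative expectation: the per-offset mutation counts observed at
#' the inactive (DHS-free) sites of the same motif, scaled so the total
#' matches the active stack's total mutations.
#'
#' @param activeStack,inactiveStack [WindowStack]s over the same motif
#'   with mutations tracks.
#' @return Numeric per-offset expected counts.
#' @export
inactiveBackgroundProfile <- function(activeStack, inactiveStack) {
  .check(nSites(inactiveStack) > 0L, "inactive stack is empty")
  inact <- stackProfile(inactiveStack, "mutations")
  tot <- sum(inact)
  .check(tot > 0, "inactive stack has no mutations")
  inact * sum(stackProfile(activeStack, "mutations")) / tot
}
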