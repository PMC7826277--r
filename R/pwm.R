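# Motif scanning: log-odds PWM construction, peak-restricted scanning on
# both strands, DHS-based activity classification, and the padded jaccard
# statistic between active site sets.

#' Build a log-odds PWM from a count matrix
#'
#' `logOdds[b, i] = log2(((counts[b, i] + pseudocount * background[b]) /
#' (colsum_i + pseudocount)) / background[b])`, the standard smoothed
#' log-odds construction used by MOODS-style scanners.
#'
#' @param motif a [MotifMatrix].
#' @param pseudocount positive smoothing constant (default 0.8, split
#'   across bases by the background).
#' @param background length-4 base composition (A,C,G,T), summing to 1;
#'   defaults to uniform. Use [genomeBackground()] to take the genome
#'   composition.
#' @return A [MotifPWM].
#' @export
buildPWM <- function(motif, pseudocount = 0.8, background = rep(0.25, 4)) {
  stopifnot(is(motif, "MotifMatrix"))
  .check(pseudocount > 0, "pseudocount must be > 0")
  background <- background / sum(background)
  cnt <- motif@counts
  cs <- colSums(cnt)
  .check(all(cs > 0), "zero PFM column")
  freq <- sweep(cnt + pseudocount * background, 2L, cs + pseudocount, "/")
  lo <- log2(freq / background)
  dimnames(lo) <- dimnames(cnt)
  new("MotifPWM", motifId = motif@motifId, logOdds = lo,
      background = background, pseudocount = pseudocount)
}

#' @rdname buildPWM
#' @param genome a `DNAStringSet`.
#' @export
genomeBackground <- function(genome) {
  f <- colSums(Biostrings::alphabetFrequency(genome)[, BASES, drop = FALSE])
  f / sum(f)
}

#' @rdname buildPWM
#' @param pwm a [MotifPWM].
#' @export
pwmMaxScore <- function(pwm) sum(apply(pwm@logOdds, 2L, max))

#' @rdname buildPWM
#' @export
pwmMinScore <- function(pwm) sum(apply(pwm@logOdds, 2L, min))

#' @rdname buildPWM
#' @param seq character(1) sequence of the motif length.
#' @export
pwmScore <- function(pwm, seq) {
  code <- .codeChars(strsplit(toupper(seq), "")[[1]])
  .check(length(code) == ncol(pwm@logOdds), "sequence length != motif length")
  if (anyNA(code)) return(NA_real_)
  sum(pwm@logOdds[cbind(code, seq_along(code))])
}

# Score every offset of a coded sequence on one strand. Returns a numeric
# vector over start offsets (NA where the window contains N).
.scanCodes <- function(code, lo) {
  L <- ncol(lo)
  n <- length(code) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(L)) {
    cj <- code[j:(j + n - 1L)]
    ok <- ok & !is.na(cj)
    cj[is.na(cj)] <- 1L
    sc <- sc + lo[cbind(cj, rep(j, n))]
  }
  sc[!ok] <- NA_real_
  sc
}

#' Scan a motif over ChIP-seq peaks
#'
#' Scores every offset of every peak on both strands and reports sites
#' whose score reaches `thresholdFraction * pwmMaxScore(pwm)`. Within a
#' peak, overlapping hits are resolved by keeping the best-scoring hit
#' (ties: leftmost, then plus strand); non-overlapping hits are all
#' kept. Peaks shorter than the motif are skipped with a warning.
#'
#' @param genome `DNAStringSet`.
#' @param peaks `GRanges` of peak intervals.
#' @param pwm a [MotifPWM].
#' @param thresholdFraction scalar in (0, 1], default 0.85.
#' @return `GRanges` of binding sites (width = motif length) with
#'   metadata columns `motif_id`, `score`, `center` (genomic position of
#'   the central motif base, `start + floor(L/2)`), and `active` (NA
#'   until [classifyActivity()]).
#' @export
scanMotif <- function(genome, peaks, pwm, thresholdFraction = 0.85) {
  .check(thresholdFraction > 0 && thresholdFraction <= 1,
         "thresholdFraction must be in (0, 1]")
  L <- ncol(pwm@logOdds)
  thr <- thresholdFraction * pwmMaxScore(pwm)
  loF <- pwm@logOdds
  loR <- loF[4:1, L:1]                      # reverse-complement scan
  chroms <- unique(as.character(GenomicRanges::seqnames(peaks)))
  codeByChrom <- lapply(stats::setNames(chroms, chroms), function(ch)
    .codeChars(strsplit(as.character(genome[[ch]]), "")[[1]]))
  hits <- list()
  nShort <- 0L
  for (i in seq_along(peaks)) {
    ch <- as.character(GenomicRanges::seqnames(peaks))[i]
    s <- GenomicRanges::start(peaks)[i]; e <- GenomicRanges::end(peaks)[i]
    if (e - s + 1L < L) { nShort <- nShort + 1L; next }
    code <- codeByChrom[[ch]][s:e]
    scF <- .scanCodes(code, loF)
    scR <- .scanCodes(code, loR)
    offs <- which(!is.na(scF) & scF >= thr)
    offsR <- which(!is.na(scR) & scR >= thr)
    if (length(offs) + length(offsR) == 0L) next
    cand <- data.frame(
      start = s + c(offs, offsR) - 1L,
      score = c(scF[offs], scR[offsR]),
      strand = c(rep("+", length(offs)), rep("-", length(offsR))))
    # best-hit resolution among overlapping candidates
    ord <- order(-cand$score, cand$start, cand$strand)
    keep <- logical(nrow(cand))
    ends <- cand$start + L - 1L
    for (j in ord) {
      if (!any(keep & cand$start <= ends[j] & ends >= cand$start[j]))
        keep[j] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(cand$start, cand$strand), , drop = FALSE]
    hits[[length(hits) + 1L]] <- cbind(chrom = ch, cand)
  }
  if (nShort > 0L)
    warning(sprintf("skipped %d peaks shorter than the motif", nShort))
  if (length(hits) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    df <- do.call(rbind, hits)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, width = L),
                                 strand = df$strand)
    S4Vectors::mcols(gr)$score <- df$score
  }
  S4Vectors::mcols(gr)$motif_id <- rep(pwm@motifId, length(gr))
  S4Vectors::mcols(gr)$center <- GenomicRanges::start(gr) + L %/% 2L
  S4Vectors::mcols(gr)$active <- rep(NA, length(gr))
  gr
}

#' Classify binding sites as active or inactive by DHS overlap
#'
#' A site is active iff it overlaps (by >= 1 bp) at least one interval
#' in *every* supplied DHS set (e.g. one set per cell type); all other
#' sites are inactive.
#'
#' @param sites binding sites `GRanges` from [scanMotif()].
#' @param dhsSets list of one or more `GRanges` of DHS intervals.
#' @return `sites` with the `active` metadata column filled.
#' @export
classifyActivity <- function(sites, dhsSets) {
  if (inherits(dhsSets, "GRanges")) dhsSets <- list(dhsSets)
  .check(length(dhsSets) >= 1L, "at least one DHS set is required")
  active <- rep(TRUE, length(sites))
  for (dhs in dhsSets)
    active <- active & IRanges::overlapsAny(sites, dhs, ignore.strand = TRUE)
  S4Vectors::mcols(sites)$active <- active
  sites
}

#' Jaccard overlap between two padded site sets
#'
#' Each site is expanded to `center +/- pad`, the per-set intervals are
#' merged, and the ratio of total intersection to total union length is
#' returned (bedtools-jaccard semantics).
#'
#' @param sitesA,sitesB binding site `GRanges` (need a `center` column).
#' @param pad expansion in bases around the motif center (default 50).
#' @return Scalar in `[0, 1]`.
#' @export
jaccardOverlap <- function(sitesA, sitesB, pad = 50) {
  .check(pad >= 0, "pad must be >= 0")
  expand <- function(s) {
    c0 <- S4Vectors::mcols(s)$center
    GenomicRanges::reduce(GenomicRanges::GRanges(
      GenomicRanges::seqnames(s),
      IRanges::IRanges(pmax(c0 - pad, 1), c0 + pad)), ignore.strand = TRUE)
  }
  a <- expand(sitesA); b <- expand(sitesB)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(a, b,
                                                             ignore.strand = TRUE)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(a, b,
                                                       ignore.strand = TRUE)))
  if (uni == 0) return(0)
  inter / uni
}
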