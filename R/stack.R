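# Window stacking: the 2001-bp oriented windows around motif centers, the
# four-region geometry, per-offset event tracks, and the motif-level
# inclusion filters.

#' Analysis configuration
#'
#' Central numeric parameters of the analysis. The default geometry is a
#' 2001-bp window around each motif center split into four regions:
#' motif (21 bp), TFBS (101 bp containing the motif), DHS flanks (200 bp
#' per side) and flanks (750 bp per side); the widths must satisfy
#' `2 * halfWidth + 1 = tfbsWidth + 2 * dhsFlankWidth + 2 * flankWidth`.
#'
#' @param halfWidth window half width in nt (default 1000).
#' @param motifWidth central motif width (default 21).
#' @param tfbsWidth TFBS width, containing the motif (default 101).
#' @param dhsFlankWidth DHS flank width per side (default 200).
#' @param flankWidth outer flank width per side (default 750).
#' @param minSites minimum active sites per motif (default 5000).
#' @param minMedianMutations minimum median per-offset mutation count
#'   (default 2).
#' @param ctFractionMin minimum per-sample C>T fraction (default 0.70).
#' @param conservationMin dipyrimidine conservation threshold (default 0.5).
#' @param samplingIters tetranucleotide-matched sampling iterations
#'   (default 50).
#' @param jaccardPad padding around motif centers for the jaccard overlap
#'   (default 50).
#' @param thresholdFraction motif scan threshold as a fraction of the
#'   maximum PWM score (default 0.85).
#' @param pseudocount PWM pseudocount (default 0.8).
#' @param k substitution-model context size, 3 or 5 (default 3).
#' @return A validated named list of class `uvmotif_config`.
#' @export
analysisConfig <- function(halfWidth = 1000L, motifWidth = 21L,
                           tfbsWidth = 101L, dhsFlankWidth = 200L,
                           flankWidth = 750L, minSites = 5000L,
                           minMedianMutations = 2, ctFractionMin = 0.70,
                           conservationMin = 0.5, samplingIters = 50L,
                           jaccardPad = 50L, thresholdFraction = 0.85,
                           pseudocount = 0.8, k = 3L) {
  cfg <- list(halfWidth = as.integer(halfWidth),
              motifWidth = as.integer(motifWidth),
              tfbsWidth = as.integer(tfbsWidth),
              dhsFlankWidth = as.integer(dhsFlankWidth),
              flankWidth = as.integer(flankWidth),
              minSites = as.integer(minSites),
              minMedianMutations = minMedianMutations,
              ctFractionMin = ctFractionMin,
              conservationMin = conservationMin,
              samplingIters = as.integer(samplingIters),
              jaccardPad = as.integer(jaccardPad),
              thresholdFraction = thresholdFraction,
              pseudocount = pseudocount, k = as.integer(k))
  .check(cfg$motifWidth %% 2L == 1L && cfg$tfbsWidth %% 2L == 1L,
         "motifWidth and tfbsWidth must be odd")
  .check(2L * cfg$halfWidth + 1L ==
           cfg$tfbsWidth + 2L * cfg$dhsFlankWidth + 2L * cfg$flankWidth,
         "inconsistent region widths: window length != tfbs + dhs flanks + flanks")
  .check(cfg$k %in% c(3L, 5L), "k must be 3 or 5")
  class(cfg) <- "uvmotif_config"
  cfg
}

#' Region labels across the window
#'
#' Assigns every offset `-halfWidth .. +halfWidth` its finest region
#' label: `motif` for the central `motifWidth` offsets, `tfbs` for the
#' remaining TFBS offsets, then `dhs_flank` and `flank`. Region
#' summaries for "TFBS" include the motif offsets (the TFBS contains the
#' motif); use [regionIndices()] for that convention.
#'
#' @param config an [analysisConfig()].
#' @return Factor of length `2 * halfWidth + 1` with levels
#'   `motif`, `tfbs`, `dhs_flank`, `flank`.
#' @export
regionMask <- function(config) {
  off <- abs(seq.int(-config$halfWidth, config$halfWidth))
  mot <- config$motifWidth %/% 2L
  tfbs <- config$tfbsWidth %/% 2L
  dhs <- tfbs + config$dhsFlankWidth
  lab <- ifelse(off <= mot, "motif",
                ifelse(off <= tfbs, "tfbs",
                       ifelse(off <= dhs, "dhs_flank", "flank")))
  factor(lab, levels = c("motif", "tfbs", "dhs_flank", "flank"))
}

#' @rdname regionMask
#' @param region one of `"motif"`, `"tfbs"`, `"dhs_flank"`, `"flank"`.
#' @param includeMotifInTfbs logical; when TRUE (default) the `tfbs`
#'   region includes the motif offsets.
#' @return Integer positions (1-based columns into the window).
#' @export
regionIndices <- function(config, region, includeMotifInTfbs = TRUE) {
  mask <- regionMask(config)
  if (region == "tfbs" && includeMotifInTfbs)
    which(mask %in% c("motif", "tfbs"))
  else which(mask == region)
}

#' Build a window stack around binding sites
#'
#' Extracts the oriented `2 * halfWidth + 1` bp window around the center
#' of every (active) binding site of one motif and initialises an empty
#' event-track container. Minus-strand sites are reverse complemented so
#' the motif strand always reads left to right. Windows extending past a
#' chromosome end are discarded (keeping every column at equal depth);
#' the discard count is kept in the `nDiscarded` slot.
#'
#' @param sites binding sites `GRanges` from [scanMotif()] /
#'   [classifyActivity()] (needs `center`; `active` used when
#'   `activeOnly`).
#' @param genome `DNAStringSet`.
#' @param config an [analysisConfig()].
#' @param motifId stack label; defaults to the sites' `motif_id`.
#' @param activeOnly keep only sites flagged active (default TRUE).
#' @return A [WindowStack].
#' @export
buildWindowStack <- function(sites, genome, config = analysisConfig(),
                             motifId = NULL, activeOnly = TRUE) {
  mc <- S4Vectors::mcols(sites)
  if (is.null(motifId))
    motifId <- if (length(sites)) as.character(mc$motif_id[1]) else "motif"
  if (activeOnly && !is.null(mc$active) && !all(is.na(mc$active)))
    sites <- sites[which(mc$active)]
  hw <- config$halfWidth
  margin <- 2L
  center <- S4Vectors::mcols(sites)$center
  chrom <- as.character(GenomicRanges::seqnames(sites))
  chrLen <- stats::setNames(Biostrings::width(genome), names(genome))
  inside <- center - hw - margin >= 1L & center + hw + margin <= chrLen[chrom]
  nDiscarded <- sum(!inside)
  sites <- sites[inside]
  center <- center[inside]; chrom <- chrom[inside]
  windows <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(center - hw, center + hw))
  S4Vectors::mcols(windows)$center <- center
  S4Vectors::mcols(windows)$siteStrand <-
    as.character(GenomicRanges::strand(sites))
  seqGr <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(center - hw - margin,
                                                   center + hw + margin))
  seqs <- .getSeqs(genome, seqGr)
  minus <- S4Vectors::mcols(windows)$siteStrand == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  new("WindowStack", motifId = motifId, config = unclass(config),
      windows = windows, seqs = seqs, tracks = list(),
      expected = numeric(0), nDiscarded = as.integer(nDiscarded),
      cache = new.env(parent = emptyenv()))
}

# Strand-aware genomic-position -> window-offset mapping for event hits.
# `g` genomic positions, `win` window indices into stack@windows.
.orientOffsets <- function(stack, g, win) {
  center <- S4Vectors::mcols(stack@windows)$center[win]
  plus <- S4Vectors::mcols(stack@windows)$siteStrand[win] == "+"
  ifelse(plus, g - center, center - g)
}

#' Map point events or CPD records onto a stack
#'
#' Mutations (no `count` column) each add 1 at their oriented offset.
#' CPD records add their `count` at the oriented offset of the
#' dipyrimidine (anchored at the smaller oriented offset of the two
#' bases), split by strand relative to the motif orientation; dimers not
#' fully inside the window are dropped for that window. Events falling
#' in two overlapping windows are counted in each window.
#'
#' @param stack a [WindowStack].
#' @param events mutations or CPD `GRanges`.
#' @param track track name; defaults to `"mutations"` for mutation
#'   events and the CPD `timepoint` label (prefixed `cpd_`) otherwise.
#' @return The stack with the track added (replacing any same-named
#'   track).
#' @export
mapEvents <- function(stack, events, track = NULL) {
  n <- nSites(stack)
  hw <- stack@config$halfWidth
  ncols <- 2L * hw + 1L
  isCpd <- "count" %in% names(S4Vectors::mcols(events))
  ov <- GenomicRanges::findOverlaps(events, stack@windows,
                                    ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); w <- S4Vectors::subjectHits(ov)
  if (!isCpd) {
    if (is.null(track)) track <- "mutations"
    off <- .orientOffsets(stack, GenomicRanges::start(events)[q], w)
    m <- Matrix::sparseMatrix(i = w, j = off + hw + 1L, x = 1,
                              dims = c(n, ncols))
    stack@tracks[[track]] <- m
  } else {
    if (is.null(track))
      track <- paste0("cpd_", S4Vectors::mcols(events)$timepoint[1])
    a <- GenomicRanges::start(events)[q]
    o1 <- .orientOffsets(stack, a, w)
    o2 <- .orientOffsets(stack, a + 1L, w)
    pairStart <- pmin(o1, o2)
    keep <- pairStart >= -hw & pairStart + 1L <= hw
    q <- q[keep]; w <- w[keep]; pairStart <- pairStart[keep]
    evStrand <- as.character(GenomicRanges::strand(events))[q]
    winPlus <- S4Vectors::mcols(stack@windows)$siteStrand[w] == "+"
    rel <- ifelse(winPlus, evStrand,
                  ifelse(evStrand == "+", "-", "+"))
    cnt <- S4Vectors::mcols(events)$count[q]
    mk <- function(sel) Matrix::sparseMatrix(
      i = w[sel], j = pairStart[sel] + hw + 1L, x = cnt[sel],
      dims = c(n, ncols))
    stack@tracks[[track]] <- list(plus = mk(rel == "+"),
                                  minus = mk(rel == "-"))
  }
  stack
}

#' Per-offset totals of a track
#'
#' Sums a track over windows; CPD tracks sum both motif-relative
#' strands.
#'
#' @param stack a [WindowStack].
#' @param track track name.
#' @return Numeric vector over the `2 * halfWidth + 1` offsets.
#' @export
stackProfile <- function(stack, track) {
  tr <- stack@tracks[[track]]
  .check(!is.null(tr), "no track named '%s'", track)
  if (is.list(tr)) Matrix::colSums(tr$plus) + Matrix::colSums(tr$minus)
  else Matrix::colSums(tr)
}

#' @rdname stackProfile
#' @export
windowMutationCounts <- function(stack, track = "mutations") {
  tr <- stack@tracks[[track]]
  .check(!is.null(tr) && !is.list(tr), "no mutation-like track '%s'", track)
  Matrix::rowSums(tr)
}

#' @rdname stackProfile
#' @export
stackOffsets <- function(stack)
  seq.int(-stack@config$halfWidth, stack@config$halfWidth)

#' Motif-level inclusion filters
#'
#' Keeps a stack iff it has at least `minSites` windows *and* the median
#' of the per-offset mutation counts is at least `minMedianMutations`.
#'
#' @param stacks list of [WindowStack]s with a mutations track.
#' @param config an [analysisConfig()].
#' @return `list(kept = <stacks>, report = <data.frame>)`; the report
#'   lists every stack with its site count, median mutation count and
#'   the exclusion reason (`""` when retained).
#' @export
filterMotifs <- function(stacks, config = analysisConfig()) {
  rep <- do.call(rbind, lapply(stacks, function(st) {
    med <- median(stackProfile(st, "mutations"))
    n <- nSites(st)
    reason <- if (n < config$minSites) "site count"
      else if (med < config$minMedianMutations) "median mutations"
      else ""
    data.frame(motif_id = st@motifId, n_sites = n, median_mutations = med,
               kept = reason == "", reason = reason,
               stringsAsFactors = FALSE)
  }))
  rownames(rep) <- NULL
  list(kept = stacks[rep$kept], report = rep)
}

#' Window-total normalisation of a per-offset profile
#'
#' Divides a per-offset count vector by its total so the window sums
#' to 1 (the zoom-out normalisation applied to CPD tracks).
#'
#' @param profile numeric per-offset counts.
#' @param name track name used in the error message.
#' @return Numeric fractions summing to 1.
#' @export
normalizeWindowTrack <- function(profile, name = "track") {
  tot <- sum(profile)
  .check(tot > 0, "track '%s' has zero total", name)
  profile / tot
}
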