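# Within-motif analysis: conserved dipyrimidine sites, the
# tetranucleotide-matched flank sampling null, and per-site repair
# differences in percentage points.

# Track column for an oriented offset.
.offCol <- function(stack, o) o + stack@config$halfWidth + 1L
# Sequence-matrix column (sequences carry a 2-base margin).
.seqCol <- function(stack, o) o + stack@config$halfWidth + 3L

# Flank pair offsets whose two bases both lie in the flank region.
.flankPairOffsets <- function(config) {
  hw <- config$halfWidth
  inner <- config$tfbsWidth %/% 2L + config$dhsFlankWidth  # last dhs offset
  c(seq.int(-hw, -inner - 2L), seq.int(inner + 1L, hw - 1L))
}

# Tetranucleotide integer codes (1..256) at pair offsets, per strand.
# Returns list(offsets, plus = n x m, minus = n x m), NA where any base
# is N. Memoised on the stack cache.
.flankTetraCodes <- function(stack) {
  if (!is.null(stack@cache$flankTetra)) return(stack@cache$flankTetra)
  codes <- .stackCodes(stack)
  offs <- .flankPairOffsets(stack@config)
  cols <- .seqCol(stack, offs)
  tet <- function(strand) {
    out <- matrix(NA_integer_, nrow = nrow(codes), ncol = length(offs))
    b <- lapply(-1:2, function(d) codes[, cols + d, drop = FALSE])
    ok <- !(is.na(b[[1]]) | is.na(b[[2]]) | is.na(b[[3]]) | is.na(b[[4]]))
    if (strand == "+") {
      code <- (b[[1]] - 1L) * 64L + (b[[2]] - 1L) * 16L +
        (b[[3]] - 1L) * 4L + b[[4]]
      # inner pair must be pyrimidines on +
      ok <- ok & (b[[2]] == 2L | b[[2]] == 4L) & (b[[3]] == 2L | b[[3]] == 4L)
    } else {
      code <- (4L - b[[4]]) * 64L + (4L - b[[3]]) * 16L +
        (4L - b[[2]]) * 4L + (5L - b[[1]])
      ok <- ok & (b[[2]] == 1L | b[[2]] == 3L) & (b[[3]] == 1L | b[[3]] == 3L)
    }
    code[!ok] <- NA_integer_
    out[] <- code
    out
  }
  res <- list(offsets = offs, plus = tet("+"), minus = tet("-"))
  stack@cache$flankTetra <- res
  res
}

# Tetranucleotide code of the site (o, o+1, strand) per window.
.siteTetraCodes <- function(stack, offset, strand) {
  codes <- .stackCodes(stack)
  cols <- .seqCol(stack, offset) + (-1:2)
  b <- lapply(seq_len(4L), function(j) codes[, cols[j]])
  ok <- !(is.na(b[[1]]) | is.na(b[[2]]) | is.na(b[[3]]) | is.na(b[[4]]))
  if (strand == "+")
    code <- (b[[1]] - 1L) * 64L + (b[[2]] - 1L) * 16L +
      (b[[3]] - 1L) * 4L + b[[4]]
  else
    code <- (4L - b[[4]]) * 64L + (4L - b[[3]]) * 16L +
      (4L - b[[2]]) * 4L + (5L - b[[1]])
  code[!ok] <- NA_integer_
  code
}

#' Conserved dipyrimidine sites within the motif
#'
#' For every adjacent offset pair inside the motif and both
#' motif-relative strands, computes the fraction of windows carrying
#' each specific dipyrimidine type (TT, TC, CT, CC read 5' to 3' on that
#' strand) and reports sites where one type reaches `minConservation`.
#'
#' @param stack a [WindowStack].
#' @param minConservation conservation threshold (default from the
#'   stack's config, normally 0.5).
#' @return `data.frame(motif_id, offset, strand, type, conservation,
#'   n_carriers)`; `offset` is the motif-oriented offset of the 5'-most
#'   base of the pair (the smaller offset).
#' @export
conservedDipyrimidines <- function(stack,
                                   minConservation =
                                     stack@config$conservationMin) {
  codes <- .stackCodes(stack)
  n <- nrow(codes)
  half <- stack@config$motifWidth %/% 2L
  rows <- list()
  for (o in seq.int(-half, half - 1L)) {
    c1 <- codes[, .seqCol(stack, o)]
    c2 <- codes[, .seqCol(stack, o + 1L)]
    for (strand in c("+", "-")) {
      type <- .dipyrType(c1, c2, strand)
      tb <- table(type)
      for (tp in names(tb)) {
        frac <- as.numeric(tb[[tp]]) / n
        if (frac >= minConservation)
          rows[[length(rows) + 1L]] <- data.frame(
            motif_id = stack@motifId, offset = o, strand = strand,
            type = tp, conservation = frac,
            n_carriers = as.integer(tb[[tp]]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(motif_id = character(), offset = integer(),
                      strand = character(), type = character(),
                      conservation = numeric(), n_carriers = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Carrier windows of a dipyrimidine site.
.siteCarriers <- function(stack, site) {
  codes <- .stackCodes(stack)
  c1 <- codes[, .seqCol(stack, site$offset)]
  c2 <- codes[, .seqCol(stack, site$offset + 1L)]
  which(!is.na(.dipyrType(c1, c2, site$strand)) &
          .dipyrType(c1, c2, site$strand) == site$type)
}

#' Draw tetranucleotide-matched flank positions for a site
#'
#' For each sampling iteration and each carrier window, draws one flank
#' dipyrimidine (either strand) uniformly among those sharing that
#' window's own 5'-base + dipyrimidine + 3'-base tetranucleotide.
#' Windows with no matching flank tetranucleotide are skipped and
#' counted. The same draws can then be evaluated against any track with
#' [evaluateDraws()], which keeps multi-track comparisons (e.g. 0h vs
#' 48h repair) on identical sampled positions.
#'
#' @param stack a [WindowStack].
#' @param site one row of [conservedDipyrimidines()].
#' @param nIter iterations (default from config, normally 50).
#' @param seed RNG seed.
#' @return list with `carriers`, `draws` (carriers x nIter candidate
#'   index, NA for skipped windows), `offsets`/`strands` decoding the
#'   candidate index, and `nSkipped`.
#' @export
drawMatchedSamples <- function(stack, site,
                               nIter = stack@config$samplingIters,
                               seed = 1L) {
  ft <- .flankTetraCodes(stack)
  carriers <- .siteCarriers(stack, site)
  tet <- .siteTetraCodes(stack, site$offset, site$strand)
  m <- length(ft$offsets)
  draws <- matrix(NA_integer_, nrow = length(carriers), ncol = nIter)
  nSkipped <- 0L
  set.seed(seed)
  for (i in seq_along(carriers)) {
    w <- carriers[i]
    if (is.na(tet[w])) { nSkipped <- nSkipped + 1L; next }
    matches <- c(which(ft$plus[w, ] == tet[w]),
                 which(ft$minus[w, ] == tet[w]) + m)
    if (length(matches) == 0L) { nSkipped <- nSkipped + 1L; next }
    draws[i, ] <- if (length(matches) == 1L) rep(matches, nIter)
      else sample(matches, nIter, replace = TRUE)
  }
  list(carriers = carriers, draws = draws, offsets = ft$offsets,
       nCandidates = m, nSkipped = nSkipped, seed = seed)
}

#' @rdname drawMatchedSamples
#' @param drawn result of `drawMatchedSamples()`.
#' @param track track name; mutation-like tracks sum both bases of the
#'   sampled dipyrimidine, CPD tracks take the strand-specific record of
#'   the sampled pair.
#' @return `list(perIter, expected)`: the per-iteration summed counts
#'   over carrier windows and their mean.
#' @export
evaluateDraws <- function(stack, drawn, track) {
  tr <- stack@tracks[[track]]
  .check(!is.null(tr), "no track named '%s'", track)
  nIter <- ncol(drawn$draws)
  perIter <- numeric(nIter)
  ok <- !is.na(drawn$draws[, 1L])
  if (!any(ok)) return(list(perIter = perIter, expected = NA_real_))
  wIdx <- drawn$carriers[ok]
  for (it in seq_len(nIter)) {
    d <- drawn$draws[ok, it]
    minus <- d > drawn$nCandidates
    off <- drawn$offsets[ifelse(minus, d - drawn$nCandidates, d)]
    col <- .offCol(stack, off)
    if (is.list(tr)) {
      v <- numeric(length(d))
      if (any(!minus))
        v[!minus] <- tr$plus[cbind(wIdx[!minus], col[!minus])]
      if (any(minus))
        v[minus] <- tr$minus[cbind(wIdx[minus], col[minus])]
    } else {
      v <- tr[cbind(wIdx, col)] + tr[cbind(wIdx, col + 1L)]
    }
    perIter[it] <- sum(v)
  }
  list(perIter = perIter, expected = mean(perIter))
}

#' Observed track count at a dipyrimidine site
#'
#' Mutations sum both bases of the pair over carrier windows; CPD tracks
#' take the strand-specific dimer records anchored at the site.
#'
#' @param stack a [WindowStack].
#' @param site one row of [conservedDipyrimidines()].
#' @param track track name.
#' @return Scalar count.
#' @export
siteObserved <- function(stack, site, track) {
  tr <- stack@tracks[[track]]
  .check(!is.null(tr), "no track named '%s'", track)
  carriers <- .siteCarriers(stack, site)
  col <- .offCol(stack, site$offset)
  if (is.list(tr)) {
    m <- if (site$strand == "+") tr$plus else tr$minus
    sum(m[carriers, col])
  } else {
    sum(tr[carriers, col]) + sum(tr[carriers, col + 1L])
  }
}

#' Percent deviation of observed from expected
#' @param observed,expected counts; `expected` must be > 0 (otherwise
#'   NA is returned).
#' @return `100 * (observed - expected) / expected`.
#' @export
percentOverExpected <- function(observed, expected) {
  if (is.na(expected) || expected <= 0) return(NA_real_)
  100 * (observed - expected) / expected
}

#' Within-motif repair difference in percentage points
#'
#' Normalises site and sampled-flank CPD counts by the genome-wide CPD
#' totals of each timepoint, computes the percent change after 48h at
#' the site and at the matched flank positions (identical draws at both
#' timepoints), and returns site minus flank in percentage points.
#' Positive values mean the site lost a smaller share of CPDs than its
#' matched flanks, i.e. was less repaired.
#'
#' @param stack a [WindowStack] with `cpd_0h` and `cpd_48h` tracks.
#' @param site one row of [conservedDipyrimidines()].
#' @param genomeTotals numeric(2) genome-wide CPD totals `c(t0, t48)`.
#' @param drawn matched draws from [drawMatchedSamples()] (drawn once,
#'   reused for both timepoints).
#' @param track0,track48 track names (defaults `cpd_0h`, `cpd_48h`).
#' @return `list(pp_diff, site_percent_change, flank_percent_change)`.
#' @export
withinMotifRepair <- function(stack, site, genomeTotals, drawn,
                              track0 = "cpd_0h", track48 = "cpd_48h") {
  .check(length(genomeTotals) == 2L && all(genomeTotals > 0),
         "genomeTotals must be two positive totals")
  n0 <- siteObserved(stack, site, track0)
  n48 <- siteObserved(stack, site, track48)
  if (n0 == 0)
    return(list(pp_diff = NA_real_, site_percent_change = NA_real_,
                flank_percent_change = NA_real_))
  e0 <- evaluateDraws(stack, drawn, track0)$expected
  e48 <- evaluateDraws(stack, drawn, track48)$expected
  sitePct <- 100 * (n48 / genomeTotals[2] - n0 / genomeTotals[1]) /
    (n0 / genomeTotals[1])
  flankPct <- if (!is.na(e0) && e0 > 0)
    100 * (e48 / genomeTotals[2] - e0 / genomeTotals[1]) /
      (e0 / genomeTotals[1])
  else NA_real_
  list(pp_diff = if (is.na(flankPct)) NA_real_ else sitePct - flankPct,
       site_percent_change = sitePct, flank_percent_change = flankPct)
}

#' Full within-motif summary table
#'
#' Runs the conserved-dipyrimidine selection and, per site and per
#' requested track, the matched-flank expectation, percent over
#' expected, a Poisson G-test significance call, and (when both CPD
#' timepoints and genome totals are given) the repair difference in
#' percentage points.
#'
#' @param stack a [WindowStack].
#' @param tracks track names to evaluate (default mutations + any CPD
#'   tracks present).
#' @param nIter sampling iterations (default config, 50).
#' @param seed RNG seed recorded in the output.
#' @param genomeTotals optional named list of genome-wide totals for the
#'   repair comparison: `list(cpd_0h = t0, cpd_48h = t48)`.
#' @param minConservation conservation threshold.
#' @return `data.frame`, one row per site x track.
#' @export
withinMotifSummary <- function(stack, tracks = trackNames(stack),
                               nIter = stack@config$samplingIters,
                               seed = 1L, genomeTotals = NULL,
                               minConservation =
                                 stack@config$conservationMin) {
  sites <- conservedDipyrimidines(stack, minConservation)
  if (nrow(sites) == 0L) return(sites)
  rows <- list()
  for (s in seq_len(nrow(sites))) {
    site <- sites[s, ]
    drawn <- drawMatchedSamples(stack, site, nIter = nIter,
                                seed = seed + s)
    ppDiff <- NA_real_
    if (!is.null(genomeTotals) &&
        all(c("cpd_0h", "cpd_48h") %in% trackNames(stack))) {
      rp <- withinMotifRepair(stack, site,
                              c(genomeTotals$cpd_0h, genomeTotals$cpd_48h),
                              drawn)
      ppDiff <- rp$pp_diff
    }
    for (tr in tracks) {
      obs <- siteObserved(stack, site, tr)
      ev <- evaluateDraws(stack, drawn, tr)
      tst <- poissonGTest(obs, ev$expected)
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = site$motif_id, offset = site$offset,
        strand = site$strand, type = site$type,
        conservation = site$conservation, track = tr, observed = obs,
        expected = ev$expected,
        percent_over_expected = percentOverExpected(obs, ev$expected),
        repair_pp_diff = ppDiff, statistic = tst$statistic,
        p_value = tst$p_value, n_skipped_windows = drawn$nSkipped,
        seed = seed + s, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
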