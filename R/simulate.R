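# Self-contained synthetic study generator: genome, implanted motif
# instances, DHS marks, fixed-depth CPD maps at naked/0h/48h with planted
# damage multipliers and region-wise repair impairment, and a UV-dominated
# mutation cohort. Every output is reproducible from (parameters, seed)
# and the planted truth is returned alongside, so every pipeline stage can
# be validated by parameter recovery.

# Default 21-bp consensus. Plus-strand dipyrimidines: TT at oriented
# offsets (-8,-7) (the default damage-spike target), TC at (-7,-6) and
# (8,9), CC at (4,5); four more on the minus strand.
DEFAULT_CONSENSUS <- "GATTCGCATGACGCCAGTCAG"

#' Synthetic motif model
#'
#' Builds a sharp [MotifMatrix] around a consensus: the consensus base
#' gets `sharpness` of each column's mass, the rest is split evenly.
#'
#' @param consensus consensus string (default a fixed 21-mer with a TT
#'   dimer at oriented offsets -8,-7).
#' @param sharpness consensus base frequency per column (default 0.97).
#' @param motifId label.
#' @return A [MotifMatrix].
#' @export
syntheticMotif <- function(consensus = DEFAULT_CONSENSUS, sharpness = 0.97,
                           motifId = "SYN1") {
  code <- .codeChars(strsplit(consensus, "")[[1]])
  .check(!anyNA(code), "consensus must be ACGT only")
  counts <- matrix(round(1000 * (1 - sharpness) / 3), 4L, length(code),
                   dimnames = list(BASES, NULL))
  counts[cbind(code, seq_along(code))] <- round(1000 * sharpness)
  MotifMatrix(motifId, counts, tfName = motifId, tfFamily = "Synthetic")
}

#' Generate a random genome
#'
#' i.i.d. bases at the requested GC content; deterministic per seed.
#'
#' @param length genome length (single chromosome `chr1`).
#' @param gc GC fraction in (0, 1) -- or 0/1 for AT-/GC-only genomes.
#' @param seed RNG seed.
#' @return A `DNAStringSet` with one sequence.
#' @export
simulateGenome <- function(length, gc = 0.4, seed = 1L) {
  .check(gc >= 0 && gc <= 1, "gc must be in [0, 1]")
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chars <- sample(BASES, length, replace = TRUE, prob = p)
  Biostrings::DNAStringSet(stats::setNames(paste(chars, collapse = ""),
                                           "chr1"))
}

#' Implant motif instances into a genome
#'
#' Writes motif instances (the consensus, optionally degraded by
#' `fidelity`) into the genome at regularly spaced, shuffled positions
#' on random strands, and emits the matching peak and DHS annotation:
#' peaks cover every implanted site; two synthetic "cell type" DHS sets
#' cover the active sites only, so DHS classification recovers the
#' planted active/inactive split.
#'
#' @param genome `DNAStringSet` (single chromosome).
#' @param motif a [MotifMatrix].
#' @param nActive,nInactive planted site counts.
#' @param spacing distance between consecutive site centers; >= the
#'   window length keeps windows disjoint (default 2100).
#' @param fidelity per-base probability of keeping the consensus base
#'   (default 1 = exact consensus instances).
#' @param seed RNG seed.
#' @return list with the modified `genome`, `sites` (truth `GRanges`
#'   with `motif_id`, `center`, `active`), `peaks`, `dhs1`, `dhs2`.
#' @export
implantSites <- function(genome, motif = syntheticMotif(), nActive = 6000L,
                         nInactive = 1000L, spacing = 2100L, fidelity = 1,
                         seed = 1L) {
  .check(length(genome) == 1L, "implantSites expects a single chromosome")
  L <- motifLength(motif)
  n <- nActive + nInactive
  len <- Biostrings::width(genome)[1]
  lead <- 1100L
  .check(lead + (n - 1L) * spacing + lead <= len,
         "cannot place %d sites with spacing %d in a %d bp genome; use a longer genome",
         n, spacing, len)
  set.seed(seed)
  centers <- lead + (seq_len(n) - 1L) * spacing
  active <- logical(n)
  active[sample.int(n, nActive)] <- TRUE
  strand <- sample(c("+", "-"), n, replace = TRUE)
  consensus <- BASES[apply(motifCounts(motif), 2L, which.max)]
  inst <- matrix(rep(consensus, n), nrow = n, byrow = TRUE)
  if (fidelity < 1) {
    flip <- matrix(stats::runif(n * L) > fidelity, n, L)
    inst[flip] <- sample(BASES, sum(flip), replace = TRUE)
  }
  instStr <- apply(inst, 1L, paste, collapse = "")
  instSet <- Biostrings::DNAStringSet(instStr)
  minus <- strand == "-"
  if (any(minus))
    instSet[minus] <- Biostrings::reverseComplement(instSet[minus])
  starts <- centers - L %/% 2L
  chr <- Biostrings::replaceAt(genome[[1]],
                               IRanges::IRanges(starts, width = L),
                               instSet)
  genome <- Biostrings::DNAStringSet(stats::setNames(as.character(chr),
                                                     names(genome)[1]))
  sites <- GenomicRanges::GRanges(names(genome)[1],
                                  IRanges::IRanges(starts, width = L),
                                  strand = strand)
  S4Vectors::mcols(sites)$motif_id <- motifId(motif)
  S4Vectors::mcols(sites)$score <- NA_real_
  S4Vectors::mcols(sites)$center <- centers
  S4Vectors::mcols(sites)$active <- active
  mkSet <- function(centers, pad) GenomicRanges::GRanges(
    names(genome)[1], IRanges::IRanges(centers - pad, centers + pad))
  list(genome = genome, sites = sites,
       peaks = mkSet(centers, 30L),
       dhs1 = mkSet(centers[active], 80L),
       dhs2 = mkSet(centers[active], 120L))
}

#' Genome-wide dipyrimidine inventory
#'
#' Every position (both strands) where two adjacent bases are
#' pyrimidines read on that strand. Records are anchored at the
#' leftmost (reference-strand) base of the pair; `type` is the
#' dipyrimidine read 5' to 3' on its strand.
#'
#' @param genome `DNAStringSet`.
#' @return `data.table(chrom, pos, strand, type)`.
#' @export
dipyrimidineInventory <- function(genome) {
  out <- lapply(names(genome), function(ch) {
    code <- .codeChars(strsplit(as.character(genome[[ch]]), "")[[1]])
    n <- length(code)
    c1 <- code[-n]; c2 <- code[-1L]
    plusType <- .dipyrType(c1, c2, "+")
    minusType <- .dipyrType(c1, c2, "-")
    iP <- which(!is.na(plusType)); iM <- which(!is.na(minusType))
    data.table::data.table(
      chrom = ch,
      pos = c(iP, iM),
      strand = rep(c("+", "-"), c(length(iP), length(iM))),
      type = c(plusType[iP], minusType[iM]))
  })
  data.table::rbindlist(out)
}

# Per-dipyrimidine CPD intensities under the planted truth. Returns the
# inventory extended with site index (0 = background), region, oriented
# pairStart/relStrand within the site window, and intensity columns
# Inaked, I0, I48.
.cpdIntensityTable <- function(genome, sites, config, baseline, survival,
                               backgroundSurvival, damageMotif, spike,
                               backgroundWeight) {
  inv <- dipyrimidineInventory(genome)
  act <- sites[S4Vectors::mcols(sites)$active]
  nAct <- length(act)
  # normalise per-site parameter shapes
  if (is.null(dim(damageMotif)))
    damageMotif <- rep(damageMotif, length.out = nAct)
  regions <- c("motif", "tfbs", "dhs_flank", "flank")
  if (is.null(dim(survival))) {
    .check(all(regions %in% names(survival)),
           "survival needs entries motif, tfbs, dhs_flank, flank")
    survival <- matrix(rep(survival[regions], each = nAct), nrow = nAct,
                       dimnames = list(NULL, regions))
  } else {
    survival <- as.matrix(survival[, regions, drop = FALSE])
    .check(nrow(survival) == nAct, "survival needs one row per active site")
  }
  hw <- config$halfWidth
  centers <- S4Vectors::mcols(act)$center
  winGr <- GenomicRanges::GRanges(GenomicRanges::seqnames(act),
                                  IRanges::IRanges(centers - hw,
                                                   centers + hw))
  invGr <- GenomicRanges::GRanges(inv$chrom,
                                  IRanges::IRanges(inv$pos, inv$pos))
  ov <- GenomicRanges::findOverlaps(invGr, winGr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); sIdx <- S4Vectors::subjectHits(ov)
  d <- inv$pos[q] - centers[sIdx]
  sPlus <- as.character(GenomicRanges::strand(act))[sIdx] == "+"
  pairStartVec <- as.integer(ifelse(sPlus, d, -d - 1L))
  relStrandVec <- ifelse(sPlus, inv$strand[q],
                         ifelse(inv$strand[q] == "+", "-", "+"))
  mask <- as.character(regionMask(config))
  regionVec <- mask[pmin(pmax(pairStartVec, -hw), hw - 1L) + hw + 1L]
  inv[, `:=`(site = 0L, region = "background", pairStart = NA_integer_,
             relStrand = NA_character_)]
  data.table::set(inv, i = q, j = "site", value = sIdx)
  data.table::set(inv, i = q, j = "region", value = regionVec)
  data.table::set(inv, i = q, j = "pairStart", value = pairStartVec)
  data.table::set(inv, i = q, j = "relStrand", value = relStrandVec)
  base <- baseline[inv$type]
  bg <- inv$site == 0L
  wgt <- ifelse(bg, backgroundWeight, 1)
  inv[, Inaked := base * wgt]
  I0 <- base * wgt
  inMotif <- !bg & inv$region == "motif"
  I0[inMotif] <- I0[inMotif] * damageMotif[inv$site[inMotif]]
  if (!is.null(spike)) {
    hit <- !bg & inv$pairStart == spike$offset & inv$relStrand == spike$strand
    hit[is.na(hit)] <- FALSE
    I0[hit] <- I0[hit] * spike$factor
  }
  inv[, I0 := I0]
  sv <- rep(backgroundSurvival, nrow(inv))
  inw <- which(!bg)
  sv[inw] <- survival[cbind(inv$site[inw],
                            match(inv$region[inw], regions))]
  inv[, I48 := I0 * sv]
  inv
}

# Draw one fixed-depth map from an intensity column. Exact multinomial
# when the depth fits an integer; independent Poisson (the standard
# large-depth approximation of the fixed-depth multinomial) otherwise.
.sampleCpdMap <- function(intens, column, depth, timepoint, seed) {
  set.seed(seed)
  I <- intens[[column]]
  tot <- sum(I)
  .check(tot > 0, "all-zero intensity for %s", column)
  if (depth < .Machine$integer.max) {
    counts <- as.numeric(rmultinom(1L, size = as.integer(depth), prob = I))
  } else {
    counts <- rpois(length(I), depth * I / tot)
  }
  nz <- counts > 0
  gr <- GenomicRanges::GRanges(intens$chrom[nz],
                               IRanges::IRanges(intens$pos[nz],
                                                intens$pos[nz]),
                               strand = intens$strand[nz])
  S4Vectors::mcols(gr)$count <- counts[nz]
  S4Vectors::mcols(gr)$timepoint <- timepoint
  gr
}

#' Simulate fixed-depth CPD maps with planted truth
#'
#' Per-dipyrimidine 0h intensity is `baseline(type)`, times the
#' per-site motif damage multiplier inside the motif region, times the
#' spike factor at the spiked dipyrimidine; naked-DNA intensity is the
#' baseline only (no bound protein); 48h intensity is the 0h intensity
#' times the region survival fraction. Each timepoint's map is a
#' fixed-depth draw over all genomic dipyrimidines, so only relative
#' information survives -- absolute repair is deliberately destroyed.
#'
#' Survival fractions are expressed relative to the genomic background
#' (`backgroundSurvival = 1`): with fixed-depth maps only
#' survival-relative-to-background is identifiable. `backgroundWeight`
#' scales the intensity of background dipyrimidines so that a
#' desk-scale genome reproduces the genome-scale situation in which
#' windows hold a small share of the total CPD mass.
#'
#' @param genome `DNAStringSet`.
#' @param sites truth sites from [implantSites()] (active sites get the
#'   damage and repair structure; inactive sites behave as background).
#' @param config an [analysisConfig()].
#' @param depth total reads per timepoint; alternatively give
#'   `depthPerWindow` (expected 0h reads per active window).
#' @param depthPerWindow see `depth`.
#' @param baseline named per-type formation propensities.
#' @param survival named vector (or per-active-site data.frame) of
#'   survival fractions for motif/tfbs/dhs_flank/flank.
#' @param backgroundSurvival background survival (default 1; reference
#'   unit).
#' @param damageMotif motif-region damage multiplier, scalar or one per
#'   active site.
#' @param spike `list(offset, strand, factor)` single-dipyrimidine
#'   damage spike in motif-oriented coordinates, or NULL.
#' @param backgroundWeight intensity multiplier for background
#'   dipyrimidines (default 1).
#' @param timepoints subset of `c("naked", "0h", "48h")`.
#' @param seed RNG seed.
#' @return list: `maps` (named list of CPD `GRanges`), `intensities`
#'   (the truth table), `depth`.
#' @export
simulateCpdMaps <- function(genome, sites, config = analysisConfig(),
                            depth = NULL, depthPerWindow = NULL,
                            baseline = c(TT = 1, TC = 0.6, CT = 0.4,
                                         CC = 0.3),
                            survival = c(motif = 0.8, tfbs = 0.7,
                                         dhs_flank = 0.55, flank = 0.4),
                            backgroundSurvival = 1, damageMotif = 1,
                            spike = list(offset = -8L, strand = "+",
                                         factor = 2),
                            backgroundWeight = 1,
                            timepoints = c("naked", "0h", "48h"),
                            seed = 1L) {
  intens <- .cpdIntensityTable(genome, sites, config, baseline, survival,
                               backgroundSurvival, damageMotif, spike,
                               backgroundWeight)
  if (is.null(depth)) {
    .check(!is.null(depthPerWindow), "give depth or depthPerWindow")
    nWin <- sum(S4Vectors::mcols(sites)$active)
    wFrac <- sum(intens$I0[intens$site > 0L]) / sum(intens$I0)
    depth <- round(depthPerWindow * nWin / wFrac)
  }
  cols <- c(naked = "Inaked", `0h` = "I0", `48h` = "I48")
  maps <- lapply(seq_along(timepoints), function(i) {
    tp <- timepoints[i]
    .sampleCpdMap(intens, cols[[tp]], depth, tp, seed + i)
  })
  names(maps) <- timepoints
  list(maps = maps, intensities = intens, depth = depth)
}

#' Simulate a UV-dominated mutation cohort
#'
#' Per sample, C>T mutations are placed at cytosines inside
#' dipyrimidines with probability proportional to the damage intensity
#' of the containing dimer (by default the 48h-surviving intensity --
#' mutations arise from lesions that escaped repair; `from = "0h"` is
#' the negative control), and `1 - ctFraction` of records are non-C>T
#' noise placed uniformly.
#'
#' @param genome `DNAStringSet`.
#' @param intensities truth table from [simulateCpdMaps()].
#' @param nSamples,mutsPerSample cohort shape.
#' @param ctFraction per-sample C>T fraction (default 0.9).
#' @param from `"48h"` or `"0h"` damage law.
#' @param seed RNG seed.
#' @return Mutations `GRanges` (as from [readMutations()]).
#' @export
simulateMutationCohort <- function(genome, intensities, nSamples = 40L,
                                   mutsPerSample = 5000L, ctFraction = 0.9,
                                   from = c("48h", "0h"), seed = 1L) {
  from <- match.arg(from)
  .check(ctFraction >= 0 && ctFraction <= 1, "ctFraction must be in [0,1]")
  icol <- if (from == "48h") "I48" else "I0"
  set.seed(seed)
  # candidate cytosines inside dipyrimidines (plus-strand C, or G = C on
  # the minus strand), weighted by the containing dimer's intensity
  t1 <- substr(intensities$type, 1L, 1L)
  t2 <- substr(intensities$type, 2L, 2L)
  plus <- intensities$strand == "+"
  candPos <- c(intensities$pos[t1 == "C" & plus],
               intensities$pos[t2 == "C" & plus] + 1L,
               intensities$pos[t1 == "C" & !plus] + 1L,
               intensities$pos[t2 == "C" & !plus])
  candChrom <- c(intensities$chrom[t1 == "C" & plus],
                 intensities$chrom[t2 == "C" & plus],
                 intensities$chrom[t1 == "C" & !plus],
                 intensities$chrom[t2 == "C" & !plus])
  candRef <- rep(c("C", "C", "G", "G"),
                 c(sum(t1 == "C" & plus), sum(t2 == "C" & plus),
                   sum(t1 == "C" & !plus), sum(t2 == "C" & !plus)))
  w <- intensities[[icol]]
  candW <- c(w[t1 == "C" & plus], w[t2 == "C" & plus],
             w[t1 == "C" & !plus], w[t2 == "C" & !plus])
  .check(length(candPos) > 0 && sum(candW) > 0, "no mutable cytosines")
  nCT <- round(mutsPerSample * ctFraction)
  nNoise <- mutsPerSample - nCT
  chrLen <- stats::setNames(Biostrings::width(genome), names(genome))
  rows <- lapply(seq_len(nSamples), function(sm) {
    idx <- sample.int(length(candPos), nCT, replace = TRUE, prob = candW)
    ct <- data.table::data.table(
      sample = sprintf("S%03d", sm), chrom = candChrom[idx],
      pos = candPos[idx], ref = candRef[idx],
      alt = ifelse(candRef[idx] == "C", "T", "A"))
    if (nNoise > 0L) {
      ch <- sample(names(genome), nNoise, replace = TRUE,
                   prob = chrLen / sum(chrLen))
      np <- as.integer(floor(runif(nNoise) * (chrLen[ch] - 2L))) + 1L
      refGr <- GenomicRanges::GRanges(ch, IRanges::IRanges(np, np))
      ref <- as.character(.getSeqs(genome, refGr))
      alt <- vapply(ref, function(r) switch(r,
        C = sample(c("A", "G"), 1L), G = sample(c("C", "T"), 1L),
        A = sample(c("C", "G", "T"), 1L), T = sample(c("A", "C", "G"), 1L),
        N = "A"), character(1))
      keep <- ref != "N"
      noise <- data.table::data.table(
        sample = sprintf("S%03d", sm), chrom = ch[keep], pos = np[keep],
        ref = ref[keep], alt = alt[keep])
      ct <- rbind(ct, noise)
    }
    ct
  })
  dt <- data.table::rbindlist(rows)
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
  S4Vectors::mcols(gr)$sample <- dt$sample
  S4Vectors::mcols(gr)$ref <- dt$ref
  S4Vectors::mcols(gr)$alt <- dt$alt
  gr
}

#' Generate a complete synthetic study
#'
#' Composes [simulateGenome()], [implantSites()], [simulateCpdMaps()]
#' and [simulateMutationCohort()] under one seed. The defaults are the
#' study conditions used throughout the package's validation: 6000
#' active + 1000 inactive sites at 2100-bp spacing, 10^4 expected 0h
#' reads per window, a 2x damage spike at the consensus TT, and motif
#' survival 0.8 vs flank survival 0.4 (relative to background).
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param config an [analysisConfig()].
#' @param nActive,nInactive,spacing,gc,fidelity implant/genome shape.
#' @param depthPerWindow expected 0h reads per active window.
#' @param baseline,survival,damageMotif,spike,backgroundWeight,
#'   backgroundSurvival damage/repair truth (see [simulateCpdMaps()]).
#' @param nSamples,mutsPerSample,ctFraction,mutationsFrom cohort truth.
#' @param timepoints CPD maps to draw.
#' @param writeDir optional directory; when given, all exchange files
#'   (genome.fa, peaks.bed, dhs1/2.bed, motif.pfm, mutations.tsv,
#'   cpd_*.bed, truth.json) are written there.
#' @return list with all objects plus the planted `truth` parameters.
#' @export
simulateStudy <- function(seed = 1L, config = analysisConfig(),
                          nActive = 6000L, nInactive = 1000L,
                          spacing = 2100L, gc = 0.4, fidelity = 1,
                          depthPerWindow = 10000,
                          baseline = c(TT = 1, TC = 0.6, CT = 0.4,
                                       CC = 0.3),
                          survival = c(motif = 0.8, tfbs = 0.7,
                                       dhs_flank = 0.55, flank = 0.4),
                          backgroundSurvival = 1, damageMotif = 1,
                          spike = list(offset = -8L, strand = "+",
                                       factor = 2),
                          backgroundWeight = 220,
                          nSamples = 40L, mutsPerSample = 5000L,
                          ctFraction = 0.9,
                          mutationsFrom = c("48h", "0h"),
                          timepoints = c("naked", "0h", "48h"),
                          writeDir = NULL) {
  mutationsFrom <- match.arg(mutationsFrom)
  n <- nActive + nInactive
  genomeLength <- 2200L + as.integer(n) * as.integer(spacing)
  genome0 <- simulateGenome(genomeLength, gc = gc, seed = seed)
  motif <- syntheticMotif()
  imp <- implantSites(genome0, motif, nActive = nActive,
                      nInactive = nInactive, spacing = spacing,
                      fidelity = fidelity, seed = seed + 1L)
  cpd <- simulateCpdMaps(imp$genome, imp$sites, config,
                         depthPerWindow = depthPerWindow,
                         baseline = baseline, survival = survival,
                         backgroundSurvival = backgroundSurvival,
                         damageMotif = damageMotif, spike = spike,
                         backgroundWeight = backgroundWeight,
                         timepoints = timepoints, seed = seed + 10L)
  muts <- simulateMutationCohort(imp$genome, cpd$intensities,
                                 nSamples = nSamples,
                                 mutsPerSample = mutsPerSample,
                                 ctFraction = ctFraction,
                                 from = mutationsFrom, seed = seed + 20L)
  truth <- list(seed = seed, genomeLength = genomeLength, gc = gc,
                nActive = nActive, nInactive = nInactive,
                spacing = spacing, fidelity = fidelity,
                consensus = DEFAULT_CONSENSUS,
                depthPerWindow = depthPerWindow, depth = cpd$depth,
                baseline = as.list(baseline), survival = as.list(survival),
                backgroundSurvival = backgroundSurvival,
                damageMotif = damageMotif, spike = spike,
                backgroundWeight = backgroundWeight, nSamples = nSamples,
                mutsPerSample = mutsPerSample, ctFraction = ctFraction,
                mutationsFrom = mutationsFrom)
  study <- list(genome = imp$genome, motif = motif, sites = imp$sites,
                peaks = imp$peaks, dhs1 = imp$dhs1, dhs2 = imp$dhs2,
                maps = cpd$maps, intensities = cpd$intensities,
                mutations = muts, truth = truth, config = config)
  if (!is.null(writeDir)) writeStudy(study, writeDir)
  study
}

#' @rdname simulateStudy
#' @param study a study list from `simulateStudy()`.
#' @param dir output directory (created if needed).
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenome(study$genome, file.path(dir, "genome.fa"))
  writeBedIntervals(study$peaks, file.path(dir, "peaks.bed"))
  writeBedIntervals(study$dhs1, file.path(dir, "dhs1.bed"))
  writeBedIntervals(study$dhs2, file.path(dir, "dhs2.bed"))
  writeJasparPfm(study$motif, file.path(dir, "motif.pfm"))
  writeMutations(study$mutations, file.path(dir, "mutations.tsv"))
  for (tp in names(study$maps))
    writeCpdMap(study$maps[[tp]],
                file.path(dir, paste0("cpd_", tp, ".bed")))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Synthetic multi-motif panel with varied damage and repair truth
#'
#' Builds one genome holding `nMotifs` different random motifs, each
#' with its own planted TFBS damage multiplier `d` and TFBS survival
#' `s`, simulates a reference 0h/48h map pair, an independent target 0h
#' map from the same damage law, and a mutation cohort generated from
#' the 48h-surviving damage. Used to test that predicted-48h damage
#' tracks the mutation rate across motifs better than 0h damage does.
#'
#' @param nMotifs panel size (default 10).
#' @param sitesPerMotif active sites per motif (default 400).
#' @param damageRange,survivalRange uniform ranges the per-motif `d`
#'   and `s` are drawn from.
#' @param depthPerWindow expected 0h reads per window.
#' @param mutsPerSample,nSamples cohort shape.
#' @param config an [analysisConfig()].
#' @param seed RNG seed (drives motif sequences, truth draws, maps and
#'   cohort).
#' @param genome optional pre-built panel scaffold from a previous call
#'   (reuses `genome`, `sites`, motif assignment) so replicates resample
#'   only truth, maps and mutations.
#' @return list: `stacks` (per motif, with `mutations`, `cpd_ref0`,
#'   `cpd_ref48`, `cpd_target0` tracks), `truth`
#'   (`data.frame(motif_id, damage, survival)`), and the scaffold.
#' @export
simulatePanel <- function(nMotifs = 10L, sitesPerMotif = 200L,
                          damageRange = c(0.7, 1.6),
                          survivalRange = c(0.3, 0.9),
                          depthPerWindow = 2000, mutsPerSample = 3000L,
                          nSamples = 20L, config = analysisConfig(),
                          seed = 1L, genome = NULL) {
  if (is.null(genome)) {
    set.seed(seed)
    n <- nMotifs * sitesPerMotif
    spacing <- 2100L
    g <- simulateGenome(2200L + n * spacing, gc = 0.4, seed = seed)
    motifIdx <- rep(seq_len(nMotifs), sitesPerMotif)[sample.int(n)]
    consensi <- vapply(seq_len(nMotifs), function(i)
      paste(sample(BASES, 21L, replace = TRUE), collapse = ""),
      character(1))
    chr <- g[[1]]
    lead <- 1100L
    centers <- lead + (seq_len(n) - 1L) * spacing
    strand <- sample(c("+", "-"), n, replace = TRUE)
    inst <- Biostrings::DNAStringSet(consensi[motifIdx])
    minus <- strand == "-"
    inst[minus] <- Biostrings::reverseComplement(inst[minus])
    chr <- Biostrings::replaceAt(chr, IRanges::IRanges(centers - 10L,
                                                       width = 21L), inst)
    g <- Biostrings::DNAStringSet(stats::setNames(as.character(chr), "chr1"))
    sites <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(centers - 10L,
                                                     width = 21L),
                                    strand = strand)
    S4Vectors::mcols(sites)$motif_id <- paste0("SYN", motifIdx)
    S4Vectors::mcols(sites)$center <- centers
    S4Vectors::mcols(sites)$active <- TRUE
    ids <- paste0("SYN", seq_len(nMotifs))
    # cache the truth-independent parts: dipyrimidine/region table and
    # trackless per-motif stacks (replicates only redraw truth and reads)
    invBase <- .cpdIntensityTable(g, sites, config,
                                  baseline = c(TT = 1, TC = 0.6,
                                               CT = 0.4, CC = 0.3),
                                  survival = c(motif = 1, tfbs = 1,
                                               dhs_flank = 1, flank = 1),
                                  backgroundSurvival = 1, damageMotif = 1,
                                  spike = NULL, backgroundWeight = 1)
    stacks0 <- lapply(seq_len(nMotifs), function(m)
      buildWindowStack(sites[motifIdx == m], g, config, motifId = ids[m]))
    names(stacks0) <- ids
    scaffold <- list(genome = g, sites = sites, motifIdx = motifIdx,
                     consensi = consensi, nMotifs = nMotifs,
                     invBase = invBase, stacks0 = stacks0, ids = ids)
  } else scaffold <- genome
  set.seed(seed + 1L)
  d <- runif(scaffold$nMotifs, damageRange[1], damageRange[2])
  s <- runif(scaffold$nMotifs, survivalRange[1], survivalRange[2])
  nAct <- length(scaffold$sites)
  perSiteD <- d[scaffold$motifIdx]
  perSiteS <- s[scaffold$motifIdx]
  intens <- data.table::copy(scaffold$invBase)
  # damage multiplier over the whole TFBS; survival impairment likewise
  inTf <- intens$site > 0L & intens$region %in% c("motif", "tfbs")
  I0 <- intens$Inaked
  I0[inTf] <- I0[inTf] * perSiteD[intens$site[inTf]]
  sv <- rep(1, nrow(intens))
  sv[inTf] <- perSiteS[intens$site[inTf]]
  data.table::set(intens, j = "I0", value = I0)
  data.table::set(intens, j = "I48", value = I0 * sv)
  wFrac <- sum(intens$I0[intens$site > 0L]) / sum(intens$I0)
  depth <- round(depthPerWindow * nAct / wFrac)
  maps <- list(ref0 = .sampleCpdMap(intens, "I0", depth, "0h", seed + 2L),
               ref48 = .sampleCpdMap(intens, "I48", depth, "48h",
                                     seed + 3L),
               target0 = .sampleCpdMap(intens, "I0", depth, "0h",
                                       seed + 4L))
  muts <- simulateMutationCohort(scaffold$genome, intens,
                                 nSamples = nSamples,
                                 mutsPerSample = mutsPerSample,
                                 ctFraction = 0.95, from = "48h",
                                 seed = seed + 5L)
  ids <- scaffold$ids
  stacks <- lapply(scaffold$stacks0, function(st) {
    st <- mapEvents(st, muts, "mutations")
    st <- mapEvents(st, maps$ref0, "cpd_ref0")
    st <- mapEvents(st, maps$ref48, "cpd_ref48")
    mapEvents(st, maps$target0, "cpd_target0")
  })
  list(stacks = stacks,
       truth = data.frame(motif_id = ids, damage = d, survival = s),
       scaffold = scaffold)
}

#' Damage-vs-mutation correlation contrast on a panel
#'
#' Computes the across-motif Pearson correlation between the
#' TFBS-to-flanks mutation ratio and (a) the observed 0h damage ratio
#' and (b) the predicted-48h damage ratio ([predictCpds48h()] applied
#' to the target 0h profile using the reference 0h/48h pair).
#'
#' @param panel result of [simulatePanel()].
#' @param config an [analysisConfig()].
#' @return `list(r0, r48, n)`.
#' @export
panelCorrelationContrast <- function(panel, config = analysisConfig()) {
  prof0 <- lapply(panel$stacks, stackProfile, track = "cpd_target0")
  pred <- lapply(panel$stacks, function(st)
    predictCpds48h(stackProfile(st, "cpd_target0"),
                   stackProfile(st, "cpd_ref0"),
                   stackProfile(st, "cpd_ref48")))
  r0 <- correlateDamageMutation(panel$stacks, prof0, config)
  r48 <- correlateDamageMutation(panel$stacks, pred, config)
  list(r0 = r0$r, r48 = r48$r, n = r0$n)
}
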