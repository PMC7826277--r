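# End-to-end orchestration over exchange files: catalog -> stack ->
# background model -> region summaries -> repair -> within-motif, with a
# run manifest for reproducibility. Stage outputs are pure functions of
# (inputs, config, seed); re-running with the same inputs and seed
# reproduces byte-identical files.

.writeTsv <- function(dt, path, header) {
  con <- file(path, "w")
  writeLines(paste0("# ", header), con)
  writeLines("# coordinates: offsets are motif-oriented, 0 = motif center",
             con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' Run the full analysis over an input directory
#'
#' Expects the exchange files of a study in `inputDir`: `genome.fa`,
#' `peaks.bed`, one or more `dhs*.bed`, `motif.pfm` (one or more
#' motifs), `mutations.tsv`, and CPD maps `cpd_naked.bed`, `cpd_0h.bed`,
#' `cpd_48h.bed` (any subset). Writes to `outDir`: the binding-site
#' catalog, per-motif stack/repair/within-motif tables, the
#' substitution model, region summaries, the motif exclusion report and
#' a JSON run manifest.
#'
#' @param inputDir directory of input files (e.g. from
#'   [simulateStudy()]'s `writeDir`).
#' @param outDir output directory (created).
#' @param config an [analysisConfig()].
#' @param seed RNG seed for the within-motif sampling.
#' @param applyFilters apply the motif inclusion filters (default TRUE;
#'   disable for small fixtures).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(inputDir, outDir, config = analysisConfig(),
                        seed = 1L, applyFilters = TRUE) {
  stage <- "io"
  fail <- function(e) stop(sprintf("stage '%s' failed: %s", stage,
                                   conditionMessage(e)), call. = FALSE)
  tryCatch({
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      genome = file.path(inputDir, "genome.fa"),
      peaks = file.path(inputDir, "peaks.bed"),
      pfm = file.path(inputDir, "motif.pfm"),
      mutations = file.path(inputDir, "mutations.tsv"))
    for (p in paths) .check(file.exists(p), "missing input: %s", p)
    dhsFiles <- sort(Sys.glob(file.path(inputDir, "dhs*.bed")))
    .check(length(dhsFiles) >= 1L, "missing input: dhs*.bed")
    cpdFiles <- sort(Sys.glob(file.path(inputDir, "cpd_*.bed")))
    genome <- readGenome(paths$genome)
    peaks <- readBedIntervals(paths$peaks)
    dhsSets <- lapply(dhsFiles, readBedIntervals)
    motifs <- readJasparPfm(paths$pfm)
    mutations <- readMutations(paths$mutations, genome)
    cpds <- lapply(cpdFiles, function(f) {
      tp <- sub("^cpd_(.*)\\.bed$", "\\1", basename(f))
      readCpdMap(f, tp, genome)
    })
    names(cpds) <- vapply(cpds, function(x)
      S4Vectors::mcols(x)$timepoint[1], character(1))
    stage <- "repair"
    .check(all(c("0h", "48h") %in% names(cpds)),
           "missing CPD map for timepoint(s): %s",
           paste(setdiff(c("0h", "48h"), names(cpds)), collapse = ", "))
    stage <- "io"

    stage <- "catalog"
    bg <- genomeBackground(genome)
    siteSets <- lapply(motifs, function(m) {
      pwm <- buildPWM(m, pseudocount = config$pseudocount, background = bg)
      sites <- scanMotif(genome, peaks, pwm,
                         thresholdFraction = config$thresholdFraction)
      classifyActivity(sites, dhsSets)
    })
    catalog <- do.call(rbind, lapply(siteSets, function(s) data.frame(
      chrom = as.character(GenomicRanges::seqnames(s)),
      start = GenomicRanges::start(s) - 1L, end = GenomicRanges::end(s),
      motif_id = S4Vectors::mcols(s)$motif_id,
      score = round(S4Vectors::mcols(s)$score, 4),
      strand = as.character(GenomicRanges::strand(s)),
      center = S4Vectors::mcols(s)$center,
      active = S4Vectors::mcols(s)$active)))
    .writeTsv(catalog, file.path(outDir, "catalog.tsv"),
              "binding site catalog; start is 0-based, end exclusive")

    stage <- "cohort"
    coh <- filterCohort(mutations, config$ctFractionMin)
    .writeTsv(data.table::as.data.table(coh$report),
              file.path(outDir, "cohort_report.tsv"),
              "per-sample C>T filter report")

    stage <- "stack"
    stacks <- list()
    for (m in names(siteSets)) {
      st <- buildWindowStack(siteSets[[m]], genome, config, motifId = m)
      if (nSites(st) == 0L) next
      st <- mapEvents(st, coh$muts, "mutations")
      for (tp in names(cpds))
        st <- mapEvents(st, cpds[[tp]], paste0("cpd_", tp))
      stacks[[m]] <- st
    }
    .check(length(stacks) > 0L, "no motif produced any active site")
    flt <- filterMotifs(stacks, config)
    .writeTsv(data.table::as.data.table(flt$report),
              file.path(outDir, "motif_filter_report.tsv"),
              "motif inclusion filters")
    if (applyFilters) stacks <- flt$kept
    .check(length(stacks) > 0L, "no motif passed the inclusion filters")

    stage <- "expect"
    model <- fitSubstitutionModel(coh$muts, genome, k = config$k)
    .writeTsv(data.table::data.table(
      kmer = names(model@prob), genome_count = model@genomeCounts,
      mutation_count = model@mutationCounts, probability = model@prob),
      file.path(outDir, "substitution_model.tsv"),
      sprintf("pyrimidine-centered %d-mer substitution model", model@k))
    stacks <- lapply(stacks, expectedProfile, model = model)

    stage <- "report"
    genomeTotals <- lapply(cpds, function(x)
      sum(S4Vectors::mcols(x)$count))
    summaries <- list()
    for (st in stacks) {
      m <- st@motifId
      prof <- list(mutations = stackProfile(st, "mutations"))
      for (tr in setdiff(trackNames(st), "mutations"))
        prof[[tr]] <- stackProfile(st, tr)
      out <- data.table::data.table(
        offset = stackOffsets(st), region = as.character(regionMask(config)),
        n_windows = nSites(st), mutation_count = prof$mutations,
        expected_mutations = expectedMutations(st))
      for (tr in setdiff(names(prof), "mutations"))
        out[[tr]] <- prof[[tr]]
      .writeTsv(out, file.path(outDir, paste0("stack_", m, ".tsv")),
                sprintf("per-offset stack of %d windows", nSites(st)))
      summaries[[paste0(m, ".mut")]] <- summarizeRegions(
        prof$mutations, expectedMutations(st), config,
        metric = "mutations", motifId = m)
      if (!is.null(prof$cpd_0h) && !is.null(prof$cpd_naked))
        summaries[[paste0(m, ".dmg")]] <- cbind(
          motif_id = m, metric = "cpd0_vs_naked",
          damageVsNakedSummary(prof$cpd_0h, prof$cpd_naked, config))
      if (!is.null(prof$cpd_0h) && !is.null(prof$cpd_48h)) {
        stage <- "repair"
        rp <- relativeRepairProfile(prof$cpd_0h, prof$cpd_48h, "window")
        .writeTsv(data.table::as.data.table(rp),
                  file.path(outDir, paste0("repair_", m, ".tsv")),
                  "relative repair profile (window-normalised)")
        rpG <- relativeRepairProfile(prof$cpd_0h, prof$cpd_48h, "genome",
                                     genomeTotals = c(genomeTotals$`0h`,
                                                      genomeTotals$`48h`))
        for (ref in c("flank", "dhs_flank"))
          summaries[[paste0(m, ".rep.", ref)]] <- cbind(
            motif_id = m, metric = paste0("repair_vs_", ref),
            regionRepairRatio(rpG, config, ref, prof$cpd_0h, prof$cpd_48h))
        stage <- "within_motif"
        wm <- withinMotifSummary(
          st, tracks = intersect(trackNames(st),
                                 c("mutations", "cpd_0h", "cpd_48h")),
          seed = seed,
          genomeTotals = list(cpd_0h = genomeTotals$`0h`,
                              cpd_48h = genomeTotals$`48h`))
        .writeTsv(data.table::as.data.table(wm),
                  file.path(outDir, paste0("within_motif_", m, ".tsv")),
                  sprintf("within-motif dipyrimidine analysis, seed %d",
                          seed))
        stage <- "report"
      }
    }
    regionSummary <- data.table::rbindlist(summaries, fill = TRUE)
    .writeTsv(regionSummary, file.path(outDir, "region_summary.tsv"),
              "per-region observed/expected summaries")

    stage <- "manifest"
    manifest <- list(
      config = unclass(config), seed = seed,
      inputs = as.list(tools::md5sum(c(unlist(paths), dhsFiles, cpdFiles))),
      n_sites = vapply(stacks, nSites, integer(1)),
      n_samples_kept = sum(coh$report$kept),
      motifs_kept = names(stacks),
      exclusions = flt$report$motif_id[!flt$report$kept])
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
  }, error = fail)
}
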