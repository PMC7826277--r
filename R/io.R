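# Readers and writers for the exchange formats. All files use standard
# public conventions: FASTA; BED (0-based, half-open); JASPAR PFM text;
# a 1-based mutations TSV; and a BED-like CPD map. Internally everything
# is carried in 1-based GRanges/IRanges coordinates, so each reader is
# the single conversion point for its format.

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and any character outside A,C,G,T,N is
#' replaced by N (with a warning giving the replacement count).
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readGenome <- function(path) {
  .check(file.exists(path), "no such file: %s", path)
  set <- Biostrings::readBStringSet(path)
  .check(length(set) > 0L, "empty FASTA: %s", path)
  nms <- sub("\\s.*$", "", names(set))
  .check(!anyDuplicated(nms), "duplicate FASTA header in %s", path)
  names(set) <- nms
  .check(all(Biostrings::width(set) >= 1L), "zero-length sequence in %s", path)
  chr <- toupper(as.character(set))
  bad <- vapply(chr, function(s)
    sum(strsplit(s, "")[[1]] %in% c(BASES, "N") == FALSE), integer(1))
  if (sum(bad) > 0L) {
    warning(sprintf("%d non-ACGTN characters mapped to N", sum(bad)))
    chr <- vapply(chr, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  Biostrings::DNAStringSet(stats::setNames(chr, nms))
}

#' Write a genome to FASTA
#' @param genome a `DNAStringSet`.
#' @param path output file.
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' BED3/BED6, 0-based half-open on disk; returned as 1-based closed
#' `GRanges` preserving input order. Column 6 is used as strand when
#' present; otherwise strand is `*`.
#'
#' @param path BED file.
#' @return A [GenomicRanges::GRanges] with `name` and `score` metadata
#'   columns when the file has them.
#' @export
readBedIntervals <- function(path) {
  .check(file.exists(path), "no such file: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  .check(ncol(dt) >= 3L, "BED needs >= 3 columns: %s", path)
  start0 <- as.numeric(dt[[2]]); end0 <- as.numeric(dt[[3]])
  bad <- which(start0 >= end0)
  .check(length(bad) == 0L, "start >= end at line %s of %s",
         paste(head(bad, 5L), collapse = ","), path)
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6]]) else rep(".", nrow(dt))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(dt[[1]],
                               IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  if (ncol(dt) >= 4L) S4Vectors::mcols(gr)$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5L) S4Vectors::mcols(gr)$score <- as.numeric(dt[[5]])
  gr
}

#' Write intervals to BED6
#' @param gr a `GRanges`; `name`/`score` metadata columns are used when
#'   present.
#' @param path output file.
#' @export
writeBedIntervals <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  name <- if ("name" %in% names(mc)) mc$name else rep(".", length(gr))
  score <- if ("score" %in% names(mc)) mc$score else rep(0, length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = name, score = score, strand = strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses JASPAR text (one or more motifs; `>` header then four rows
#' `A [ ... ]` ... `T [ ... ]`, brackets optional). The optional second
#' and third header tokens are taken as TF name and family.
#'
#' @param path JASPAR PFM text file.
#' @return Named list of [MotifMatrix] objects.
#' @export
readJasparPfm <- function(path) {
  .check(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  .check(length(lines) > 0L, "empty PFM file: %s", path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) { lines <- c(">motif", lines); hdr <- 1L }
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    .check(length(block) == 4L, "motif block must have 4 rows in %s", path)
    toks <- strsplit(trimws(sub("^>", "", lines[hdr[i]])), "\\s+")[[1]]
    id <- toks[1]
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGT]\\s*", "", trimws(l))
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    lens <- lengths(rows)
    .check(length(unique(lens)) == 1L,
           "unequal PFM row lengths (%s) in %s", paste(lens, collapse = ","),
           path)
    counts <- do.call(rbind, rows)
    rownames(counts) <- BASES
    .check(all(colSums(counts) > 0),
           "all-zero (uninformative) PFM column in %s", path)
    out[[id]] <- MotifMatrix(id, counts,
                             tfName = if (length(toks) >= 2) toks[2] else id,
                             tfFamily = if (length(toks) >= 3) toks[3] else "")
  }
  out
}

#' @rdname readJasparPfm
#' @param motif a [MotifMatrix].
#' @param path output file.
#' @param append append to an existing file (default FALSE).
#' @export
writeJasparPfm <- function(motif, path, append = FALSE) {
  cnt <- motifCounts(motif)
  lines <- c(paste0(">", paste(c(motifId(motif), motif@tfName,
                                 if (nzchar(motif@tfFamily))
                                   motif@tfFamily), collapse = " ")),
             vapply(BASES, function(b)
               sprintf("%s  [ %s ]", b,
                       paste(format(cnt[b, ], trim = TRUE),
                             collapse = "  ")), character(1)))
  cat(lines, file = path, sep = "\n", append = append)
  invisible(path)
}

#' Read a somatic SNV cohort
#'
#' Accepts the tab-separated cohort format (header
#' `sample chrom pos ref alt`, 1-based positions) or a VCF (SNVs only;
#' INFO/FORMAT ignored; the sample label is the file stem). Indel rows
#' are skipped with a warning. When `genome` is supplied every `ref`
#' is checked against the reference base.
#'
#' @param path mutations TSV or `.vcf` file.
#' @param genome optional `DNAStringSet` for reference checking.
#' @return A `GRanges` (width 1, 1-based) with metadata columns
#'   `sample`, `ref`, `alt`.
#' @export
readMutations <- function(path, genome = NULL) {
  .check(file.exists(path), "no such file: %s", path)
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    dt <- data.table::fread(path, skip = "#CHROM", sep = "\t",
                            header = TRUE, colClasses = list(character = 1))
    dt <- data.table::data.table(
      sample = rep(sub("\\.vcf$", "", basename(path), ignore.case = TRUE),
                   nrow(dt)),
      chrom = dt[[1]], pos = as.integer(dt[[2]]),
      ref = as.character(dt[[4]]), alt = as.character(dt[[5]]))
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = c(1, 2)))
    .check(all(c("sample", "chrom", "pos", "ref", "alt") %in% names(dt)),
           "mutations TSV must have columns sample chrom pos ref alt: %s",
           path)
  }
  indel <- nchar(dt$ref) != 1L | nchar(dt$alt) != 1L |
    !(dt$ref %in% BASES) | !(dt$alt %in% BASES)
  if (any(indel)) {
    warning(sprintf("skipped %d non-SNV records", sum(indel)))
    dt <- dt[!indel, ]
  }
  .check(!any(dt$ref == dt$alt), "ref == alt in %s", path)
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
  S4Vectors::mcols(gr)$sample <- dt$sample
  S4Vectors::mcols(gr)$ref <- dt$ref
  S4Vectors::mcols(gr)$alt <- dt$alt
  if (!is.null(genome)) {
    obs <- as.character(.getSeqs(genome, gr))
    bad <- which(obs != dt$ref)
    .check(length(bad) == 0L,
           "ref does not match genome for %d records (first rows: %s)",
           length(bad), paste(head(bad, 5L), collapse = ","))
  }
  gr
}

#' Write a mutation cohort to the 1-based TSV format
#' @param muts mutations `GRanges` as returned by [readMutations()].
#' @param path output file.
#' @export
writeMutations <- function(muts, path) {
  dt <- data.table::data.table(
    sample = S4Vectors::mcols(muts)$sample,
    chrom = as.character(GenomicRanges::seqnames(muts)),
    pos = GenomicRanges::start(muts),
    ref = S4Vectors::mcols(muts)$ref,
    alt = S4Vectors::mcols(muts)$alt)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a single-nucleotide CPD map
#'
#' BED-like file: `chrom  start  end  count  strand`, where `start` is
#' the 0-based position of the leftmost (reference-strand) base of the
#' dipyrimidine and `end = start + 1`. Records are returned anchored at
#' that base (1-based, width 1). When `genome` is supplied, records
#' whose two bases are not pyrimidines read on `strand` are dropped and
#' the drop count is attached as `attr(, "nDropped")` (and warned).
#'
#' @param path CPD map file.
#' @param timepoint label such as `"0h"`, `"48h"`, `"naked"`.
#' @param genome optional `DNAStringSet` for dipyrimidine validation.
#' @return `GRanges` with metadata columns `count` and `timepoint`.
#' @export
readCpdMap <- function(path, timepoint, genome = NULL) {
  .check(file.exists(path), "no such file: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  .check(ncol(dt) >= 5L, "CPD map needs 5 columns: %s", path)
  count <- as.numeric(dt[[4]])
  .check(all(count >= 0), "negative CPD count in %s", path)
  gr <- GenomicRanges::GRanges(dt[[1]],
                               IRanges::IRanges(as.numeric(dt[[2]]) + 1,
                                                width = 1),
                               strand = as.character(dt[[5]]))
  S4Vectors::mcols(gr)$count <- count
  S4Vectors::mcols(gr)$timepoint <- timepoint
  nDropped <- 0L
  if (!is.null(genome)) {
    pair <- GenomicRanges::resize(gr, 2L, fix = "start", ignore.strand = TRUE)
    inside <- GenomicRanges::end(pair) <=
      Biostrings::width(genome)[match(as.character(GenomicRanges::seqnames(pair)),
                                      names(genome))]
    pairU <- GenomicRanges::granges(pair, use.names = FALSE)
    GenomicRanges::strand(pairU) <- "*"   # plus-strand letters; strand handled below
    two <- rep(NA_character_, length(gr))
    two[inside] <- as.character(.getSeqs(genome, pairU[inside]))
    plus <- as.character(GenomicRanges::strand(gr)) == "+"
    ok <- inside & ifelse(plus, grepl("^[CT][CT]$", two),
                          grepl("^[AG][AG]$", two))
    nDropped <- sum(!ok)
    if (nDropped > 0L)
      warning(sprintf("dropped %d CPD records failing the dipyrimidine check",
                      nDropped))
    gr <- gr[ok]
  }
  attr(gr, "nDropped") <- nDropped
  gr
}

#' Write a CPD map to the BED-like exchange format
#' @param cpds CPD `GRanges` as returned by [readCpdMap()].
#' @param path output file.
#' @export
writeCpdMap <- function(cpds, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(cpds)),
    start = GenomicRanges::start(cpds) - 1L,
    end = GenomicRanges::start(cpds),
    count = S4Vectors::mcols(cpds)$count,
    strand = as.character(GenomicRanges::strand(cpds)))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
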