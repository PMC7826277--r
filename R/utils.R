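# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Integer coding A=1 C=2 G=3 T=4, anything else NA.
.codeChars <- function(x) match(x, BASES)

# Complement in code space (A<->T, C<->G).
.compCode <- function(code) 5L - code

# Dipyrimidine type read 5'->3' on `strand` for pairs of plus-strand codes
# (c1, c2) at increasing genomic position (pyrimidine codes: C=2, T=4).
# Vectorised; returns NA where either base is not a pyrimidine on `strand`.
.dipyrType <- function(c1, c2, strand) {
  isPyr <- function(x) !is.na(x) & (x == 2L | x == 4L)
  isPur <- function(x) !is.na(x) & (x == 1L | x == 3L)
  out <- rep(NA_character_, length(c1))
  if (strand == "+") {
    ok <- isPyr(c1) & isPyr(c2)
    out[ok] <- paste0(BASES[c1[ok]], BASES[c2[ok]])
  } else {
    ok <- isPur(c1) & isPur(c2)
    out[ok] <- paste0(BASES[5L - c2[ok]], BASES[5L - c1[ok]])
  }
  out
}

# Convert an equal-width DNAStringSet to an integer code matrix, chunked to
# bound transient memory.
.codeMatrix <- function(seqs, chunk = 1000L) {
  n <- length(seqs)
  w <- unique(Biostrings::width(seqs))
  stopifnot(length(w) == 1L)
  out <- matrix(NA_integer_, nrow = n, ncol = w)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    m <- as.matrix(seqs[i:j])
    out[i:j, ] <- match(m, BASES)
    i <- j + 1L
  }
  out
}

# k-mer integer codes (1 .. 4^k) for every window position, given a code
# matrix and the columns holding the k-mer centers. NA where any base is NA.
.kmerCodes <- function(codes, centerCols, k) {
  flank <- (k - 1L) %/% 2L
  idx <- matrix(0L, nrow = nrow(codes), ncol = length(centerCols))
  ok <- matrix(TRUE, nrow = nrow(codes), ncol = length(centerCols))
  for (j in seq_len(k)) {
    cc <- codes[, centerCols + (j - flank - 1L), drop = FALSE]
    ok <- ok & !is.na(cc)
    cc[is.na(cc)] <- 1L
    idx <- idx + (cc - 1L) * 4L^(k - j)
  }
  idx <- idx + 1L
  idx[!ok] <- NA_integer_
  idx
}

# All k-mer strings in code order (code 1 = AA..A).
.allKmers <- function(k) {
  g <- do.call(expand.grid, rep(list(BASES), k))[, k:1, drop = FALSE]
  do.call(paste0, g)
}

# Reverse complement of k-mer strings.
.revcompKmers <- function(kmers) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
}

# Centered moving average with shrinking windows at the edges.
.movingAverage <- function(x, bw) {
  if (bw <= 1L) return(x)
  half <- bw %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Extract plus-strand sequences at GRanges positions from a DNAStringSet
# genome, preserving query order.
.getSeqs <- function(genome, gr) {
  out <- Biostrings::DNAStringSet(rep("", length(gr)))
  for (ch in unique(as.character(GenomicRanges::seqnames(gr)))) {
    idx <- which(as.character(GenomicRanges::seqnames(gr)) == ch)
    out[idx] <- Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(GenomicRanges::start(gr)[idx],
                                     GenomicRanges::end(gr)[idx]))
  }
  out
}

# stopifnot with a formatted message.
.check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
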