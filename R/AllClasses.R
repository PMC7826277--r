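#' @import methods
#' @importFrom stats median pchisq cor setNames rmultinom rpois runif
#' @importFrom utils head tail
NULL

#' Position frequency matrix for one binding motif
#'
#' Holds the 4 x L count matrix (rows A, C, G, T) describing one binding
#' motif of one transcription factor, together with identifying labels.
#'
#' @slot motifId character(1), e.g. a JASPAR accession.
#' @slot tfName character(1) transcription factor name.
#' @slot tfFamily character(1) structural family label (may be `""`).
#' @slot counts 4 x L non-negative numeric matrix, rownames A,C,G,T;
#'   every column must have a positive sum and L >= 4.
#'
#' @examples
#' m <- MotifMatrix("M1", counts = matrix(c(10, 0, 0, 0), 4, 5,
#'   dimnames = list(c("A", "C", "G", "T"), NULL)) + 1)
#' motifLength(m)
#' @export
setClass("MotifMatrix",
  representation(motifId = "character", tfName = "character",
                 tfFamily = "character", counts = "matrix"),
  validity = function(object) {
    cnt <- object@counts
    if (!is.numeric(cnt) || nrow(cnt) != 4L)
      return("counts must be a numeric 4 x L matrix (rows A,C,G,T)")
    if (!identical(rownames(cnt), BASES))
      return("counts rownames must be A, C, G, T")
    if (ncol(cnt) < 4L) return("motif length must be >= 4")
    if (any(cnt < 0)) return("counts must be non-negative")
    if (any(colSums(cnt) <= 0)) return("every column sum must be > 0")
    TRUE
  })

#' @rdname MotifMatrix-class
#' @param motifId,tfName,tfFamily identifying labels.
#' @param counts 4 x L count matrix.
#' @export
MotifMatrix <- function(motifId, counts, tfName = motifId, tfFamily = "") {
  if (is.null(rownames(counts))) rownames(counts) <- BASES
  new("MotifMatrix", motifId = motifId, tfName = tfName,
      tfFamily = tfFamily, counts = counts)
}

#' @rdname MotifMatrix-class
#' @param x a `MotifMatrix` or `MotifPWM`.
#' @export
motifLength <- function(x) ncol(if (is(x, "MotifMatrix")) x@counts else x@logOdds)

#' @rdname MotifMatrix-class
#' @export
motifCounts <- function(x) x@counts

#' @rdname MotifMatrix-class
#' @export
motifId <- function(x) x@motifId

#' @rdname MotifMatrix-class
#' @export
tfFamily <- function(x) x@tfFamily

setMethod("show", "MotifMatrix", function(object) {
  cat("MotifMatrix", object@motifId, "(", object@tfName, ")",
      "length", ncol(object@counts), "\n")
})

#' Log-odds position weight matrix
#'
#' MOODS-style log2-odds matrix derived from a [MotifMatrix] by
#' [buildPWM()]. The score of a sequence is the sum of per-position
#' entries; `pwmMaxScore()` gives the consensus score.
#'
#' @slot motifId character(1).
#' @slot logOdds 4 x L numeric matrix of log2 odds.
#' @slot background length-4 base composition used as reference.
#' @slot pseudocount positive scalar used for smoothing.
#' @export
setClass("MotifPWM",
  representation(motifId = "character", logOdds = "matrix",
                 background = "numeric", pseudocount = "numeric"),
  validity = function(object) {
    if (nrow(object@logOdds) != 4L) return("logOdds must have 4 rows")
    if (length(object@background) != 4L) return("background must have 4 entries")
    if (any(object@background <= 0)) return("background entries must be > 0")
    if (abs(sum(object@background) - 1) > 1e-8)
      return("background must sum to 1")
    if (object@pseudocount <= 0) return("pseudocount must be > 0")
    TRUE
  })

setMethod("show", "MotifPWM", function(object) {
  cat("MotifPWM", object@motifId, "length", ncol(object@logOdds),
      sprintf("max score %.2f bits\n", pwmMaxScore(object)))
})

#' k-mer substitution background model
#'
#' Pyrimidine-centered k-mer mutability table: for every k-mer with a C or
#' T center, the number of cohort mutations observed at genomic occurrences
#' of that k-mer divided by the number of occurrences (each genomic
#' position counted once, on its pyrimidine-bearing strand).
#'
#' @slot k 3 or 5.
#' @slot prob named numeric, mutability per pyrimidine-centered k-mer.
#' @slot genomeCounts named numeric, genome occurrences per k-mer.
#' @slot mutationCounts named numeric, cohort mutations per k-mer.
#' @export
setClass("SubstitutionModel",
  representation(k = "integer", prob = "numeric", genomeCounts = "numeric",
                 mutationCounts = "numeric"),
  validity = function(object) {
    if (!object@k %in% c(3L, 5L)) return("k must be 3 or 5")
    if (any(object@prob < 0)) return("probabilities must be >= 0")
    ctr <- substr(names(object@prob), (object@k + 1L) %/% 2L,
                  (object@k + 1L) %/% 2L)
    if (!all(ctr %in% c("C", "T")))
      return("all k-mer keys must have a pyrimidine center")
    TRUE
  })

setMethod("show", "SubstitutionModel", function(object) {
  cat(sprintf("SubstitutionModel k=%d, %d contexts, %g mutations\n",
              object@k, length(object@prob), sum(object@mutationCounts)))
})

#' Stacked, oriented windows around the binding sites of one motif
#'
#' All 2001-bp windows centered on the (active) instances of one binding
#' motif, oriented so the motif strand reads left to right. Per-window,
#' per-offset event counts are held as sparse matrices: a `mutations`
#' track plus strand-resolved CPD tracks per timepoint. Window sequences
#' are stored with a 2-base margin so that pentanucleotide contexts and
#' tetranucleotide flank matching are defined at every offset.
#'
#' @slot motifId character(1).
#' @slot config the [analysisConfig()] list in force.
#' @slot windows `GRanges` of the 2001-bp windows; `mcols()` carry
#'   `center` (genomic position of the motif center) and `siteStrand`.
#' @slot seqs `DNAStringSet` of oriented window sequences (width 2005).
#' @slot tracks named list; each mutation-like track is an
#'   nSites x 2001 `dgCMatrix`; each CPD track is a list with `plus` and
#'   `minus` matrices (strand relative to motif orientation), counts
#'   anchored at the smaller oriented offset of the dipyrimidine.
#' @slot expected per-offset expected mutation counts (length 2001, or
#'   length 0 before [expectedProfile()] is run).
#' @slot nDiscarded windows dropped for crossing a chromosome end.
#' @slot cache environment memoising the sequence code matrix.
#' @export
setClass("WindowStack",
  representation(motifId = "character", config = "list", windows = "GRanges",
                 seqs = "DNAStringSet", tracks = "list", expected = "numeric",
                 nDiscarded = "integer", cache = "environment"),
  validity = function(object) {
    if (length(object@seqs) != length(object@windows))
      return("seqs and windows lengths differ")
    w <- 2L * object@config$halfWidth + 1L + 4L
    if (length(object@seqs) && any(Biostrings::width(object@seqs) != w))
      return(sprintf("window sequences must all have width %d", w))
    TRUE
  })

setMethod("show", "WindowStack", function(object) {
  cat("WindowStack", object@motifId, ":", length(object@windows), "sites,",
      "tracks:", paste(names(object@tracks), collapse = ", "), "\n")
})

#' @rdname WindowStack-class
#' @param stack a `WindowStack`.
#' @export
nSites <- function(stack) length(stack@windows)

#' @rdname WindowStack-class
#' @export
trackNames <- function(stack) names(stack@tracks)

#' @rdname WindowStack-class
#' @export
stackConfig <- function(stack) stack@config

# Memoised integer code matrix of the oriented window sequences.
.stackCodes <- function(stack) {
  if (is.null(stack@cache$codes))
    stack@cache$codes <- .codeMatrix(stack@seqs)
  stack@cache$codes
}
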