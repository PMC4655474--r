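#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Aligned binding sites for one transcription factor
#'
#' Holds the aligned, equal-length binding-site sequences that form the
#' positive training set for one TF. Sequences are strictly over
#' \{A,C,G,T\}; ambiguity codes are rejected because every position must
#' map to exactly one single-base feature.
#'
#' @slot tfName name of the transcription factor.
#' @slot sequences a [Biostrings::DNAStringSet] of identical width.
#'
#' @seealso [readSites()], [buildPWM()]
#' @export
setClass("BindingSiteSet",
  representation(tfName = "character", sequences = "DNAStringSet"))

setValidity("BindingSiteSet", function(object) {
  s <- object@sequences
  if (length(s) < 2L) return("need at least 2 binding sequences")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1L])[1L]
    return(sprintf("length mismatch: record %d has width %d, expected %d",
                   bad, w[bad], w[1L]))
  }
  if (w[1L] < 2L) return("motif width must be >= 2")
  freq <- Biostrings::alphabetFrequency(s, collapse = TRUE)
  if (sum(freq[DNA_BASES4]) != sum(freq)) {
    return("sequences must contain only A, C, G, T")
  }
  TRUE
})

#' @describeIn BindingSiteSet constructor from a character vector or
#'   `DNAStringSet`.
#' @param sequences character vector or `DNAStringSet` of aligned sites.
#' @param tfName TF name used in reports.
#' @export
BindingSiteSet <- function(sequences, tfName = "TF") {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  new("BindingSiteSet", tfName = tfName, sequences = sequences)
}

#' @describeIn BindingSiteSet number of sites.
#' @param x,object a `BindingSiteSet`.
#' @export
setMethod("length", "BindingSiteSet", function(x) length(x@sequences))

#' Motif width of an object
#'
#' @param x an object with a motif width (binding-site set, PWM, model...).
#' @return integer motif width L.
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))

#' @rdname motifWidth
#' @export
setMethod("motifWidth", "BindingSiteSet",
          function(x) Biostrings::width(x@sequences)[1L])

#' Sequences as a plain character vector
#' @param x an object holding sequences.
#' @export
setGeneric("siteSequences", function(x) standardGeneric("siteSequences"))

#' @rdname siteSequences
#' @export
setMethod("siteSequences", "BindingSiteSet",
          function(x) unname(as.character(x@sequences)))

#' @rdname BindingSiteSet
#' @export
setGeneric("tfName", function(object) standardGeneric("tfName"))

#' @rdname BindingSiteSet
#' @export
setMethod("tfName", "BindingSiteSet", function(object) object@tfName)

setMethod("show", "BindingSiteSet", function(object) {
  cat(sprintf("BindingSiteSet '%s': %d sites of width %d\n",
              object@tfName, length(object), motifWidth(object)))
})

#' Genome sequence used for scanning and background estimation
#'
#' A single nucleotide sequence over \{A,C,G,T,N\}. Multi-record FASTA
#' files are concatenated with a single `N` separator so that no scanning
#' window can span two records (windows containing `N` are never scored);
#' the original record boundaries are kept for coordinate mapping.
#'
#' @slot id genome identifier.
#' @slot sequence the (possibly concatenated) sequence, character scalar.
#' @slot topology `"linear"` or `"circular"` (annotation only; scanning
#'   treats the sequence linearly).
#' @slot records data.frame with columns `name`, `start`, `end` (1-based,
#'   in concatenated coordinates).
#' @seealso [readGenome()], [scanGenome()]
#' @export
setClass("GenomeSeq",
  representation(id = "character", sequence = "character",
                 topology = "character", records = "data.frame"))

setValidity("GenomeSeq", function(object) {
  if (!object@topology %in% c("linear", "circular")) {
    return("topology must be 'linear' or 'circular'")
  }
  if (nchar(object@sequence) < 2L) return("genome too short")
  if (grepl("[^ACGTN]", object@sequence)) {
    return("genome may contain only A, C, G, T, N")
  }
  TRUE
})

#' @describeIn GenomeSeq constructor from a character scalar.
#' @param sequence genome sequence (character scalar, A/C/G/T/N).
#' @param id genome identifier.
#' @param topology `"linear"` or `"circular"`.
#' @export
GenomeSeq <- function(sequence, id = "genome", topology = "linear") {
  sequence <- toupper(sequence)
  new("GenomeSeq", id = id, sequence = sequence, topology = topology,
      records = data.frame(name = id, start = 1L,
                           end = nchar(sequence),
                           stringsAsFactors = FALSE))
}

#' @describeIn GenomeSeq genome length in bases.
#' @param x,object a `GenomeSeq`.
#' @export
setMethod("length", "GenomeSeq", function(x) nchar(x@sequence))

#' @rdname GenomeSeq
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname GenomeSeq
#' @export
setMethod("genomeSequence", "GenomeSeq", function(x) x@sequence)

setMethod("show", "GenomeSeq", function(object) {
  cat(sprintf("GenomeSeq '%s': %s bp (%s), %d record(s)\n", object@id,
              format(length(object), big.mark = ","), object@topology,
              nrow(object@records)))
})

#' Position probability matrix of a binding motif
#'
#' Row `p` holds the probabilities of A, C, G, T at motif position `p`,
#' estimated from site counts with an additive pseudocount.
#'
#' @slot probs L x 4 matrix, rows summing to 1, columns A,C,G,T.
#' @slot pseudocount the pseudocount used at construction.
#' @seealso [buildPWM()], [scoreWindow()], [informationContent()]
#' @export
setClass("MotifPWM",
  representation(probs = "matrix", pseudocount = "numeric"))

setValidity("MotifPWM", function(object) {
  p <- object@probs
  if (ncol(p) != 4L) return("probs must have 4 columns (A,C,G,T)")
  if (any(p < 0)) return("probabilities must be nonnegative")
  if (any(abs(rowSums(p) - 1) > 1e-12)) return("rows must sum to 1")
  if (object@pseudocount > 0 && any(p == 0)) {
    return("zero probability despite positive pseudocount")
  }
  TRUE
})

#' @rdname motifWidth
#' @export
setMethod("motifWidth", "MotifPWM", function(x) nrow(x@probs))

#' @describeIn MotifPWM probability matrix accessor.
#' @param object a `MotifPWM`.
#' @export
setGeneric("pwmProbs", function(object) standardGeneric("pwmProbs"))

#' @rdname MotifPWM
#' @export
setMethod("pwmProbs", "MotifPWM", function(object) object@probs)

setMethod("show", "MotifPWM", function(object) {
  ic <- informationContent(object)
  cat(sprintf("MotifPWM: width %d, %.3f bits/position (pseudocount %g)\n",
              motifWidth(object), ic$widthNormalized, object@pseudocount))
})

#' First-order Markov background model of a genome
#'
#' Mononucleotide initial distribution plus a 4 x 4 transition matrix
#' P(next | current), Laplace-smoothed, estimated from all adjacent non-N
#' base pairs of the scanned strand. The background probability of a
#' window w is `initial(w1) * prod transition(w_p | w_{p-1})`.
#'
#' @slot initial length-4 probability vector (A,C,G,T).
#' @slot transition 4 x 4 row-stochastic matrix.
#' @seealso [estimateBackground()], [scoreWindow()]
#' @export
setClass("MarkovBackground",
  representation(initial = "numeric", transition = "matrix"))

setValidity("MarkovBackground", function(object) {
  if (length(object@initial) != 4L) return("initial must have 4 entries")
  if (abs(sum(object@initial) - 1) > 1e-9) return("initial must sum to 1")
  if (any(object@initial <= 0)) return("initial must be positive (smoothed)")
  tr <- object@transition
  if (!all(dim(tr) == c(4L, 4L))) return("transition must be 4x4")
  if (any(abs(rowSums(tr) - 1) > 1e-9)) return("transition rows must sum to 1")
  if (any(tr <= 0)) return("transition entries must be positive (smoothed)")
  TRUE
})

setMethod("show", "MarkovBackground", function(object) {
  cat("MarkovBackground (first-order)\n initial:",
      sprintf("%.3f", object@initial), "\n")
})
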