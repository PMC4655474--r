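## Table of sum-to-zero dummy codes: base -> (Z_n, Z_n+1, Z_n+2)
DUMMY_CODES <- matrix(c(1, 0, 0,
                        0, 1, 0,
                        0, 0, 1,
                        -1, -1, -1),
                      nrow = 4L, byrow = TRUE,
                      dimnames = list(DNA_BASES4, NULL))

#' Dummy-code a sequence into 3L coded single-base features
#'
#' Each position contributes three coded features: A maps to (1,0,0),
#' C to (0,1,0), G to (0,0,1) and T to (-1,-1,-1), laid out at
#' `n = 3(p-1)+1`. The coding is a bijection, so the sequence can be
#' recovered from its code.
#'
#' @param sequence DNA string (A/C/G/T) of the motif width, or a character
#'   vector of such strings.
#' @return numeric vector of length 3L (or an n x 3L matrix for a vector
#'   input) with names/colnames `Z1..Z3L`.
#' @export
dummyCode <- function(sequence) {
  m <- seqMatrix(sequence)
  if (anyNA(m)) stop("sequence must contain only A, C, G, T")
  L <- ncol(m)
  out <- matrix(0, nrow = nrow(m), ncol = 3L * L)
  for (p in seq_len(L)) {
    out[, (3L * (p - 1L) + 1L):(3L * p)] <- DUMMY_CODES[m[, p], , drop = FALSE]
  }
  colnames(out) <- paste0("Z", seq_len(3L * L))
  if (length(sequence) == 1L) out[1L, ] else out
}

#' Invert the dummy coding
#'
#' @param z numeric vector of length 3L as produced by [dummyCode()].
#' @return the DNA string.
#' @export
dummyDecode <- function(z) {
  L <- length(z) / 3L
  stopifnot(L == as.integer(L))
  v <- vapply(seq_len(L), function(p) {
    trip <- z[(3L * (p - 1L) + 1L):(3L * p)]
    hit <- which(apply(DUMMY_CODES, 1L, function(r) all(r == trip)))
    if (!length(hit)) stop("invalid dummy code at position ", p)
    hit
  }, integer(1))
  intToDna(v)
}

#' Binary-code the association features of a sequence
#'
#' `a_j = 1` iff every member single-base feature of association feature j
#' is present in the sequence.
#'
#' @param sequence DNA string(s) of the motif width.
#' @param features data.frame from [integrateFeatures()].
#' @return binary vector of length K (or n x K matrix), named by feature id.
#' @export
associationCode <- function(sequence, features) {
  m <- seqMatrix(sequence)
  K <- nrow(features)
  out <- matrix(0, nrow = nrow(m), ncol = K)
  for (j in seq_len(K)) {
    codes <- features$items[[j]]
    pos <- itemPosition(codes)
    if (any(pos > ncol(m))) stop("feature position beyond sequence length")
    base <- itemBase(codes)
    hit <- m[, pos, drop = FALSE] == rep(base, each = nrow(m))
    out[, j] <- as.numeric(.rowAll(hit))
  }
  colnames(out) <- features$id
  if (length(sequence) == 1L) out[1L, ] else out
}

.sampleUnique <- function(pool, k, seed, what) {
  pool <- unique(pool)
  if (length(pool) < k) {
    warning(sprintf("%s pool supplies only %d of %d requested sequences",
                    what, length(pool), k))
    k <- length(pool)
  }
  if (!k) return(character(0))
  withSeed(seed, sample(pool, k))
}

#' Negative sequences from column-permuted PWM scans
#'
#' Scans the genome with a column-permuted PWM (score threshold 0,
#' strict) and samples `X * nPos` unique hit windows without replacement.
#' Permuted-matrix hits share the composition of the motif but not its
#' positional arrangement. A shortfall (small genomes, sharp motifs) is
#' reported with a warning and all available windows are returned.
#'
#' @param pwm original [MotifPWM-class].
#' @param bg [MarkovBackground-class].
#' @param genome [GenomeSeq-class].
#' @param nPos number of positive sequences (the "X" of the 10X rule).
#' @param X negatives per positive drawn from this pool (default 10).
#' @param seed integer seed.
#' @param nPermutations pool scans of this many independent column
#'   permutations (default 1).
#' @return character vector of negative sequences.
#' @export
negativesPermuted <- function(pwm, bg, genome, nPos, X = 10L, seed = 1L,
                              nPermutations = 1L) {
  pool <- character(0)
  for (i in seq_len(nPermutations)) {
    pp <- permuteColumns(pwm, seed = childSeed(seed, 101L, i))
    hits <- scanGenome(pp, bg, genome, minScore = 0)
    pool <- c(pool, uniqueHitSequences(hits))
  }
  .sampleUnique(pool, X * nPos, childSeed(seed, 102L), "permuted-PWM")
}

#' GC-matched random negative sequences
#'
#' Generates `X * nPos` i.i.d. sequences of the motif width whose expected
#' GC content equals the pooled GC fraction of the positive set: per base,
#' P(G) = P(C) = g/2 and P(A) = P(T) = (1-g)/2.
#'
#' @param positives a [BindingSiteSet-class].
#' @inheritParams negativesPermuted
#' @return character vector of `X * length(positives)` sequences.
#' @export
negativesGCRandom <- function(positives, X = 10L, seed = 1L) {
  L <- motifWidth(positives)
  n <- X * length(positives)
  freq <- Biostrings::alphabetFrequency(positives@sequences, collapse = TRUE)
  g <- sum(freq[c("C", "G")]) / sum(freq[DNA_BASES4])
  p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  withSeed(seed, {
    m <- matrix(sample.int(4L, n * L, replace = TRUE, prob = p),
                nrow = n, ncol = L)
    apply(m, 1L, intToDna)
  })
}

#' Low-scoring genomic windows as negatives
#'
#' Samples `X * nPos` unique windows whose PWM log-odds score lies in the
#' closed-open band `[-2, 0)` — sequences the motif model itself rejects,
#' but not arbitrarily dissimilar ones.
#'
#' @inheritParams negativesPermuted
#' @param lowerBound inclusive lower score bound (default -2).
#' @return character vector of negative sequences.
#' @export
negativesLowScore <- function(pwm, bg, genome, nPos, X = 10L, seed = 1L,
                              lowerBound = -2) {
  hits <- scanGenome(pwm, bg, genome, minScore = lowerBound, maxScore = 0,
                     minInclusive = TRUE)
  pool <- uniqueHitSequences(hits)
  .sampleUnique(pool, X * nPos, childSeed(seed, 103L), "low-score")
}

#' Labeled design matrix for the regularized logistic regression
#'
#' Rows are coded training sequences: 3L sum-to-zero dummy-coded
#' single-base features followed by K binary association features. By
#' construction the negative block holds 30 non-redundant negatives per
#' positive (10 from each generation procedure) unless a pool fell short,
#' which is recorded in `shortfall`.
#'
#' @slot x numeric matrix, columns `Z1..Z3L` then feature ids.
#' @slot y integer labels (1 positive, 0 negative).
#' @slot sequences the training sequences, row order.
#' @slot provenance per-row origin: `positive`, `permuted`, `gc-random`,
#'   `low-score`.
#' @slot motifLength L.
#' @slot features the association-feature table used for coding.
#' @slot shortfall named integer: requested minus delivered per pool.
#' @seealso [assembleDesign()], [fitELRM()]
#' @export
setClass("DesignMatrix",
  representation(x = "matrix", y = "integer", sequences = "character",
                 provenance = "character", motifLength = "integer",
                 features = "data.frame", shortfall = "integer"))

setValidity("DesignMatrix", function(object) {
  if (nrow(object@x) != length(object@y)) return("x rows != labels")
  if (length(object@provenance) != length(object@y)) {
    return("provenance length != labels")
  }
  K <- nrow(object@features)
  if (ncol(object@x) != 3L * object@motifLength + K) {
    return("column count must be 3L + K")
  }
  if (!all(object@y %in% c(0L, 1L))) return("labels must be 0/1")
  TRUE
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf(
    "DesignMatrix: %d rows (%d positive, %d negative), %d columns (3L=%d + K=%d)\n",
    nrow(object@x), sum(object@y == 1L), sum(object@y == 0L),
    ncol(object@x), 3L * object@motifLength, nrow(object@features)))
  if (any(object@shortfall > 0L)) {
    cat(" shortfall:",
        paste(names(object@shortfall)[object@shortfall > 0L],
              object@shortfall[object@shortfall > 0L], collapse = ", "),
        "\n")
  }
})

#' @describeIn DesignMatrix predictor matrix.
#' @param object a `DesignMatrix`.
#' @export
setGeneric("designX", function(object) standardGeneric("designX"))

#' @rdname DesignMatrix
#' @export
setMethod("designX", "DesignMatrix", function(object) object@x)

#' @describeIn DesignMatrix 0/1 labels.
#' @export
setGeneric("designY", function(object) standardGeneric("designY"))

#' @rdname DesignMatrix
#' @export
setMethod("designY", "DesignMatrix", function(object) object@y)

#' @describeIn DesignMatrix per-row provenance.
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname DesignMatrix
#' @export
setMethod("provenance", "DesignMatrix", function(object) object@provenance)

#' @rdname motifWidth
#' @export
setMethod("motifWidth", "DesignMatrix", function(x) x@motifLength)

#' Assemble the labeled training matrix
#'
#' Pools the three negative sets, deduplicates them exactly (first
#' occurrence wins, pool order: permuted, gc-random, low-score), purges
#' any negative identical to a positive string, and codes all rows with
#' the dummy and association codings. Positive duplicates (identical
#' binding sites at different loci) are kept. Shortfalls against the
#' requested 10X per pool are reported in the `shortfall` slot and via a
#' message.
#'
#' @param positives a [BindingSiteSet-class].
#' @param features association features from [integrateFeatures()] (zero
#'   rows allowed: the matrix then has exactly 3L columns).
#' @param negPermuted,negGCRandom,negLowScore character vectors from the
#'   three negative generators.
#' @param X requested negatives per positive per pool.
#' @return a [DesignMatrix-class].
#' @export
assembleDesign <- function(positives, features, negPermuted, negGCRandom,
                           negLowScore, X = 10L) {
  posSeqs <- siteSequences(positives)
  nPos <- length(posSeqs)
  pools <- list(`permuted` = negPermuted, `gc-random` = negGCRandom,
                `low-score` = negLowScore)
  negs <- unlist(pools, use.names = FALSE)
  prov <- rep(names(pools), lengths(pools))
  keep <- !duplicated(negs) & !(negs %in% posSeqs)
  negs <- negs[keep]
  prov <- prov[keep]
  if (!length(negs)) stop("no negatives remain after deduplication")
  requested <- X * nPos
  delivered <- table(factor(prov, levels = names(pools)))
  shortfall <- pmax(0L, as.integer(requested - delivered))
  names(shortfall) <- names(pools)
  if (any(shortfall > 0L)) {
    message("negative-pool shortfall: ",
            paste(names(shortfall)[shortfall > 0L],
                  shortfall[shortfall > 0L], collapse = ", "))
  }

  seqs <- c(posSeqs, negs)
  z <- dummyCode(seqs)
  x <- if (nrow(features)) cbind(z, associationCode(seqs, features)) else z
  new("DesignMatrix",
      x = x,
      y = c(rep(1L, nPos), rep(0L, length(negs))),
      sequences = seqs,
      provenance = c(rep("positive", nPos), prov),
      motifLength = motifWidth(positives),
      features = features,
      shortfall = shortfall)
}

#' Export a design matrix as TSV
#'
#' Single-base columns are labeled `Z{n}(base,pos)` per the dummy-coding
#' table, association columns by canonical feature id; a provenance
#' column is included.
#'
#' @param design a [DesignMatrix-class].
#' @param path output path.
#' @export
writeDesignTSV <- function(design, path) {
  L <- design@motifLength
  zn <- seq_len(3L * L)
  ## each coded triple spans all four bases at one position
  codedNames <- sprintf("Z%d(p%d)", zn, (zn - 1L) %/% 3L + 1L)
  df <- data.frame(label = design@y, provenance = design@provenance,
                   sequence = design@sequences, design@x,
                   check.names = FALSE)
  names(df)[4:(3 + 3L * L)] <- codedNames
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
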