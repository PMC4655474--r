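#' Estimate a first-order Markov background from a genome
#'
#' Counts all adjacent non-N base pairs on the given strand, applies
#' Laplace (+1) smoothing to the 4 x 4 transition counts, and uses the
#' smoothed mononucleotide frequencies as the initial distribution.
#'
#' @param genome a [GenomeSeq-class].
#' @return a [MarkovBackground-class].
#' @export
estimateBackground <- function(genome) {
  x <- match(strsplit(genome@sequence, "")[[1L]], DNA_BASES4)
  nonN <- !is.na(x)
  if (sum(nonN) < 2L) stop("genome must contain at least 2 non-N bases")
  mono <- tabulate(x[nonN], 4L) + 1
  a <- x[-length(x)]
  b <- x[-1L]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("genome has no adjacent non-N base pair")
  tab <- table(factor(a[keep], levels = 1:4), factor(b[keep], levels = 1:4))
  tc <- 1 + matrix(as.numeric(tab), 4L, 4L)
  tr <- tc / rowSums(tc)
  dimnames(tr) <- list(DNA_BASES4, DNA_BASES4)
  init <- mono / sum(mono)
  names(init) <- DNA_BASES4
  new("MarkovBackground", initial = init, transition = tr)
}

#' Build a position probability matrix from aligned sites
#'
#' `probs[p, b] = (count[p, b] + pseudocount) / (n + 4 * pseudocount)`.
#' The default pseudocount of 1 (Laplace) matters for the very small
#' positive sets common for bacterial TFs (down to 4 sites).
#'
#' @param sites a [BindingSiteSet-class].
#' @param pseudocount nonnegative additive smoothing count per cell.
#' @return a [MotifPWM-class].
#' @export
buildPWM <- function(sites, pseudocount = 1.0) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  cm <- siteCounts(sites)
  n <- length(sites)
  probs <- (cm + pseudocount) / (n + 4 * pseudocount)
  new("MotifPWM", probs = probs, pseudocount = pseudocount)
}

#' Per-position base counts of a binding-site set
#'
#' @param sites a [BindingSiteSet-class].
#' @return L x 4 integer matrix of base counts (columns A,C,G,T); each row
#'   sums to the number of sites.
#' @export
siteCounts <- function(sites) {
  m <- seqMatrix(siteSequences(sites))
  cm <- t(apply(m, 2L, tabulate, nbins = 4L))
  colnames(cm) <- DNA_BASES4
  cm
}

## log-probability matrices used by the scanner
.pwmLogProbs <- function(pwm) log(pwm@probs)

## background log-prob of integer windows is computed inline by scanner;
## this scalar version backs scoreWindow
.bgLogProb <- function(bg, v) {
  lp <- log(bg@initial[v[1L]])
  if (length(v) > 1L) {
    lp <- lp + sum(log(bg@transition[cbind(v[-length(v)], v[-1L])]))
  }
  unname(lp)
}

#' Log-odds score of one window
#'
#' `score = sum_p log probs[p, w_p] - log P_bg(w)` with
#' `P_bg(w) = initial(w_1) * prod_p transition(w_p | w_{p-1})`, in natural
#' log units.
#'
#' @param pwm a [MotifPWM-class].
#' @param bg a [MarkovBackground-class].
#' @param window DNA string of the motif width, A/C/G/T only.
#' @return finite numeric log-odds (natural log).
#' @export
scoreWindow <- function(pwm, bg, window) {
  v <- dnaToInt(window)
  if (anyNA(v)) stop("window contains non-ACGT characters; not scoreable")
  if (length(v) != motifWidth(pwm)) {
    stop("window length ", length(v), " != motif width ", motifWidth(pwm))
  }
  lp <- .pwmLogProbs(pwm)
  sum(lp[cbind(seq_along(v), v)]) - .bgLogProb(bg, v)
}

## vectorized scores of all windows on one integer strand; NA where the
## window overlaps an N
.scanStrand <- function(lp, bg, x, L) {
  n <- length(x)
  nw <- n - L + 1L
  if (nw < 1L) return(numeric(0))
  xi <- x
  xi[is.na(xi)] <- 1L
  sc <- numeric(nw)
  idx <- seq_len(nw)
  for (p in seq_len(L)) {
    lpp <- lp[p, ]
    sc <- sc + lpp[xi[idx + p - 1L]]
  }
  ## background: initial + cumulative transition log-probs
  tl <- log(bg@transition)[cbind(xi[-n], xi[-1L])]
  ct <- c(0, cumsum(tl))
  bgs <- log(bg@initial)[xi[idx]] + (ct[idx + L - 1L] - ct[idx])
  score <- sc - bgs
  ## invalidate windows containing N
  cn <- c(0L, cumsum(is.na(x)))
  score[(cn[idx + L] - cn[idx]) > 0L] <- NA_real_
  score
}

#' Scan a genome with a PWM on both strands
#'
#' Scores every window of the motif width on both strands against the
#' first-order Markov background and keeps windows whose log-odds score
#' falls in the requested band. The default band (`minScore = 0`, strict)
#' collects the candidate sequences that feed association mining; the
#' low-scoring negative pool uses the closed-open band `[-2, 0)` via
#' `minInclusive = TRUE`. Windows overlapping `N` are never scored.
#'
#' @param pwm a [MotifPWM-class].
#' @param bg a [MarkovBackground-class].
#' @param genome a [GenomeSeq-class].
#' @param minScore lower score bound (strict unless `minInclusive`).
#' @param maxScore upper score bound (strict unless `maxInclusive`).
#' @param minInclusive,maxInclusive whether the bounds are closed.
#' @return a [GenomicRanges::GRanges] sorted by start then strand, with
#'   seqnames mapped back to the source FASTA records and metadata columns
#'   `window` (the matched sequence, reverse-complemented for `-` hits)
#'   and `score` (natural-log odds).
#' @export
scanGenome <- function(pwm, bg, genome, minScore = 0,
                       maxScore = Inf, minInclusive = FALSE,
                       maxInclusive = FALSE) {
  L <- motifWidth(pwm)
  if (L > length(genome)) stop("motif wider than genome")
  lp <- .pwmLogProbs(pwm)
  x <- match(strsplit(genome@sequence, "")[[1L]], DNA_BASES4)
  n <- length(x)

  keepBand <- function(s) {
    ok <- !is.na(s)
    lo <- if (minInclusive) s >= minScore else s > minScore
    hi <- if (maxInclusive) s <= maxScore else s < maxScore
    ok & lo & hi
  }

  fwd <- .scanStrand(lp, bg, x, L)
  kf <- which(keepBand(fwd))
  xrc <- rev(5L - x)
  rc <- .scanStrand(lp, bg, xrc, L)
  kr <- which(keepBand(rc))
  ## - strand window starting at j (1-based, rc coords) covers forward
  ## positions (n - j - L + 2) .. (n - j + 1)
  startsR <- n - kr - L + 2L

  starts <- c(kf, startsR)
  strands <- rep(c("+", "-"), c(length(kf), length(kr)))
  scores <- c(fwd[kf], rc[kr])
  windowOf <- function(st, strand) {
    if (!length(st)) return(character(0))
    w <- substring(genome@sequence, st, st + L - 1L)
    flip <- strand == "-"
    if (any(flip)) {
      w[flip] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(w[flip])))
    }
    w
  }
  wins <- windowOf(starts, strands)

  ord <- order(starts, strands)
  starts <- starts[ord]; strands <- strands[ord]
  scores <- scores[ord]; wins <- wins[ord]

  ## map concatenated coordinates back to source records
  recs <- genome@records
  ri <- findInterval(starts, recs$start)
  ri[ri < 1L] <- 1L
  gr <- GenomicRanges::GRanges(
    seqnames = recs$name[ri],
    ranges = IRanges::IRanges(start = starts - recs$start[ri] + 1L, width = L),
    strand = strands,
    window = wins,
    score = scores)
  gr
}

#' Unique hit window sequences, order-stable
#'
#' Deduplicates the matched window strings of a scan (first occurrence
#' kept). These unique candidate sequences are the transactions for
#' association mining. By default a window and its reverse complement are
#' distinct strings; set `strandAware = TRUE` to collapse them.
#'
#' @param hits `GRanges` from [scanGenome()].
#' @param strandAware collapse a window with its reverse complement.
#' @return character vector of window sequences.
#' @export
uniqueHitSequences <- function(hits, strandAware = FALSE) {
  w <- S4Vectors::mcols(hits)$window
  if (is.null(w)) return(character(0))
  if (!strandAware) return(unique(w))
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(w)))
  key <- pmin(w, rc)
  w[!duplicated(key)]
}

#' Randomly permute the columns (positions) of a PWM
#'
#' Draws a uniform random permutation of the motif positions, resampling
#' until it differs from the identity (guaranteed possible for L >= 2).
#' Scanning with column-permuted PWMs supplies negative training
#' sequences that match the original composition but not its positional
#' arrangement.
#'
#' @param pwm a [MotifPWM-class] of width >= 2.
#' @param seed integer seed; same seed, same permutation.
#' @return a [MotifPWM-class] with permuted rows.
#' @export
permuteColumns <- function(pwm, seed = 1L) {
  L <- motifWidth(pwm)
  if (L < 2L) stop("need motif width >= 2 to permute")
  withSeed(seed, {
    repeat {
      perm <- sample.int(L)
      if (any(perm != seq_len(L))) break
    }
    new("MotifPWM", probs = pwm@probs[perm, , drop = FALSE],
        pseudocount = pwm@pseudocount)
  })
}

#' Information content of a motif
#'
#' Per-position `IC_p = 2 + sum_b f_pb log2 f_pb` (with `0 log 0 = 0`)
#' against a uniform reference, and the width-normalized total
#' `sum_p IC_p / L` in bits per position — the binding-specificity proxy
#' correlated with the association-feature ratio.
#'
#' @param x a [MotifPWM-class], or an L x 4 matrix of counts or
#'   probabilities (columns A,C,G,T).
#' @return list with `perPosition` (bits) and `widthNormalized`
#'   (bits/position).
#' @export
informationContent <- function(x) {
  f <- if (is(x, "MotifPWM")) x@probs else {
    m <- as.matrix(x)
    stopifnot(ncol(m) == 4L)
    m / rowSums(m)
  }
  h <- rowSums(ifelse(f > 0, f * log2(f), 0))
  ic <- 2 + h
  list(perPosition = unname(ic), widthNormalized = sum(ic) / nrow(f))
}

#' Write / read a PWM as a JASPAR-like tab-separated matrix
#'
#' Four rows labeled A/C/G/T with one column per motif position, plus a
#' `#pseudocount` header comment.
#'
#' @param pwm a [MotifPWM-class].
#' @param path file path.
#' @return `readPWM` returns a [MotifPWM-class].
#' @export
writePWM <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#pseudocount\t%.17g", pwm@pseudocount), con)
  p <- t(pwm@probs)
  for (b in 1:4) {
    writeLines(paste(c(DNA_BASES4[b], sprintf("%.17g", p[b, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname writePWM
#' @export
readPWM <- function(path) {
  lines <- readLines(path)
  pc <- 1.0
  if (startsWith(lines[1L], "#pseudocount")) {
    pc <- as.numeric(strsplit(lines[1L], "\t")[[1L]][2L])
    lines <- lines[-1L]
  }
  rows <- strsplit(lines, "\t")
  bases <- vapply(rows, `[[`, "", 1L)
  stopifnot(setequal(bases, DNA_BASES4))
  vals <- lapply(rows, function(r) as.numeric(r[-1L]))
  m <- do.call(rbind, vals[match(DNA_BASES4, bases)])
  probs <- t(m)
  colnames(probs) <- DNA_BASES4
  new("MotifPWM", probs = probs, pseudocount = pc)
}

#' Export scan hits as BED
#'
#' 0-based half-open intervals; the score column carries the natural-log
#' odds, the name column the matched window.
#'
#' @param hits `GRanges` from [scanGenome()].
#' @param path output path.
#' @export
writeHitsBED <- function(hits, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(hits)),
    start = GenomicRanges::start(hits) - 1L,
    end = GenomicRanges::end(hits),
    name = S4Vectors::mcols(hits)$window,
    score = S4Vectors::mcols(hits)$score,
    strand = as.character(GenomicRanges::strand(hits)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
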