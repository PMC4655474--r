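#' Ground truth of a synthetic motif/genome case
#'
#' Records where motif instances were planted in a synthetic genome and
#' which positional dependencies were imposed, so downstream stages can be
#' verified against a known answer.
#'
#' @slot plantedPositions data.frame with columns `offset` (0-based genome
#'   offset of the planted window), `strand` (`"+"`/`"-"`).
#' @slot dependencySpec list of dependency groups; each group is a list
#'   with `positions` (1-based motif positions), `patterns` (character
#'   vector of joint base assignments, one character per position) and
#'   `probs` (joint distribution over the patterns, summing to 1).
#' @slot marginals L x 4 matrix of per-position marginal base
#'   distributions used for non-dependent positions.
#' @seealso [generateSyntheticCase()]
#' @export
setClass("SyntheticTruth",
  representation(plantedPositions = "data.frame", dependencySpec = "list",
                 marginals = "matrix"))

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d planted sites, %d dependency group(s)\n",
              nrow(object@plantedPositions), length(object@dependencySpec)))
})

#' Read an aligned binding-site set
#'
#' Accepts FASTA or plain one-sequence-per-line text. All records must
#' have identical width and use only A/C/G/T (uppercased on read).
#'
#' @param path path to the input file.
#' @param tfName TF name attached to the returned object.
#' @return a [BindingSiteSet-class].
#' @export
readSites <- function(path, tfName = "TF") {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(trimws(first), ">")) {
    s <- Biostrings::readDNAStringSet(path)
    seqs <- toupper(as.character(s))
    nm <- names(s)
  } else {
    seqs <- toupper(trimws(readLines(path)))
    seqs <- seqs[nzchar(seqs)]
    nm <- as.character(seq_along(seqs))
  }
  if (!length(seqs)) stop("no sequences in ", path)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1L])[1L]
    stop(sprintf("length mismatch in '%s': width %d, expected %d",
                 nm[bad], w[bad], w[1L]))
  }
  badAlpha <- grepl("[^ACGT]", seqs)
  if (any(badAlpha)) {
    stop(sprintf("non-ACGT character in record '%s'", nm[which(badAlpha)[1L]]))
  }
  BindingSiteSet(seqs, tfName = tfName)
}

#' Write a binding-site set as FASTA
#'
#' @param x a [BindingSiteSet-class].
#' @param path output path.
#' @export
writeSites <- function(x, path) {
  s <- x@sequences
  if (is.null(names(s))) {
    names(s) <- paste0(x@tfName, "_", seq_along(s))
  }
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Multi-record files are concatenated with a single `N` separator between
#' records; scanning never scores a window containing `N`, so no window
#' can be chimeric. Record boundaries are kept for mapping hits back.
#'
#' @param path FASTA path.
#' @param topology `"linear"` (default) or `"circular"` (annotation only).
#' @return a [GenomeSeq-class].
#' @export
readGenome <- function(path, topology = "linear") {
  if (!file.exists(path)) stop("no such file: ", path)
  s <- Biostrings::readDNAStringSet(path)
  if (!length(s) || sum(Biostrings::width(s)) == 0L) {
    stop("empty genome FASTA: ", path)
  }
  chunks <- toupper(as.character(s))
  if (any(grepl("[^ACGTN]", chunks))) {
    stop("genome contains characters other than A, C, G, T, N")
  }
  nm <- names(s) %||% paste0("record", seq_along(s))
  nm <- sub("\\s.*$", "", nm)
  concat <- paste(chunks, collapse = "N")
  starts <- cumsum(c(1L, head(nchar(chunks), -1L) + 1L))
  g <- new("GenomeSeq", id = nm[1L], sequence = concat, topology = topology,
           records = data.frame(name = nm, start = starts,
                                end = starts + nchar(chunks) - 1L,
                                stringsAsFactors = FALSE))
  validObject(g)
  g
}

#' Write a genome as FASTA
#'
#' Writes one FASTA record per original record boundary.
#'
#' @param x a [GenomeSeq-class].
#' @param path output path.
#' @export
writeGenome <- function(x, path) {
  recs <- x@records
  seqs <- substring(x@sequence, recs$start, recs$end)
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- recs$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## per-position base distribution reaching a target information content
## (consensus base gets probability p, the rest (1-p)/3 each)
.icMarginal <- function(ic, consensus) {
  stopifnot(ic >= 0, ic <= 2)
  f <- function(p) {
    q <- (1 - p) / 3
    terms <- c(p, q, q, q)
    2 + sum(ifelse(terms > 0, terms * log2(terms), 0)) - ic
  }
  p <- if (ic <= 1e-12) 0.25
       else if (ic >= 2 - 1e-12) 1
       else uniroot(f, c(0.25, 1), tol = 1e-12)$root
  out <- rep((1 - p) / 3, 4)
  out[consensus] <- p
  out
}

.checkDependencySpec <- function(dependencySpec, width) {
  for (g in dependencySpec) {
    stopifnot(is.numeric(g$positions), is.character(g$patterns),
              is.numeric(g$probs))
    if (any(g$positions < 1L) || any(g$positions > width)) {
      stop("dependency positions must lie in 1..width")
    }
    if (any(nchar(g$patterns) != length(g$positions))) {
      stop("each pattern must have one base per group position")
    }
    if (abs(sum(g$probs) - 1) > 1e-9) {
      stop("dependency joint distribution must sum to 1")
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic genome with planted, dependence-bearing motif sites
#'
#' Builds a random background genome (i.i.d. or first-order Markov),
#' draws `nSites` motif instances from a product of per-position marginals
#' overridden by joint distributions on the specified dependency groups,
#' and plants them at non-overlapping positions on random strands. This
#' emulates the statistical structure the method targets: conserved
#' positions plus correlated position groups (e.g. the covarying bases of
#' an inverted-repeat pair).
#'
#' @param width motif width L.
#' @param nSites number of instances to plant (= positive set size).
#' @param genomeLen background genome length in bases.
#' @param dependencySpec list of dependency groups (see
#'   [SyntheticTruth-class]); positions not covered by any group are
#'   independent with `infoContentTarget` bits each. `NULL` for none.
#' @param infoContentTarget information content, in bits, of each
#'   independent position (0 = uniform, 2 = invariant). The default,
#'   1.7 bits, emulates a highly specific TF: the genome-scan candidate
#'   pool is then dominated by genuine planted instances, the regime in
#'   which within-motif dependence is recoverable by association mining.
#' @param seed integer seed; identical inputs give byte-identical outputs.
#' @param backgroundOrder 0 for i.i.d. uniform background, 1 (default) for
#'   a first-order Markov background with mildly uneven transitions.
#' @param tfName name for the generated site set.
#' @return list with elements `genome` ([GenomeSeq-class]),
#'   `sites` ([BindingSiteSet-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @examples
#' case <- generateSyntheticCase(width = 12, nSites = 50, genomeLen = 2e4,
#'   dependencySpec = list(list(positions = c(3, 8),
#'                              patterns = c("CG", "AT"),
#'                              probs = c(0.5, 0.5))),
#'   seed = 1)
#' case$sites
#' @export
generateSyntheticCase <- function(width, nSites, genomeLen,
                                  dependencySpec = NULL,
                                  infoContentTarget = 1.7,
                                  seed = 1L,
                                  backgroundOrder = 1L,
                                  tfName = "synthTF") {
  stopifnot(width >= 2L, nSites >= 2L,
            infoContentTarget >= 0, infoContentTarget <= 2)
  dependencySpec <- dependencySpec %||% list()
  .checkDependencySpec(dependencySpec, width)
  depPos <- unlist(lapply(dependencySpec, `[[`, "positions"))
  if (anyDuplicated(depPos)) {
    stop("dependency groups must cover disjoint positions")
  }
  if (genomeLen < nSites * width) {
    stop("genome too short to place sites without overlap")
  }

  withSeed(seed, {
    ## per-position marginals for independent positions
    consensus <- sample.int(4L, width, replace = TRUE)
    marg <- t(vapply(seq_len(width),
                     function(p) .icMarginal(infoContentTarget, consensus[p]),
                     numeric(4)))
    colnames(marg) <- DNA_BASES4

    ## draw site matrix
    m <- matrix(0L, nrow = nSites, ncol = width)
    for (p in setdiff(seq_len(width), depPos)) {
      m[, p] <- sample.int(4L, nSites, replace = TRUE, prob = marg[p, ])
    }
    for (g in dependencySpec) {
      pick <- sample.int(length(g$patterns), nSites, replace = TRUE,
                         prob = g$probs)
      pat <- seqMatrix(g$patterns)
      for (j in seq_along(g$positions)) {
        m[, g$positions[j]] <- pat[pick, j]
      }
    }
    siteSeqs <- apply(m, 1L, intToDna)

    ## background genome
    if (backgroundOrder == 0L) {
      gx <- sample.int(4L, genomeLen, replace = TRUE)
    } else {
      ## mildly uneven first-order chain (rows normalized gamma draws)
      tr <- matrix(rgamma(16L, shape = 30), 4L, 4L)
      tr <- tr / rowSums(tr)
      cum <- t(apply(tr, 1L, cumsum))
      gx <- integer(genomeLen)
      gx[1L] <- sample.int(4L, 1L)
      u <- runif(genomeLen)
      for (i in 2:genomeLen) {
        gx[i] <- findInterval(u[i], cum[gx[i - 1L], ]) + 1L
      }
    }

    ## non-overlapping planting offsets (sorted slack + stacked widths)
    slack <- genomeLen - nSites * width
    u <- sort(sample.int(slack + 1L, nSites, replace = TRUE))
    starts <- u + (seq_len(nSites) - 1L) * width  # 1-based
    strands <- sample(c("+", "-"), nSites, replace = TRUE)
    for (i in seq_len(nSites)) {
      inst <- m[i, ]
      if (strands[i] == "-") inst <- rev(5L - inst)
      gx[starts[i]:(starts[i] + width - 1L)] <- inst
    }

    genome <- GenomeSeq(intToDna(gx), id = paste0(tfName, "_genome"))
    sites <- BindingSiteSet(siteSeqs, tfName = tfName)
    truth <- new("SyntheticTruth",
                 plantedPositions = data.frame(offset = starts - 1L,
                                               strand = strands,
                                               stringsAsFactors = FALSE),
                 dependencySpec = dependencySpec,
                 marginals = marg)
    list(genome = genome, sites = sites, truth = truth)
  })
}

#' Write synthetic ground truth as a JSON sidecar
#' @param truth a [SyntheticTruth-class].
#' @param path output path.
#' @export
writeSyntheticTruth <- function(truth, path) {
  jsonlite::write_json(
    list(plantedPositions = truth@plantedPositions,
         dependencySpec = truth@dependencySpec,
         marginals = truth@marginals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
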