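#' Convert candidate sequences into transactions of single-base items
#'
#' Each equal-length DNA string becomes one transaction holding exactly
#' one item per motif position; the item at position p is the single-base
#' feature `<base><p>` (e.g. `"C2"`). Multiplicity is kept: identical
#' sequences yield identical, separately counted transactions.
#'
#' @param sequences character vector of equal-length A/C/G/T strings.
#' @return a `TransactionDB`: list with the integer base matrix `mat`
#'   (n x L), `n` and `L`.
#' @export
itemize <- function(sequences) {
  if (!length(sequences)) stop("no sequences to itemize")
  w <- nchar(sequences)
  if (any(w == 0L)) stop("empty sequence")
  if (length(unique(w)) != 1L) stop("sequences must have equal length")
  m <- seqMatrix(sequences)
  if (anyNA(m)) stop("sequences must contain only A, C, G, T")
  structure(list(mat = m, n = nrow(m), L = ncol(m)), class = "TransactionDB")
}

#' Support of an itemset
#'
#' Fraction of transactions containing every item of the set. Items at
#' the same position are mutually exclusive, so any itemset with two
#' items at one position has support 0.
#'
#' @param items integer item codes (see [itemLabel()]) or character
#'   labels like `c("A2","C5")`.
#' @param db a `TransactionDB` from [itemize()].
#' @return support in `[0, 1]`.
#' @export
itemSupport <- function(items, db) {
  codes <- if (is.character(items)) parseItemLabel(items) else as.integer(items)
  if (!length(codes)) stop("itemset must be nonempty")
  .supportOf(codes, db$mat)
}

.supportOf <- function(codes, mat) {
  pos <- itemPosition(codes)
  base <- itemBase(codes)
  if (anyDuplicated(pos)) return(0)
  sub <- mat[, pos, drop = FALSE]
  hit <- sub == rep(base, each = nrow(mat))
  mean(.rowAll(hit))
}

.rowAll <- function(logmat) {
  if (ncol(logmat) == 1L) return(logmat[, 1L])
  rowSums(logmat) == ncol(logmat)
}

#' Mine frequent single-base itemsets with the Apriori algorithm
#'
#' Level-wise candidate generation by (k-1)-prefix join with anti-monotone
#' pruning. Candidates holding two items at the same motif position are
#' pruned a priori (they can never co-occur). Returns exactly the
#' itemsets of size `<= maxSize` whose support is `>= minSupport`.
#'
#' The default size cap of 6 is generous — the most complex published
#' bacterial models average ~3.4 members per association feature — and
#' guards against combinatorial blow-up on highly conserved motifs; a
#' warning is emitted if the cap truncates the lattice.
#'
#' @param db a `TransactionDB` from [itemize()].
#' @param minSupport minimum support in `(0, 1]`.
#' @param maxSize maximum itemset size (>= 1).
#' @return data.frame with columns `id` (canonical label, items sorted by
#'   position and ":"-joined), `size`, `support`, and list-column `items`
#'   (integer codes).
#' @export
apriori <- function(db, minSupport, maxSize = 6L) {
  stopifnot(inherits(db, "TransactionDB"))
  if (db$n == 0L) stop("empty transaction database")
  if (minSupport <= 0 || minSupport > 1) stop("minSupport must be in (0,1]")
  mat <- db$mat
  n <- db$n
  L <- db$L

  ## level 1: per-position base frequencies
  outItems <- list()
  outSup <- numeric(0)
  lvl <- list()      # frequent itemsets at current level (sorted codes)
  lvlSup <- numeric(0)
  for (p in seq_len(L)) {
    f <- tabulate(mat[, p], 4L) / n
    for (b in which(f >= minSupport)) {
      lvl[[length(lvl) + 1L]] <- itemCode(b, p)
      lvlSup <- c(lvlSup, f[b])
    }
  }
  outItems <- lvl
  outSup <- lvlSup

  k <- 1L
  while (length(lvl) > 1L && k < maxSize) {
    ## prefix join: pairs sharing the first k-1 items
    keys <- vapply(lvl, function(s) paste(s[-length(s)], collapse = ","), "")
    lasts <- vapply(lvl, function(s) s[length(s)], integer(1))
    ord <- order(keys, lasts)
    lvl <- lvl[ord]; keys <- keys[ord]; lasts <- lasts[ord]
    frequentSet <- new.env(hash = TRUE, parent = emptyenv())
    for (s in lvl) assign(paste(s, collapse = ","), TRUE, frequentSet)

    cand <- list()
    groups <- split(seq_along(lvl), keys)
    for (g in groups) {
      if (length(g) < 2L) next
      for (i in seq_len(length(g) - 1L)) {
        for (j in (i + 1L):length(g)) {
          a <- lvl[[g[i]]]; b <- lasts[g[j]]
          if (itemPosition(b) == itemPosition(lasts[g[i]])) next
          cs <- c(a, b)  # sorted by construction
          ## anti-monotone pruning: all k-subsets must be frequent
          ok <- TRUE
          if (k >= 2L) {
            for (drop in seq_len(length(cs) - 1L)) {
              sub <- cs[-drop]
              if (!exists(paste(sub, collapse = ","), frequentSet,
                          inherits = FALSE)) { ok <- FALSE; break }
            }
          }
          if (ok) cand[[length(cand) + 1L]] <- cs
        }
      }
    }
    if (!length(cand)) break
    sup <- vapply(cand, .supportOf, numeric(1), mat = mat)
    keep <- sup >= minSupport
    lvl <- cand[keep]
    lvlSup <- sup[keep]
    outItems <- c(outItems, lvl)
    outSup <- c(outSup, lvlSup)
    k <- k + 1L
  }
  if (k == maxSize && length(lvl) > 1L) {
    warning("frequent-itemset lattice truncated at maxSize = ", maxSize)
  }

  data.frame(
    id = vapply(outItems, itemsetId, ""),
    size = vapply(outItems, length, integer(1)),
    support = outSup,
    items = I(outItems),
    stringsAsFactors = FALSE)
}

#' Confidence and correlation strength of a candidate rule
#'
#' For disjoint itemsets A and B: confidence is the conditional
#' probability `conf(A -> B) = sup(A u B) / sup(A)`; the correlation
#' strength is the phi coefficient
#' `corr = (sup(AuB) - sup(A) sup(B)) / sqrt(sup(A)(1-sup(A)) sup(B)(1-sup(B)))`,
#' defined as 0 when either marginal support is 0 or 1.
#'
#' @param A,B item codes or labels of the antecedent / consequent.
#' @param db a `TransactionDB`.
#' @return list with `confidence` and `correlation`.
#' @export
ruleMeasures <- function(A, B, db) {
  a <- if (is.character(A)) parseItemLabel(A) else as.integer(A)
  b <- if (is.character(B)) parseItemLabel(B) else as.integer(B)
  if (!length(a) || !length(b)) stop("A and B must be nonempty")
  if (length(intersect(a, b))) stop("A and B must be disjoint")
  supA <- .supportOf(a, db$mat)
  if (supA == 0) stop("undefined confidence: sup(A) = 0")
  supB <- .supportOf(b, db$mat)
  supX <- .supportOf(c(a, b), db$mat)
  list(confidence = supX / supA,
       correlation = .phi(supA, supB, supX))
}

.phi <- function(supA, supB, supX) {
  den <- supA * (1 - supA) * supB * (1 - supB)
  if (den <= 0) return(0)
  (supX - supA * supB) / sqrt(den)
}

## confidence of each rule polarity from the three supports
.polarityConfidence <- function(polarity, supA, supB, supX) {
  switch(polarity,
    "A->B" = supX / supA,
    "A->!B" = (supA - supX) / supA,
    "!A->B" = if (supA < 1) (supB - supX) / (1 - supA) else NA_real_,
    "!A->!B" = if (supA < 1) (1 - supA - supB + supX) / (1 - supA)
               else NA_real_,
    stop("unknown polarity: ", polarity))
}

.polaritySign <- function(polarity) {
  switch(polarity, "A->B" = 1, "!A->!B" = 1, "A->!B" = -1, "!A->B" = -1)
}

RULE_POLARITIES <- c("A->B", "A->!B", "!A->B", "!A->!B")

#' Derive valid association rules from frequent itemsets
#'
#' For every frequent itemset X with at least two items and every ordered
#' bipartition (A, B) with `A u B = X`, `A n B = {}`, tests each requested
#' polarity: the positive rule `A -> B` plus the negative rules
#' `A -> !B`, `!A -> B`, `!A -> !B` on the complemented events. A rule is
#' valid when its confidence is `>= mc` and the absolute correlation
#' strength of (A, B) is `>= MCS`; the reported correlation carries the
#' phi value signed by polarity (negated for the mixed polarities).
#'
#' @param frequents output of [apriori()].
#' @param db the `TransactionDB` the itemsets were mined from.
#' @param mc minimum confidence in `(0, 1]`.
#' @param MCS minimum correlation strength in `[0, 1]`.
#' @param polarities subset of `c("A->B", "A->!B", "!A->B", "!A->!B")`.
#' @return data.frame with columns `baseId` (canonical id of X),
#'   `antecedent`, `consequent` (":"-joined labels), `polarity`,
#'   `support` (of X), `confidence`, `correlation`, and list-columns
#'   `itemsA`, `itemsB`.
#' @export
deriveRules <- function(frequents, db, mc, MCS,
                        polarities = RULE_POLARITIES) {
  stopifnot(mc > 0, mc <= 1, MCS >= 0, MCS <= 1)
  polarities <- match.arg(polarities, RULE_POLARITIES, several.ok = TRUE)
  supEnv <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(frequents))) {
    assign(paste(frequents$items[[i]], collapse = ","),
           frequents$support[i], supEnv)
  }
  lookup <- function(codes) {
    key <- paste(sort(codes), collapse = ",")
    if (exists(key, supEnv, inherits = FALSE)) get(key, supEnv)
    else .supportOf(codes, db$mat)
  }

  rows <- vector("list", 256L)
  nr <- 0L
  big <- frequents[frequents$size >= 2L, , drop = FALSE]
  for (i in seq_len(nrow(big))) {
    X <- big$items[[i]]
    supX <- big$support[i]
    k <- length(X)
    ## every nonempty proper subset as antecedent
    for (mask in 1:(2L^k - 2L)) {
      sel <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)))
      A <- X[sel]
      B <- X[!sel]
      supA <- lookup(A)
      supB <- lookup(B)
      if (supA == 0) next
      phi <- .phi(supA, supB, supX)
      if (abs(phi) < MCS) next
      for (pol in polarities) {
        conf <- .polarityConfidence(pol, supA, supB, supX)
        if (is.na(conf) || conf < mc) next
        nr <- nr + 1L
        if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nr]] <- list(baseId = big$id[i],
                           antecedent = itemsetId(A),
                           consequent = itemsetId(B),
                           polarity = pol,
                           support = supX,
                           confidence = conf,
                           correlation = .polaritySign(pol) * phi,
                           itemsA = list(sort(A)),
                           itemsB = list(sort(B)))
      }
    }
  }
  if (!nr) {
    return(data.frame(baseId = character(0), antecedent = character(0),
                      consequent = character(0), polarity = character(0),
                      support = numeric(0), confidence = numeric(0),
                      correlation = numeric(0),
                      itemsA = I(list()), itemsB = I(list()),
                      stringsAsFactors = FALSE))
  }
  rows <- rows[seq_len(nr)]
  data.frame(
    baseId = vapply(rows, `[[`, "", "baseId"),
    antecedent = vapply(rows, `[[`, "", "antecedent"),
    consequent = vapply(rows, `[[`, "", "consequent"),
    polarity = vapply(rows, `[[`, "", "polarity"),
    support = vapply(rows, `[[`, numeric(1), "support"),
    confidence = vapply(rows, `[[`, numeric(1), "confidence"),
    correlation = vapply(rows, `[[`, numeric(1), "correlation"),
    itemsA = I(lapply(rows, function(r) r$itemsA[[1L]])),
    itemsB = I(lapply(rows, function(r) r$itemsB[[1L]])),
    stringsAsFactors = FALSE)
}

#' Integrate association rules into association features
#'
#' Rules sharing the same base itemset X (= antecedent union consequent)
#' are integrated into one association feature whose members are the
#' single-base features of X, identified canonically by position-sorted
#' ":"-joined labels (e.g. `"C2:G5"`). Negative-polarity rules contribute
#' to the same positive-literal feature; the signed regression
#' coefficient later expresses the direction of the dependence.
#'
#' @param rules output of [deriveRules()].
#' @return data.frame with columns `id`, `size`, `nRules`, and
#'   list-columns `items` (integer codes) and `positions`.
#' @export
integrateFeatures <- function(rules) {
  if (!nrow(rules)) {
    return(data.frame(id = character(0), size = integer(0),
                      nRules = integer(0), items = I(list()),
                      positions = I(list()), stringsAsFactors = FALSE))
  }
  ids <- unique(rules$baseId)
  items <- lapply(ids, function(id) {
    i <- which(rules$baseId == id)[1L]
    sort(c(rules$itemsA[[i]], rules$itemsB[[i]]))
  })
  data.frame(
    id = ids,
    size = vapply(items, length, integer(1)),
    nRules = as.integer(table(rules$baseId)[ids]),
    items = I(items),
    positions = I(lapply(items, itemPosition)),
    stringsAsFactors = FALSE)
}

#' Export rules or features as TSV
#' @param x data.frame from [deriveRules()] or [integrateFeatures()].
#' @param path output path.
#' @export
writeRulesTSV <- function(x, path) {
  flat <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
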