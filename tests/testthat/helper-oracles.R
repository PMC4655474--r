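## Independent brute-force oracles. These deliberately avoid the package's
## own code paths (no apriori joins, no cumulative-sum scanning) so that
## agreement is evidence, not tautology.

## log-odds of a window by direct probability products
bruteScore <- function(probs, initial, transition, window) {
  v <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
  num <- prod(probs[cbind(seq_along(v), v)])
  den <- initial[v[1]]
  if (length(v) > 1) {
    for (i in 2:length(v)) den <- den * transition[v[i - 1], v[i]]
  }
  log(num) - log(den)
}

## all itemsets with support >= minSupport, by exhaustive enumeration of
## position subsets and projection counting
bruteFrequentItemsets <- function(mat, minSupport, maxSize = 6L) {
  n <- nrow(mat)
  L <- ncol(mat)
  out <- list()
  sup <- numeric(0)
  for (k in seq_len(min(maxSize, L))) {
    for (posSet in combn(L, k, simplify = FALSE)) {
      proj <- mat[, posSet, drop = FALSE]
      key <- apply(proj, 1, paste, collapse = ",")
      tab <- table(key) / n
      keep <- tab[tab >= minSupport]
      for (nm in names(keep)) {
        bases <- as.integer(strsplit(nm, ",")[[1]])
        codes <- sort((posSet - 1L) * 4L + bases)
        out[[length(out) + 1L]] <- codes
        sup <- c(sup, as.numeric(keep[[nm]]))
      }
    }
  }
  list(items = out, support = sup)
}

## support by direct row matching
bruteSupport <- function(codes, mat) {
  pos <- (codes - 1L) %/% 4L + 1L
  base <- (codes - 1L) %% 4L + 1L
  if (anyDuplicated(pos)) return(0)
  ok <- rep(TRUE, nrow(mat))
  for (i in seq_along(pos)) ok <- ok & mat[, pos[i]] == base[i]
  mean(ok)
}

## all valid rules over all frequent X, ordered bipartitions, 4 polarities
bruteRules <- function(freq, mat, mc, MCS) {
  res <- list()
  for (i in seq_along(freq$items)) {
    X <- freq$items[[i]]
    k <- length(X)
    if (k < 2L) next
    supX <- freq$support[i]
    for (mask in 1:(2^k - 2)) {
      sel <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
      A <- X[sel]; B <- X[!sel]
      supA <- bruteSupport(A, mat)
      supB <- bruteSupport(B, mat)
      if (supA == 0) next
      den <- supA * (1 - supA) * supB * (1 - supB)
      phi <- if (den <= 0) 0 else (supX - supA * supB) / sqrt(den)
      if (abs(phi) < MCS) next
      confs <- c(
        "A->B" = supX / supA,
        "A->!B" = (supA - supX) / supA,
        "!A->B" = if (supA < 1) (supB - supX) / (1 - supA) else NA,
        "!A->!B" = if (supA < 1) (1 - supA - supB + supX) / (1 - supA)
                   else NA)
      for (pol in names(confs)) {
        if (is.na(confs[[pol]]) || confs[[pol]] < mc) next
        res[[length(res) + 1L]] <- paste(
          paste(sort(A), collapse = ","), paste(sort(B), collapse = ","),
          pol, sep = "|")
      }
    }
  }
  sort(as.character(unlist(res)))
}

## AUC by counting concordant pairs
bruteAUC <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## random transaction database as integer matrix (skewed base frequencies
## so that some itemsets clear the support thresholds)
randomDbMat <- function(n, L) {
  m <- matrix(0L, n, L)
  for (p in seq_len(L)) {
    pr <- as.numeric(rmultinom(1, 20, rep(0.25, 4)) + 1)
    m[, p] <- sample.int(4L, n, replace = TRUE, prob = pr / sum(pr))
  }
  m
}

dbFromMat <- function(mat) {
  structure(list(mat = mat, n = nrow(mat), L = ncol(mat)),
            class = "TransactionDB")
}

## canonical string form of a mined rule table, for set comparison
ruleKeys <- function(rules) {
  if (!nrow(rules)) return(character(0))
  sort(paste(
    vapply(rules$itemsA, function(x) paste(sort(x), collapse = ","), ""),
    vapply(rules$itemsB, function(x) paste(sort(x), collapse = ","), ""),
    rules$polarity, sep = "|"))
}

itemsetKeys <- function(items) {
  sort(vapply(items, function(x) paste(sort(x), collapse = ","), ""))
}

## minimal hand-built ELRMModel (bypasses fitting) for accessor tests
manualModel <- function(decoded, betaA = numeric(0), featureIds = character(0),
                        featureItems = list(), intercept = 0) {
  L <- nrow(decoded)
  betaZ <- as.numeric(t(decoded[, 1:3, drop = FALSE]))
  feats <- data.frame(
    id = featureIds,
    size = vapply(featureItems, length, integer(1)),
    nRules = rep(1L, length(featureIds)),
    items = I(featureItems),
    positions = I(lapply(featureItems, function(x) (x - 1L) %/% 4L + 1L)),
    stringsAsFactors = FALSE)
  new("ELRMModel", intercept = intercept, betaZ = betaZ, betaA = betaA,
      decoded = decodeCoefficients(betaZ), alpha = 0.5, lambdaOpt = 0.1,
      features = feats, motifLength = L, cvMeanError = numeric(0),
      lambdaPath = numeric(0), nonzeroPath = integer(0))
}

## small planted-dependence case shared by several tests
smallDepCase <- function(seed, nSites = 100L, genomeLen = 3e4L,
                         width = 12L, positions = c(3L, 8L)) {
  generateSyntheticCase(
    width = width, nSites = nSites, genomeLen = genomeLen,
    dependencySpec = list(list(positions = positions,
                               patterns = c("CG", "AT"),
                               probs = c(0.5, 0.5))),
    seed = seed)
}

## does any selected association feature cover all planted positions?
plantedSelected <- function(model, positions) {
  sel <- selectFeatures(model)
  if (!nrow(sel$assoc)) return(FALSE)
  idx <- match(sel$assoc$id, model@features$id)
  any(vapply(model@features$positions[idx],
             function(p) all(positions %in% p), logical(1)))
}
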