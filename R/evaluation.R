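#' Rank-based area under the ROC curve
#'
#' Mann-Whitney form with midrank tie handling: the probability that a
#' random positive scores above a random negative (ties count 1/2).
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## fold assignment over the positive set: LOO when n <= 10, else
## 10-fold (deterministic shuffle given seed)
.positiveFolds <- function(nPos, seed) {
  if (nPos <= 10L) {
    list(scheme = "LOO", foldOf = seq_len(nPos), k = nPos)
  } else {
    foldOf <- withSeed(childSeed(seed, 77L),
                       sample(rep_len(seq_len(10L), nPos)))
    list(scheme = "10-fold", foldOf = foldOf, k = 10L)
  }
}

## Shared cross-validation engine. Per fold: PWM and scan from the
## training positives only, one negative set per (fold, seed) reused
## across all mining-threshold settings, then per-setting mining + fit.
## Held-out positives are scored together with fold-specific evaluation
## negatives generated independently of the training negatives.
.cvEngine <- function(positives, genome, settings, fitConfig, seed,
                      X = 10L, maxItemsetSize = 6L, bg = NULL,
                      returnModels = FALSE) {
  nPos <- length(positives)
  if (nPos < 3L) stop("cross-validation needs at least 3 positive sequences")
  posSeqs <- siteSequences(positives)
  bg <- bg %||% estimateBackground(genome)
  fd <- .positiveFolds(nPos, seed)
  nSettings <- length(settings)
  scores <- vector("list", nSettings)
  labels <- vector("list", nSettings)
  models <- if (returnModels) {
    lapply(seq_len(nSettings), function(i) vector("list", fd$k))
  } else NULL
  minSupAll <- min(vapply(settings, `[[`, numeric(1), "minSupport"))

  for (f in seq_len(fd$k)) {
    testIdx <- which(fd$foldOf == f)
    if (!length(testIdx)) next
    trainSeqs <- posSeqs[-testIdx]
    testSeqs <- posSeqs[testIdx]
    trainSites <- BindingSiteSet(trainSeqs, tfName = tfName(positives))
    pwm <- buildPWM(trainSites)
    ## one scan covers both the candidate band (> 0) and the low-score
    ## negative band [-2, 0)
    allHits <- scanGenome(pwm, bg, genome, minScore = -2, minInclusive = TRUE)
    sc <- S4Vectors::mcols(allHits)$score
    cand <- uniqueHitSequences(allHits[sc > 0])
    poolLow <- uniqueHitSequences(allHits[sc < 0])
    ## mine once at the loosest support; filter per setting
    db <- if (length(cand)) itemize(cand) else NULL
    frequents <- if (!is.null(db)) {
      suppressWarnings(apriori(db, minSupAll, maxSize = maxItemsetSize))
    } else NULL

    nTrain <- length(trainSeqs)
    nTest <- length(testSeqs)
    fseed <- childSeed(seed, 500L, f)
    ## one permuted-PWM scan backs both the training and evaluation draws
    permPWM <- permuteColumns(pwm, seed = childSeed(fseed, 1L))
    poolPerm <- uniqueHitSequences(scanGenome(permPWM, bg, genome,
                                              minScore = 0))
    drawSplit <- function(pool, seed2) {
      pool <- withSeed(seed2, sample(pool))
      n1 <- min(X * nTrain, length(pool))
      n2 <- min(X * nTest, length(pool) - n1)
      list(train = pool[seq_len(n1)],
           eval = pool[n1 + seq_len(max(0L, n2))])
    }
    spP <- drawSplit(poolPerm, childSeed(fseed, 2L))
    spL <- drawSplit(poolLow, childSeed(fseed, 3L))
    gcAll <- negativesGCRandom(trainSites, X = X, seed = childSeed(fseed, 4L))
    gcEv <- negativesGCRandom(trainSites, X = X, seed = childSeed(fseed, 5L))
    gcEv <- gcEv[seq_len(min(X * nTest, length(gcEv)))]
    negP <- spP$train; negG <- gcAll; negL <- spL$train
    evalNegs <- unique(c(spP$eval, gcEv, spL$eval))
    evalNegs <- setdiff(evalNegs, c(negP, negG, negL, posSeqs))
    if (!length(evalNegs)) {
      stop("no evaluation negatives available for fold ", f)
    }

    for (si in seq_len(nSettings)) {
      st <- settings[[si]]
      feats <- if (is.null(frequents)) {
        integrateFeatures(data.frame(
          baseId = character(0), itemsA = I(list()), itemsB = I(list()),
          stringsAsFactors = FALSE))
      } else {
        fr <- frequents[frequents$support >= st$minSupport, , drop = FALSE]
        integrateFeatures(deriveRules(fr, db, mc = st$minConfidence,
                                      MCS = st$minCorrelation))
      }
      design <- suppressMessages(suppressWarnings(
        assembleDesign(trainSites, feats, negP, negG, negL, X = X)))
      cfg <- fitConfig
      cfg@seed <- childSeed(fseed, 7L)
      ## tiny folds trip glmnet's small-class warnings; harmless here
      model <- suppressWarnings(fitELRM(design, cfg))
      sc <- predictProbability(model, c(testSeqs, evalNegs))
      scores[[si]] <- c(scores[[si]], sc)
      labels[[si]] <- c(labels[[si]],
                        rep(c(1L, 0L), c(nTest, length(evalNegs))))
      if (returnModels) models[[si]][[f]] <- model
    }
  }
  list(scheme = fd$scheme, k = fd$k, foldOf = fd$foldOf,
       auc = vapply(seq_len(nSettings),
                    function(si) aucScore(labels[[si]], scores[[si]]),
                    numeric(1)),
       scores = scores, labels = labels, models = models)
}

#' Cross-validate the full modeling pipeline
#'
#' Leave-one-out when the positive set has ten or fewer sequences,
#' stratified ten-fold otherwise. The whole pipeline — PWM, genome scan,
#' association mining, negative-set construction, elastic-net fit — is
#' re-run inside each training fold, so held-out positives never
#' influence mining, negative sampling or fitting. Out-of-fold predicted
#' probabilities of the held-out positives and of fold-specific
#' evaluation negatives are pooled into a single rank-based AUC.
#'
#' @param positives a [BindingSiteSet-class] (>= 3 sequences).
#' @param genome a [GenomeSeq-class].
#' @param minSupport,minConfidence,minCorrelation mining thresholds.
#' @param fitConfig a [FitConfig-class].
#' @param seed master seed; fold-specific seeds are derived from it.
#' @param X negatives per positive per pool.
#' @param maxItemsetSize cap on mined itemset size.
#' @param returnModels keep the per-fold fitted models (for diagnostics).
#' @return a `CVResult`: list with `scheme` (`"LOO"`/`"10-fold"`), `k`,
#'   `foldOf` (fold of each positive), pooled `labels` and `scores`,
#'   `auc`, and optionally `models`.
#' @export
crossValidate <- function(positives, genome, minSupport = 0.2,
                          minConfidence = 0.6, minCorrelation = 0.1,
                          fitConfig = FitConfig(), seed = 1L, X = 10L,
                          maxItemsetSize = 6L, returnModels = FALSE) {
  res <- .cvEngine(positives, genome,
                   settings = list(list(minSupport = minSupport,
                                        minConfidence = minConfidence,
                                        minCorrelation = minCorrelation)),
                   fitConfig = fitConfig, seed = seed, X = X,
                   maxItemsetSize = maxItemsetSize,
                   returnModels = returnModels)
  structure(list(scheme = res$scheme, k = res$k, foldOf = res$foldOf,
                 labels = res$labels[[1L]], scores = res$scores[[1L]],
                 auc = res$auc[[1L]],
                 models = if (returnModels) res$models[[1L]]),
            class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("CVResult: %s (%d folds), pooled AUC %.4f over %d scores\n",
              x$scheme, x$k, x$auc, length(x$scores)))
  invisible(x)
}

#' Screen mining-threshold combinations for stability
#'
#' Evaluates every combination of the minimum-support, minimum-confidence
#' and minimum-correlation grids (default 3 x 4 x 4 = 48 settings) by
#' cross-validating each case in a panel. A setting is *stable* when (1)
#' the per-case AUCs contain at most `outlierBudget` outliers (Tukey's
#' rule: below Q1 - 1.5 IQR; the budget defaults to a panel-size-scaled
#' 6-of-86) and (2) the worst-case AUC exceeds 0.8. The *optimal* setting
#' is the stable one with the smallest AUC standard deviation, ties
#' broken by the larger mean AUC. The negative set is fixed per (case,
#' fold, seed) across all settings so that the comparison isolates the
#' mining thresholds.
#'
#' @param cases list of cases, each a list with elements `sites`
#'   ([BindingSiteSet-class]) and `genome` ([GenomeSeq-class]).
#' @param supports,confidences,correlations the threshold grids.
#' @param fitConfig a [FitConfig-class].
#' @param seed master seed.
#' @param outlierBudget maximum tolerated AUC outliers per setting;
#'   default `ceiling(6 / 86 * length(cases))`.
#' @param minWorstAUC stability floor on the worst-case AUC.
#' @param X negatives per positive per pool.
#' @return a `ScreeningResult`: list with `grid` (one row per setting:
#'   thresholds, mean/sd/min AUC, `nOutliers`, `stable`), `aucMatrix`
#'   (settings x cases), and `optimal` (row index into `grid`, or `NA`
#'   when no setting is stable).
#' @export
screenThresholds <- function(cases,
                             supports = c(0.1, 0.15, 0.2),
                             confidences = c(0.5, 0.6, 0.7, 0.8),
                             correlations = c(0.05, 0.1, 0.15, 0.2),
                             fitConfig = FitConfig(), seed = 1L,
                             outlierBudget = NULL, minWorstAUC = 0.8,
                             X = 10L) {
  stopifnot(length(cases) >= 1L)
  grid <- expand.grid(minSupport = supports, minConfidence = confidences,
                      minCorrelation = correlations,
                      KEEP.OUT.ATTRS = FALSE)
  settings <- lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, ]))
  outlierBudget <- outlierBudget %||% ceiling(6 / 86 * length(cases))

  aucMat <- matrix(NA_real_, nrow = nrow(grid), ncol = length(cases))
  for (ci in seq_along(cases)) {
    res <- .cvEngine(cases[[ci]]$sites, cases[[ci]]$genome, settings,
                     fitConfig = fitConfig,
                     seed = childSeed(seed, 900L, ci), X = X)
    aucMat[, ci] <- res$auc
  }

  nOut <- apply(aucMat, 1L, function(a) {
    q <- quantile(a, c(0.25, 0.75), names = FALSE, type = 7)
    sum(a < q[1L] - 1.5 * (q[2L] - q[1L]))
  })
  grid$meanAUC <- rowMeans(aucMat)
  grid$sdAUC <- apply(aucMat, 1L, sd)
  grid$minAUC <- apply(aucMat, 1L, min)
  grid$nOutliers <- as.integer(nOut)
  grid$stable <- grid$nOutliers <= outlierBudget & grid$minAUC > minWorstAUC

  optimal <- NA_integer_
  if (any(grid$stable)) {
    cand <- which(grid$stable)
    cand <- cand[grid$sdAUC[cand] == min(grid$sdAUC[cand])]
    cand <- cand[grid$meanAUC[cand] == max(grid$meanAUC[cand])]
    optimal <- cand[1L]
  } else {
    warning("no stable setting found")
  }
  structure(list(grid = grid, aucMatrix = aucMat, optimal = optimal,
                 outlierBudget = outlierBudget),
            class = "ScreeningResult")
}

#' @export
print.ScreeningResult <- function(x, ...) {
  cat(sprintf("ScreeningResult: %d settings, %d stable\n",
              nrow(x$grid), sum(x$grid$stable)))
  if (!is.na(x$optimal)) {
    o <- x$grid[x$optimal, ]
    cat(sprintf(
      " optimal: support %.2f, confidence %.2f, correlation %.2f (mean AUC %.4f, sd %.4f)\n",
      o$minSupport, o$minConfidence, o$minCorrelation, o$meanAUC, o$sdAUC))
  }
  invisible(x)
}

#' Correlation between association-feature ratio and binding specificity
#'
#' Pearson correlation between per-model association-feature ratios
#' ([featureRatio()]) and width-normalized information contents
#' ([informationContent()]). A positive value indicates that more
#' specific motifs carry more within-motif dependence.
#'
#' @param ratios numeric vector of association-feature ratios.
#' @param ics numeric vector of width-normalized information contents
#'   (bits/position), same length.
#' @return Pearson correlation; `NaN` with a warning when either input
#'   has zero variance.
#' @export
specificityCorrelation <- function(ratios, ics) {
  stopifnot(length(ratios) == length(ics), length(ratios) >= 3L)
  if (sd(ratios) == 0 || sd(ics) == 0) {
    warning("zero variance: correlation undefined")
    return(NaN)
  }
  cor(ratios, ics)
}

#' Overlap between base-readout positions and association features
#'
#' Compares an annotated set of base-readout positions (protein-base
#' contact positions from a structural study) with the union of motif
#' positions involved in the model's selected association features.
#'
#' @param model an [ELRMModel-class].
#' @param readoutPositions 1-based motif positions with base readout.
#' @return list with `fracReadoutInAssoc` (fraction of readout positions
#'   covered by association features), `fracAssocIsReadout` (fraction of
#'   association-feature positions that are readout; 0 with attribute
#'   `undefined = TRUE` when no association feature is selected),
#'   `assocPositions`.
#' @export
readoutOverlap <- function(model, readoutPositions) {
  readoutPositions <- unique(as.integer(readoutPositions))
  if (any(readoutPositions < 1L | readoutPositions > model@motifLength)) {
    stop("readout positions must lie in 1..L")
  }
  sel <- selectFeatures(model)
  assocPos <- if (nrow(sel$assoc)) {
    sort(unique(unlist(
      model@features$positions[match(sel$assoc$id, model@features$id)])))
  } else integer(0)
  inter <- intersect(readoutPositions, assocPos)
  fr <- if (length(readoutPositions)) {
    length(inter) / length(readoutPositions)
  } else 0
  fa <- if (length(assocPos)) length(inter) / length(assocPos) else {
    structure(0, undefined = TRUE)
  }
  list(fracReadoutInAssoc = fr, fracAssocIsReadout = fa,
       assocPositions = assocPos)
}

#' Positions admitting multiple binding configurations
#'
#' Positions at which the fitted model selected two or more single-base
#' features (e.g. both T7 and C7), indicating alternative bases that each
#' participate in a valid binding configuration.
#'
#' @param model an [ELRMModel-class].
#' @param tolerance passed to [selectFeatures()].
#' @return data.frame with columns `position` (ascending) and `bases`
#'   (comma-joined selected bases); zero rows when every position has at
#'   most one selected base.
#' @export
detectMultiConfig <- function(model, tolerance = 0) {
  sel <- selectFeatures(model, tolerance)$single
  if (!nrow(sel)) {
    return(data.frame(position = integer(0), bases = character(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(sel$position)
  multi <- sort(as.integer(names(tab)[tab >= 2L]))
  data.frame(
    position = multi,
    bases = vapply(multi, function(p) {
      paste(sel$base[sel$position == p], collapse = ",")
    }, ""),
    stringsAsFactors = FALSE)
}

#' Binding-configuration graph of a fitted model
#'
#' Nodes are single-base features (selected ones, plus every member of a
#' selected association feature) with their decoded coefficients;
#' hyperedges are the selected association features (>= 2 endpoints) with
#' their coefficients. The `associated` node flag is a layout hint:
#' associated nodes are conventionally drawn on top, unassociated ones at
#' the bottom.
#'
#' @param model an [ELRMModel-class].
#' @param tolerance passed to [selectFeatures()].
#' @return a `ModelGraph`: list with data.frame `nodes` (`id`, `position`,
#'   `base`, `coefficient`, `associated`) and list `hyperedges` (each with
#'   `id`, `members`, `coefficient`).
#' @export
exportGraph <- function(model, tolerance = 0) {
  sel <- selectFeatures(model, tolerance)
  edges <- lapply(seq_len(nrow(sel$assoc)), function(i) {
    id <- sel$assoc$id[i]
    fi <- match(id, model@features$id)
    list(id = id, members = itemLabel(model@features$items[[fi]]),
         coefficient = sel$assoc$coefficient[i])
  })
  edgeMembers <- unique(unlist(lapply(edges, `[[`, "members")))
  nodeIds <- union(sel$single$label, edgeMembers)
  if (length(nodeIds)) {
    codes <- parseItemLabel(nodeIds)
    nodes <- data.frame(
      id = nodeIds,
      position = itemPosition(codes),
      base = DNA_BASES4[itemBase(codes)],
      coefficient = model@decoded[cbind(itemPosition(codes),
                                        itemBase(codes))],
      associated = nodeIds %in% edgeMembers,
      stringsAsFactors = FALSE)
    nodes <- nodes[order(nodes$position, nodes$base), , drop = FALSE]
    rownames(nodes) <- NULL
  } else {
    nodes <- data.frame(id = character(0), position = integer(0),
                        base = character(0), coefficient = numeric(0),
                        associated = logical(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, hyperedges = edges), class = "ModelGraph")
}

#' @export
print.ModelGraph <- function(x, ...) {
  cat(sprintf("ModelGraph: %d nodes, %d hyperedge(s)\n",
              nrow(x$nodes), length(x$hyperedges)))
  invisible(x)
}

#' Serialize a binding-configuration graph
#'
#' `graphToJSON`/`graphFromJSON` round-trip exactly; `graphToDOT` writes
#' a Graphviz representation in which each hyperedge is expanded through
#' a star node connected to its member single-base features.
#'
#' @param graph a `ModelGraph` from [exportGraph()].
#' @param path optional path; when given, the serialization is written
#'   there and the path returned invisibly.
#' @return JSON string / DOT string (or the path).
#' @export
graphToJSON <- function(graph, path = NULL) {
  js <- jsonlite::toJSON(
    list(nodes = graph$nodes, hyperedges = graph$hyperedges),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  js
}

#' @rdname graphToJSON
#' @param json JSON string or path to a JSON file.
#' @export
graphFromJSON <- function(json) {
  o <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  nodes <- as.data.frame(lapply(o$nodes, unlist),
                         stringsAsFactors = FALSE)
  if (!nrow(nodes)) {
    nodes <- data.frame(id = character(0), position = integer(0),
                        base = character(0), coefficient = numeric(0),
                        associated = logical(0), stringsAsFactors = FALSE)
  } else {
    nodes$position <- as.integer(nodes$position)
  }
  edges <- lapply(o$hyperedges, function(e) {
    list(id = e$id, members = unlist(e$members),
         coefficient = as.numeric(e$coefficient))
  })
  structure(list(nodes = nodes, hyperedges = edges), class = "ModelGraph")
}

#' @rdname graphToJSON
#' @export
graphToDOT <- function(graph, path = NULL) {
  esc <- function(x) gsub('"', '\\\\"', x)
  lines <- c("graph elrm {", "  node [shape=box];")
  for (i in seq_len(nrow(graph$nodes))) {
    n <- graph$nodes[i, ]
    lines <- c(lines, sprintf('  "%s" [label="%s\\n%.3f"%s];',
                              esc(n$id), esc(n$id), n$coefficient,
                              if (!n$associated) ", rank=sink" else ""))
  }
  for (e in graph$hyperedges) {
    star <- sprintf("assoc_%s", gsub("[^A-Za-z0-9]", "_", e$id))
    lines <- c(lines,
               sprintf('  "%s" [shape=point, xlabel="%.3f"];', star,
                       e$coefficient),
               sprintf('  "%s" -- "%s";', star, esc(e$members)))
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(path))
  }
  dot
}
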