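#' Mine association features from candidate sequences
#'
#' Runs the mining stage: itemize the candidate (genome-scan hit)
#' sequences, mine frequent itemsets, derive positive and negative
#' association rules, and integrate them into association features.
#'
#' @param candidates character vector of equal-length candidate sequences
#'   (typically [uniqueHitSequences()] of a score > 0 scan).
#' @param minSupport minimum itemset support (optimal published setting
#'   0.2).
#' @param minConfidence minimum rule confidence `mc` (optimal 0.6).
#' @param minCorrelation minimum correlation strength `MCS` (optimal 0.1).
#' @param maxItemsetSize cap on itemset size (default 6).
#' @param polarities rule polarities to mine (default all four).
#' @return list with `frequents`, `rules`, `features`.
#' @export
mineFeatures <- function(candidates, minSupport = 0.2, minConfidence = 0.6,
                         minCorrelation = 0.1, maxItemsetSize = 6L,
                         polarities = RULE_POLARITIES) {
  if (!length(candidates)) {
    noFreq <- data.frame(id = character(0), size = integer(0),
                         support = numeric(0), items = I(list()),
                         stringsAsFactors = FALSE)
    noRules <- data.frame(baseId = character(0), antecedent = character(0),
                          consequent = character(0), polarity = character(0),
                          support = numeric(0), confidence = numeric(0),
                          correlation = numeric(0), itemsA = I(list()),
                          itemsB = I(list()), stringsAsFactors = FALSE)
    return(list(frequents = noFreq, rules = noRules,
                features = integrateFeatures(noRules)))
  }
  db <- itemize(candidates)
  frequents <- apriori(db, minSupport, maxSize = maxItemsetSize)
  rules <- deriveRules(frequents, db, mc = minConfidence,
                       MCS = minCorrelation, polarities = polarities)
  list(frequents = frequents, rules = rules,
       features = integrateFeatures(rules))
}

#' Train a complete binding-motif model from sites and a genome
#'
#' The full workflow: build the PWM from the positive set, estimate the
#' first-order Markov background, scan the genome on both strands, mine
#' association features from the unique score > 0 hit sequences, build
#' the 30X negative set (10X column-permuted-PWM hits, 10X GC-matched
#' random sequences, 10X low-scoring genomic windows), code everything
#' into the design matrix, and fit the elastic-net regularized logistic
#' regression.
#'
#' @param sites a [BindingSiteSet-class] (the positive set).
#' @param genome a [GenomeSeq-class].
#' @param minSupport,minConfidence,minCorrelation mining thresholds.
#' @param X negatives per positive per pool (default 10, giving 30X).
#' @param fitConfig a [FitConfig-class].
#' @param seed master seed for all randomness (permutation choice,
#'   negative sampling, CV folds).
#' @param maxItemsetSize cap on mined itemset size.
#' @param bg optional precomputed [MarkovBackground-class].
#' @param verbose emit per-stage counts.
#' @return list with `model` ([ELRMModel-class]), `design`
#'   ([DesignMatrix-class]), `pwm`, `bg`, `features`, `rules`,
#'   `frequents`, and `nHits`.
#' @examples
#' case <- generateSyntheticCase(width = 10, nSites = 30, genomeLen = 2e4,
#'                               seed = 7)
#' fit <- trainELRM(case$sites, case$genome, seed = 7)
#' fit$model
#' @export
trainELRM <- function(sites, genome, minSupport = 0.2, minConfidence = 0.6,
                      minCorrelation = 0.1, X = 10L,
                      fitConfig = FitConfig(), seed = 1L,
                      maxItemsetSize = 6L, bg = NULL, verbose = FALSE) {
  bg <- bg %||% estimateBackground(genome)
  pwm <- buildPWM(sites)
  hits <- scanGenome(pwm, bg, genome, minScore = 0)
  cand <- uniqueHitSequences(hits)
  mined <- mineFeatures(cand, minSupport, minConfidence, minCorrelation,
                        maxItemsetSize)
  if (verbose) {
    message(sprintf(
      "scan: %d hits, %d unique; mining: %d frequent itemsets, %d rules, %d features",
      length(hits), length(cand), nrow(mined$frequents),
      nrow(mined$rules), nrow(mined$features)))
  }
  nPos <- length(sites)
  negP <- negativesPermuted(pwm, bg, genome, nPos, X = X,
                            seed = childSeed(seed, 1L))
  negG <- negativesGCRandom(sites, X = X, seed = childSeed(seed, 2L))
  negL <- negativesLowScore(pwm, bg, genome, nPos, X = X,
                            seed = childSeed(seed, 3L))
  design <- assembleDesign(sites, mined$features, negP, negG, negL, X = X)
  if (verbose) show(design)
  cfg <- fitConfig
  cfg@seed <- childSeed(seed, 4L)
  model <- fitELRM(design, cfg)
  list(model = model, design = design, pwm = pwm, bg = bg,
       features = mined$features, rules = mined$rules,
       frequents = mined$frequents, nHits = length(hits))
}
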