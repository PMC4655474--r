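#' Fit configuration for the elastic-net regularized logistic regression
#'
#' @slot alpha elastic-net mixing parameter in `[0, 1]`; the default 0.5
#'   balances lasso selection against ridge retention of correlated
#'   feature groups.
#' @slot nLambda number of penalty values on the descending geometric grid.
#' @slot lambdaMinRatio smallest lambda as a fraction of the
#'   all-coefficients-zero lambda; `NA` defers to the fitting backend's
#'   dimension-dependent default (1e-4, or 1e-2 when columns exceed rows).
#' @slot cvFolds cross-validation folds for the lambda choice (>= 2).
#' @slot seed integer seed controlling fold assignment.
#' @slot standardize standardize predictors internally during fitting
#'   (coefficients are always reported on the original coding scale).
#' @slot thresh coordinate-descent convergence threshold. The default
#'   1e-6 is tighter than needed for stable feature selection on these
#'   designs while avoiding excessive iteration in the dense low-lambda
#'   tail of the path.
#' @seealso [fitELRM()]
#' @export
setClass("FitConfig",
  representation(alpha = "numeric", nLambda = "integer",
                 lambdaMinRatio = "numeric", cvFolds = "integer",
                 seed = "integer", standardize = "logical",
                 thresh = "numeric"))

setValidity("FitConfig", function(object) {
  if (object@alpha < 0 || object@alpha > 1) return("alpha must be in [0,1]")
  if (object@cvFolds < 2L) return("cvFolds must be >= 2")
  TRUE
})

#' @describeIn FitConfig constructor with the package defaults.
#' @param alpha,nLambda,lambdaMinRatio,cvFolds,seed,standardize see slots.
#' @export
FitConfig <- function(alpha = 0.5, nLambda = 100L, lambdaMinRatio = NA_real_,
                      cvFolds = 10L, seed = 1L, standardize = TRUE,
                      thresh = 1e-6) {
  new("FitConfig", alpha = alpha, nLambda = as.integer(nLambda),
      lambdaMinRatio = lambdaMinRatio, cvFolds = as.integer(cvFolds),
      seed = as.integer(seed), standardize = standardize, thresh = thresh)
}

#' Elastic-net regularized logistic regression model of a binding motif
#'
#' Holds the fitted intercept and coefficients over the 3L coded
#' single-base features and K association features, the decoded L x 4
#' per-base coefficient matrix (rows sum to 0 by the decode identity),
#' and the selected features.
#'
#' @slot intercept unpenalized intercept.
#' @slot betaZ coefficients of the 3L coded single-base features.
#' @slot betaA coefficients of the K association features.
#' @slot decoded L x 4 matrix of decoded per-base coefficients.
#' @slot alpha,lambdaOpt mixing parameter and the penalty minimizing mean
#'   CV deviance.
#' @slot features association-feature table used at training.
#' @slot motifLength L.
#' @slot cvMeanError mean cross-validated deviance along the lambda path.
#' @slot lambdaPath the fitted lambda grid (descending).
#' @slot nonzeroPath number of nonzero penalized coefficients per lambda.
#' @seealso [fitELRM()], [selectFeatures()], [predictProbability()]
#' @export
setClass("ELRMModel",
  representation(intercept = "numeric", betaZ = "numeric", betaA = "numeric",
                 decoded = "matrix", alpha = "numeric", lambdaOpt = "numeric",
                 features = "data.frame", motifLength = "integer",
                 cvMeanError = "numeric", lambdaPath = "numeric",
                 nonzeroPath = "integer"))

setMethod("show", "ELRMModel", function(object) {
  sel <- selectFeatures(object)
  cat(sprintf(
    "ELRMModel: width %d, alpha %.2f, lambda %.4g\n  selected: %d single-base, %d association feature(s); ratio %.3f\n",
    object@motifLength, object@alpha, object@lambdaOpt,
    nrow(sel$single), nrow(sel$assoc), featureRatio(object)))
})

#' @rdname motifWidth
#' @export
setMethod("motifWidth", "ELRMModel", function(x) x@motifLength)

## stratified fold ids, deterministic given seed
.strataFolds <- function(y, k, seed) {
  foldid <- integer(length(y))
  withSeed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  foldid
}

#' Fit the elastic-net regularized logistic regression
#'
#' Minimizes the penalized negative binomial log-likelihood with penalty
#' `lambda * ((1 - alpha)/2 ||beta||_2^2 + alpha ||beta||_1)` (intercept
#' unpenalized) along a descending geometric lambda grid, choosing the
#' lambda with minimum mean cross-validated deviance (ties resolve to the
#' larger, i.e. sparser, lambda). Folds are stratified on the labels —
#' with 30 negatives per positive unstratified folds can lose the
#' positive class entirely.
#'
#' @param design a [DesignMatrix-class].
#' @param config a [FitConfig-class].
#' @return an [ELRMModel-class].
#' @export
fitELRM <- function(design, config = FitConfig()) {
  y <- design@y
  if (length(unique(y)) < 2L) stop("both labels must be present")
  x <- design@x
  L <- design@motifLength
  K <- nrow(design@features)
  foldid <- .strataFolds(y, config@cvFolds, config@seed)
  xs <- Matrix::Matrix(x, sparse = TRUE)  # assoc block is sparse
  args <- list(x = xs, y = y, family = "binomial", alpha = config@alpha,
               nlambda = config@nLambda, standardize = config@standardize,
               foldid = foldid, type.measure = "deviance",
               thresh = config@thresh)
  if (!is.na(config@lambdaMinRatio)) {
    args$lambda.min.ratio <- config@lambdaMinRatio
  }
  cvfit <- do.call(glmnet::cv.glmnet, args)
  lambdaOpt <- cvfit$lambda.min  # largest lambda at the CV minimum
  beta <- as.numeric(coef(cvfit, s = lambdaOpt))
  intercept <- beta[1L]
  betaZ <- beta[1L + seq_len(3L * L)]
  betaA <- if (K) beta[1L + 3L * L + seq_len(K)] else numeric(0)
  new("ELRMModel",
      intercept = intercept, betaZ = betaZ, betaA = betaA,
      decoded = decodeCoefficients(betaZ),
      alpha = config@alpha, lambdaOpt = lambdaOpt,
      features = design@features, motifLength = L,
      cvMeanError = cvfit$cvm, lambdaPath = cvfit$lambda,
      nonzeroPath = as.integer(cvfit$nzero))
}

#' Decode coded single-base coefficients to per-base coefficients
#'
#' Inverts the sum-to-zero dummy coding: with the three coefficients
#' `(b1, b2, b3)` of position p, the per-base coefficients are
#' `a_A = b1`, `a_C = b2`, `a_G = b3`, `a_T = -(b1 + b2 + b3)` — the
#' inner product of each base's code with the position's coefficients.
#' Every decoded row sums to exactly 0.
#'
#' @param betaZ numeric vector of length 3L.
#' @return L x 4 matrix (columns A,C,G,T).
#' @export
decodeCoefficients <- function(betaZ) {
  L <- length(betaZ) / 3L
  if (L != as.integer(L)) stop("betaZ length must be a multiple of 3")
  L <- as.integer(L)
  b <- matrix(betaZ, nrow = L, ncol = 3L, byrow = TRUE)
  aT <- -(b[, 1L] + b[, 2L] + b[, 3L])
  out <- cbind(b, aT)
  colnames(out) <- DNA_BASES4
  out
}

#' Selected (nonzero-coefficient) features of a fitted model
#'
#' Features with zero coefficients are irrelevant and discarded.
#' Single-base features are counted on the decoded per-base scale (as
#' drawn in a binding-configuration graph), association features on
#' their own coefficients.
#'
#' @param model an [ELRMModel-class].
#' @param tolerance magnitude at or below which a coefficient counts as
#'   zero (default 0: strict).
#' @return list with data.frames `single` (columns `position`, `base`,
#'   `coefficient`, `label`) and `assoc` (columns `id`, `coefficient`).
#' @export
selectFeatures <- function(model, tolerance = 0) {
  d <- model@decoded
  hit <- which(abs(d) > tolerance, arr.ind = TRUE)
  single <- data.frame(
    position = as.integer(hit[, 1L]),
    base = DNA_BASES4[hit[, 2L]],
    coefficient = d[hit],
    stringsAsFactors = FALSE)
  single <- single[order(single$position, single$base), , drop = FALSE]
  single$label <- paste0(single$base, single$position)
  rownames(single) <- NULL
  ai <- which(abs(model@betaA) > tolerance)
  assoc <- data.frame(
    id = model@features$id[ai],
    coefficient = model@betaA[ai],
    stringsAsFactors = FALSE)
  list(single = single, assoc = assoc)
}

#' Predicted binding probability of a sequence
#'
#' Codes the sequence exactly as at training (dummy + association codes)
#' and applies the logistic function to the linear predictor.
#'
#' @param model an [ELRMModel-class].
#' @param sequence DNA string of the motif width.
#' @return probability in (0, 1).
#' @export
predictProbability <- function(model, sequence) {
  if (any(nchar(sequence) != model@motifLength)) {
    stop("sequence length must equal the motif width")
  }
  z <- dummyCode(sequence)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  eta <- model@intercept + drop(z %*% model@betaZ)
  if (nrow(model@features)) {
    a <- associationCode(sequence, model@features)
    if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
    eta <- eta + drop(a %*% model@betaA)
  }
  unname(sigmoid(eta))
}

#' Ratio of association features among selected features
#'
#' `|selected association| / (|selected association| + |selected
#' single-base|)`; 0 when nothing is selected. Across a panel of motifs
#' this ratio tracks binding specificity (width-normalized information
#' content).
#'
#' @param model an [ELRMModel-class].
#' @param tolerance passed to [selectFeatures()].
#' @return numeric in `[0, 1]`.
#' @export
featureRatio <- function(model, tolerance = 0) {
  sel <- selectFeatures(model, tolerance)
  nA <- nrow(sel$assoc)
  nS <- nrow(sel$single)
  if (nA + nS == 0L) return(0)
  nA / (nA + nS)
}

#' Count of selected features relative to the PWM parameterization
#'
#' Selected features (single-base + association) divided by the number
#' of PWM parameters; the denominator is configurable between the 3L
#' free parameters of the sum-to-zero coding and the 4L probability
#' cells.
#'
#' @param model an [ELRMModel-class].
#' @param denominator `"3L"` (default) or `"4L"`.
#' @return numeric ratio.
#' @export
featureCountVsPWM <- function(model, denominator = c("3L", "4L")) {
  denominator <- match.arg(denominator)
  sel <- selectFeatures(model)
  denom <- if (denominator == "3L") 3L * model@motifLength
           else 4L * model@motifLength
  (nrow(sel$single) + nrow(sel$assoc)) / denom
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model an [ELRMModel-class].
#' @param path file path.
#' @return `readELRMModel` returns an [ELRMModel-class].
#' @export
writeELRMModel <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model@intercept, betaZ = model@betaZ,
         betaA = model@betaA, alpha = model@alpha,
         lambdaOpt = model@lambdaOpt, motifLength = model@motifLength,
         features = list(id = model@features$id,
                         items = lapply(model@features$items, itemLabel)),
         lambdaPath = model@lambdaPath, cvMeanError = model@cvMeanError,
         nonzeroPath = model@nonzeroPath),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeELRMModel
#' @export
readELRMModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  o$intercept <- unlist(o$intercept)
  o$betaZ <- unlist(o$betaZ)
  o$betaA <- unlist(o$betaA)
  o$alpha <- unlist(o$alpha)
  o$lambdaOpt <- unlist(o$lambdaOpt)
  o$motifLength <- unlist(o$motifLength)
  o$cvMeanError <- unlist(o$cvMeanError)
  o$lambdaPath <- unlist(o$lambdaPath)
  o$nonzeroPath <- unlist(o$nonzeroPath)
  o$features$id <- unlist(o$features$id)
  items <- lapply(o$features$items, function(x) parseItemLabel(unlist(x)))
  feats <- data.frame(
    id = as.character(o$features$id %||% character(0)),
    size = vapply(items, length, integer(1)),
    nRules = rep(NA_integer_, length(items)),
    items = I(items),
    positions = I(lapply(items, itemPosition)),
    stringsAsFactors = FALSE)
  betaZ <- as.numeric(o$betaZ)
  new("ELRMModel",
      intercept = as.numeric(o$intercept), betaZ = betaZ,
      betaA = as.numeric(o$betaA %||% numeric(0)),
      decoded = decodeCoefficients(betaZ),
      alpha = as.numeric(o$alpha), lambdaOpt = as.numeric(o$lambdaOpt),
      features = feats, motifLength = as.integer(o$motifLength),
      cvMeanError = as.numeric(o$cvMeanError),
      lambdaPath = as.numeric(o$lambdaPath),
      nonzeroPath = as.integer(o$nonzeroPath))
}
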