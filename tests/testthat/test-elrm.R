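test_that("coefficient decoding is the coding-table inner product", {
  expect_equal(unname(decodeCoefficients(c(1, 0, 0))[1, ]),
               c(1, 0, 0, -1))
  expect_equal(unname(decodeCoefficients(c(0, 0, 0))[1, ]),
               c(0, 0, 0, 0))
  expect_equal(unname(decodeCoefficients(c(1, 1, 1))[1, ]),
               c(1, 1, 1, -3))
  ## decoded rows sum to exactly zero, including for irrational inputs
  set.seed(8)
  b <- rnorm(3 * 7)
  d <- decodeCoefficients(b)
  expect_identical(d[, 1] + d[, 2] + d[, 3] + d[, 4], rep(0, 7))
  expect_error(decodeCoefficients(rnorm(7)), "multiple of 3")
})

test_that("feature selection and ratio follow the zero-discard rule", {
  ## nothing selected from an all-zero model
  z <- manualModel(decodeCoefficients(rep(0, 12)))
  expect_equal(nrow(selectFeatures(z)$single), 0L)
  expect_equal(featureRatio(z), 0)

  ## hand-built model: 2 single-base features, 1 association feature
  dec <- decodeCoefficients(c(1.5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  m <- manualModel(dec, betaA = c(0.7),
                   featureIds = "C2:G3",
                   featureItems = list(c(6L, 11L)))
  sel <- selectFeatures(m)
  ## position 1 decodes to A = 1.5 and T = -1.5
  expect_setequal(sel$single$label, c("A1", "T1"))
  expect_equal(sel$assoc$id, "C2:G3")
  expect_equal(featureRatio(m), 1 / 3)
  ## infinite tolerance discards everything
  selInf <- selectFeatures(m, tolerance = Inf)
  expect_equal(nrow(selInf$single) + nrow(selInf$assoc), 0L)

  ## published-style counts: 25 association, 0 single-base -> ratio 1
  m25 <- manualModel(decodeCoefficients(rep(0, 12)), betaA = rep(1, 25),
                     featureIds = sprintf("A1:C%d", 2:26),
                     featureItems = lapply(2:26, function(p)
                       sort(c(1L, (p - 1L) * 4L + 2L))))
  expect_equal(featureRatio(m25), 1)
})

test_that("prediction applies the logistic to the training coding", {
  zero <- manualModel(decodeCoefficients(rep(0, 12)))
  expect_equal(predictProbability(zero, "ACGT"), 0.5)
  expect_equal(predictProbability(zero, "TTTT"), 0.5)

  ## model with one dominant association feature A2:C3
  m <- manualModel(decodeCoefficients(rep(0, 12)), betaA = 4,
                   featureIds = "A2:C3", featureItems = list(c(5L, 10L)),
                   intercept = -2)
  pOn <- predictProbability(m, "TACT")
  pOff <- predictProbability(m, "TGCT")  # break the feature at position 2
  expect_equal(pOn, plogis(2))
  expect_equal(pOff, plogis(-2))
  expect_lt(pOff, pOn)
  ## invariance on positions with zero coefficients
  expect_equal(predictProbability(m, "AACG"), predictProbability(m, "CACC"))
  expect_error(predictProbability(m, "ACGTA"), "motif width")
})

## one small but real fit shared by several checks (memoized)
fitSmall <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      case <- smallDepCase(seed = 21, nSites = 80, genomeLen = 25000)
      memo <<- suppressWarnings(suppressMessages(
        trainELRM(case$sites, case$genome, seed = 21)))
    }
    memo
  }
})

test_that("the elastic-net fit recovers planted dependence", {
  fit <- fitSmall()
  model <- fit$model
  expect_s4_class(model, "ELRMModel")
  expect_true(plantedSelected(model, c(3, 8)))
  ## planted association outweighs any single-base effect at its positions
  sel <- selectFeatures(model)
  idx <- match(sel$assoc$id, model@features$id)
  covers <- vapply(model@features$positions[idx],
                   function(p) all(c(3, 8) %in% p), logical(1))
  expect_gt(max(abs(sel$assoc$coefficient[covers])),
            max(abs(model@decoded[c(3, 8), ])))
  ## mutating a planted-dependence position lowers the probability
  pos1 <- fit$design@sequences[designY(fit$design) == 1][1]
  mut <- pos1
  substr(mut, 3, 3) <- if (substr(pos1, 3, 3) == "C") "G" else "C"
  expect_lt(predictProbability(model, mut),
            predictProbability(model, pos1))
})

test_that("decode identity holds on fitted models", {
  fit <- fitSmall()
  d <- fit$model@decoded
  expect_identical(d[, 1] + d[, 2] + d[, 3] + d[, 4],
                   rep(0, nrow(d)))
})

test_that("the penalty path starts empty and the null model is prevalence", {
  fit <- fitSmall()
  model <- fit$model
  ## at the largest lambda all penalized coefficients are zero
  expect_equal(model@nonzeroPath[1], 0L)
  ## glmnet reports the intercept-only deviance at that point; the
  ## corresponding intercept equals the logit of class prevalence
  y <- designY(fit$design)
  x <- designX(fit$design)
  path <- glmnet::glmnet(x, y, family = "binomial", alpha = 0.5,
                         lambda = model@lambdaPath[1])
  expect_equal(as.numeric(path$a0), qlogis(mean(y)), tolerance = 1e-4)
  expect_equal(as.numeric(path$beta), rep(0, ncol(x)))
})

test_that("permuted labels select almost nothing", {
  case <- smallDepCase(seed = 30, nSites = 60, genomeLen = 2e4)
  fit <- suppressWarnings(suppressMessages(
    trainELRM(case$sites, case$genome, seed = 30)))
  x <- designX(fit$design)
  fracs <- numeric(10)
  for (i in 1:10) {
    set.seed(100 + i)
    yperm <- sample(designY(fit$design))
    dperm <- new("DesignMatrix", x = x, y = yperm,
                 sequences = fit$design@sequences,
                 provenance = provenance(fit$design),
                 motifLength = motifWidth(fit$design),
                 features = fit$design@features,
                 shortfall = fit$design@shortfall)
    mp <- suppressWarnings(fitELRM(dperm, FitConfig(seed = i)))
    sel <- selectFeatures(mp)
    ## count on the coded scale: nonzero penalized coefficients
    fracs[i] <- (sum(mp@betaZ != 0) + sum(mp@betaA != 0)) / ncol(x)
  }
  expect_lt(mean(fracs), 0.05)
})

test_that("lasso drops duplicated columns that ridge keeps", {
  set.seed(77)
  n <- 300
  informative <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 2.5 * informative))
  x <- cbind(dup1 = informative, dup2 = informative,
             noise = matrix(rnorm(n * 3), n))
  lasso <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                             nfolds = 5)
  bl <- as.numeric(coef(lasso, s = lasso$lambda.min))[2:3]
  ridge <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                             nfolds = 5)
  br <- as.numeric(coef(ridge, s = ridge$lambda.min))[2:3]
  ## ridge spreads weight evenly over the duplicates
  expect_equal(br[1], br[2], tolerance = 0.01)
  expect_true(all(br != 0))
  ## lasso concentrates it (possibly entirely on one)
  expect_lt(min(abs(bl)), 0.05 * max(abs(bl)) + 1e-8)
})

test_that("model JSON round trip preserves the fit", {
  fit <- fitSmall()
  f <- tempfile(fileext = ".json")
  writeELRMModel(fit$model, f)
  back <- readELRMModel(f)
  expect_equal(back@intercept, fit$model@intercept)
  expect_equal(back@betaZ, fit$model@betaZ)
  expect_equal(back@betaA, fit$model@betaA)
  expect_equal(back@decoded, fit$model@decoded)
  expect_identical(back@features$id, fit$model@features$id)
  s <- fit$design@sequences[1]
  expect_equal(predictProbability(back, s),
               predictProbability(fit$model, s))
})

test_that("fitting refuses degenerate designs", {
  positives <- BindingSiteSet(c("ACGT", "ACGG", "ACGT"))
  feats <- data.frame(id = character(0), size = integer(0),
                      nRules = integer(0), items = I(list()),
                      positions = I(list()), stringsAsFactors = FALSE)
  d <- suppressMessages(assembleDesign(positives, feats,
                                       c("TTTT", "GGGG"), character(0),
                                       character(0)))
  dOne <- new("DesignMatrix", x = designX(d), y = rep(1L, nrow(designX(d))),
              sequences = d@sequences, provenance = provenance(d),
              motifLength = 4L, features = feats,
              shortfall = d@shortfall)
  expect_error(fitELRM(dOne), "both labels")
})
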