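## the worked 4-transaction database: items A1,C2 stand in for the
## single-base features at two motif positions
workedDb <- function() itemize(c("AC", "AC", "AG", "TC"))

test_that("itemization is definitional and keeps multiplicity", {
  db <- itemize(c("ACG"))
  expect_equal(db$n, 1L)
  expect_equal(db$L, 3L)
  expect_equal(itemSupport("A1", db), 1)
  expect_equal(itemSupport("C2", db), 1)
  expect_equal(itemSupport("G3", db), 1)
  expect_equal(itemSupport("G1", db), 0)

  dup <- itemize(rep("ACGT", 100))
  expect_equal(dup$n, 100L)
  expect_equal(itemSupport(c("A1", "T4"), dup), 1)

  expect_error(itemize(character(0)), "no sequences")
  expect_error(itemize(c("")), "empty")
  expect_error(itemize(c("AC", "ACG")), "equal length")
})

test_that("support is the containment proportion", {
  db <- itemize(c("AC", "AG"))
  expect_equal(itemSupport("A1", db), 1.0)
  expect_equal(itemSupport("C2", db), 0.5)
  expect_equal(itemSupport("T1", db), 0.0)
  ## two items at one position can never co-occur
  expect_equal(itemSupport(c("A1", "C1"), db), 0.0)
  expect_error(itemSupport(integer(0), db), "nonempty")
})

test_that("apriori reproduces the worked example exactly", {
  fr <- apriori(workedDb(), minSupport = 0.5)
  expect_setequal(fr$id, c("A1", "C2", "A1:C2"))
  expect_equal(fr$support[fr$id == "A1"], 0.75)
  expect_equal(fr$support[fr$id == "C2"], 0.75)
  expect_equal(fr$support[fr$id == "A1:C2"], 0.5)
  ## support above the best singleton leaves nothing
  expect_equal(nrow(apriori(workedDb(), minSupport = 0.8)), 0L)
})

test_that("apriori equals exhaustive enumeration on random databases", {
  set.seed(101)
  for (trial in 1:40) {
    L <- sample(2:6, 1)
    n <- sample(5:60, 1)
    mat <- randomDbMat(n, L)
    ms <- runif(1, 0.1, 0.5)
    got <- apriori(dbFromMat(mat), ms)
    want <- bruteFrequentItemsets(mat, ms)
    gotKeys <- vapply(got$items, paste, "", collapse = ",")
    wantKeys <- vapply(want$items, paste, "", collapse = ",")
    expect_identical(sort(gotKeys), sort(wantKeys))
    ## supports agree item-for-item
    expect_equal(got$support[order(gotKeys)], want$support[order(wantKeys)])
  }
})

test_that("frequent itemsets shrink as minimum support rises", {
  set.seed(7)
  mat <- randomDbMat(50, 5)
  db <- dbFromMat(mat)
  counts <- vapply(c(0.1, 0.15, 0.2),
                   function(ms) nrow(apriori(db, ms)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  ## and no frequent itemset ever repeats a position
  fr <- apriori(db, 0.1)
  for (s in fr$items) {
    pos <- (s - 1L) %/% 4L + 1L
    expect_false(anyDuplicated(pos) > 0)
  }
})

test_that("confidence and phi correlation match direct probability", {
  db <- workedDb()
  m <- ruleMeasures("A1", "C2", db)
  expect_equal(m$confidence, 2 / 3, tolerance = 1e-12)
  expect_equal(m$correlation, -1 / 3, tolerance = 1e-12)
  ## symmetry of phi
  expect_equal(ruleMeasures("C2", "A1", db)$correlation, m$correlation)
  ## bounds
  expect_gte(m$confidence, 0); expect_lte(m$confidence, 1)
  expect_gte(m$correlation, -1); expect_lte(m$correlation, 1)
  expect_error(ruleMeasures("G1", "C2", db), "sup\\(A\\) = 0")
  expect_error(ruleMeasures("A1", "A1", db), "disjoint")
})

test_that("independent items have near-zero correlation", {
  set.seed(33)
  s <- paste0(sample(c("A", "G"), 1e4, TRUE, c(0.5, 0.5)),
              sample(c("C", "T"), 1e4, TRUE, c(0.4, 0.6)))
  db <- itemize(s)
  expect_lt(abs(ruleMeasures("A1", "C2", db)$correlation), 0.05)
})

test_that("rule derivation matches the exhaustive bipartition oracle", {
  set.seed(202)
  for (trial in 1:30) {
    L <- sample(2:5, 1)
    n <- sample(8:50, 1)
    mat <- randomDbMat(n, L)
    db <- dbFromMat(mat)
    ms <- runif(1, 0.15, 0.4)
    mc <- runif(1, 0.4, 0.9)
    MCS <- runif(1, 0, 0.3)
    fr <- apriori(db, ms)
    got <- deriveRules(fr, db, mc = mc, MCS = MCS)
    want <- bruteRules(bruteFrequentItemsets(mat, ms), mat, mc, MCS)
    expect_identical(ruleKeys(got), want)
  }
})

test_that("rule validity respects the threshold semantics", {
  ## C2 always accompanies A1 -> conf(A1 -> C2) = 1
  db <- itemize(c("AC", "AC", "AC", "TC", "TG"))
  fr <- apriori(db, 0.3)
  rules <- deriveRules(fr, db, mc = 0.95, MCS = 0)
  posRules <- rules[rules$polarity == "A->B", ]
  expect_true("A1" %in% posRules$antecedent[posRules$consequent == "C2"])
  ## MCS = 1 keeps only perfectly correlated pairs
  perfect <- itemize(c("AC", "AC", "TG", "TG"))
  frp <- apriori(perfect, 0.3)
  rp <- deriveRules(frp, perfect, mc = 0.5, MCS = 1)
  expect_true(all(abs(rp$correlation) == 1))
  expect_gt(nrow(rp), 0)
  rnone <- deriveRules(fr, db, mc = 0.5, MCS = 1)
  expect_true(all(abs(rnone$correlation) == 1))
})

test_that("negative-rule confidences use complemented events", {
  db <- workedDb()
  fr <- apriori(db, 0.2)
  rules <- deriveRules(fr, db, mc = 0.01, MCS = 0)
  r <- rules[rules$antecedent == "A1" & rules$consequent == "C2", ]
  getConf <- function(pol) r$confidence[r$polarity == pol]
  ## sup(A1)=0.75, sup(C2)=0.75, sup(X)=0.5
  expect_equal(getConf("A->B"), 0.5 / 0.75)
  expect_equal(getConf("A->!B"), 0.25 / 0.75)
  expect_equal(getConf("!A->B"), 0.25 / 0.25)
  expect_length(getConf("!A->!B"), 0)  # zero confidence is never valid
  ## sign convention: mixed polarities flip the phi sign
  expect_equal(r$correlation[r$polarity == "A->B"], -1 / 3)
  expect_equal(r$correlation[r$polarity == "A->!B"], 1 / 3)
})

test_that("feature integration groups rules by base itemset", {
  db <- itemize(c("ACCA", "ACCA", "ACCG", "TCCA", "ACGA"))
  fr <- apriori(db, 0.2)
  rules <- deriveRules(fr, db, mc = 0.5, MCS = 0.05)
  feats <- integrateFeatures(rules)
  ## one feature per distinct base itemset
  expect_equal(nrow(feats), length(unique(rules$baseId)))
  expect_false(anyDuplicated(feats$id) > 0)
  expect_true(all(feats$size >= 2))
  ## empty input gives an empty table
  expect_equal(nrow(integrateFeatures(rules[0, ])), 0L)
})

test_that("planted dependence yields a feature covering its positions", {
  case <- generateSyntheticCase(
    width = 12, nSites = 200, genomeLen = 3e4,
    dependencySpec = list(list(positions = c(2, 5),
                               patterns = c("CG", "AT"),
                               probs = c(0.5, 0.5))),
    seed = 13)
  bg <- estimateBackground(case$genome)
  pwm <- buildPWM(case$sites)
  cand <- uniqueHitSequences(scanGenome(pwm, bg, case$genome, 0))
  mined <- suppressWarnings(
    mineFeatures(cand, minSupport = 0.2, minConfidence = 0.6,
                 minCorrelation = 0.1))
  covers <- vapply(mined$features$positions,
                   function(p) all(c(2, 5) %in% p), logical(1))
  expect_true(any(covers))
})
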