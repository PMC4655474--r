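uniformBg <- function() {
  new("MarkovBackground", initial = rep(0.25, 4),
      transition = matrix(0.25, 4, 4))
}

test_that("background estimation recovers transition structure", {
  g <- GenomeSeq(strrep("AC", 5000))
  bg <- estimateBackground(g)
  expect_gt(bg@transition["A", "C"], 0.99)
  expect_gt(bg@transition["C", "A"], 0.99)
  expect_equal(rowSums(bg@transition), rep(1, 4), ignore_attr = TRUE)

  set.seed(1)
  giid <- GenomeSeq(paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
                          collapse = ""))
  bgiid <- estimateBackground(giid)
  expect_true(all(abs(bgiid@transition - 0.25) < 0.02))
  expect_true(all(abs(bgiid@initial - 0.25) < 0.02))

  expect_error(estimateBackground(GenomeSeq("AN")), "at least 2 non-N")
})

test_that("PWM probabilities follow the pseudocount formula", {
  sites <- BindingSiteSet(c("AA", "AC"))
  pwm <- buildPWM(sites, pseudocount = 1)
  expect_equal(unname(pwmProbs(pwm)[1, "A"]), 3 / 6)
  expect_equal(unname(pwmProbs(pwm)[2, "C"]), 2 / 6)
  expect_equal(unname(pwmProbs(pwm)[1, "C"]), 1 / 6)
  expect_equal(rowSums(pwmProbs(pwm)), rep(1, 2), ignore_attr = TRUE)

  hard <- buildPWM(BindingSiteSet(c("AG", "AG")), pseudocount = 0)
  expect_equal(pwmProbs(hard)[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_error(buildPWM(sites, pseudocount = -1), ">= 0")
})

test_that("window scoring matches a brute-force product oracle", {
  ## flat PWM against uniform iid background scores zero
  flat <- new("MotifPWM", probs = matrix(0.25, 6, 4,
                                         dimnames = list(NULL, c("A","C","G","T"))),
              pseudocount = 0)
  expect_equal(scoreWindow(flat, uniformBg(), "ACGTAC"), 0)

  ## consensus window under a sharp PWM scores positive
  sharp <- buildPWM(BindingSiteSet(rep("ACGTAC", 5)), pseudocount = 0.1)
  expect_gt(scoreWindow(sharp, uniformBg(), "ACGTAC"), 0)

  ## equality with independent direct computation on random 6-mers
  set.seed(42)
  for (i in 1:1000) {
    probs <- matrix(rgamma(24, 1), 6, 4)
    probs <- probs / rowSums(probs)
    colnames(probs) <- c("A","C","G","T")
    pwm <- new("MotifPWM", probs = probs, pseudocount = 0)
    init <- rgamma(4, 5); init <- init / sum(init)
    tr <- matrix(rgamma(16, 5), 4, 4); tr <- tr / rowSums(tr)
    bg <- new("MarkovBackground", initial = init, transition = tr)
    w <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
               collapse = "")
    expect_equal(scoreWindow(pwm, bg, w), bruteScore(probs, init, tr, w),
                 tolerance = 1e-9)
  }

  expect_error(scoreWindow(sharp, uniformBg(), "ACGNAC"), "not-?scoreable|non-ACGT")
  expect_error(scoreWindow(sharp, uniformBg(), "ACGTA"), "width")
})

test_that("genome scanning finds planted sites and honors bounds", {
  case <- smallDepCase(seed = 9, nSites = 40, genomeLen = 2e4)
  bg <- estimateBackground(case$genome)
  pwm <- buildPWM(case$sites)
  hits <- scanGenome(pwm, bg, case$genome, minScore = 0)
  off <- GenomicRanges::start(hits) - 1L
  expect_true(all(case$truth@plantedPositions$offset %in% off))
  ## scan scores agree with scoreWindow on the reported windows
  i <- seq_len(min(25L, length(hits)))
  expect_equal(S4Vectors::mcols(hits)$score[i],
               vapply(S4Vectors::mcols(hits)$window[i],
                      function(w) scoreWindow(pwm, bg, w), numeric(1)),
               tolerance = 1e-9, ignore_attr = TRUE)
  ## minus-strand windows are reverse complements of the genome slice
  minus <- hits[as.character(GenomicRanges::strand(hits)) == "-"]
  if (length(minus)) {
    j <- 1L
    slice <- substr(genomeSequence(case$genome),
                    GenomicRanges::start(minus)[j],
                    GenomicRanges::end(minus)[j])
    expect_identical(
      S4Vectors::mcols(minus)$window[j],
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(slice))))
  }
  expect_length(scanGenome(pwm, bg, case$genome, minScore = Inf), 0L)
  band <- scanGenome(pwm, bg, case$genome, minScore = -2, maxScore = 0,
                     minInclusive = TRUE)
  sc <- S4Vectors::mcols(band)$score
  expect_true(all(sc >= -2 & sc < 0))
})

test_that("scanning is strand-symmetric", {
  case <- generateSyntheticCase(width = 8, nSites = 20, genomeLen = 5e3,
                                seed = 17)
  bg0 <- uniformBg()  # symmetric background isolates the strand contract
  pwm <- buildPWM(case$sites)
  g <- case$genome
  grc <- GenomeSeq(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genomeSequence(g)))), id = g@id)
  h1 <- scanGenome(pwm, bg0, g, minScore = 1)
  h2 <- scanGenome(pwm, bg0, grc, minScore = 1)
  n <- length(g)
  ## a + hit at start s maps to a - hit at n - s - L + 2 on the rc genome
  key1 <- paste(GenomicRanges::start(h1),
                as.character(GenomicRanges::strand(h1)))
  flip <- c("+" = "-", "-" = "+")
  key2 <- paste(n - GenomicRanges::end(h2) + 1L,
                flip[as.character(GenomicRanges::strand(h2))])
  expect_setequal(key1, key2)
  expect_setequal(S4Vectors::mcols(h1)$window, S4Vectors::mcols(h2)$window)
})

test_that("unique hit sequences deduplicate in first-occurrence order", {
  gr <- GenomicRanges::GRanges("g", IRanges::IRanges(c(1, 5, 9), width = 4),
                               strand = "+",
                               window = c("ACGT", "TTTT", "ACGT"),
                               score = c(1, 2, 3))
  expect_identical(uniqueHitSequences(gr), c("ACGT", "TTTT"))
  expect_identical(uniqueHitSequences(gr[0]), character(0))
  ## strand-aware collapse merges a window with its reverse complement
  gr2 <- GenomicRanges::GRanges("g", IRanges::IRanges(c(1, 5), width = 4),
                                strand = c("+", "-"),
                                window = c("ACGG", "CCGT"),
                                score = c(1, 1))
  expect_length(uniqueHitSequences(gr2), 2L)
  expect_length(uniqueHitSequences(gr2, strandAware = TRUE), 1L)
})

test_that("column permutation preserves rows and avoids identity", {
  pwm <- buildPWM(BindingSiteSet(c("ACGTA", "ACGTC", "ACGGA")))
  for (s in 1:20) {
    pp <- permuteColumns(pwm, seed = s)
    expect_false(identical(pwmProbs(pp), pwmProbs(pwm)))
    ## row multiset preserved (sort rows lexicographically)
    sortRows <- function(m) m[do.call(order, as.data.frame(m)), ]
    expect_equal(sortRows(pwmProbs(pp)), sortRows(pwmProbs(pwm)),
                 ignore_attr = TRUE)
  }
  expect_identical(pwmProbs(permuteColumns(pwm, 7)),
                   pwmProbs(permuteColumns(pwm, 7)))
  two <- buildPWM(BindingSiteSet(c("AC", "AG")))
  expect_equal(pwmProbs(permuteColumns(two, 1)),
               pwmProbs(two)[2:1, ], ignore_attr = TRUE)
})

test_that("information content follows the entropy definition", {
  counts <- rbind(c(10, 0, 0, 0),   # invariant: 2 bits
                  c(5, 5, 0, 0),    # two-base: 1 bit
                  c(1, 1, 1, 1))    # uniform: 0 bits
  ic <- informationContent(counts)
  expect_equal(ic$perPosition, c(2, 1, 0))
  expect_equal(ic$widthNormalized, 1)
  ## bounded and monotone under sharpening toward a point mass
  prev <- -Inf
  for (p in seq(0.25, 1, by = 0.05)) {
    m <- matrix(c(p, (1 - p) / 3, (1 - p) / 3, (1 - p) / 3), 1)
    v <- informationContent(m)$widthNormalized
    expect_gte(v, prev - 1e-12)
    expect_gte(v, 0)
    expect_lte(v, 2)
    prev <- v
  }
})

test_that("PWM file round trip and BED export work", {
  pwm <- buildPWM(BindingSiteSet(c("ACGTA", "ACGTC", "TCGGA")))
  f <- tempfile()
  writePWM(pwm, f)
  back <- readPWM(f)
  expect_equal(pwmProbs(back), pwmProbs(pwm))
  expect_equal(back@pseudocount, pwm@pseudocount)

  gr <- GenomicRanges::GRanges("rec", IRanges::IRanges(11, width = 5),
                               strand = "-", window = "ACGTA", score = 1.5)
  bed <- tempfile()
  writeHitsBED(gr, bed)
  ln <- strsplit(readLines(bed), "\t")[[1]]
  expect_identical(ln[1:4], c("rec", "10", "15", "ACGTA"))
  expect_identical(ln[6], "-")
})
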