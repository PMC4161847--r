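# Per-read likelihood, pair statistic, the two Bayesian callers, the
# MaxTwo baseline and the homozygosity rule.

test_that("readLoglik has the stated closed forms and limits", {
  expect_equal(readLoglik(10, 0, 0.02), 10 * log(0.98))
  # at delta = 0.75 every base outcome is equally likely
  expect_equal(readLoglik(3, 1, 0.75), 4 * log(1 / 4))
  expect_error(readLoglik(5, 1, 0), "delta")
  expect_error(readLoglik(5, 1, 1), "delta")
})

test_that("counts-mode likelihood normalizes over all outcomes", {
  # L = 2: sum over all 16 two-base reads of exp(loglik) is exactly 1
  allele <- c("A", "C")
  outcomes <- expand.grid(b1 = c("A", "C", "G", "T"),
                          b2 = c("A", "C", "G", "T"),
                          stringsAsFactors = FALSE)
  for (delta in c(0.02, 0.2, 0.75)) {
    tot <- sum(apply(outcomes, 1L, function(o) {
      m <- sum(o == allele)
      exp(readLoglik(m, 2 - m, delta))
    }))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("pairStatistic sums per-read maxima and is symmetric", {
  S <- matrix(c(1, 5, 2,
                4, 1, 3), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(pairStatistic(S, "a", "a"), sum(S[, "a"]))
  expect_equal(pairStatistic(S, "a", "b"), 4 + 5 + 3)
  expect_equal(pairStatistic(S, "a", "b"), pairStatistic(S, "b", "a"))
})

test_that("bayesTyping0 picks the generating pair on clean support", {
  # reads supporting exactly alleles a1 and a2
  S <- rbind(c(10, 1, 1), c(10, 2, 1), c(1, 10, 2), c(0, 9, 1))
  colnames(S) <- c("a1", "a2", "a3")
  call <- bayesTyping0(S)
  expect_equal(calledPairs(call), matrix(c("a1", "a2"), 1L))
  expect_equal(zygosity(call), "het")
  expect_false(isAmbiguous(call))
})

test_that("both callers match the exhaustive enumeration oracle", {
  set.seed(51)
  params0 <- TypingParams(m = 0)
  for (i in 1:25) {
    n <- sample(3:10, 1); A <- sample(2:6, 1)
    S <- randomSupport(n, A)
    m <- sample(c(0, 0.2, 0.3), 1)
    orc <- oracleBestPairs(S, m)
    call <- if (m == 0) bayesTyping0(S, params0) else
      bayesTyping1(S, TypingParams(m = m))
    expect_equal(objectiveValue(call), orc$objective, tolerance = 1e-9,
                 info = paste("case", i))
    # the called genotypes are the zygosity-collapsed images of the
    # oracle's co-optimal pairs (all retained reads count)
    collapsed <- unique(lapply(orc$pairs, function(p)
      callZygosity(S, p)$pair))
    called <- lapply(seq_len(nrow(calledPairs(call))), function(r)
      calledPairs(call)[r, ])
    expect_setequal(called, collapsed)
  }
})

test_that("trimming shortcut equals explicit noise-subset enumeration", {
  set.seed(52)
  for (i in 1:15) {
    n <- sample(4:9, 1); A <- sample(2:5, 1)
    S <- randomSupport(n, A)
    m <- 0.25
    k <- floor(m * n)
    orc <- oracleBestPairs(S, m)
    # recompute the shortcut for every pair and compare the maximum
    vals <- c()
    for (a in seq_len(A)) for (b in a:A) {
      v <- pmax(S[, a], S[, b])
      vals <- c(vals, if (k > 0)
        sum(v) - sum(sort(v, partial = seq_len(k))[seq_len(k)])
        else sum(v))
    }
    expect_equal(max(vals), orc$objective, tolerance = 1e-9)
  }
})

test_that("bayesTyping1 reduces to bayesTyping0 at m = 0", {
  set.seed(53)
  for (i in 1:20) {
    S <- randomSupport(sample(3:10, 1), sample(2:6, 1))
    c0 <- bayesTyping0(S)
    c1 <- bayesTyping1(S, TypingParams(m = 0))
    expect_equal(calledPairs(c1), calledPairs(c0))
    expect_equal(objectiveValue(c1), objectiveValue(c0))
  }
})

test_that("bayesTyping1 at m = 1 ties every pair", {
  set.seed(54)
  S <- randomSupport(6, 4)
  call <- bayesTyping1(S, TypingParams(m = 1))
  expect_equal(objectiveValue(call), 0)
  # all pairs are co-optimal; distinct zygosity-collapsed genotypes > 1
  expect_true(isAmbiguous(call))
})

test_that("bayesTyping1 flags planted outlier reads as noise", {
  # 8 reads from {a1, a2} plus 2 reads copied from a3, m = 0.2
  S <- rbind(matrix(rep(c(10, 2, 0), 4), 4, 3, byrow = TRUE),
             matrix(rep(c(2, 10, 0), 4), 4, 3, byrow = TRUE),
             matrix(rep(c(0, 1, 10), 2), 2, 3, byrow = TRUE))
  colnames(S) <- c("a1", "a2", "a3")
  rownames(S) <- sprintf("r%d", 1:10)
  call <- bayesTyping1(S, TypingParams(m = 0.2))
  expect_equal(calledPairs(call), matrix(c("a1", "a2"), 1L))
  pr <- perReadAssignment(call)
  expect_equal(pr$read[pr$noise], c("r9", "r10"))
})

test_that("a uniform prior does not change the winner", {
  set.seed(55)
  S <- randomSupport(8, 4)
  c0 <- bayesTyping0(S)
  cU <- bayesTyping0(S, prior = setNames(rep(0.25, 4), colnames(S)))
  expect_equal(calledPairs(cU), calledPairs(c0))
})

test_that("maxTwo counts best-score reads and breaks ties by name", {
  # 6/4 split between two alleles
  S <- rbind(matrix(rep(c(9, 1, 0), 6), 6, 3, byrow = TRUE),
             matrix(rep(c(1, 9, 0), 4), 4, 3, byrow = TRUE))
  colnames(S) <- c("b", "a", "c")
  call <- maxTwo(S)
  expect_equal(sort(calledPairs(call)[1L, ]), c("a", "b"))
  expect_equal(zygosity(call), "het")

  # all reads best on one allele: homozygous after the zygosity rule
  S1 <- matrix(rep(c(9, 1), 8), 8, 2, byrow = TRUE,
               dimnames = list(NULL, c("a", "b")))
  expect_equal(zygosity(maxTwo(S1)), "hom")
  expect_equal(calledPairs(maxTwo(S1))[1L, ], c("a", "a"))

  # three-way count tie: the first two alleles by name order
  S3 <- matrix(9, 3, 3, dimnames = list(NULL, c("c", "a", "b")))
  expect_equal(sort(calledPairs(maxTwo(S3))[1L, ]), c("a", "b"))
})

test_that("the homozygosity rule uses a strict minority threshold", {
  mk <- function(ca, cb) {
    rbind(matrix(rep(c(9, 1), ca), ca, 2, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b"))),
          matrix(rep(c(1, 9), cb), cb, 2, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b"))))
  }
  z <- callZygosity(mk(40, 39), c("a", "b"))
  expect_equal(z$zygosity, "het")
  z <- callZygosity(mk(40, 10), c("a", "b"))
  expect_equal(z$zygosity, "hom")
  expect_equal(z$pair, c("a", "a"))
  # ratio exactly 0.5 stays heterozygous (strict inequality)
  z <- callZygosity(mk(40, 20), c("a", "b"))
  expect_equal(z$zygosity, "het")
  # ties credit half a read to each allele
  S <- matrix(c(5, 5), 1, 2, dimnames = list("r1", c("a", "b")))
  z <- callZygosity(S, c("a", "b"))
  expect_equal(unname(z$counts), c(0.5, 0.5))
  expect_error(callZygosity(S, c("a", "b"), noise = TRUE), "no reads")
})

test_that("relabelling alleles only permutes the output labels", {
  set.seed(56)
  S <- randomSupport(8, 4)
  call <- bayesTyping1(S, TypingParams(m = 0.2))
  perm <- sample(ncol(S))
  S2 <- S[, perm]
  map <- setNames(colnames(S)[perm], colnames(S)[perm])
  call2 <- bayesTyping1(S2, TypingParams(m = 0.2))
  expect_setequal(as.vector(calledPairs(call2)),
                  as.vector(calledPairs(call)))
  expect_equal(objectiveValue(call2), objectiveValue(call))
})

test_that("extra support for an allele never demotes its pairs", {
  set.seed(57)
  S <- randomSupport(6, 4)
  a1 <- colnames(S)[1L]
  statBefore <- vapply(colnames(S), function(x)
    pairStatistic(S, a1, x), 0)
  othersBefore <- pairStatistic(S, "a2", "a3")
  # append a read strongly supporting a1
  S2 <- rbind(S, newRead = c(100, 1, 1, 1))
  statAfter <- vapply(colnames(S), function(x)
    pairStatistic(S2, a1, x), 0)
  othersAfter <- pairStatistic(S2, "a2", "a3")
  # every a1 pair gains at least as much as any non-a1 pair
  expect_true(all(statAfter - statBefore >=
                    othersAfter - othersBefore - 1e-9))
})
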