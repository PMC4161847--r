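# Mapping, exon trimming, support-matrix construction and the two
# filters.

test_that("error-free reads map to the reference with full identity", {
  fx <- tinyLocus(seed = 21)
  tg <- as.character(targetSeqs(fx$panel)[[1L]])
  reads <- simulateCcsReads(tg, 10,
                            ReadErrorModel(accuracyMean = 1,
                                           accuracySd = 0,
                                           lengthMean = 250,
                                           lengthSd = 40, minLength = 50),
                            seed = 1)
  m <- mapToReference(reads, fx$reference)
  expect_true(all(m$accepted))
  expect_true(all(m$identity == 1))
})

test_that("random reads are rejected by the identity threshold", {
  fx <- tinyLocus(seed = 22)
  set.seed(23)
  rnd <- Biostrings::DNAStringSet(replicate(200, randomDna(200)))
  m <- mapToReference(rnd, fx$reference)
  expect_false(any(m$accepted))
  expect_true(all(m$reason != ""))
})

test_that("reads with ~8% error still pass the 90% mapping filter", {
  fx <- tinyLocus(seed = 24)
  tg <- as.character(targetSeqs(fx$panel)[[1L]])
  reads <- simulateCcsReads(tg, 40,
                            ReadErrorModel(accuracyMean = 0.92,
                                           accuracySd = 0,
                                           lengthMean = 250,
                                           lengthSd = 40, minLength = 50),
                            seed = 25)
  m <- mapToReference(reads, fx$reference)
  expect_gt(mean(m$accepted), 0.9)
})

test_that("minus-strand reads are mapped and trimmed like plus-strand", {
  fx <- tinyLocus(seed = 26)
  tg <- as.character(targetSeqs(fx$panel)[[1L]])
  fwd <- simulateCcsReads(tg, 6,
                          ReadErrorModel(accuracyMean = 1, accuracySd = 0,
                                         lengthMean = 250, lengthSd = 0,
                                         minLength = 50), seed = 27)
  rev <- Biostrings::reverseComplement(fwd)
  names(rev) <- names(fwd)
  S4Vectors::mcols(rev) <- S4Vectors::mcols(fwd)
  mf <- mapToReference(fwd, fx$reference)
  mr <- mapToReference(rev, fx$reference)
  expect_true(all(mr$accepted))
  expect_true(all(mr$strand == "-"))
  tf <- trimToExons(fwd, mf, fx$reference)
  tr <- trimToExons(rev, mr, fx$reference)
  expect_equal(as.character(tr$trimmed), as.character(tf$trimmed))
})

test_that("exon trimming keeps exactly the exon-aligned read columns", {
  fx <- tinyLocus(seed = 28)
  ref <- fx$reference
  g <- as.character(genomicSeq(ref))
  ex <- exonIntervals(ref)
  # a read spanning exon2 - intron - exon3, error-free: the trimmed read
  # is the spliced exon content of the covered window
  from <- IRanges::start(ex)[2L] - 30L
  to <- IRanges::end(ex)[3L] + 25L
  read <- Biostrings::DNAStringSet(setNames(substr(g, from, to), "r1"))
  m <- mapToReference(read, ref)
  tr <- trimToExons(read, m, ref)
  truth <- paste0(substr(g, IRanges::start(ex)[2L], IRanges::end(ex)[2L]),
                  substr(g, IRanges::start(ex)[3L], IRanges::end(ex)[3L]))
  expect_equal(unname(as.character(tr$trimmed)), truth)

  # a read wholly inside one exon is unchanged
  inEx <- substr(g, IRanges::start(ex)[2L] + 5L, IRanges::end(ex)[2L] - 5L)
  read2 <- Biostrings::DNAStringSet(setNames(inEx, "r2"))
  m2 <- mapToReference(read2, ref)
  tr2 <- trimToExons(read2, m2, ref)
  expect_equal(unname(as.character(tr2$trimmed)), inEx)

  # a wholly intronic read is dropped as too short after trimming
  intr <- substr(g, IRanges::end(ex)[2L] + 2L, IRanges::start(ex)[3L] - 2L)
  read3 <- Biostrings::DNAStringSet(setNames(intr, "r3"))
  m3 <- mapToReference(read3, ref)
  tr3 <- trimToExons(read3, m3, ref)
  expect_equal(length(tr3$trimmed), 0L)
  expect_equal(tr3$dropped$reason, "short_after_trim")
})

test_that("support-matrix cells equal the independent DP oracle", {
  fx <- tinyLocus(seed = 29, nAlleles = 3)
  cds <- panelCds(fx$panel)
  set.seed(30)
  reads <- Biostrings::DNAStringSet(setNames(
    c(substr(as.character(cds[[1L]]), 10, 90),
      substr(as.character(cds[[2L]]), 40, 130),
      randomDna(80)), c("r1", "r2", "r3")))
  sm <- scoreAgainstAlleles(reads, fx$panel)
  sc <- scoreMatrix(sm)
  for (i in 1:3) for (a in seq_along(cds)) {
    expect_equal(sc[i, a],
                 oracleScore(as.character(reads[[i]]),
                             as.character(cds[[a]])),
                 info = paste(i, a))
  }
  # an exact exon copy attains its per-read maximum on the source allele
  expect_equal(unname(which.max(sc[1L, ])), 1L)
  expect_equal(max(sc[1L, ]), readMaxScore(sm)[1L])
  # panel deduplication implies pairwise-distinct columns
  expect_false(any(duplicated(t(sc))))
})

test_that("the allele filter drops under-supported columns only", {
  # 10 reads; allele best for 1 read (= ceiling(0.1 * 10)) is retained,
  # allele best for 0 reads is dropped
  sc <- matrix(0, 10, 3, dimnames = list(sprintf("r%d", 1:10),
                                         c("a", "b", "c")))
  sc[, "a"] <- 100; sc[1, "b"] <- 200; sc[, "c"] <- 10
  sm <- SummarizedExperiment::SummarizedExperiment(
    assays = list(score = sc, identity = sc * 0 + 1, matches = sc,
                  mismatches = sc * 0, gaps = sc * 0),
    rowData = S4Vectors::DataFrame(maxScore = apply(sc, 1, max)))
  sm <- new("SupportMatrix", sm)
  out <- filterAlleles(sm)
  expect_setequal(colnames(out), c("a", "b"))
  expect_equal(droppedRecords(out)$id, "c")
  # per-read maxima are kept from the full matrix
  expect_equal(readMaxScore(out), apply(sc, 1, max))
  # idempotent
  out2 <- filterAlleles(out)
  expect_equal(colnames(out2), colnames(out))

  # a single-allele matrix is always retained
  one <- sm[, 1]
  expect_equal(colnames(filterAlleles(one)), "a")
})

test_that("the read filter applies a strict identity cutoff", {
  idm <- matrix(c(1.0, 0.96, 0.959, 0.5), 4, 1,
                dimnames = list(sprintf("r%d", 1:4), "a"))
  sc <- idm * 100
  sm <- SummarizedExperiment::SummarizedExperiment(
    assays = list(score = sc, identity = idm, matches = sc,
                  mismatches = sc * 0, gaps = sc * 0),
    rowData = S4Vectors::DataFrame(maxScore = apply(sc, 1, max)))
  sm <- new("SupportMatrix", sm)
  out <- filterReads(sm)
  # 0.96 exactly is retained (the rule is strictly 'less than')
  expect_setequal(rownames(out), c("r1", "r2"))
  expect_setequal(droppedRecords(out)$id, c("r3", "r4"))
  expect_equal(rownames(filterReads(out)), rownames(out))

  allLow <- sm[3:4, ]
  expect_error(filterReads(allLow), "all reads dropped")
})

test_that("cell independence: removing a read leaves other rows unchanged", {
  fx <- tinyLocus(seed = 31)
  reads <- simulateSampleReads(fx$panel, names(targetSeqs(fx$panel))[1L],
                               names(targetSeqs(fx$panel))[2L], 6,
                               tinyModel(), seed = 32)
  sm <- preprocessReads(reads, fx$panel, applyFilters = FALSE)
  smDrop <- preprocessReads(reads[-1L], fx$panel, applyFilters = FALSE)
  common <- intersect(rownames(sm), rownames(smDrop))
  expect_equal(scoreMatrix(sm)[common, ], scoreMatrix(smDrop)[common, ])
})

test_that("most reads survive pre-processing on noise-free samples", {
  fx <- tinyLocus(seed = 33)
  reps <- names(targetSeqs(fx$panel))
  survived <- 0L; total <- 0L
  for (s in 1:3) {
    reads <- simulateSampleReads(fx$panel, reps[1L], reps[2L], 10,
                                 tinyModel(), sampleId = s,
                                 seed = 33 + s)
    sm <- preprocessReads(reads, fx$panel)
    survived <- survived + nrow(sm)
    total <- total + length(reads)
  }
  expect_gte(survived / total, 0.95)
})
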