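# Parsing the CDS-alignment dialect, genomic reconstruction, target
# extraction and target deduplication.

test_that("parseCdsAlignment expands the identity dialect", {
  aln <- parseCdsAlignment(c("REF*01:01 ACGT", "ALT*01:02 ----"))
  expect_equal(unname(alignmentRows(aln)["ALT*01:02"]), "ACGT")

  aln <- parseCdsAlignment(c("REF*01:01 ACGT", "ALT*01:02 -T--"))
  expect_equal(unname(alignmentRows(aln)["ALT*01:02"]), "ATGT")
  # row order preserved, reference first
  expect_equal(names(alignmentRows(aln)), c("REF*01:01", "ALT*01:02"))
})

test_that("parseCdsAlignment preserves unsequenced and gap symbols", {
  aln <- parseCdsAlignment(c("REF*01:01 ACGT", "ALT*01:02 **--"))
  expect_equal(unname(alignmentRows(aln)["ALT*01:02"]), "**GT")
  aln <- parseCdsAlignment(c("REF*01:01 AC.GT", "ALT*01:02 --.-A"))
  expect_equal(unname(alignmentRows(aln)["ALT*01:02"]), "AC.GA")
})

test_that("parseCdsAlignment handles blocks, exon bars and errors", {
  txt <- c("REF*01:01 AC|G", "ALT*02:01 -T|-", "",
           "REF*01:01 TA", "ALT*02:01 --")
  aln <- parseCdsAlignment(txt)
  expect_equal(unname(alignmentRows(aln)["REF*01:01"]), "ACGTA")
  expect_equal(unname(alignmentRows(aln)["ALT*02:01"]), "ATGTA")
  expect_equal(exonLengths(aln), c(2L, 3L))

  expect_error(parseCdsAlignment(c("A*01 ACGT", "B*01 ACG")), "ragged")
  expect_error(parseCdsAlignment(c("A*01 ACXT", "B*01 ----")),
               "non-alphabet")
  expect_error(parseCdsAlignment(c("A*01 AC-T", "B*01 ----")),
               "reference")
})

test_that("alignment round trip: parse of write reproduces the rows", {
  fx <- tinyLocus(seed = 11)
  txt <- writeCdsAlignment(fx$alignment)
  back <- parseCdsAlignment(txt)
  expect_identical(alignmentRows(back), alignmentRows(fx$alignment))
  expect_identical(exonLengths(back), exonLengths(fx$alignment))
})

test_that("locateExons finds the unique spliced placement", {
  ex <- locateExons("AAACCGGGTTTAA", "CCTTT", c(2, 3))
  expect_equal(IRanges::start(ex), c(4L, 9L))
  expect_equal(IRanges::end(ex), c(5L, 11L))

  g <- "ACGTACGGT"
  ex <- locateExons(g, g, nchar(g))
  expect_equal(IRanges::start(ex), 1L)
  expect_equal(IRanges::width(ex), nchar(g))

  expect_error(locateExons("AAAA", "AC", 2), "placement")
  expect_error(locateExons("ACAC", "AC", 2), "ambiguous")
})

test_that("buildGenomicSeq replaces exons and fills unknowns from donor", {
  fx <- tinyLocus(seed = 3)
  aln <- fx$alignment
  ref <- fx$reference
  refName <- names(alignmentRows(aln))[1L]

  # allele identical to the reference reproduces the reference genomic
  expect_equal(buildGenomicSeq(aln, refName, ref),
               as.character(genomicSeq(ref)))

  # a single exon-2 substitution lands at exactly the mapped position
  rows <- alignmentRows(aln)
  cdsPos <- exonLengths(aln)[1L] + 5L  # 5th base of exon 2
  ch <- strsplit(rows[[refName]], "")[[1L]]
  ch[cdsPos] <- setdiff(c("A", "C", "G", "T"), ch[cdsPos])[1L]
  rows2 <- c(rows, mut = paste(ch, collapse = ""))
  names(rows2)[length(rows2)] <- "T*99:01"
  aln2 <- new("CdsAlignmentSet", locus = "T", referenceAllele = refName,
              rows = rows2, exonLengths = exonLengths(aln))
  g2 <- buildGenomicSeq(aln2, "T*99:01", ref)
  g0 <- as.character(genomicSeq(ref))
  diffs <- which(strsplit(g2, "")[[1L]] != strsplit(g0, "")[[1L]])
  expGenomicPos <- IRanges::start(exonIntervals(ref))[2L] + 4L
  expect_equal(diffs, expGenomicPos)

  # '*' over all of exon 1 copies the donor (reference) bases there
  ch <- strsplit(rows[[2L]], "")[[1L]]
  ch[seq_len(exonLengths(aln)[1L])] <- "*"
  rows3 <- rows
  rows3[[2L]] <- paste(ch, collapse = "")
  aln3 <- new("CdsAlignmentSet", locus = "T", referenceAllele = refName,
              rows = rows3, exonLengths = exonLengths(aln))
  g3 <- buildGenomicSeq(aln3, names(rows)[2L], ref)
  e1 <- exonIntervals(ref)[1L]
  expect_equal(substr(g3, IRanges::start(e1), IRanges::end(e1)),
               substr(as.character(genomicSeq(ref)), IRanges::start(e1),
                      IRanges::end(e1)))
})

test_that("extractTarget applies the 1-based window and checks bounds", {
  g <- randomDna(2000)
  ref <- ReferenceLocus("A", "A*01", g, IRanges::IRanges(500, 900),
                        targetStart = 380, targetLength = 1100)
  tg <- extractTarget(g, ref)
  expect_equal(nchar(tg), 1100L)
  expect_equal(tg, substr(g, 380, 1479))

  refAll <- ReferenceLocus("A", "A*01", g, IRanges::IRanges(500, 900),
                           targetStart = 1, targetLength = nchar(g))
  expect_equal(extractTarget(g, refAll), g)

  expect_error(ReferenceLocus("A", "A*01", g, IRanges::IRanges(500, 900),
                              targetStart = 1500, targetLength = 1100),
               "window")
  expect_error(extractTarget(substr(g, 1, 100), ref), "out of range")
})

test_that("extractTarget honours the 0-based coordinate switch", {
  g <- randomDna(100)
  r1 <- ReferenceLocus("A", "A*01", g, IRanges::IRanges(10, 20),
                       targetStart = 5, targetLength = 10)
  r0 <- ReferenceLocus("A", "A*01", g, IRanges::IRanges(10, 20),
                       targetStart = 4, targetLength = 10,
                       oneBasedStart = FALSE)
  expect_equal(extractTarget(g, r0), extractTarget(g, r1))
})

test_that("dedupeTargets groups identical targets deterministically", {
  g <- randomDna(200)
  ref <- ReferenceLocus("A", "A*01", g, IRanges::IRanges(50, 80),
                        targetStart = 1, targetLength = 200)
  tg <- c("A*02:01" = "ACGT", "A*01:01" = "ACGT",
          "A*03:01" = "AGGT", "A*04:01" = "AGGT")
  panel <- dedupeTargets(tg, ref)
  expect_equal(length(targetSeqs(panel)), 2L)
  expect_equal(lengths(memberAlleles(panel)), c("A*01:01" = 2L,
                                                "A*03:01" = 2L))
  # representative is the lexicographically smallest member
  expect_equal(names(targetSeqs(panel)), c("A*01:01", "A*03:01"))
  expect_setequal(unlist(memberAlleles(panel)), names(tg))

  # all-distinct targets give the identity grouping
  tg2 <- c("A*01" = "AAAA", "A*02" = "CCCC", "A*03" = "GGGG")
  p2 <- dedupeTargets(tg2, ref)
  expect_equal(length(targetSeqs(p2)), 3L)
  expect_equal(unname(lengths(memberAlleles(p2))), rep(1L, 3L))
})

test_that("panel construction round-trips exon content", {
  fx <- tinyLocus(seed = 5)
  panel <- fx$panel
  ref <- fx$reference
  aln <- fx$alignment
  # target restricted to in-window exon positions equals the panel CDS,
  # which in turn matches the allele's own exonic CDS content
  exLen <- exonLengths(aln)
  for (rep in names(targetSeqs(panel))) {
    row <- alignmentRows(aln)[[rep]]
    inWindowCds <- substr(row, exLen[1L] + 1L, sum(exLen))
    expect_equal(as.character(panelCds(panel)[[rep]]), inWindowCds)
  }
  # every allele appears in exactly one member list
  expect_setequal(unlist(memberAlleles(panel)), names(alignmentRows(aln)))
})

test_that("panel export writes FASTA and a coherent group map", {
  fx <- tinyLocus(seed = 6)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  tab <- writePanel(fx$panel, fa, tsv)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(seqs), as.character(targetSeqs(fx$panel)))
  back <- read.delim(tsv)
  expect_equal(nrow(back), length(unlist(memberAlleles(fx$panel))))
  unlink(c(fa, tsv))
})
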