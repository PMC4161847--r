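# Synthetic per-locus fixtures: a reference locus, a CDS alignment, a
# deduplicated target panel and a population frequency table, emulating
# the three external inputs (nuc-alignment file, reference FASTA,
# frequency TSV) so the whole pipeline runs without downloads.

#' Generate a synthetic HLA-like locus
#'
#' Builds a random reference genomic sequence with a class-I-like exon
#' layout (one exon upstream of the typing window, two polymorphic exons
#' inside it), a set of alleles derived from the reference by private
#' exonic substitutions, the corresponding CDS alignment, the
#' deduplicated target panel and an allele-group frequency table.
#'
#' Each non-reference allele carries `ceiling(divergence * targetLength)`
#' substitutions at in-window exonic positions drawn disjointly across
#' alleles, so every pair of target sequences differs at a fraction of at
#' least `divergence` of the window.
#'
#' @param locus Locus name (default `"A"`).
#' @param nAlleles Number of alleles including the reference.
#' @param divergence Minimum pairwise target divergence (fraction of the
#'   window; default 0.02).
#' @param groupsOf Alleles per two-digit group (default 2).
#' @param genomicLength Reference genomic length in bp.
#' @param targetStart,targetLength Target window (1-based start).
#' @param exonIntervals `IRanges` of exon positions; the default layout
#'   places exon 1 outside the window and exons 2-3 inside it.
#' @param seed Optional RNG seed.
#' @return A list: `alignment` ([CdsAlignmentSet-class]), `reference`
#'   ([ReferenceLocus-class]), `panel` ([AlleleTargetPanel-class]) and
#'   `frequency` (`data.frame` of locus, group, frequency).
#' @export
syntheticLocus <- function(locus = "A", nAlleles = 8, divergence = 0.02,
                           groupsOf = 2, genomicLength = 2000,
                           targetStart = 380, targetLength = 1100,
                           exonIntervals = IRanges(
                             start = c(120, 450, 950),
                             end = c(200, 719, 1224)),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nAlleles >= 2,
            max(end(exonIntervals)) <= genomicLength)
  genomic <- paste(sample(.BASES, genomicLength, replace = TRUE),
                   collapse = "")
  exonLengths <- width(exonIntervals)
  gch <- strsplit(genomic, "")[[1L]]
  refCds <- paste(unlist(lapply(seq_along(exonIntervals), function(e)
    gch[start(exonIntervals)[e]:end(exonIntervals)[e]])), collapse = "")

  # CDS coordinates of exonic positions inside the target window
  winEnd <- targetStart + targetLength - 1L
  exonPos <- unlist(lapply(seq_along(exonIntervals), function(e)
    start(exonIntervals)[e]:end(exonIntervals)[e]))
  inWindow <- which(exonPos >= targetStart & exonPos <= winEnd)
  k <- ceiling(divergence * targetLength)
  need <- k * (nAlleles - 1L)
  if (need > length(inWindow))
    stop("not enough in-window exonic positions for the requested ",
         "divergence: need ", need, ", have ", length(inWindow))

  pool <- sample(inWindow)
  names <- sprintf("%s*%02d:%02d", locus,
                   (seq_len(nAlleles) - 1L) %/% groupsOf + 1L,
                   (seq_len(nAlleles) - 1L) %% groupsOf + 1L)
  refChars <- strsplit(refCds, "")[[1L]]
  rows <- setNames(character(nAlleles), names)
  rows[1L] <- refCds
  for (i in seq_len(nAlleles - 1L)) {
    sites <- pool[((i - 1L) * k + 1L):(i * k)]
    ch <- refChars
    ch[sites] <- .SUBALT[cbind(sample.int(3L, k, replace = TRUE),
                               match(ch[sites], .BASES))]
    rows[i + 1L] <- paste(ch, collapse = "")
  }

  aln <- new("CdsAlignmentSet", locus = locus, referenceAllele = names[1L],
             rows = rows, exonLengths = as.integer(exonLengths))
  ref <- ReferenceLocus(locus, names[1L], genomic,
                        locateExons(genomic, refCds, exonLengths),
                        targetStart, targetLength)
  panel <- buildPanel(aln, ref)
  groups <- unique(alleleGroup(names))
  freq <- data.frame(locus = locus, group = groups,
                     frequency = rep(1 / length(groups), length(groups)))
  list(alignment = aln, reference = ref, panel = panel, frequency = freq)
}

#' Write a synthetic locus fixture to disk in the external input formats
#'
#' Emits the three files the pipeline accepts from real data: the
#' nuc-alignment dialect (`<locus>_nuc.txt`), the reference genomic FASTA
#' (`<locus>_ref.fasta`) and the frequency TSV (`frequencies.tsv`).
#'
#' @param fixture The list returned by [syntheticLocus].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the written files.
#' @export
writeSyntheticFixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  loc <- locusName(fixture$alignment)
  nucFile <- file.path(dir, paste0(loc, "_nuc.txt"))
  fastaFile <- file.path(dir, paste0(loc, "_ref.fasta"))
  freqFile <- file.path(dir, "frequencies.tsv")
  writeCdsAlignment(fixture$alignment, nucFile)
  g <- DNAStringSet(as.character(genomicSeq(fixture$reference)))
  names(g) <- fixture$reference@referenceAllele
  writeXStringSet(g, fastaFile)
  write.table(fixture$frequency, freqFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(nuc = nucFile, fasta = fastaFile, freq = freqFile))
}
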