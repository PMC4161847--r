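#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   readDNAStringSet writeXStringSet matchPattern
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom utils combn head read.delim write.table
#' @importFrom stats rnorm runif setNames aggregate fisher.test dhyper
#' @importFrom Rcpp evalCpp
#' @useDynLib BayesHLA, .registration = TRUE
NULL

setOldClass("data.frame")

#' Reference locus: genomic backbone, exon layout and typing window
#'
#' Holds the reference genomic sequence of one HLA locus together with the
#' positions of its exons and the trimmed target window (the region covering
#' exon 2 + intron 2 + exon 3 for class I loci, or exon 2 for class II) used
#' for typing. The target start is stored 1-based inclusive; exon intervals
#' are an [IRanges::IRanges] in 1-based genomic coordinates.
#'
#' @slot locus Locus name, e.g. `"A"`.
#' @slot referenceAllele Name of the allele the genomic sequence belongs to.
#' @slot genomic Reference genomic sequence ([Biostrings::DNAString]).
#' @slot exonIntervals Exon positions on `genomic` (ascending, disjoint).
#' @slot targetStart 1-based start of the target window on `genomic`.
#' @slot targetLength Length of the target window in bp.
#' @export
setClass("ReferenceLocus",
  representation(locus = "character", referenceAllele = "character",
                 genomic = "DNAString", exonIntervals = "IRanges",
                 targetStart = "integer", targetLength = "integer"))

setValidity("ReferenceLocus", function(object) {
  msg <- character()
  ex <- object@exonIntervals
  if (length(ex)) {
    if (is.unsorted(start(ex)) ||
        any(start(ex)[-1] <= end(ex)[-length(ex)]))
      msg <- c(msg, "exon intervals must be ascending and disjoint")
    if (min(start(ex)) < 1L || max(end(ex)) > length(object@genomic))
      msg <- c(msg, "exon intervals must lie within the genomic sequence")
  }
  ts <- object@targetStart; tl <- object@targetLength
  if (ts < 1L || ts + tl - 1L > length(object@genomic))
    msg <- c(msg, "target window must lie within the genomic sequence")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceLocus
#'
#' @param locus Locus name.
#' @param referenceAllele Reference allele name.
#' @param genomic Reference genomic sequence (character or `DNAString`).
#' @param exonIntervals `IRanges` of exon positions (1-based).
#' @param targetStart Start of the target window; interpreted as 1-based
#'   inclusive when `oneBasedStart = TRUE` (the convention of published
#'   locus tables), as 0-based otherwise.
#' @param targetLength Target window length in bp.
#' @param oneBasedStart Coordinate convention switch for `targetStart`.
#' @return A [ReferenceLocus-class] object.
#' @export
ReferenceLocus <- function(locus, referenceAllele, genomic, exonIntervals,
                           targetStart, targetLength, oneBasedStart = TRUE) {
  if (is.character(genomic)) genomic <- DNAString(genomic)
  ts <- as.integer(targetStart) + if (oneBasedStart) 0L else 1L
  new("ReferenceLocus", locus = locus, referenceAllele = referenceAllele,
      genomic = genomic, exonIntervals = exonIntervals,
      targetStart = ts, targetLength = as.integer(targetLength))
}

#' Parsed per-locus coding-sequence alignment
#'
#' The expanded content of an IMGT-style `*_nuc.txt` alignment: one aligned
#' CDS row per allele over the alphabet `{A,C,G,T,*,.}` after identity
#' dashes have been replaced by the reference base. `*` marks unsequenced
#' positions, `.` alignment gaps. The first row is the reference allele,
#' fully spelled out. `exonLengths` partitions the ungapped reference CDS
#' into exons.
#'
#' @slot locus Locus name.
#' @slot referenceAllele Name of the reference (first) row.
#' @slot rows Named character vector of aligned, dash-expanded CDS rows.
#' @slot exonLengths Integer vector of exon lengths in CDS coordinates.
#' @export
setClass("CdsAlignmentSet",
  representation(locus = "character", referenceAllele = "character",
                 rows = "character", exonLengths = "integer"))

setValidity("CdsAlignmentSet", function(object) {
  msg <- character()
  r <- object@rows
  if (!length(r)) return("alignment has no rows")
  if (length(unique(nchar(r))) != 1L)
    msg <- c(msg, "alignment rows must have equal length")
  ref <- r[[1L]]
  if (grepl("[-*]", ref))
    msg <- c(msg, "reference row must not contain '-' or '*'")
  refLen <- nchar(gsub(".", "", ref, fixed = TRUE))
  if (sum(object@exonLengths) != refLen)
    msg <- c(msg, "exon lengths must sum to the ungapped reference CDS length")
  if (length(msg)) msg else TRUE
})

#' Deduplicated allele target panel for one locus
#'
#' One representative allele per group of alleles whose target sequences
#' (the trimmed genomic window) are identical. `targets` holds the target
#' sequence of each representative; `cds` the concatenated exonic sequence
#' inside the target window, against which exon-trimmed reads are scored;
#' `members` the full allele names collapsed onto each representative.
#'
#' @slot locus Locus name.
#' @slot targets Named [Biostrings::DNAStringSet] of target sequences.
#' @slot cds Named `DNAStringSet` of in-window exonic (coding) sequences.
#' @slot members Named list mapping representative -> member allele names.
#' @slot reference The [ReferenceLocus-class] the panel was built against.
#' @export
setClass("AlleleTargetPanel",
  representation(locus = "character", targets = "DNAStringSet",
                 cds = "DNAStringSet", members = "list",
                 reference = "ReferenceLocus"))

setValidity("AlleleTargetPanel", function(object) {
  msg <- character()
  tg <- as.character(object@targets)
  if (anyDuplicated(tg))
    msg <- c(msg, "target sequences must be pairwise distinct")
  if (!identical(names(object@targets), names(object@members)))
    msg <- c(msg, "targets and members must share representative names")
  mem <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(mem))
    msg <- c(msg, "each allele may belong to exactly one target group")
  if (length(msg)) msg else TRUE
})

#' CCS read error model
#'
#' Length and accuracy model for simulated circular-consensus reads.
#' Read length and per-read accuracy are drawn from normal distributions
#' truncated (by clipping) to `[minLength, target length]` and `[0.5, 1]`
#' respectively; sequencing errors are placed i.i.d. per base at rate
#' `1 - accuracy` and split into substitutions, insertions and deletions
#' according to `errorMix`.
#'
#' @slot lengthMean,lengthSd Read length distribution (bp).
#' @slot accuracyMean,accuracySd Per-read accuracy distribution (fraction).
#' @slot errorMix Named fractions `substitution`/`insertion`/`deletion`,
#'   summing to 1.
#' @slot minLength Minimum read length (bp).
#' @export
setClass("ReadErrorModel",
  representation(lengthMean = "numeric", lengthSd = "numeric",
                 accuracyMean = "numeric", accuracySd = "numeric",
                 errorMix = "numeric", minLength = "integer"),
  prototype(lengthMean = 450, lengthSd = 170,
            accuracyMean = 0.98, accuracySd = 0.02,
            errorMix = c(substitution = 0.5, insertion = 0.25,
                         deletion = 0.25),
            minLength = 100L))

setValidity("ReadErrorModel", function(object) {
  msg <- character()
  if (object@accuracyMean <= 0 || object@accuracyMean > 1)
    msg <- c(msg, "accuracyMean must be in (0, 1]")
  mix <- object@errorMix
  if (length(mix) != 3L || any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
    msg <- c(msg, "errorMix must be 3 nonnegative fractions summing to 1")
  if (object@minLength < 1L)
    msg <- c(msg, "minLength must be positive")
  if (length(msg)) msg else TRUE
})

#' @param lengthMean,lengthSd,accuracyMean,accuracySd,errorMix,minLength
#'   Model parameters; the defaults are the standard CCS settings
#'   (length 450 +/- 170 bp, accuracy 0.98 +/- 0.02).
#' @return A [ReadErrorModel-class] object.
#' @rdname ReadErrorModel-class
#' @export
ReadErrorModel <- function(lengthMean = 450, lengthSd = 170,
                           accuracyMean = 0.98, accuracySd = 0.02,
                           errorMix = c(substitution = 0.5,
                                        insertion = 0.25, deletion = 0.25),
                           minLength = 100L) {
  new("ReadErrorModel", lengthMean = lengthMean, lengthSd = lengthSd,
      accuracyMean = accuracyMean, accuracySd = accuracySd,
      errorMix = errorMix, minLength = as.integer(minLength))
}

#' Multiplexing run design
#'
#' A sequencing-run design: reads per allele, samples per group, number of
#' sample groups, read-regeneration iterations and noise levels (numbers of
#' reads misassigned into each sample). The total number of correct reads
#' per locus is `readsPerAllele * 2 * samplesPerGroup` (960 for the three
#' standard designs with 40/12, 20/24 and 10/48).
#'
#' @slot readsPerAllele Correct reads simulated per allele.
#' @slot samplesPerGroup Samples multiplexed per group.
#' @slot groups Number of independently drawn sample groups.
#' @slot iterations Read-regeneration iterations per group.
#' @slot noiseLevels Integer vector of noise read counts per sample.
#' @export
setClass("RunPlan",
  representation(readsPerAllele = "integer", samplesPerGroup = "integer",
                 groups = "integer", iterations = "integer",
                 noiseLevels = "integer"))

setValidity("RunPlan", function(object) {
  msg <- character()
  if (object@readsPerAllele < 1L) msg <- c(msg, "readsPerAllele must be >= 1")
  if (object@samplesPerGroup < 1L) msg <- c(msg, "samplesPerGroup must be >= 1")
  if (object@groups < 1L) msg <- c(msg, "groups must be >= 1")
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  if (any(object@noiseLevels < 0L)) msg <- c(msg, "noise levels must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param readsPerAllele,samplesPerGroup,groups,iterations,noiseLevels
#'   Design parameters; see the class description.
#' @return A [RunPlan-class] object.
#' @rdname RunPlan-class
#' @export
RunPlan <- function(readsPerAllele, samplesPerGroup, groups = 1L,
                    iterations = 1L, noiseLevels = 0L) {
  new("RunPlan", readsPerAllele = as.integer(readsPerAllele),
      samplesPerGroup = as.integer(samplesPerGroup),
      groups = as.integer(groups), iterations = as.integer(iterations),
      noiseLevels = as.integer(noiseLevels))
}

#' Typing parameters
#'
#' Parameters of the Bayesian genotype callers: the assumed sequencing
#' error rate `delta`, the assumed noise-read ratio `m` (the fraction of
#' input reads discounted per candidate pair by the trimmed-likelihood
#' caller), the per-read support mode (`"score"` uses the local-alignment
#' score, `"counts"` the match/mismatch log-likelihood), the homozygosity
#' ratio below which the minority allele is discarded, and whether
#' co-optimal calls are reported as ties.
#'
#' @slot delta Sequencing error rate in (0, 1).
#' @slot m Assumed noise ratio in [0, 1].
#' @slot mode `"score"` or `"counts"`.
#' @slot homozygousRatio Homozygosity threshold on the minority/majority
#'   assigned-read ratio (default 0.5).
#' @slot reportTies Report all co-optimal genotypes.
#' @export
setClass("TypingParams",
  representation(delta = "numeric", m = "numeric", mode = "character",
                 homozygousRatio = "numeric", reportTies = "logical"),
  prototype(delta = 0.02, m = 0.2, mode = "score",
            homozygousRatio = 0.5, reportTies = TRUE))

setValidity("TypingParams", function(object) {
  msg <- character()
  if (object@delta <= 0 || object@delta >= 1)
    msg <- c(msg, "delta must be in (0, 1)")
  if (object@m < 0 || object@m > 1)
    msg <- c(msg, "m must be in [0, 1]")
  if (!object@mode %in% c("score", "counts"))
    msg <- c(msg, "mode must be 'score' or 'counts'")
  if (object@homozygousRatio < 0 || object@homozygousRatio > 1)
    msg <- c(msg, "homozygousRatio must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param delta,m,mode,homozygousRatio,reportTies Parameters; see the class
#'   description. Defaults: `delta = 0.02`, `m = 0.2`, score mode.
#' @return A [TypingParams-class] object.
#' @rdname TypingParams-class
#' @export
TypingParams <- function(delta = 0.02, m = 0.2, mode = "score",
                         homozygousRatio = 0.5, reportTies = TRUE) {
  new("TypingParams", delta = delta, m = m, mode = mode,
      homozygousRatio = homozygousRatio, reportTies = reportTies)
}

#' Per-(read, allele) alignment support matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with reads as rows and
#' allele representatives as columns, carrying one assay per alignment
#' summary statistic (`score`, `identity`, `matches`, `mismatches`,
#' `gaps`), each cell the best local alignment for that (read, allele)
#' pair. `rowData` records each read's maximum score over the full panel
#' (kept fixed when alleles are filtered); `metadata(x)$dropped` records
#' removed reads and alleles with reason codes.
#'
#' @export
setClass("SupportMatrix", contains = "SummarizedExperiment")

setValidity("SupportMatrix", function(object) {
  need <- c("score", "identity", "matches", "mismatches", "gaps")
  have <- SummarizedExperiment::assayNames(object)
  if (!all(need %in% have))
    return(paste("missing assays:", paste(setdiff(need, have), collapse = ", ")))
  if (!"maxScore" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData must contain maxScore")
  TRUE
})

#' Genotype call for one sample at one locus
#'
#' The result of a typing method: the called allele pair(s) (each row of
#' `pairs` an unordered pair, already collapsed by the homozygosity rule),
#' the objective value attained, per-read assignments for the primary
#' (first) pair, the zygosity call, per-allele assigned-read counts and an
#' ambiguity flag (more than one co-optimal genotype).
#'
#' @slot pairs Character matrix (k x 2) of called genotype(s), rows sorted.
#' @slot objective Objective value of the winning pair(s).
#' @slot perRead `data.frame` with columns `read`, `allele`, `noise`.
#' @slot zygosity `"hom"` or `"het"`.
#' @slot counts Named numeric of assigned reads per called allele.
#' @slot ambiguous More than one distinct co-optimal genotype.
#' @slot method Name of the caller that produced the call.
#' @export
setClass("GenotypeCall",
  representation(pairs = "matrix", objective = "numeric",
                 perRead = "data.frame", zygosity = "character",
                 counts = "numeric", ambiguous = "logical",
                 method = "character"))

setValidity("GenotypeCall", function(object) {
  if (ncol(object@pairs) != 2L) return("pairs must have two columns")
  if (!object@zygosity %in% c("hom", "het")) return("zygosity must be hom/het")
  TRUE
})

#' 2x2 contingency table of call correctness by zygosity
#'
#' Counts of correct and wrong genotype predictions for homozygous and
#' heterozygous samples, the input of the exact-test comparison.
#'
#' @slot correctHom,errorHom,correctHet,errorHet Nonnegative counts.
#' @export
setClass("ContingencyTable",
  representation(correctHom = "numeric", errorHom = "numeric",
                 correctHet = "numeric", errorHet = "numeric"))

setValidity("ContingencyTable", function(object) {
  v <- c(object@correctHom, object@errorHom, object@correctHet,
         object@errorHet)
  if (any(v < 0)) return("counts must be nonnegative")
  TRUE
})

#' @param correctHom,errorHom,correctHet,errorHet Counts.
#' @return A [ContingencyTable-class] object.
#' @rdname ContingencyTable-class
#' @export
ContingencyTable <- function(correctHom, errorHom, correctHet, errorHet) {
  new("ContingencyTable", correctHom = correctHom, errorHom = errorHom,
      correctHet = correctHet, errorHet = errorHet)
}
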