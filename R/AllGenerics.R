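# Accessor generics and show methods.

#' @export
setGeneric("calledPairs", function(x) standardGeneric("calledPairs"))
#' @export
setGeneric("zygosity", function(x) standardGeneric("zygosity"))
#' @export
setGeneric("isAmbiguous", function(x) standardGeneric("isAmbiguous"))
#' @export
setGeneric("perReadAssignment",
           function(x) standardGeneric("perReadAssignment"))
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))
#' @export
setGeneric("targetSeqs", function(x) standardGeneric("targetSeqs"))
#' @export
setGeneric("panelCds", function(x) standardGeneric("panelCds"))
#' @export
setGeneric("memberAlleles", function(x) standardGeneric("memberAlleles"))
#' @export
setGeneric("referenceLocus", function(x) standardGeneric("referenceLocus"))
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))
#' @export
setGeneric("exonIntervals", function(x) standardGeneric("exonIntervals"))
#' @export
setGeneric("genomicSeq", function(x) standardGeneric("genomicSeq"))
#' @export
setGeneric("targetWindow", function(x) standardGeneric("targetWindow"))
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))
#' @export
setGeneric("exonLengths", function(x) standardGeneric("exonLengths"))
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))
#' @export
setGeneric("identityMatrix", function(x) standardGeneric("identityMatrix"))
#' @export
setGeneric("readMaxScore", function(x) standardGeneric("readMaxScore"))
#' @export
setGeneric("droppedRecords", function(x) standardGeneric("droppedRecords"))
#' @export
setGeneric("totalReadsPerLocus",
           function(x) standardGeneric("totalReadsPerLocus"))
#' @export
setGeneric("asCounts", function(x) standardGeneric("asCounts"))

#' @describeIn GenotypeCall-class called genotype(s), one row per pair
#' @param x object
#' @export
setMethod("calledPairs", "GenotypeCall", function(x) x@pairs)
#' @describeIn GenotypeCall-class zygosity of the primary call
#' @export
setMethod("zygosity", "GenotypeCall", function(x) x@zygosity)
#' @describeIn GenotypeCall-class whether several genotypes are co-optimal
#' @export
setMethod("isAmbiguous", "GenotypeCall", function(x) x@ambiguous)
#' @describeIn GenotypeCall-class per-read assignments for the primary pair
#' @export
setMethod("perReadAssignment", "GenotypeCall", function(x) x@perRead)
#' @describeIn GenotypeCall-class objective value of the winning pair
#' @export
setMethod("objectiveValue", "GenotypeCall", function(x) x@objective)
#' @describeIn GenotypeCall-class assigned-read counts per called allele
#' @export
setMethod("alleleCounts", "GenotypeCall", function(x) x@counts)

#' @describeIn AlleleTargetPanel-class target sequences of representatives
#' @param x object
#' @export
setMethod("targetSeqs", "AlleleTargetPanel", function(x) x@targets)
#' @describeIn AlleleTargetPanel-class in-window coding sequences
#' @export
setMethod("panelCds", "AlleleTargetPanel", function(x) x@cds)
#' @describeIn AlleleTargetPanel-class member alleles per representative
#' @export
setMethod("memberAlleles", "AlleleTargetPanel", function(x) x@members)
#' @describeIn AlleleTargetPanel-class the underlying reference locus
#' @export
setMethod("referenceLocus", "AlleleTargetPanel", function(x) x@reference)
#' @describeIn AlleleTargetPanel-class locus name
#' @export
setMethod("locusName", "AlleleTargetPanel", function(x) x@locus)

#' @describeIn ReferenceLocus-class locus name
#' @param x object
#' @export
setMethod("locusName", "ReferenceLocus", function(x) x@locus)
#' @describeIn ReferenceLocus-class exon positions on the genomic sequence
#' @export
setMethod("exonIntervals", "ReferenceLocus", function(x) x@exonIntervals)
#' @describeIn ReferenceLocus-class the reference genomic sequence
#' @export
setMethod("genomicSeq", "ReferenceLocus", function(x) x@genomic)
#' @describeIn ReferenceLocus-class the target window as an IRanges
#' @export
setMethod("targetWindow", "ReferenceLocus", function(x)
  IRanges(x@targetStart, width = x@targetLength))

#' @describeIn CdsAlignmentSet-class dash-expanded alignment rows
#' @param x object
#' @export
setMethod("alignmentRows", "CdsAlignmentSet", function(x) x@rows)
#' @describeIn CdsAlignmentSet-class exon lengths in CDS coordinates
#' @export
setMethod("exonLengths", "CdsAlignmentSet", function(x) x@exonLengths)
#' @describeIn CdsAlignmentSet-class locus name
#' @export
setMethod("locusName", "CdsAlignmentSet", function(x) x@locus)

#' @describeIn SupportMatrix-class best-alignment score per (read, allele)
#' @param x object
#' @export
setMethod("scoreMatrix", "SupportMatrix", function(x)
  SummarizedExperiment::assay(x, "score"))
#' @describeIn SupportMatrix-class best-alignment identity per (read, allele)
#' @export
setMethod("identityMatrix", "SupportMatrix", function(x)
  SummarizedExperiment::assay(x, "identity"))
#' @describeIn SupportMatrix-class per-read maximum score over the full panel
#' @export
setMethod("readMaxScore", "SupportMatrix", function(x)
  SummarizedExperiment::rowData(x)$maxScore)
#' @describeIn SupportMatrix-class dropped reads/alleles with reason codes
#' @export
setMethod("droppedRecords", "SupportMatrix", function(x) {
  d <- metadata(x)$dropped
  if (is.null(d))
    d <- data.frame(id = character(), kind = character(),
                    reason = character())
  d
})

#' @describeIn RunPlan-class total correct reads per locus implied by the
#'   design (`readsPerAllele * 2 * samplesPerGroup`)
#' @param x object
#' @export
setMethod("totalReadsPerLocus", "RunPlan", function(x)
  x@readsPerAllele * 2L * x@samplesPerGroup)

#' @describeIn ContingencyTable-class the counts as a 2x2 matrix (rows:
#'   correct/error; columns: homozygous/heterozygous)
#' @param x object
#' @export
setMethod("asCounts", "ContingencyTable", function(x)
  matrix(c(x@correctHom, x@errorHom, x@correctHet, x@errorHet), nrow = 2,
         dimnames = list(c("correct", "error"), c("hom", "het"))))

setMethod("show", "ReferenceLocus", function(object) {
  cat("ReferenceLocus", object@locus, "(", object@referenceAllele, ")\n")
  cat("  genomic:", length(object@genomic), "bp;",
      length(object@exonIntervals), "exons\n")
  cat("  target window: start", object@targetStart, "length",
      object@targetLength, "bp\n")
})

setMethod("show", "CdsAlignmentSet", function(object) {
  cat("CdsAlignmentSet", object@locus, ":", length(object@rows),
      "alleles,", nchar(object@rows[[1L]]), "alignment columns,",
      length(object@exonLengths), "exons\n")
})

setMethod("show", "AlleleTargetPanel", function(object) {
  cat("AlleleTargetPanel", object@locus, ":", length(object@targets),
      "unique targets covering",
      length(unlist(object@members, use.names = FALSE)), "alleles\n")
})

setMethod("show", "GenotypeCall", function(object) {
  cat("GenotypeCall [", object@method, "] ",
      paste(object@pairs[1L, ], collapse = " / "),
      " (", object@zygosity, ")\n", sep = "")
  if (nrow(object@pairs) > 1L)
    cat("  ambiguous:", nrow(object@pairs), "co-optimal genotypes\n")
  cat("  objective:", format(object@objective), " reads:",
      paste(sprintf("%s=%g", names(object@counts), object@counts),
            collapse = ", "), "\n")
})

setMethod("show", "RunPlan", function(object) {
  cat("RunPlan:", object@readsPerAllele, "reads/allele x",
      object@samplesPerGroup, "samples/group x", object@groups,
      "groups x", object@iterations, "iterations\n")
  cat("  noise levels:", paste(object@noiseLevels, collapse = ", "),
      "; correct reads/locus:", totalReadsPerLocus(object), "\n")
})

setMethod("show", "ContingencyTable", function(object) {
  cat("ContingencyTable\n")
  print(asCounts(object))
})
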