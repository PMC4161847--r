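# Pre-processing pipeline: map reads to the reference genomic sequence,
# trim intron-aligned regions, score the trimmed reads against every
# unique allele, and apply the allele and read filters.

#' Map reads to the reference genomic sequence
#'
#' Aligns each read (both strands) to the locus reference genomic sequence
#' and accepts it when the alignment reaches the identity and coverage
#' thresholds; rejected reads are recorded with a reason. The identity
#' used here is the column identity (matches over all alignment columns,
#' gaps included), so gap-riddled chance alignments of unrelated sequence
#' do not slip through.
#'
#' @param reads A `DNAStringSet`.
#' @param ref A [ReferenceLocus-class].
#' @param minIdentity Minimum alignment identity (default 0.90).
#' @param minCoverage Minimum fraction of the read aligned (default 0.70).
#' @param scoring An [alignScoring] scheme.
#' @return A `data.frame` (one row per read) with alignment statistics,
#'   an `accepted` flag and a `reason` for rejections; the per-column
#'   position maps needed for exon trimming are kept in
#'   `attr(, "paths")`.
#' @export
mapToReference <- function(reads, ref, minIdentity = 0.90,
                           minCoverage = 0.70, scoring = alignScoring()) {
  if (is.null(names(reads)))
    names(reads) <- sprintf("read_%d", seq_along(reads))
  # lazy second strand: a read meeting both thresholds on '+' is in its
  # biological orientation; only reads failing them are retried on '-'
  df <- .alignSet(reads, genomicSeq(ref), scoring, strands = "+",
                  keepPath = TRUE)
  retry <- which(df$colIdentity < minIdentity | df$coverage < minCoverage)
  if (length(retry)) {
    rc <- reverseComplement(reads[retry])
    df2 <- .alignSet(rc, genomicSeq(ref), scoring, strands = "+",
                     keepPath = TRUE)
    better <- df2$score > df$score[retry]
    if (any(better)) {
      sel <- retry[better]
      p <- attr(df, "paths")
      df[sel, ] <- df2[better, ]
      df$strand[sel] <- "-"
      p[sel] <- attr(df2, "paths")[better]
      attr(df, "paths") <- p
    }
  }
  df$accepted <- df$colIdentity >= minIdentity & df$coverage >= minCoverage
  df$reason <- ifelse(df$accepted, "",
                      ifelse(df$colIdentity < minIdentity,
                             "low_identity_to_reference",
                             "low_coverage"))
  df
}

#' Trim reads to their exon-aligned regions
#'
#' Keeps, for each read accepted by [mapToReference], the read columns
#' whose reference column falls inside an exon, concatenated in read
#' order (insertions relative to the reference carry no reference column
#' and are dropped). Reads mapped on the minus strand are trimmed on
#' their reverse complement, so all trimmed reads come out oriented to
#' the reference forward strand. Results shorter than `minLength` are
#' rejected.
#'
#' @param reads The `DNAStringSet` passed to [mapToReference].
#' @param mapping The return value of [mapToReference].
#' @param ref A [ReferenceLocus-class].
#' @param minLength Minimum trimmed length in bp (default 50).
#' @return A list with `trimmed` (a `DNAStringSet` of retained reads,
#'   `mcols` preserved) and `dropped` (a `data.frame` of read id and
#'   reason).
#' @export
trimToExons <- function(reads, mapping, ref, minLength = 50) {
  if (is.null(names(reads)))
    names(reads) <- sprintf("read_%d", seq_along(reads))
  stopifnot(nrow(mapping) == length(reads))
  paths <- attr(mapping, "paths")
  ex <- exonIntervals(ref)
  inExon <- logical(length(genomicSeq(ref)))
  for (e in seq_along(ex))
    inExon[start(ex)[e]:end(ex)[e]] <- TRUE

  trimmed <- character(0)
  keptIdx <- integer(0)
  dropped <- data.frame(id = character(0), reason = character(0))
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    if (!mapping$accepted[i]) {
      dropped <- rbind(dropped,
                       data.frame(id = id, reason = mapping$reason[i]))
      next
    }
    p <- paths[[i]]
    seqi <- if (mapping$strand[i] == "-")
      as.character(reverseComplement(reads[[i]])) else
      as.character(reads[[i]])
    keep <- !is.na(p$qpos) & !is.na(p$spos) & inExon[pmax(p$spos, 1L)]
    qkeep <- sort(p$qpos[keep])
    res <- paste(strsplit(seqi, "")[[1L]][qkeep], collapse = "")
    if (nchar(res) < minLength) {
      dropped <- rbind(dropped,
                       data.frame(id = id, reason = "short_after_trim"))
    } else {
      trimmed <- c(trimmed, setNames(res, id))
      keptIdx <- c(keptIdx, i)
    }
  }
  out <- DNAStringSet(trimmed)
  if (length(keptIdx)) mcols(out) <- mcols(reads)[keptIdx, , drop = FALSE]
  list(trimmed = out, dropped = dropped)
}

#' Score trimmed reads against every unique allele
#'
#' Builds the [SupportMatrix-class]: for each (read, allele
#' representative) pair the best local alignment of the trimmed read
#' against the allele's in-window coding sequence. Trimmed reads are
#' already oriented to the reference forward strand, so only that strand
#' is aligned by default; set `bothStrands = TRUE` for reads of unknown
#' orientation.
#'
#' @param trimmed A `DNAStringSet` of exon-trimmed reads.
#' @param panel An [AlleleTargetPanel-class].
#' @param scoring An [alignScoring] scheme.
#' @param bothStrands Also try the reverse complement of each read.
#' @return A [SupportMatrix-class].
#' @export
scoreAgainstAlleles <- function(trimmed, panel, scoring = alignScoring(),
                                bothStrands = FALSE) {
  cds <- panelCds(panel)
  if (!length(cds)) stop("empty allele panel")
  if (!length(trimmed)) stop("no reads to score")
  if (is.null(names(trimmed)))
    names(trimmed) <- sprintf("read_%d", seq_along(trimmed))
  nr <- length(trimmed); na <- length(cds)
  dims <- list(names(trimmed), names(cds))
  stat <- c("score", "identity", "matches", "mismatches", "gaps")
  assays <- lapply(stat, function(s)
    matrix(NA_real_, nr, na, dimnames = dims))
  names(assays) <- stat
  strands <- if (bothStrands) c("+", "-") else "+"
  for (a in seq_len(na)) {
    df <- .alignSet(trimmed, as.character(cds[[a]]), scoring,
                    strands = strands, keepPath = FALSE)
    for (s in stat) assays[[s]][, a] <- df[[s]]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(maxScore = as.numeric(apply(assays$score, 1L,
                                                    max)),
                        readLength = nchar(as.character(trimmed))),
    colData = DataFrame(representative = names(cds),
                        nMembers = lengths(memberAlleles(panel)),
                        row.names = names(cds)))
  metadata(se)$dropped <- data.frame(id = character(0),
                                     kind = character(0),
                                     reason = character(0))
  new("SupportMatrix", se)
}

.addDropped <- function(sm, ids, kind, reason) {
  d <- droppedRecords(sm)
  if (length(ids))
    d <- rbind(d, data.frame(id = ids, kind = kind, reason = reason))
  metadata(sm)$dropped <- d
  sm
}

#' Drop alleles with too few best-matching reads
#'
#' Removes allele columns for which fewer than `minBestFraction` of the
#' reads attain their per-read maximum alignment score (ties credit every
#' attaining allele). Per-read maxima are taken from the full matrix and
#' are not recomputed afterwards: the filter is a pruning device and must
#' not cascade.
#'
#' @param sm A [SupportMatrix-class].
#' @param minBestFraction Retention threshold (default 0.10); an allele is
#'   dropped when strictly fewer than `minBestFraction * nrow(sm)` reads
#'   are best on it.
#' @return The filtered [SupportMatrix-class].
#' @export
filterAlleles <- function(sm, minBestFraction = 0.10) {
  sc <- scoreMatrix(sm)
  best <- sc == readMaxScore(sm)
  nBest <- colSums(best)
  keep <- nBest >= minBestFraction * nrow(sm)
  if (!any(keep))
    stop("all alleles dropped by the best-read filter: unusable sample")
  out <- sm[, keep]
  .addDropped(out, colnames(sm)[!keep], "allele", "few_best_reads")
}

#' Drop reads with low identity to every remaining allele
#'
#' Removes read rows whose best alignment identity over the remaining
#' alleles is strictly below `minIdentity` — the mechanism that discards
#' most barcode-miscalled noise reads, whose own allele has typically
#' been pruned by [filterAlleles].
#'
#' @param sm A [SupportMatrix-class] (allele filter already applied).
#' @param minIdentity Identity threshold (default 0.96).
#' @return The filtered [SupportMatrix-class].
#' @export
filterReads <- function(sm, minIdentity = 0.96) {
  idm <- identityMatrix(sm)
  bestId <- apply(idm, 1L, max)
  keep <- bestId >= minIdentity
  if (!any(keep))
    stop("all reads dropped by the identity filter: unusable sample")
  out <- sm[keep, ]
  .addDropped(out, rownames(sm)[!keep], "read", "low_identity_to_alleles")
}

#' Full pre-processing pipeline for one sample
#'
#' Maps reads to the reference genomic sequence, trims intron-aligned
#' regions, scores the surviving reads against every unique allele and
#' applies the allele and read filters.
#'
#' @param reads A `DNAStringSet` of the sample's reads.
#' @param panel An [AlleleTargetPanel-class].
#' @param scoring An [alignScoring] scheme.
#' @param minIdentity,minCoverage Mapping thresholds ([mapToReference]).
#' @param minTrimmedLength Minimum exon-trimmed read length
#'   ([trimToExons]).
#' @param alleleBestFraction Allele filter threshold ([filterAlleles]).
#' @param readIdentity Read filter threshold ([filterReads]).
#' @param applyFilters Apply the two filters (disable to inspect the raw
#'   matrix).
#' @return A [SupportMatrix-class]; reads and alleles removed along the
#'   way are recorded in `droppedRecords()`.
#' @export
preprocessReads <- function(reads, panel, scoring = alignScoring(),
                            minIdentity = 0.90, minCoverage = 0.70,
                            minTrimmedLength = 50,
                            alleleBestFraction = 0.10,
                            readIdentity = 0.96, applyFilters = TRUE) {
  ref <- referenceLocus(panel)
  mapping <- mapToReference(reads, ref, minIdentity, minCoverage, scoring)
  tr <- trimToExons(reads, mapping, ref, minTrimmedLength)
  if (!length(tr$trimmed))
    stop("no reads survived mapping and exon trimming")
  sm <- scoreAgainstAlleles(tr$trimmed, panel, scoring)
  if (nrow(tr$dropped))
    sm <- .addDropped(sm, tr$dropped$id, "read", tr$dropped$reason)
  if (applyFilters) {
    sm <- filterAlleles(sm, alleleBestFraction)
    sm <- filterReads(sm, readIdentity)
  }
  sm
}
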