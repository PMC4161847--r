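# Allele database construction: parse per-locus CDS alignments, rebuild
# genomic sequences against a reference backbone, extract the trimmed
# target window and deduplicate identical targets into a typing panel.

.NUC_ALPHABET <- c("A", "C", "G", "T", "-", "*", ".")

#' Parse an IMGT-style per-locus CDS alignment
#'
#' Reads the `*_nuc.txt` dialect: one or more blocks of lines, each line an
#' allele name followed by whitespace-separated chunks of aligned sequence;
#' chunks of the same allele are concatenated across blocks. The first
#' allele is the reference and must be spelled out in full. In non-reference
#' rows `-` denotes identity with the reference base, `*` an unsequenced
#' position and `.` an alignment gap; `|` characters mark exon boundaries
#' and are stripped (exon lengths are taken from the reference row).
#'
#' @param x Path to a file, or a character vector of lines (a single string
#'   containing newlines is split).
#' @param locus Locus name; defaults to the part of the reference allele
#'   name before `*`.
#' @param exonLengths Exon lengths in CDS coordinates, used when the
#'   alignment carries no `|` markers; defaults to one exon spanning the
#'   whole CDS.
#' @return A [CdsAlignmentSet-class] with identity dashes expanded to the
#'   reference base (`*` and `.` are preserved).
#' @examples
#' txt <- c("REF*01:01 ACG|T", "ALT*01:02 -T-|-")
#' aln <- parseCdsAlignment(txt)
#' alignmentRows(aln)
#' @export
parseCdsAlignment <- function(x, locus = NULL, exonLengths = NULL) {
  if (length(x) == 1L && (file.exists(x) || grepl("\n", x))) {
    lines <- if (file.exists(x)) readLines(x) else strsplit(x, "\n")[[1L]]
  } else lines <- x
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("alignment is empty")

  toks <- strsplit(trimws(lines), "\\s+")
  nm <- vapply(toks, `[[`, "", 1L)
  chunk <- vapply(toks, function(t) paste(t[-1L], collapse = ""), "")
  if (any(!nzchar(chunk))) stop("malformed alignment line: missing sequence")
  rows <- vapply(split(chunk, factor(nm, levels = unique(nm))),
                 paste, "", collapse = "")
  rows <- toupper(rows)

  bad <- grepl("[^ACGT*.|-]", rows)
  if (any(bad))
    stop("non-alphabet character in row(s): ",
         paste(names(rows)[bad], collapse = ", "))

  # exon boundaries from '|' in the reference row, then strip everywhere
  refRaw <- rows[[1L]]
  if (grepl("|", refRaw, fixed = TRUE)) {
    segs <- strsplit(refRaw, "|", fixed = TRUE)[[1L]]
    exonLengths <- nchar(gsub(".", "", segs, fixed = TRUE))
  }
  rows <- gsub("|", "", rows, fixed = TRUE)

  if (length(unique(nchar(rows))) != 1L)
    stop("ragged alignment: rows differ in length")

  refChars <- strsplit(rows[[1L]], "")[[1L]]
  if (any(refChars %in% c("-", "*")))
    stop("reference row must be fully spelled out (no '-' or '*')")

  # expand identity dashes to the reference base
  expand <- function(row) {
    ch <- strsplit(row, "")[[1L]]
    dash <- ch == "-"
    ch[dash] <- refChars[dash]
    paste(ch, collapse = "")
  }
  rows[-1L] <- vapply(rows[-1L], expand, "")

  refName <- names(rows)[1L]
  if (is.null(locus)) locus <- sub("\\*.*$", "", refName)
  if (is.null(exonLengths))
    exonLengths <- sum(refChars != ".")
  new("CdsAlignmentSet", locus = locus, referenceAllele = refName,
      rows = rows, exonLengths = as.integer(exonLengths))
}

#' Serialize a CDS alignment back to the nuc-alignment dialect
#'
#' Re-encodes non-reference rows with identity dashes against the reference
#' and writes exon boundaries as `|`. `parseCdsAlignment()` of the output
#' reproduces the input rows exactly.
#'
#' @param x A [CdsAlignmentSet-class].
#' @param file Optional path; when `NULL` the lines are returned.
#' @return Character vector of lines, invisibly when written to a file.
#' @export
writeCdsAlignment <- function(x, file = NULL) {
  rows <- x@rows
  refChars <- strsplit(rows[[1L]], "")[[1L]]
  # alignment column of the last CDS base of each exon
  cdsPos <- cumsum(refChars != ".")
  bounds <- cumsum(x@exonLengths)
  boundCol <- vapply(bounds[-length(bounds)],
                     function(b) max(which(cdsPos == b)), 0L)
  encode <- function(ch) {
    out <- character(length(ch) + length(boundCol))
    ins <- 0L
    j <- 1L
    for (i in seq_along(ch)) {
      out[j] <- ch[i]; j <- j + 1L
      if (ins < length(boundCol) && i == boundCol[ins + 1L]) {
        out[j] <- "|"; j <- j + 1L; ins <- ins + 1L
      }
    }
    paste(out, collapse = "")
  }
  body <- vapply(seq_along(rows), function(i) {
    ch <- strsplit(rows[[i]], "")[[1L]]
    if (i > 1L) {
      same <- ch == refChars & !ch %in% c("*", ".")
      ch[same] <- "-"
    }
    encode(ch)
  }, "")
  lines <- paste(format(names(rows), width = max(nchar(names(rows)))), body)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Locate exons of a CDS on a genomic sequence
#'
#' Finds the unique ascending, disjoint placement of the exon substrings of
#' `cds` (split according to `exonLengths`) on `genomic`, by exhaustive
#' spliced-substring search. The reference CDS is by construction a spliced
#' substring of its own genomic sequence, so exact placement suffices.
#'
#' @param genomic Genomic sequence (character or `DNAString`).
#' @param cds Ungapped CDS of the same allele.
#' @param exonLengths Exon lengths partitioning `cds`.
#' @return An [IRanges::IRanges] of exon positions (1-based).
#' @examples
#' locateExons("AAACCGGGTTTAA", "CCTTT", c(2, 3))
#' @export
locateExons <- function(genomic, cds, exonLengths) {
  genomic <- toupper(as.character(genomic))
  cds <- toupper(as.character(cds))
  exonLengths <- as.integer(exonLengths)
  if (sum(exonLengths) != nchar(cds))
    stop("exon lengths do not sum to the CDS length")
  ends <- cumsum(exonLengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  exons <- substring(cds, starts, ends)

  gseq <- DNAString(genomic)
  occ <- lapply(exons, function(e) start(matchPattern(DNAString(e), gseq)))
  if (any(lengths(occ) == 0L))
    stop("no consistent exon placement: an exon is absent from the genomic")

  solutions <- list()
  search <- function(i, minStart, acc) {
    if (length(solutions) >= 2L) return()
    if (i > length(exons)) {
      solutions[[length(solutions) + 1L]] <<- acc
      return()
    }
    for (s in occ[[i]][occ[[i]] >= minStart])
      search(i + 1L, s + exonLengths[i], c(acc, s))
  }
  search(1L, 1L, integer())
  if (!length(solutions)) stop("no consistent exon placement")
  if (length(solutions) > 1L) stop("ambiguous exon placement")
  IRanges(solutions[[1L]], width = exonLengths)
}

# exon index of each alignment column (0 for columns preceding the first
# reference base); insertion columns (reference '.') attach to the exon of
# the preceding reference base
.columnExon <- function(refChars, exonLengths) {
  cdsPos <- cumsum(refChars != ".")
  exonOfCds <- rep(seq_along(exonLengths), exonLengths)
  ifelse(cdsPos == 0L, 1L, exonOfCds[pmax(cdsPos, 1L)])
}

#' Rebuild an allele's genomic sequence against the reference backbone
#'
#' Replaces the exons of the reference genomic sequence with the allele's
#' exon sequences taken from the CDS alignment. Unsequenced positions
#' (`*`) are filled from a donor: the reference base at the same alignment
#' column when the reference is sequenced there, otherwise the first row in
#' file order carrying a base. Alignment-gap columns (`.`) contribute no
#' base, so the result length can differ from the reference only through
#' them. Non-exon (intron and flank) positions copy the reference genomic.
#'
#' @param aln A [CdsAlignmentSet-class].
#' @param allele Allele name (a row of `aln`).
#' @param ref A [ReferenceLocus-class]; its exon intervals must match the
#'   alignment's exon lengths.
#' @return The allele's genomic sequence as a character string.
#' @export
buildGenomicSeq <- function(aln, allele, ref) {
  rows <- aln@rows
  if (!allele %in% names(rows)) stop("unknown allele: ", allele)
  exonLengths <- aln@exonLengths
  ex <- ref@exonIntervals
  if (length(ex) != length(exonLengths) ||
      !all(width(ex) == exonLengths))
    stop("exon/CDS length bookkeeping mismatch between alignment and reference")

  refChars <- strsplit(rows[[1L]], "")[[1L]]
  ch <- strsplit(rows[[allele]], "")[[1L]]

  unk <- which(ch == "*")
  if (length(unk)) {
    donor <- refChars[unk]
    need <- which(!donor %in% c("A", "C", "G", "T"))
    for (i in need) {
      col <- unk[i]
      for (r in rows) {
        b <- substr(r, col, col)
        if (b %in% c("A", "C", "G", "T")) { donor[i] <- b; break }
      }
      if (!donor[i] %in% c("A", "C", "G", "T")) donor[i] <- "."
    }
    ch[unk] <- donor
  }

  exonOf <- .columnExon(refChars, exonLengths)
  alleleExon <- vapply(seq_along(exonLengths), function(e) {
    keep <- exonOf == e & ch != "."
    paste(ch[keep], collapse = "")
  }, "")

  g <- as.character(ref@genomic)
  pieces <- character(2L * length(ex) + 1L)
  prev <- 0L
  for (e in seq_along(ex)) {
    pieces[2L * e - 1L] <- substr(g, prev + 1L, start(ex)[e] - 1L)
    pieces[2L * e] <- alleleExon[e]
    prev <- end(ex)[e]
  }
  pieces[2L * length(ex) + 1L] <- substr(g, prev + 1L, nchar(g))
  paste(pieces, collapse = "")
}

#' Extract the trimmed target window from a genomic sequence
#'
#' @param genomic Genomic sequence (character or `DNAString`).
#' @param ref A [ReferenceLocus-class] carrying the window coordinates
#'   (start 1-based inclusive).
#' @return The target substring.
#' @export
extractTarget <- function(genomic, ref) {
  g <- as.character(genomic)
  s <- ref@targetStart
  e <- s + ref@targetLength - 1L
  if (s < 1L || e > nchar(g))
    stop("target window [", s, ", ", e, "] out of range for a ",
         nchar(g), " bp sequence")
  substr(g, s, e)
}

#' Deduplicate target sequences into a typing panel
#'
#' Groups alleles with identical target sequences and keeps one
#' representative per group: the lexicographically smallest allele name
#' (C-locale ordering), a deterministic and benign choice since accuracy
#' is scored at group-membership level.
#'
#' @param targets Named character vector (or `DNAStringSet`) of target
#'   sequences, one per allele.
#' @param cds Optional named character vector of in-window coding sequences
#'   per allele (defaults to the targets themselves).
#' @param ref A [ReferenceLocus-class].
#' @param locus Locus name; defaults to `locusName(ref)`.
#' @return An [AlleleTargetPanel-class].
#' @export
dedupeTargets <- function(targets, ref, cds = NULL, locus = NULL) {
  tg <- setNames(as.character(targets), names(targets))
  if (is.null(names(tg)) || any(!nzchar(names(tg))))
    stop("targets must be named by allele")
  if (is.null(cds)) cds <- tg
  cds <- setNames(as.character(cds), names(cds))
  grp <- split(names(tg), factor(tg, levels = unique(tg)))
  reps <- vapply(grp, function(g) sort(g, method = "radix")[1L], "")
  ord <- order(reps, method = "radix")
  reps <- reps[ord]
  members <- lapply(grp[ord], function(g) sort(g, method = "radix"))
  names(members) <- reps
  if (is.null(locus)) locus <- ref@locus
  new("AlleleTargetPanel", locus = locus,
      targets = setNames(DNAStringSet(tg[reps]), reps),
      cds = setNames(DNAStringSet(cds[reps]), reps),
      members = members, reference = ref)
}

# coding positions of the reference inside the target window, relative to
# the window start
.windowExonPositions <- function(ref) {
  win <- ref@targetStart:(ref@targetStart + ref@targetLength - 1L)
  exPos <- unlist(lapply(seq_along(ref@exonIntervals), function(e)
    start(ref@exonIntervals)[e]:end(ref@exonIntervals)[e]))
  win[win %in% exPos] - ref@targetStart + 1L
}

#' Build the deduplicated target panel for one locus
#'
#' Runs the full target-preparation pipeline: for every allele in the CDS
#' alignment, rebuild its genomic sequence against the reference backbone
#' ([buildGenomicSeq]), trim the target window ([extractTarget]) and
#' deduplicate identical targets ([dedupeTargets]). The panel's scoring
#' sequences (`panelCds`) are the concatenated coding positions inside the
#' window, i.e. what an exon-trimmed read should align to.
#'
#' @param aln A [CdsAlignmentSet-class].
#' @param ref A [ReferenceLocus-class].
#' @return An [AlleleTargetPanel-class].
#' @export
buildPanel <- function(aln, ref) {
  alleles <- names(aln@rows)
  targets <- vapply(alleles, function(a)
    extractTarget(buildGenomicSeq(aln, a, ref), ref), "")
  pos <- .windowExonPositions(ref)
  cds <- vapply(targets, function(t)
    paste(strsplit(t, "")[[1L]][pos], collapse = ""), "")
  dedupeTargets(targets, ref, cds = cds, locus = aln@locus)
}

#' Build a target panel from the external input files
#'
#' Convenience wrapper for file-based workflows: parses the nuc-alignment
#' file, reads the reference genomic FASTA, locates the exons of the
#' reference CDS on it and builds the deduplicated panel for the given
#' target window.
#'
#' @param nucFile Path to the per-locus CDS alignment
#'   (see [parseCdsAlignment]).
#' @param fastaFile Path to the reference genomic FASTA (first record).
#' @param targetStart,targetLength Target window (1-based start).
#' @param locus Locus name; defaults to the alignment's.
#' @return An [AlleleTargetPanel-class].
#' @export
buildPanelFromFiles <- function(nucFile, fastaFile, targetStart,
                                targetLength, locus = NULL) {
  aln <- parseCdsAlignment(nucFile, locus = locus)
  g <- readDNAStringSet(fastaFile)[[1L]]
  refRow <- alignmentRows(aln)[[1L]]
  refCds <- gsub(".", "", refRow, fixed = TRUE)
  ex <- locateExons(g, refCds, exonLengths(aln))
  ref <- ReferenceLocus(locusName(aln), aln@referenceAllele, g, ex,
                        targetStart, targetLength)
  buildPanel(aln, ref)
}

#' Write a target panel as FASTA plus a group-membership table
#'
#' @param panel An [AlleleTargetPanel-class].
#' @param fastaFile Path for the target FASTA (record id = representative).
#' @param groupFile Path for the TSV mapping representative, member, locus.
#' @return Invisibly, the group table.
#' @export
writePanel <- function(panel, fastaFile, groupFile) {
  writeXStringSet(panel@targets, fastaFile)
  tab <- data.frame(
    representative = rep(names(panel@members), lengths(panel@members)),
    member = unlist(panel@members, use.names = FALSE),
    locus = panel@locus)
  write.table(tab, groupFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Two-digit allele group of HLA-style allele names
#'
#' The first name field after the locus separator `*`, e.g. `"01"` for
#' `"A*01:01:01:01"`.
#'
#' @param alleles Character vector of allele names.
#' @return Character vector of group codes.
#' @export
alleleGroup <- function(alleles) {
  sub(":.*$", "", sub("^[^*]*\\*", "", alleles))
}
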