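# Affine-gap local alignment (front end to the compiled Gotoh aligner).

#' Alignment scoring scheme
#'
#' Substitution and affine-gap parameters of the local aligner. The
#' defaults mirror the LASTZ-style scale used throughout the pipeline:
#' match +90, mismatch -100, and the low gap penalties (open 100,
#' extend 20) appropriate for indel-rich long reads. A gap of length L
#' costs `gapOpening + L * gapExtension`.
#'
#' @param match,mismatch Substitution scores.
#' @param gapOpening,gapExtension Gap penalties (positive costs).
#' @return A named list of class `"AlignScoring"`.
#' @export
alignScoring <- function(match = 90, mismatch = -100,
                         gapOpening = 100, gapExtension = 20) {
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gapOpening = as.integer(gapOpening),
                 gapExtension = as.integer(gapExtension)),
            class = "AlignScoring")
}

# Align a set of queries against one subject on the given strands and keep
# the better alignment per query. Returns a data.frame of alignment
# statistics plus (optionally) a list of per-column position maps.
# Two identity flavours are reported: `identity` over aligned base pairs,
# matches/(matches + mismatches), the convention of the LASTZ identity
# filter; and `colIdentity` over all alignment columns including gaps,
# which penalizes gap-riddled chance alignments of unrelated sequence.
.alignSet <- function(queries, subject, scoring = alignScoring(),
                      strands = c("+", "-"), keepPath = FALSE) {
  qs <- as.character(queries)
  n <- length(qs)
  subject <- toupper(as.character(subject))
  res <- NULL
  paths <- vector("list", n)
  strandOf <- rep(strands[1L], n)
  for (st in strands) {
    q <- if (st == "+") qs else
      as.character(reverseComplement(DNAStringSet(qs)))
    raw <- alignLocalCpp(q, subject, scoring$match, scoring$mismatch,
                         scoring$gapOpening, scoring$gapExtension, keepPath)
    if (is.null(res)) {
      res <- raw$stats
      if (keepPath) paths <- raw$paths
    } else {
      better <- raw$stats[, "score"] > res[, "score"]
      if (any(better)) {
        res[better, ] <- raw$stats[better, , drop = FALSE]
        strandOf[better] <- st
        if (keepPath) paths[better] <- raw$paths[better]
      }
    }
  }
  res <- as.data.frame(res)
  res$strand <- strandOf
  alignedBases <- res$matches + res$mismatches
  cols <- alignedBases + res$gaps
  res$identity <- ifelse(alignedBases > 0, res$matches / alignedBases, 0)
  res$colIdentity <- ifelse(cols > 0, res$matches / cols, 0)
  res$coverage <- ifelse(res$qend > 0,
                         (res$qend - res$qstart + 1) / nchar(qs), 0)
  rownames(res) <- names(queries)
  if (keepPath) attr(res, "paths") <- paths
  res
}

#' Optimal affine-gap local alignment of two sequences
#'
#' Smith-Waterman alignment with affine gap costs (Gotoh algorithm) and a
#' deterministic traceback (ties prefer diagonal, then a gap in the
#' subject, then a gap in the query). Both strands of the query are tried
#' and the better alignment kept (`strand = "-"` reports coordinates on
#' the reverse complement of the query).
#'
#' @param query,subject Sequences (character or `DNAString`).
#' @param scoring An [alignScoring] scheme.
#' @param bothStrands Try the reverse complement of the query too.
#' @param keepPath Also return the per-column position map (`qpos`,
#'   `spos`; `NA` marks a gap).
#' @return A list of class `"LocalAlignment"`: `score`, `identity`
#'   (matches / aligned base pairs, gap columns excluded), `colIdentity`
#'   (matches / all alignment columns, gaps included), `coverage`
#'   (aligned query columns / query length), `readInterval`,
#'   `refInterval` (1-based inclusive), `matches`, `mismatches`, `gaps`,
#'   `strand` and optionally `qpos`/`spos`.
#' @examples
#' localAlign("ACGTACGT", "TTACGTACGTTT")$identity
#' @export
localAlign <- function(query, subject, scoring = alignScoring(),
                       bothStrands = TRUE, keepPath = FALSE) {
  df <- .alignSet(setNames(as.character(query)[1L], "q"), subject, scoring,
                  strands = if (bothStrands) c("+", "-") else "+",
                  keepPath = keepPath)
  out <- list(score = df$score, identity = df$identity,
              colIdentity = df$colIdentity, coverage = df$coverage,
              readInterval = c(df$qstart, df$qend),
              refInterval = c(df$sstart, df$send),
              matches = df$matches, mismatches = df$mismatches,
              gaps = df$gaps, strand = df$strand)
  if (keepPath) {
    p <- attr(df, "paths")[[1L]]
    out$qpos <- p$qpos
    out$spos <- p$spos
  }
  class(out) <- "LocalAlignment"
  out
}

#' @export
print.LocalAlignment <- function(x, ...) {
  cat(sprintf(
    "LocalAlignment: score %d (%s), identity %.3f, coverage %.3f\n",
    x$score, x$strand, x$identity, x$coverage))
  cat(sprintf("  read [%d, %d]  ref [%d, %d]  %d/%d/%d match/mismatch/gap\n",
              x$readInterval[1L], x$readInterval[2L], x$refInterval[1L],
              x$refInterval[2L], x$matches, x$mismatches, x$gaps))
  invisible(x)
}
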