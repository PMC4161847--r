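# Genotype inference: per-read support, pair statistic, the Bayesian
# callers (plain and trimmed-likelihood), the MaxTwo baseline and the
# homozygosity rule.

#' Per-read log-likelihood under one allele
#'
#' Counts mode of the per-read support: the probability that a sequence of
#' the read's length generated from the allele with per-base error rate
#' `delta` equals the read, `matches * log(1 - delta) +
#' mismatches * log(delta / 3)` — the unique form that sums to 1 over all
#' `4^L` length-`L` outcomes (an erroneous base is one of the 3
#' alternatives, uniformly). At `delta = 0.75` all outcomes are equally
#' likely.
#'
#' @param matches,mismatches Counts from the read-vs-allele alignment.
#' @param delta Sequencing error rate in (0, 1).
#' @return Log-likelihood value(s); vectorized over the counts.
#' @export
readLoglik <- function(matches, mismatches, delta) {
  if (delta <= 0 || delta >= 1) stop("delta must be in (0, 1)")
  matches * log1p(-delta) + mismatches * log(delta / 3)
}

#' Per-read support matrix under the chosen mode
#'
#' `"score"` mode uses each cell's best local-alignment score directly
#' (scores capture indels); `"counts"` mode uses the match/mismatch
#' log-likelihood [readLoglik].
#'
#' @param sm A [SupportMatrix-class].
#' @param params A [TypingParams-class].
#' @return Numeric matrix, reads x alleles.
#' @export
supportValues <- function(sm, params = TypingParams()) {
  if (params@mode == "score") return(scoreMatrix(sm))
  readLoglik(SummarizedExperiment::assay(sm, "matches"),
             SummarizedExperiment::assay(sm, "mismatches"), params@delta)
}

#' Pair statistic: summed per-read support of an allele pair
#'
#' A read can only be produced by one allele of the pair, so each read
#' contributes the larger of its supports under the two alleles; the pair
#' statistic is the sum over reads.
#'
#' @param S Numeric support matrix (reads x alleles).
#' @param i,j Column names or indices of the pair (possibly equal).
#' @return The pair statistic.
#' @export
pairStatistic <- function(S, i, j) {
  sum(pmax(S[, i], S[, j]))
}

# log prior of a pair from a per-allele probability vector (NULL = flat)
.pairLogPrior <- function(logp, i, j) {
  if (is.null(logp)) return(0)
  logp[i] + logp[j] + if (i != j) log(2) else 0
}

# Enumerate all unordered pairs (including i == j), compute the (trimmed)
# pair statistic, and return the co-optimal set. The trimmed statistic
# drops, per candidate pair, the k reads with the lowest support under
# that pair -- equivalent to choosing the noise indicators that maximize
# the retained sum.
.typeCore <- function(S, k = 0L, logPrior = NULL, tol = 1e-9) {
  n <- nrow(S); A <- ncol(S)
  if (!n || !A) stop("empty support matrix")
  alleles <- colnames(S)
  if (is.null(alleles)) alleles <- as.character(seq_len(A))
  best <- -Inf
  vals <- list()
  pr <- list()
  for (i in seq_len(A)) {
    Si <- S[, i]
    for (j in i:A) {
      v <- pmax(Si, S[, j])
      val <- if (k > 0L) {
        if (k >= n) 0 else sum(v) - sum(sort(v, partial = seq_len(k))[seq_len(k)])
      } else sum(v)
      val <- val + .pairLogPrior(logPrior, alleles[i], alleles[j])
      pr[[length(pr) + 1L]] <- c(i, j)
      vals[[length(vals) + 1L]] <- val
    }
  }
  vals <- unlist(vals)
  best <- max(vals)
  eps <- tol * max(1, abs(best))
  co <- which(vals >= best - eps)
  pairs <- do.call(rbind, pr[co])
  list(pairs = matrix(alleles[pairs], ncol = 2L), objective = best)
}

# noise flags for one pair: the k reads with the lowest support under the
# pair (ties broken by read order for determinism)
.noiseFlags <- function(S, pair, k) {
  n <- nrow(S)
  flags <- rep(FALSE, n)
  if (k > 0L) {
    v <- pmax(S[, pair[1L]], S[, pair[2L]])
    flags[order(v, seq_len(n))[seq_len(min(k, n))]] <- TRUE
  }
  flags
}

#' Apply the homozygosity rule and assign reads to the pair
#'
#' Each retained, non-noise read is assigned to the pair member with the
#' higher support (ties credit 0.5 to each). When the minority allele's
#' assigned count falls strictly below `homozygousRatio` times the
#' majority's, the sample is called homozygous for the majority allele.
#'
#' @param S Numeric support matrix (reads x alleles).
#' @param pair Character vector of the two called alleles.
#' @param noise Logical vector flagging reads excluded as noise.
#' @param homozygousRatio Threshold on the minority/majority ratio
#'   (default 0.5).
#' @return A list: `pair` (after collapsing), `zygosity`, `counts`,
#'   `assignment` (per-read allele, `NA` for noise-flagged reads).
#' @export
callZygosity <- function(S, pair, noise = rep(FALSE, nrow(S)),
                         homozygousRatio = 0.5) {
  keep <- which(!noise)
  if (!length(keep)) stop("no reads left to assign")
  a <- pair[1L]; b <- pair[2L]
  assign <- rep(NA_character_, nrow(S))
  if (a == b) {
    assign[keep] <- a
    counts <- setNames(length(keep), a)
    return(list(pair = c(a, a), zygosity = "hom", counts = counts,
                assignment = assign))
  }
  sa <- S[keep, a]; sb <- S[keep, b]
  assign[keep] <- ifelse(sa > sb, a, ifelse(sb > sa, b, "tie"))
  ca <- sum(sa > sb) + 0.5 * sum(sa == sb)
  cb <- sum(sb > sa) + 0.5 * sum(sa == sb)
  counts <- setNames(c(ca, cb), c(a, b))
  if (min(ca, cb) < homozygousRatio * max(ca, cb)) {
    major <- if (ca >= cb) a else b
    return(list(pair = c(major, major), zygosity = "hom",
                counts = counts, assignment = assign))
  }
  ord <- order(c(a, b), method = "radix")
  list(pair = c(a, b)[ord], zygosity = "het", counts = counts,
       assignment = assign)
}

# Collapse the co-optimal pairs of the argmax through the homozygosity
# rule and build a GenotypeCall. Ambiguity = more than one distinct final
# genotype among the co-optimal pairs.
.finalizeCall <- function(S, core, k, params, method) {
  pairs <- core$pairs
  finals <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    # all retained reads count towards the zygosity estimate: the noise
    # flags make the pair selection robust but are not evidence that a
    # flagged read is garbage (at low true noise they are real reads,
    # typically the short ones, and excluding them skews the allele
    # balance of heterozygous samples)
    finals[[p]] <- callZygosity(S, pairs[p, ],
                                homozygousRatio = params@homozygousRatio)
  }
  keys <- vapply(finals, function(z) paste(z$pair, collapse = "/"), "")
  ord <- order(keys, method = "radix")
  uniq <- !duplicated(keys[ord])
  sel <- ord[uniq]
  primary <- finals[[sel[1L]]]
  pm <- do.call(rbind, lapply(finals[sel], `[[`, "pair"))
  if (!params@reportTies) pm <- pm[1L, , drop = FALSE]
  flags <- .noiseFlags(S, pairs[sel[1L], ], k)
  reads <- rownames(S)
  if (is.null(reads)) reads <- as.character(seq_len(nrow(S)))
  perRead <- data.frame(read = reads, allele = primary$assignment,
                        noise = flags)
  new("GenotypeCall", pairs = pm, objective = core$objective,
      perRead = perRead, zygosity = primary$zygosity,
      counts = primary$counts, ambiguous = nrow(pm) > 1L,
      method = method)
}

.supportOf <- function(x, params) {
  if (is(x, "SupportMatrix")) supportValues(x, params) else as.matrix(x)
}

#' Bayesian genotype caller (all reads trusted)
#'
#' Maximizes the summed per-read support over all unordered allele pairs
#' (homozygous pairs included). With a flat prior over pairs it suffices
#' to compare the data likelihoods; when a per-allele prior is supplied
#' its log is added. The winning pair is then collapsed through the
#' homozygosity rule ([callZygosity]); co-optimal genotypes are reported
#' as ties.
#'
#' @param x A [SupportMatrix-class], or a plain numeric support matrix
#'   (reads x alleles) used as-is.
#' @param params A [TypingParams-class].
#' @param prior Optional named per-allele prior probabilities.
#' @return A [GenotypeCall-class].
#' @export
setGeneric("bayesTyping0",
           function(x, params = TypingParams(), prior = NULL)
             standardGeneric("bayesTyping0"))

#' @rdname bayesTyping0
#' @export
setMethod("bayesTyping0", "ANY", function(x, params = TypingParams(),
                                          prior = NULL) {
  S <- .supportOf(x, params)
  logPrior <- if (is.null(prior)) NULL else log(prior)
  core <- .typeCore(S, k = 0L, logPrior = logPrior)
  .finalizeCall(S, core, 0L, params, "bayes0")
})

#' Trimmed-likelihood genotype caller (noise-tolerant)
#'
#' Like [bayesTyping0], but assumes a fraction `m` of the input reads are
#' noise (misassigned between samples by barcode-calling errors): for each
#' candidate pair the `floor(m * n)` reads with the lowest support under
#' that pair are flagged as noise and excluded from the sum, and the
#' trimmed sums are compared. With `m = 0` the caller reduces exactly to
#' [bayesTyping0]; with `m = 1` every pair's trimmed sum is empty and all
#' pairs tie.
#'
#' @inheritParams bayesTyping0
#' @return A [GenotypeCall-class]; reads flagged as noise for the winning
#'   pair are marked in `perReadAssignment()`.
#' @export
setGeneric("bayesTyping1",
           function(x, params = TypingParams(), prior = NULL)
             standardGeneric("bayesTyping1"))

#' @rdname bayesTyping1
#' @export
setMethod("bayesTyping1", "ANY", function(x, params = TypingParams(),
                                          prior = NULL) {
  S <- .supportOf(x, params)
  k <- as.integer(floor(params@m * nrow(S)))
  logPrior <- if (is.null(prior)) NULL else log(prior)
  core <- .typeCore(S, k = k, logPrior = logPrior)
  .finalizeCall(S, core, k, params, "bayes1")
})

#' MaxTwo baseline caller
#'
#' Counts, for each allele, the reads whose maximum alignment score is
#' attained at that allele (ties credit every attaining allele) and calls
#' the two top-count alleles, ties broken by name; the pair is then
#' collapsed through the homozygosity rule.
#'
#' @param x A [SupportMatrix-class] or plain score matrix.
#' @param params A [TypingParams-class] (only the homozygosity ratio is
#'   used).
#' @return A [GenotypeCall-class].
#' @export
setGeneric("maxTwo", function(x, params = TypingParams())
  standardGeneric("maxTwo"))

#' @rdname maxTwo
#' @export
setMethod("maxTwo", "ANY", function(x, params = TypingParams()) {
  S <- if (is(x, "SupportMatrix")) scoreMatrix(x) else as.matrix(x)
  if (!nrow(S) || !ncol(S)) stop("empty support matrix")
  nBest <- colSums(S == apply(S, 1L, max))
  alleles <- colnames(S)
  if (is.null(alleles)) alleles <- as.character(seq_len(ncol(S)))
  ord <- order(-nBest, alleles, method = "radix")
  pair <- if (ncol(S) == 1L) rep(alleles, 2L) else alleles[ord[1:2]]
  z <- callZygosity(S, pair, homozygousRatio = params@homozygousRatio)
  reads <- rownames(S)
  if (is.null(reads)) reads <- as.character(seq_len(nrow(S)))
  new("GenotypeCall", pairs = matrix(z$pair, ncol = 2L),
      objective = sum(nBest[pair]),
      perRead = data.frame(read = reads, allele = z$assignment,
                           noise = FALSE),
      zygosity = z$zygosity, counts = z$counts, ambiguous = FALSE,
      method = "maxtwo")
})

#' Type one sample end to end
#'
#' Convenience wrapper: pre-process the reads ([preprocessReads]) and call
#' the genotype with the chosen method.
#'
#' @param reads A `DNAStringSet` of the sample's reads.
#' @param panel An [AlleleTargetPanel-class].
#' @param method `"bayes1"` (default), `"bayes0"` or `"maxtwo"`.
#' @param params A [TypingParams-class].
#' @param prior Optional named per-allele prior probabilities.
#' @param ... Passed to [preprocessReads].
#' @return A [GenotypeCall-class].
#' @export
typeSample <- function(reads, panel,
                       method = c("bayes1", "bayes0", "maxtwo"),
                       params = TypingParams(), prior = NULL, ...) {
  method <- match.arg(method)
  sm <- preprocessReads(reads, panel, ...)
  switch(method,
         bayes0 = bayesTyping0(sm, params, prior),
         bayes1 = bayesTyping1(sm, params, prior),
         maxtwo = maxTwo(sm, params))
}
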