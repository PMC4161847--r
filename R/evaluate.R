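# Experiment harness: full factorial simulation runs, accuracy summaries,
# zygosity contingency tables and the exact-test comparison.

#' Simulate the reads of one sample group at one locus
#'
#' Generates the correct reads of every sample of a group (the given
#' genotype table restricted to one locus) and the run's noise pool for
#' the locus (the union of all samples' reads).
#'
#' @param panel An [AlleleTargetPanel-class] for the locus.
#' @param genotypes The `data.frame` rows of [sampleGenotypes] for this
#'   locus.
#' @param readsPerAllele Correct reads per allele copy.
#' @param model A [ReadErrorModel-class].
#' @return A list: `samples` (list of per-sample `DNAStringSet`s, named by
#'   sample id) and `pool` (their union).
#' @export
simulateGroupReads <- function(panel, genotypes, readsPerAllele,
                               model = ReadErrorModel()) {
  stopifnot(all(genotypes$locus == locusName(panel)))
  sets <- lapply(seq_len(nrow(genotypes)), function(i) {
    g <- genotypes[i, ]
    simulateSampleReads(panel, g$allele1, g$allele2, readsPerAllele,
                        model, sampleId = g$sample)
  })
  names(sets) <- as.character(genotypes$sample)
  list(samples = sets, pool = buildNoisePool(sets))
}

.callWith <- function(sm, method, params, prior) {
  switch(method,
         bayes0 = bayesTyping0(sm, params, prior),
         bayes1 = bayesTyping1(sm, params, prior),
         maxtwo = maxTwo(sm, params),
         stop("unknown method: ", method))
}

.sortedPair <- function(a, b) sort(c(a, b), method = "radix")

#' Run a full factorial typing experiment
#'
#' The complete study design: for each sample group, genotypes are drawn
#' once; for each iteration the reads are regenerated; each sample is then
#' typed at every noise level with every method, after mixing in noise
#' reads drawn from the run's per-locus pool. All randomness flows from
#' the master seed, so a repeated call reproduces the result table
#' exactly.
#'
#' @param plan A [RunPlan-class].
#' @param panel An [AlleleTargetPanel-class] or named list of panels.
#' @param freq Allele-group frequency table (see [normalizeFrequencies]).
#' @param model A [ReadErrorModel-class].
#' @param methods Subset of `c("bayes0", "bayes1", "maxtwo")`.
#' @param params A [TypingParams-class].
#' @param seed Master RNG seed.
#' @param homozygousFraction Design fraction of homozygous samples.
#' @param scoring An [alignScoring] scheme.
#' @param prior Optional named per-allele prior probabilities.
#' @param poolSamples Optionally restrict the noise pool to the first
#'   `poolSamples` samples of the group (the pool-diversity sweep);
#'   `NULL` uses all samples.
#' @param ... Further arguments to [preprocessReads].
#' @return A `data.frame`, one row per (group, iteration, sample, locus,
#'   noise level, method): the truth pair, the called pair, `correct`
#'   (the call is unique and matches the truth), `ambiguous` (several
#'   co-optimal genotypes, the truth among them), zygosity truth/call and
#'   a `failed` reason for samples the pipeline rejected.
#' @export
runExperiment <- function(plan, panel, freq, model = ReadErrorModel(),
                          methods = c("bayes0", "bayes1", "maxtwo"),
                          params = TypingParams(), seed = NULL,
                          homozygousFraction = 0.3,
                          scoring = alignScoring(), prior = NULL,
                          poolSamples = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  panel <- .asPanelList(panel)
  rows <- list()
  for (g in seq_len(plan@groups)) {
    geno <- sampleGenotypes(freq, panel, plan@samplesPerGroup,
                            homozygousFraction)
    for (it in seq_len(plan@iterations)) {
      for (loc in names(panel)) {
        gl <- geno[geno$locus == loc, ]
        run <- simulateGroupReads(panel[[loc]], gl, plan@readsPerAllele,
                                  model)
        pool <- run$pool
        if (!is.null(poolSamples))
          pool <- pool[mcols(pool)$sample %in%
                         gl$sample[seq_len(poolSamples)]]
        for (s in seq_len(nrow(gl))) {
          truth <- .sortedPair(gl$allele1[s], gl$allele2[s])
          for (nv in plan@noiseLevels) {
            mixed <- mixReads(run$samples[[s]], pool, nv)
            sm <- tryCatch(
              preprocessReads(mixed, panel[[loc]], scoring, ...),
              error = function(e) e)
            for (meth in methods) {
              call <- if (inherits(sm, "error")) sm else
                tryCatch(.callWith(sm, meth, params, prior),
                         error = function(e) e)
              rows[[length(rows) + 1L]] <-
                .resultRow(g, it, gl$sample[s], loc, nv, meth, truth,
                           call)
            }
          }
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

.resultRow <- function(group, iteration, sample, locus, noise, method,
                       truth, call) {
  zygTruth <- if (truth[1L] == truth[2L]) "hom" else "het"
  if (inherits(call, "error"))
    return(data.frame(group = group, iteration = iteration,
                      sample = sample, locus = locus, noise = noise,
                      method = method, truth1 = truth[1L],
                      truth2 = truth[2L], called1 = NA_character_,
                      called2 = NA_character_, nCalls = 0L,
                      correct = FALSE, ambiguous = FALSE,
                      zygosityTruth = zygTruth,
                      zygosityCalled = NA_character_,
                      failed = conditionMessage(call)))
  pairs <- calledPairs(call)
  truthIn <- any(apply(pairs, 1L, function(p)
    identical(.sortedPair(p[1L], p[2L]), truth)))
  unique1 <- nrow(pairs) == 1L
  data.frame(group = group, iteration = iteration, sample = sample,
             locus = locus, noise = noise, method = method,
             truth1 = truth[1L], truth2 = truth[2L],
             called1 = pairs[1L, 1L], called2 = pairs[1L, 2L],
             nCalls = nrow(pairs),
             correct = unique1 && truthIn,
             ambiguous = !unique1 && truthIn,
             zygosityTruth = zygTruth, zygosityCalled = zygosity(call),
             failed = NA_character_)
}

#' Summarize error rates by stratum
#'
#' Error rate is `1 - correct/total` per stratum; ambiguous calls (several
#' co-optimal genotypes, the truth among them) are tallied separately and
#' count as errors in the error rate.
#'
#' @param res The result table of [runExperiment].
#' @param by Stratification columns (default locus, noise level, method).
#' @return A `data.frame` with totals, correct/ambiguous counts, and
#'   `errorRate`/`ambiguousRate` per stratum.
#' @export
accuracySummary <- function(res, by = c("locus", "noise", "method")) {
  if (!nrow(res)) {
    warning("empty result table")
    return(data.frame())
  }
  agg <- aggregate(cbind(total = rep(1L, nrow(res)),
                         correct = res$correct,
                         ambiguous = res$ambiguous),
                   by = res[, by, drop = FALSE], FUN = sum)
  agg$errorRate <- 1 - agg$correct / agg$total
  agg$ambiguousRate <- agg$ambiguous / agg$total
  agg[do.call(order, unname(as.list(agg[, by, drop = FALSE]))), ,
      drop = FALSE]
}

#' Contingency table of correctness by zygosity
#'
#' Sums correct and wrong predictions separately for homozygous and
#' heterozygous samples over the selected result rows.
#'
#' @param res The result table of [runExperiment] (subset it to one
#'   method or locus group as needed).
#' @return A [ContingencyTable-class].
#' @export
zygosityContingency <- function(res) {
  hom <- res$zygosityTruth == "hom"
  ContingencyTable(correctHom = sum(res$correct & hom),
                   errorHom = sum(!res$correct & hom),
                   correctHet = sum(res$correct & !hom),
                   errorHet = sum(!res$correct & !hom))
}

#' Exact test of homozygous versus heterozygous call accuracy
#'
#' The odds ratio is the sample odds ratio
#' `(correctHom / errorHom) / (correctHet / errorHet)`; the p-value is the
#' two-sided exact probability obtained by summing hypergeometric
#' probabilities no larger than the observed table's. When a cell is zero
#' the odds ratio is computed with a 0.5 Haldane correction on all cells
#' and flagged.
#'
#' @param x A [ContingencyTable-class], or a numeric vector/2x2 matrix of
#'   counts in the order correctHom, errorHom, correctHet, errorHet.
#' @return A list: `oddsRatio`, `pValue`, `haldane` (correction applied).
#' @examples
#' fisherExactTable(ContingencyTable(6720, 330, 15814, 1136))$oddsRatio
#' @export
fisherExactTable <- function(x) {
  if (is(x, "ContingencyTable")) x <- as.vector(asCounts(x))
  x <- as.numeric(x)
  if (length(x) != 4L) stop("expected 4 counts")
  if (any(x < 0)) stop("counts must be nonnegative")
  haldane <- any(x == 0)
  xc <- if (haldane) x + 0.5 else x
  or <- (xc[1L] / xc[2L]) / (xc[3L] / xc[4L])
  p <- fisher.test(matrix(round(x), nrow = 2L))$p.value
  list(oddsRatio = or, pValue = p, haldane = haldane)
}
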