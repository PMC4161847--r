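# Simulation of sample genotypes, CCS reads and barcode-miscall noise.

#' Normalize a population allele-group frequency table
#'
#' Replaces zero frequencies with a small pseudo-frequency (so rare groups
#' stay reachable) and renormalizes each locus to sum to 1.
#'
#' @param freq `data.frame` with columns `locus`, `group`, `frequency`.
#' @param pseudo Pseudo-frequency assigned to zero entries (default 0.001,
#'   i.e. 0.1%).
#' @return The table with normalized frequencies.
#' @examples
#' f <- data.frame(locus = "A", group = c("01", "02", "03"),
#'                 frequency = c(0.5, 0.5, 0))
#' normalizeFrequencies(f)
#' @export
normalizeFrequencies <- function(freq, pseudo = 0.001) {
  stopifnot(all(c("locus", "group", "frequency") %in% names(freq)))
  if (!nrow(freq)) stop("empty frequency table")
  if (any(freq$frequency < 0)) stop("frequencies must be nonnegative")
  for (loc in unique(freq$locus)) {
    i <- freq$locus == loc
    f <- freq$frequency[i]
    if (!length(f)) stop("empty locus: ", loc)
    f[f == 0] <- pseudo
    freq$frequency[i] <- f / sum(f)
  }
  freq
}

.asPanelList <- function(panel) {
  if (is(panel, "AlleleTargetPanel"))
    panel <- setNames(list(panel), locusName(panel))
  stopifnot(length(names(panel)) == length(panel))
  panel
}

#' Draw sample genotypes from population frequencies
#'
#' Loci are sampled independently (no linkage disequilibrium). Per locus,
#' a two-digit allele group is drawn by its population frequency and a
#' panel representative is then drawn uniformly within the group (the
#' frequency census stops at two-digit resolution). Exactly
#' `floor(homozygousFraction * n)` samples are made homozygous at each
#' locus by copying the first allele; the remaining samples receive two
#' distinct alleles (the second is redrawn on a coincidental match, so the
#' realized identical-pair fraction equals the design fraction).
#'
#' @param freq Frequency table (see [normalizeFrequencies]); normalized
#'   internally.
#' @param panel An [AlleleTargetPanel-class] or a named list of panels
#'   (one per locus in `freq`).
#' @param n Number of samples.
#' @param homozygousFraction Design fraction of homozygous samples
#'   (default 0.3).
#' @param seed Optional RNG seed.
#' @param pseudo Passed to [normalizeFrequencies].
#' @return `data.frame` with columns `sample`, `locus`, `allele1`,
#'   `allele2`, `homozygous`.
#' @export
sampleGenotypes <- function(freq, panel, n, homozygousFraction = 0.3,
                            seed = NULL, pseudo = 0.001) {
  if (!is.null(seed)) set.seed(seed)
  freq <- normalizeFrequencies(freq, pseudo)
  panel <- .asPanelList(panel)
  out <- list()
  for (loc in unique(freq$locus)) {
    if (!loc %in% names(panel)) stop("no panel for locus ", loc)
    reps <- names(targetSeqs(panel[[loc]]))
    byGroup <- split(reps, alleleGroup(reps))
    fl <- freq[freq$locus == loc, ]
    missing <- setdiff(fl$group, names(byGroup))
    if (length(missing))
      stop("locus ", loc, ": frequency group(s) without panel member: ",
           paste(missing, collapse = ", "))
    draw <- function(k) {
      g <- sample(fl$group, k, replace = TRUE, prob = fl$frequency)
      vapply(g, function(gg) {
        r <- byGroup[[gg]]
        if (length(r) == 1L) r else sample(r, 1L)
      }, "", USE.NAMES = FALSE)
    }
    a1 <- draw(n)
    a2 <- draw(n)
    nHom <- floor(homozygousFraction * n)
    homIdx <- if (nHom > 0L) sample.int(n, nHom) else integer()
    a2[homIdx] <- a1[homIdx]
    if (length(unique(reps)) > 1L) {
      het <- setdiff(seq_len(n), homIdx)
      clash <- het[a2[het] == a1[het]]
      while (length(clash)) {
        a2[clash] <- draw(length(clash))
        clash <- clash[a2[clash] == a1[clash]]
      }
    }
    out[[loc]] <- data.frame(sample = seq_len(n), locus = loc,
                             allele1 = a1, allele2 = a2,
                             homozygous = a1 == a2)
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}

.BASES <- c("A", "C", "G", "T")
# 3 substitution alternatives per base
.SUBALT <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 3, dimnames = list(NULL, .BASES))

#' Simulate CCS reads from a target sequence
#'
#' Per read, a length is drawn from `Normal(lengthMean, lengthSd)` clipped
#' to `[minLength, target length]` and a start position uniformly over
#' valid starts; a per-read accuracy is drawn from
#' `Normal(accuracyMean, accuracySd)` clipped to `[0.5, 1]`, and errors are
#' placed i.i.d. per template base at rate `1 - accuracy`, split into
#' substitutions (uniform over the 3 alternative bases), insertions
#' (a uniform base inserted after the template base) and deletions
#' according to the model's error mix.
#'
#' @param target Target sequence (character or `DNAString`).
#' @param n Number of reads; `n <= 0` yields an empty set.
#' @param model A [ReadErrorModel-class].
#' @param seed Optional RNG seed.
#' @param idPrefix Prefix for read ids.
#' @return A [Biostrings::DNAStringSet] with `mcols` columns
#'   `templateStart`, `templateEnd` (the true source substring on the
#'   target) and `accuracy` (the drawn per-read accuracy).
#' @export
simulateCcsReads <- function(target, n, model = ReadErrorModel(),
                             seed = NULL, idPrefix = "read") {
  if (!is.null(seed)) set.seed(seed)
  target <- toupper(as.character(target))
  L <- nchar(target)
  if (L < model@minLength)
    stop("target (", L, " bp) shorter than the minimum read length (",
         model@minLength, " bp)")
  if (n <= 0) {
    out <- DNAStringSet()
    mcols(out) <- DataFrame(templateStart = integer(),
                            templateEnd = integer(), accuracy = numeric())
    return(out)
  }
  len <- as.integer(pmin(pmax(round(rnorm(n, model@lengthMean,
                                          model@lengthSd)),
                              model@minLength), L))
  start <- as.integer(floor(runif(n) * (L - len + 1)) + 1L)
  acc <- pmin(pmax(rnorm(n, model@accuracyMean, model@accuracySd), 0.5), 1)
  tchars <- strsplit(target, "")[[1L]]
  mix <- model@errorMix / sum(model@errorMix)

  seqs <- character(n)
  for (i in seq_len(n)) {
    tpl <- tchars[start[i]:(start[i] + len[i] - 1L)]
    e <- 1 - acc[i]
    if (e <= 0) { seqs[i] <- paste(tpl, collapse = ""); next }
    err <- runif(len[i]) < e
    nerr <- sum(err)
    if (nerr == 0L) { seqs[i] <- paste(tpl, collapse = ""); next }
    type <- sample(c("S", "I", "D"), nerr, replace = TRUE, prob = mix)
    out <- tpl
    subIdx <- which(err)[type == "S"]
    if (length(subIdx))
      out[subIdx] <- .SUBALT[cbind(sample.int(3L, length(subIdx),
                                              replace = TRUE),
                                   match(tpl[subIdx], .BASES))]
    cnt <- rep(1L, len[i])
    cnt[which(err)[type == "D"]] <- 0L
    insIdx <- which(err)[type == "I"]
    cnt[insIdx] <- 2L
    idx <- rep(seq_len(len[i]), cnt)
    r <- out[idx]
    dup <- duplicated(idx)
    if (any(dup)) r[dup] <- sample(.BASES, sum(dup), replace = TRUE)
    seqs[i] <- paste(r, collapse = "")
  }
  out <- DNAStringSet(seqs)
  names(out) <- sprintf("%s_%d", idPrefix, seq_len(n))
  mcols(out) <- DataFrame(templateStart = start,
                          templateEnd = start + len - 1L, accuracy = acc)
  out
}

#' Simulate the correct reads of one sample at one locus
#'
#' Draws `readsPerAllele` reads from the target sequence of each of the
#' sample's two alleles (a homozygous sample thus contributes
#' `2 * readsPerAllele` reads of the same target), labelled with their
#' truth: sample, locus, source allele, `isNoise = FALSE`.
#'
#' @param panel An [AlleleTargetPanel-class].
#' @param allele1,allele2 Representative allele names of the genotype.
#' @param readsPerAllele Reads per allele copy.
#' @param model A [ReadErrorModel-class].
#' @param sampleId Sample identifier stored in the truth labels.
#' @param seed Optional RNG seed.
#' @return A `DNAStringSet` with truth labels in `mcols`.
#' @export
simulateSampleReads <- function(panel, allele1, allele2, readsPerAllele,
                                model = ReadErrorModel(), sampleId = 1L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tg <- targetSeqs(panel)
  sets <- lapply(c(allele1, allele2), function(a) {
    if (!a %in% names(tg)) stop("allele not in panel: ", a)
    r <- simulateCcsReads(as.character(tg[[a]]), readsPerAllele, model,
                          idPrefix = paste0("s", sampleId, "_", a))
    mc <- mcols(r)
    mc$sample <- sampleId
    mc$locus <- locusName(panel)
    mc$allele <- a
    mc$isNoise <- FALSE
    mcols(r) <- mc
    r
  })
  reads <- c(sets[[1L]], sets[[2L]])
  names(reads) <- sprintf("s%s_r%d", sampleId, seq_along(reads))
  reads
}

#' Pool the reads of all samples of a run at one locus
#'
#' The pool from which barcode-miscalled noise reads are drawn: the union
#' of the locus reads over all samples in the run.
#'
#' @param readSets A list of `DNAStringSet`s (per sample), or a single set.
#' @return One combined `DNAStringSet`.
#' @export
buildNoisePool <- function(readSets) {
  if (is(readSets, "DNAStringSet")) return(readSets)
  if (!length(readSets)) {
    out <- DNAStringSet()
    mcols(out) <- DataFrame(sample = integer(0))
    return(out)
  }
  do.call(c, unname(readSets))
}

#' Mix a sample's correct reads with noise reads from the run pool
#'
#' Draws `nNoise` reads uniformly without replacement from the pool and
#' appends them to the sample's correct reads, flagged `isNoise = TRUE`
#' (a drawn read that happens to originate from the focal sample keeps the
#' flag: truth labels retain its origin). The output order is shuffled.
#'
#' @param correct The sample's own reads (`isNoise` will be set `FALSE`).
#' @param pool The run's read pool for the locus ([buildNoisePool]).
#' @param nNoise Number of noise reads to add.
#' @param seed Optional RNG seed.
#' @param excludeSample Optional sample id whose reads are excluded from
#'   the draw (by default the focal sample's own pool contribution may be
#'   drawn).
#' @return A `DNAStringSet` of `length(correct) + nNoise` reads.
#' @export
mixReads <- function(correct, pool, nNoise, seed = NULL,
                     excludeSample = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mc <- mcols(correct)
  mc$isNoise <- rep(FALSE, length(correct))
  mcols(correct) <- mc
  cand <- pool
  if (!is.null(excludeSample))
    cand <- pool[mcols(pool)$sample != excludeSample]
  if (nNoise > length(cand))
    stop("nNoise (", nNoise, ") exceeds the pool size (", length(cand), ")")
  if (nNoise > 0L) {
    noise <- cand[sample.int(length(cand), nNoise)]
    mcn <- mcols(noise)
    mcn$isNoise <- rep(TRUE, length(noise))
    mcols(noise) <- mcn
    names(noise) <- sprintf("%s.n%d", names(noise), seq_along(noise))
    keep <- intersect(names(mcols(correct)), names(mcols(noise)))
    mcols(correct) <- mcols(correct)[, keep, drop = FALSE]
    mcols(noise) <- mcols(noise)[, keep, drop = FALSE]
    out <- c(correct, noise)
  } else out <- correct
  out[sample.int(length(out))]
}

#' Expected reads per multiplexed product
#'
#' The average number of reads available for one distinct sequencing
#' product when a cell's CCS yield is split over an
#' amplicons-by-barcode-pairs multiplexing design (e.g. 15,000 reads over
#' 49 amplicons x 48 barcode pairs gives 6.38 reads per product).
#'
#' @param ccsYield Usable CCS reads per cell for the insert size.
#' @param amplicons Number of amplicons multiplexed.
#' @param barcodePairs Number of barcode pairs.
#' @return Reads per distinct product.
#' @export
readsPerProduct <- function(ccsYield = 15000, amplicons = 49,
                            barcodePairs = 48) {
  ccsYield / (amplicons * barcodePairs)
}

#' Write simulated reads as FASTA plus a truth table
#'
#' @param reads A `DNAStringSet` with truth labels in `mcols`.
#' @param fastaFile Path for the FASTA output.
#' @param truthFile Optional path for a TSV of read id, sample, locus,
#'   true allele and noise flag.
#' @return Invisibly, the truth table.
#' @export
writeSimulatedReads <- function(reads, fastaFile, truthFile = NULL) {
  writeXStringSet(reads, fastaFile)
  mc <- mcols(reads)
  tab <- data.frame(read = names(reads),
                    sample = mc$sample, locus = mc$locus,
                    allele = mc$allele, is_noise = mc$isNoise)
  if (!is.null(truthFile))
    write.table(tab, truthFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(tab)
}
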