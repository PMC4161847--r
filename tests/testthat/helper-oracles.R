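# Independent oracles and small fixtures shared across tests.

# Biostrings local alignment score under the same scoring convention
# (gap of length L costs gapOpening + L * gapExtension); an established,
# independent dynamic-programming implementation.
oracleScore <- function(q, s, match = 90, mismatch = -100,
                        gapOpening = 100, gapExtension = 20) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = mat,
    gapOpening = gapOpening, gapExtension = gapExtension))
}

# Exhaustive enumeration oracle for the genotype callers: all unordered
# pairs; for the trimmed caller additionally all size-k noise subsets.
oracleBestPairs <- function(S, m = 0, tol = 1e-9) {
  n <- nrow(S); A <- ncol(S)
  alleles <- colnames(S)
  if (is.null(alleles)) alleles <- as.character(seq_len(A))
  k <- floor(m * n)
  vals <- c(); prs <- list()
  for (i in seq_len(A)) for (j in i:A) {
    v <- pmax(S[, i], S[, j])
    if (k == 0) {
      val <- sum(v)
    } else if (k >= n) {
      val <- 0
    } else {
      # best over all noise subsets of size k = drop that subset
      subs <- utils::combn(n, k)
      val <- max(apply(subs, 2L, function(drop) sum(v[-drop])))
    }
    vals <- c(vals, val)
    prs[[length(prs) + 1L]] <- sort(c(alleles[i], alleles[j]))
  }
  best <- max(vals)
  eps <- tol * max(1, abs(best))
  list(objective = best,
       pairs = unique(lapply(prs[vals >= best - eps], identity)))
}

# direct hypergeometric enumeration of the two-sided exact p-value
oracleFisherP <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# a small, fast synthetic locus for pipeline tests
tinyLocus <- function(seed = 1, nAlleles = 4, divergence = 0.03) {
  syntheticLocus(locus = "T", nAlleles = nAlleles,
                 divergence = divergence, genomicLength = 900,
                 targetStart = 150, targetLength = 400,
                 exonIntervals = IRanges::IRanges(
                   start = c(50, 200, 380), end = c(100, 320, 470)),
                 seed = seed)
}

tinyModel <- function() {
  ReadErrorModel(lengthMean = 250, lengthSd = 60, minLength = 50)
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# support matrix on plain random values for caller tests
randomSupport <- function(n, A, scale = 10) {
  S <- matrix(round(runif(n * A) * scale, 2), n, A,
              dimnames = list(sprintf("r%d", seq_len(n)),
                              sprintf("a%d", seq_len(A))))
  S
}
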