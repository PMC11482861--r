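# The Bayesian filter deciding, for each RY-matched but kmer-mismatched
# seed candidate, whether deamination (M) or spurious coincidence (not-M)
# better explains the observation.

#' @rdname FilterConfig-class
#' @param a,b power-law constants of the spurious per-base mismatch rate
#'   p = a * k^b (defaults fit from bacterial-read simulations and adopted
#'   as given).
#' @param kCutoff,longKConstant seed lengths k >= kCutoff use the flat
#'   spurious likelihood `longKConstant` for every mismatch count (the
#'   mismatch proportion tapers off for long seeds and resists a clean
#'   power-law fit).
#' @param priorV prior probability of the deamination explanation.
#' @param thresholdJ posterior cutoff for rescue (inclusive: posterior >=
#'   thresholdJ passes).
#' @export
FilterConfig <- function(a = 1.0014, b = -0.6628, kCutoff = 22L,
                         longKConstant = 0.01, priorV = 0.5,
                         thresholdJ = 0.5) {
  new("FilterConfig", a = a, b = b, kCutoff = as.integer(kCutoff),
      longKConstant = longKConstant, priorV = priorV, thresholdJ = thresholdJ)
}

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf(paste0("FilterConfig: p = %.4f * k^%.4f (flat %.3g at k >= %d), ",
                     "prior V = %.2f, threshold j = %.2f\n"),
              object@a, object@b, object@longKConstant, object@kCutoff,
              object@priorV, object@thresholdJ))
})

#' Likelihood of a seed comparison under the spurious-match model
#'
#' For k < kCutoff, the probability of observing m kmer-space mismatches in
#' a spurious RY-space match is binomial, C(k,m) p^m (1-p)^(k-m), with a
#' power-law per-base mismatch rate p = a * k^b (p is clamped into [0,1];
#' with the default constants only k = 1 would exceed 1). For k >= kCutoff
#' the likelihood is the flat constant regardless of m.
#'
#' @param k seed length.
#' @param m observed mismatch count, 0 <= m <= k.
#' @param config a [FilterConfig-class].
#' @return vector of probabilities.
#' @export
spuriousLikelihood <- function(k, m, config = FilterConfig()) {
  stopifnot(is(config, "FilterConfig"))
  n <- max(length(k), length(m))
  k <- rep_len(as.integer(k), n); m <- rep_len(as.integer(m), n)
  if (any(m < 0) || any(m > k)) stop("m must satisfy 0 <= m <= k")
  out <- numeric(n)
  long <- k >= config@kCutoff
  out[long] <- config@longKConstant
  if (any(!long)) {
    kk <- k[!long]
    p <- pmin(pmax(config@a * kk^config@b, 0), 1)
    out[!long] <- dbinom(m[!long], kk, p)
  }
  out
}

#' Build seed comparisons from read/candidate key pairs
#'
#' Expands each (read kmer, candidate minimizer) pair into per-base records
#' in read (sequenced-strand) orientation, the geometry on which the
#' deamination model is defined. For windows matched in reverse canonical
#' orientation the comparison is performed with both kmers
#' reverse-complemented back to read orientation first.
#'
#' @param readKey,candKey kmer keys, as [KmerCode-class] or hex strings.
#' @param k seed length in bases.
#' @param orient per-pair window orientation (0 = canonical key equals the
#'   read substring, 1 = its reverse complement).
#' @param readOffset 0-based offset of the seed within the read.
#' @param readLength read length in bases.
#' @return a [SeedComparisons-class].
#' @export
seedComparisons <- function(readKey, candKey, k, orient = 0L,
                            readOffset = 0L, readLength = k) {
  if (is(readKey, "KmerCode")) readKey <- readKey@bits
  if (is(candKey, "KmerCode")) candKey <- candKey@bits
  k <- as.integer(k)
  n <- max(length(readKey), length(candKey))
  readKey <- rep_len(readKey, n); candKey <- rep_len(candKey, n)
  orient <- rep_len(as.integer(orient), n)
  readOffset <- rep_len(as.integer(readOffset), n)
  readLength <- rep_len(as.integer(readLength), n)

  readSeq <- cpp_decode_kmer(readKey, k)
  candSeq <- cpp_decode_kmer(candKey, k)
  rev <- orient == 1L
  if (any(rev)) {
    readSeq[rev] <- cpp_revcomp_seq(readSeq[rev])
    candSeq[rev] <- cpp_revcomp_seq(candSeq[rev])
  }
  toMat <- function(s) {
    if (n == 0L) return(matrix(character(), 0L, k))
    matrix(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE),
           nrow = n, ncol = k, byrow = TRUE)
  }
  rb <- toMat(readSeq)
  gb <- toMat(candSeq)
  p5 <- matrix(rep(readOffset, k), nrow = n) +
    matrix(rep(0:(k - 1L), each = n), nrow = n)
  p3 <- matrix(rep(readLength, k), nrow = n) - 1L - p5
  new("SeedComparisons", readKey = readKey, candKey = candKey, k = k,
      m = as.integer(rowSums(rb != gb)), readBases = rb, refBases = gb,
      posFrom5p = p5, posFrom3p = p3, readLength = readLength)
}

setMethod("show", "SeedComparisons", function(object) {
  cat(sprintf("SeedComparisons: %d pair(s), k = %d, mismatches %s\n",
              length(object@readKey), object@k,
              if (length(object@m)) paste0("0..", max(object@m)) else "-"))
})

setMethod("length", "SeedComparisons", function(x) length(x@readKey))

#' Likelihood of a seed comparison under the deamination model
#'
#' Product over the seed's k bases, each assumed independent: a matching
#' base over reference C or G contributes 1 - delta at its position (the
#' probability deamination did not strike), any other matching base
#' contributes 1; a read-T over reference-C mismatch contributes the C>T
#' delta at its 5'-distance, a read-A over reference-G mismatch the G>A
#' delta at its 3'-distance; any other mismatch is inconsistent with
#' deamination and forces the likelihood to 0. The product is evaluated
#' over the seed's bases (the only sequence available before extension).
#'
#' @param cmp a [SeedComparisons-class].
#' @param profile a [DamageProfile-class].
#' @param beyondDepth passed to [deltaRate()].
#' @return vector of probabilities, one per pair.
#' @export
deaminationLikelihood <- function(cmp, profile, beyondDepth = "clamp") {
  stopifnot(is(cmp, "SeedComparisons"), is(profile, "DamageProfile"))
  n <- length(cmp@readKey)
  if (n == 0L) return(numeric())
  k <- cmp@k
  rb <- cmp@readBases; gb <- cmp@refBases
  p5 <- cmp@posFrom5p; p3 <- cmp@posFrom3p

  dCT <- matrix(deltaRate(profile, p5, p3, "C", "T", beyondDepth),
                nrow = n, ncol = k)
  dGA <- matrix(deltaRate(profile, p5, p3, "G", "A", beyondDepth),
                nrow = n, ncol = k)

  fac <- matrix(1, nrow = n, ncol = k)
  match <- rb == gb
  fac[match & gb == "C"] <- (1 - dCT)[match & gb == "C"]
  fac[match & gb == "G"] <- (1 - dGA)[match & gb == "G"]
  mm <- !match
  deamCT <- mm & gb == "C" & rb == "T"
  deamGA <- mm & gb == "G" & rb == "A"
  fac[deamCT] <- dCT[deamCT]
  fac[deamGA] <- dGA[deamGA]
  fac[mm & !deamCT & !deamGA] <- 0  # e.g. T>C, A>G, or any transversion

  # log-space product; a genuine zero factor makes the whole product zero
  zero <- rowSums(fac == 0) > 0L
  ll <- rowSums(log(pmax(fac, 1e-300)))
  out <- exp(ll)
  out[zero] <- 0
  out
}

#' Posterior probability that a seed mismatch is explained by deamination
#'
#' Bayes' rule over the two explanations: P(M|r) =
#' P(r|M) V / (P(r|M) V + P(r|not-M) (1-V)) with prior V from the
#' configuration. Defined as 0 when both likelihoods vanish.
#'
#' @param cmp a [SeedComparisons-class].
#' @param profile a [DamageProfile-class].
#' @param config a [FilterConfig-class].
#' @return vector of posterior probabilities, one per pair.
#' @export
rescuePosterior <- function(cmp, profile, config = FilterConfig()) {
  stopifnot(is(cmp, "SeedComparisons"))
  pm <- deaminationLikelihood(cmp, profile)
  ps <- spuriousLikelihood(cmp@k, cmp@m, config)
  num <- pm * config@priorV
  den <- num + ps * (1 - config@priorV)
  ifelse(den == 0, 0, num / den)
}

#' Filter RY-matched seed candidates
#'
#' Implements the rescue decision on the output of [queryRymers()]:
#' exact-match candidates (m = 0) pass unconditionally; mismatched
#' candidates pass iff their posterior is at least the configured
#' threshold; candidates whose minimizer already appears in the read's
#' exact-match seed set are dropped as duplicates. Survivors carry their
#' minimizer key (the rescue index's back-pointer target), posterior, and
#' a rescued tag.
#'
#' @param candidates data.frame from [queryRymers()].
#' @param readLength length of the read the candidates came from.
#' @param profile a [DamageProfile-class].
#' @param config a [FilterConfig-class].
#' @param exactKeys minimizer keys already seeded exactly for this read;
#'   candidates resolving to them are dropped as duplicates.
#' @param k seed length; taken from the `"k"` attribute [queryRymers()]
#'   attaches when not given.
#' @return data.frame: read_offset, orient, candidate, posterior, rescued.
#' @export
filterRymerCandidates <- function(candidates, readLength, profile,
                                  config = FilterConfig(),
                                  exactKeys = character(),
                                  k = attr(candidates, "k")) {
  cand <- as.data.frame(candidates)
  if (is.null(k)) stop("seed length k not given and not carried by candidates")
  if (nrow(cand) == 0L)
    return(data.frame(read_offset = integer(), orient = integer(),
                      candidate = character(), posterior = numeric(),
                      rescued = logical()))
  cand <- cand[!(cand$candidate %in% exactKeys), , drop = FALSE]
  exact <- cand[cand$exact, , drop = FALSE]
  mism <- cand[!cand$exact, , drop = FALSE]
  out <- data.frame(read_offset = exact$read_offset, orient = exact$orient,
                    candidate = exact$candidate,
                    posterior = rep(1, nrow(exact)),
                    rescued = rep(FALSE, nrow(exact)))
  if (nrow(mism) > 0L) {
    cmp <- seedComparisons(mism$key, mism$candidate, k = k,
                           orient = mism$orient,
                           readOffset = mism$read_offset,
                           readLength = readLength)
    post <- rescuePosterior(cmp, profile, config)
    keep <- post >= config@thresholdJ
    out <- rbind(out, data.frame(read_offset = mism$read_offset[keep],
                                 orient = mism$orient[keep],
                                 candidate = mism$candidate[keep],
                                 posterior = post[keep],
                                 rescued = rep(TRUE, sum(keep))))
  }
  out[order(out$read_offset, out$candidate), , drop = FALSE]
}
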