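# The Bayesian deaminated-seed filter.

test_that("spurious likelihood plateaus for long seeds and is binomial below", {
  cfg <- FilterConfig()
  expect_identical(spuriousLikelihood(25, 3, cfg), 0.01)
  expect_identical(spuriousLikelihood(22, 0, cfg), 0.01)
  expect_identical(spuriousLikelihood(29, 11, cfg), 0.01)
  # frozen independent arithmetic at k=10 with the default constants
  expect_equal(spuriousLikelihood(10, 2, cfg), 0.2991765216989319,
               tolerance = 1e-12)
  p10 <- 1.0014 * 10^-0.6628
  expect_equal(spuriousLikelihood(10, 0, cfg), (1 - p10)^10,
               tolerance = 1e-12)
  expect_error(spuriousLikelihood(10, 11, cfg), "m must")
})

test_that("spurious likelihood matches dbinom for every k < 22 and sums to 1", {
  cfg <- FilterConfig()
  for (k in 2:21) {
    p <- min(max(cfg@a * k^cfg@b, 0), 1)
    m <- 0:k
    got <- spuriousLikelihood(rep(k, k + 1L), m, cfg)
    # independent binomial arithmetic from choose() and powers
    want <- choose(k, m) * p^m * (1 - p)^(k - m)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
  # k = 1: the power law exceeds 1 and is clamped; all mass on m = 1
  expect_equal(spuriousLikelihood(1, 1, cfg), 1)
  expect_equal(spuriousLikelihood(1, 0, cfg), 0)
})

test_that("deamination likelihood follows the per-base model", {
  # single T/C mismatch at 5' position 0 with delta 0.4, all else A/A
  five <- matrix(0, 5, 12, dimnames = list(NULL, SUBSTITUTION_TYPES))
  five[1, "C>T"] <- 0.4
  prof <- DamageProfile(five, matrix(0, 5, 12,
                                     dimnames = list(NULL, SUBSTITUTION_TYPES)))
  cmp <- seedComparisons(encodeKmer("TAAAA"), encodeKmer("CAAAA"), k = 5,
                         readOffset = 0, readLength = 30)
  expect_equal(deaminationLikelihood(cmp, prof), 0.4)
  # zero-damage profile with any mismatch: likelihood 0
  zero <- zeroDamageProfile()
  expect_identical(deaminationLikelihood(cmp, zero), 0)
  # the reverse transition (read C over reference T) is not deamination
  cmpRev <- seedComparisons(encodeKmer("CAAAA"), encodeKmer("TAAAA"), k = 5,
                            readOffset = 0, readLength = 30)
  expect_identical(deaminationLikelihood(cmpRev, prof), 0)
  # matching C under nonzero delta contributes 1 - delta
  cmpMatch <- seedComparisons(encodeKmer("CAAAA"), encodeKmer("CAAAA"), k = 5,
                              readOffset = 0, readLength = 30)
  expect_equal(deaminationLikelihood(cmpMatch, prof), 0.6)
})

test_that("transversion pairs cannot form a seed comparison", {
  # read A over reference C is a transversion: the RY projections differ,
  # which the comparison container rejects by construction
  expect_error(seedComparisons(encodeKmer("AAAAA"), encodeKmer("CAAAA"),
                               k = 5, readLength = 30),
               "RY projection")
})

test_that("posterior follows Bayes' rule with the configured prior", {
  five <- matrix(0, 5, 12, dimnames = list(NULL, SUBSTITUTION_TYPES))
  five[1, "C>T"] <- 0.4
  prof <- DamageProfile(five,
                        matrix(0, 5, 12,
                               dimnames = list(NULL, SUBSTITUTION_TYPES)))
  # k = 10, m = 1: P(r|M) = 0.4 and P(r|notM) = C(10,1) p (1-p)^9
  cmp <- seedComparisons(encodeKmer("TAAAAAAAAA"), encodeKmer("CAAAAAAAAA"),
                         k = 10, readOffset = 0, readLength = 40)
  post <- rescuePosterior(cmp, prof, FilterConfig())
  p10 <- 1.0014 * 10^-0.6628
  ps1 <- 10 * p10 * (1 - p10)^9
  expect_equal(post, 0.4 / (0.4 + ps1), tolerance = 1e-9)
  # equal priors reduce to a likelihood ratio: the worked 0.4-vs-0.299 case
  expect_equal(0.4 / (0.4 + 0.2991765216989319), 0.5721, tolerance = 1e-4)
  # zero numerator: posterior 0
  expect_identical(rescuePosterior(cmp, zeroDamageProfile(), FilterConfig()), 0)
  # degenerate prior 1 with positive likelihood: posterior 1
  expect_identical(rescuePosterior(cmp, prof, FilterConfig(priorV = 1)), 1)
  # degenerate prior 0: posterior 0
  expect_identical(rescuePosterior(cmp, prof, FilterConfig(priorV = 0)), 0)
})

test_that("posterior is monotone in damage for deamination-consistent pairs", {
  mk <- function(r) {
    five <- matrix(0, 5, 12, dimnames = list(NULL, SUBSTITUTION_TYPES))
    five[, "C>T"] <- r
    DamageProfile(five, matrix(0, 5, 12,
                               dimnames = list(NULL, SUBSTITUTION_TYPES)))
  }
  cmp <- seedComparisons(encodeKmer("TACATAAGGA"), encodeKmer("CACATAAGGA"),
                         k = 10, readOffset = 0, readLength = 40)
  posts <- vapply(c(0.05, 0.15, 0.3, 0.45),
                  function(r) rescuePosterior(cmp, mk(r), FilterConfig()), 0)
  expect_true(all(diff(posts) > 0))
})

test_that("candidate filtering honours threshold, prior and the m=0 bypass", {
  set.seed(41)
  panel <- smallPanel(randomSeq(500))
  midx <- buildMinimizerIndex(panel, k = 11, w = 3)
  ridx <- buildRymerIndex(midx)
  prof <- damageFixture("ds-high")
  key <- midx@table$key[5]
  km <- decodeKmer(new("KmerCode", bits = key, length = 11L))
  # plant a C->T at a high-rate 5' position of the read
  ch <- strsplit(km, "")[[1]]
  stopifnot(any(ch == "C"))
  j <- which(ch == "C")[1]
  ch[j] <- "T"
  read <- paste(ch, collapse = "")
  cand <- queryRymers(ridx, read)
  stopifnot(key %in% cand$candidate)
  # hand-computed posterior for this single comparison
  row <- cand[cand$candidate == key, ][1, ]
  cmp <- seedComparisons(row$key, row$candidate, k = 11, orient = row$orient,
                         readOffset = row$read_offset, readLength = nchar(read))
  post <- rescuePosterior(cmp, prof, FilterConfig())
  out <- filterRymerCandidates(cand, nchar(read), prof, FilterConfig())
  got <- out[out$candidate == key & out$rescued, ]
  if (post >= 0.5) {
    expect_identical(nrow(got), 1L)
    expect_equal(got$posterior, post)
  } else {
    expect_identical(nrow(got), 0L)
  }
  # threshold 1: no mismatched candidate passes
  out1 <- filterRymerCandidates(cand, nchar(read), prof,
                                FilterConfig(thresholdJ = 1))
  expect_false(any(out1$rescued))
  # zero-damage profile: nothing passes either
  out0 <- filterRymerCandidates(cand, nchar(read), zeroDamageProfile(),
                                FilterConfig())
  expect_false(any(out0$rescued))
  # prior 0 blocks everything mismatched; prior 1 passes all
  outP0 <- filterRymerCandidates(cand, nchar(read), prof,
                                 FilterConfig(priorV = 0))
  expect_false(any(outP0$rescued))
  outP1 <- filterRymerCandidates(cand, nchar(read), prof,
                                 FilterConfig(priorV = 1, thresholdJ = 0.99))
  expect_true(key %in% outP1$candidate[outP1$rescued])
  # m = 0 bypass: exact candidates pass at any threshold and any profile
  exact <- queryRymers(ridx, km)
  outE <- filterRymerCandidates(exact, nchar(km), zeroDamageProfile(),
                                FilterConfig(thresholdJ = 1))
  expect_true(key %in% outE$candidate)
  expect_false(any(outE$rescued[outE$candidate == key]))
})

test_that("the rescued set shrinks as the threshold rises", {
  set.seed(42)
  panel <- smallPanel(randomSeq(2000))
  midx <- buildMinimizerIndex(panel, k = 9, w = 3)
  ridx <- buildRymerIndex(midx)
  prof <- damageFixture("ds-high")
  sim <- simulateReads(panel, 60, profile = prof,
                       dist = lognormalFragments(minLen = 20, maxLen = 40),
                       seed = 43)
  thresholds <- c(0.1, 0.5, 0.9, 1.0)
  sets <- lapply(thresholds, function(j) {
    rescued <- character()
    for (i in seq_along(sim$reads)) {
      cand <- queryRymers(ridx, sim$reads[[i]])
      out <- filterRymerCandidates(cand, nchar(sim$reads[[i]]), prof,
                                   FilterConfig(thresholdJ = j))
      if (any(out$rescued))
        rescued <- c(rescued,
                     paste(i, out$read_offset[out$rescued],
                           out$candidate[out$rescued]))
    }
    rescued
  })
  for (t in seq_along(thresholds)[-1])
    expect_true(all(sets[[t]] %in% sets[[t - 1]]))
  expect_identical(sets[[length(sets)]], character())
})
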