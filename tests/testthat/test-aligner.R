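# Seed collection, clustering, extension, and end-to-end mapping.

test_that("an undamaged reference copy yields an exact seed at its locus", {
  set.seed(51)
  s <- randomSeq(3000)
  panel <- smallPanel(s)
  midx <- buildMinimizerIndex(panel, k = 11, w = 3)
  read <- substr(s, 501, 560)
  seeds <- collectSeeds(read, midx)
  expect_gt(nrow(seeds), 0)
  expect_true(any(!seeds$rescued &
                    seeds$ref_offset - seeds$read_offset == 500L))
  expect_true(all(seeds$posterior == 1))
})

test_that("a deaminated-only window is rescued but vanishes at threshold 1", {
  set.seed(52)
  s <- randomSeq(3000)
  panel <- smallPanel(s)
  k <- 21L
  midx <- buildMinimizerIndex(panel, k = k, w = 3)
  ridx <- buildRymerIndex(midx)
  prof <- damageFixture("ds-high")
  # a read of exactly k bases (a single indexable window) with one C->T at
  # the highest-rate 5' position; search for a locus whose hand-computed
  # posterior clears the default threshold (matching C/G bases near the
  # seed ends can legitimately pull other loci below it)
  found <- FALSE
  for (off in sample(2000)) {
    read0 <- substr(s, off, off + k - 1)
    ch <- strsplit(read0, "")[[1]]
    if (ch[1] != "C") next
    ch[1] <- "T"
    read <- paste(ch, collapse = "")
    cand <- queryRymers(ridx, read)
    row <- cand[!cand$exact, , drop = FALSE]
    if (nrow(row) != 1L) next
    cmp <- seedComparisons(row$key, row$candidate, k = k,
                           orient = row$orient,
                           readOffset = row$read_offset, readLength = k)
    post <- rescuePosterior(cmp, prof, FilterConfig())
    if (post >= 0.5) { found <- TRUE; break }
  }
  stopifnot(found)
  exact <- collectSeeds(read, midx)
  expect_identical(nrow(exact), 0L)  # the kmer lookup misses the damaged seed
  rescued <- collectSeeds(read, midx, ridx, prof)
  hit <- rescued[rescued$rescued &
                   rescued$ref_offset - rescued$read_offset == off - 1L, ]
  expect_gt(nrow(hit), 0)
  expect_equal(hit$posterior[1], post)
  expect_true(all(rescued$posterior[rescued$rescued] < 1))
  # threshold 1.0 reproduces the exact-only seed set
  at1 <- collectSeeds(read, midx, ridx, prof,
                      config = FilterConfig(thresholdJ = 1))
  expect_identical(at1, exact)
})

test_that("diagonal clustering equals a brute-force banding oracle", {
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(3:40, 1)
    seeds <- data.frame(
      read = 1L,
      seq_id = sample(1:3, n, replace = TRUE),
      strand = sample(0:1, n, replace = TRUE),
      diag = sample(-200:200, n, replace = TRUE),
      read_offset = sample(0:50, n, replace = TRUE))
    got <- clusterSeeds(seeds, band = 16)
    # oracle on the returned rows: transitive closure of the all-pairs
    # |diag_i - diag_j| <= band relation within each (seq, strand) group
    m <- nrow(got)
    lab <- paste(got$seq_id, got$strand)
    adj <- outer(seq_len(m), seq_len(m), function(i, j)
      lab[i] == lab[j] & abs(got$diag[i] - got$diag[j]) <= 16)
    comp <- seq_len(m)
    repeat {
      prev <- comp
      for (i in seq_len(m)) comp[i] <- min(comp[adj[i, ]])
      if (identical(prev, comp)) break
    }
    # same partition iff the label pairing is a bijection
    expect_identical(length(unique(paste(got$cluster, comp))),
                     length(unique(got$cluster)))
    expect_identical(length(unique(paste(got$cluster, comp))),
                     length(unique(comp)))
  }
})

test_that("two seeds on one diagonal share a cluster; references split them", {
  seeds <- data.frame(read = 1L, seq_id = c(1L, 1L, 2L),
                      strand = 0L, diag = c(100L, 105L, 100L),
                      read_offset = c(0L, 5L, 0L))
  out <- clusterSeeds(seeds)
  expect_identical(out$cluster[1], out$cluster[2])
  expect_false(out$cluster[3] == out$cluster[1])
})

test_that("extension scores follow the scheme and rescoring validates them", {
  set.seed(54)
  s <- randomSeq(5000)
  panel <- smallPanel(s)
  midx <- buildMinimizerIndex(panel, k = 11, w = 3)
  # exact read: all-match edit script, score = length
  read <- substr(s, 1001, 1060)
  aln <- mapRead(read, panel, midx)
  expect_identical(aln$flag, 0L)
  expect_identical(aln$pos, 1001L)
  expect_identical(aln$cigar, "60M")
  expect_identical(aln$score, 60L)
  expect_identical(aln$nm, 0L)
  # one transition mismatch: score L - match - mismatch = L - 5
  ch <- strsplit(read, "")[[1]]
  ch[30] <- chartr("ACGT", "GTAC", ch[30])
  aln2 <- mapRead(paste(ch, collapse = ""), panel, midx)
  expect_identical(aln2$score, 60L - 5L)
  expect_identical(aln2$nm, 1L)
  # emitted score equals independent re-scoring of the edit script
  for (a in list(aln, aln2)) {
    rs <- rescoreAlignment(a, panel)
    expect_identical(as.integer(rs$score), a$score)
    expect_identical(as.integer(rs$nm), a$nm)
    expect_identical(as.integer(rs$read_consumed), nchar(a$seq))
  }
})

test_that("gapped fallback handles indels and the floor kills junk", {
  set.seed(55)
  s <- randomSeq(5000)
  panel <- smallPanel(s)
  midx <- buildMinimizerIndex(panel, k = 11, w = 3)
  # a 2 bp deletion mid-read forces the banded gapped path
  left <- substr(s, 2001, 2040)
  right <- substr(s, 2043, 2082)
  read <- paste0(left, right)
  aln <- mapRead(read, panel, midx)
  expect_identical(aln$flag, 0L)
  expect_identical(aln$pos, 2001L)
  expect_match(aln$cigar, "D")
  rs <- rescoreAlignment(aln, panel)
  expect_identical(as.integer(rs$score), aln$score)
  # random read: no seed survives extension
  repeat {
    junk <- randomSeq(60)
    if (!grepl(junk, s, fixed = TRUE)) break
  }
  alnJ <- mapRead(junk, panel, midx)
  expect_identical(alnJ$flag, 4L)
})

test_that("reverse-strand reads are placed and reported reference-forward", {
  set.seed(56)
  s <- randomSeq(4000)
  panel <- smallPanel(s)
  midx <- buildMinimizerIndex(panel, k = 13, w = 4)
  frag <- substr(s, 1501, 1570)
  read <- reverseComplement(frag)
  aln <- mapRead(read, panel, midx)
  expect_identical(aln$flag, 16L)
  expect_identical(aln$pos, 1501L)
  expect_identical(aln$seq, frag)  # SAM stores the reference-forward strand
})

test_that("origin-crossing reads on circular references wrap and get tagged", {
  set.seed(57)
  panel <- syntheticMitogenome(length = 2000, seed = 57)
  s <- as.character(panel@sequences[[1]])
  midx <- buildMinimizerIndex(panel, k = 13, w = 4)
  read <- paste0(substr(s, 1971, 2000), substr(s, 1, 30))
  aln <- mapRead(read, panel, midx)
  expect_identical(aln$flag, 0L)
  expect_identical(aln$pos, 1971L)
  expect_identical(aln$zc, 1L)
  expect_identical(aln$score, 60L)
})

test_that("reads shorter than k are unmapped and bad records rejected", {
  panel <- smallPanel(randomSeq(1000))
  midx <- buildMinimizerIndex(panel, k = 21, w = 3)
  aln <- mapRead(strrep("A", 15), panel, midx)
  expect_identical(aln$flag, 4L)
  expect_error(mapReads(c(r1 = "ACGT", r2 = ""), panel, midx), "malformed")
})

test_that("mapping is deterministic and rescue never loses true placements", {
  panel <- syntheticMitogenome(length = 6000, seed = 58)
  midx <- buildMinimizerIndex(panel, k = 21, w = 5)
  ridx <- buildRymerIndex(midx)
  prof <- damageFixture("ds-high")
  sim <- simulateReads(panel, 300, profile = prof, seed = 59)
  a1 <- mapReads(sim$reads, panel, midx, ridx, prof)
  a2 <- mapReads(sim$reads, panel, midx, ridx, prof)
  expect_identical(a1, a2)
  # byte-identical SAM bodies
  expect_identical(samBody(a1), samBody(a2))
  # rescue-enabled mapping finds at least as many true loci as threshold 1.0
  base <- mapReads(sim$reads, panel, midx, ridx, prof,
                   config = FilterConfig(thresholdJ = 1))
  ccR <- classifyAlignments(a1, sim$truth, panel)
  ccB <- classifyAlignments(base, sim$truth, panel)
  expect_gte(ccR@tp, ccB@tp)
})

test_that("rescued alignments carry provenance tags", {
  set.seed(60)
  panel <- syntheticMitogenome(length = 6000, seed = 60)
  midx <- buildMinimizerIndex(panel, k = 29, w = 11)
  ridx <- buildRymerIndex(midx)
  prof <- damageFixture("ds-high")
  sim <- simulateReads(panel, 400, profile = prof, seed = 61)
  aln <- mapReads(sim$reads, panel, midx, ridx, prof)
  resc <- aln[!is.na(aln$zr), , drop = FALSE]
  expect_gt(nrow(resc), 0)
  expect_true(all(resc$zr >= 1))
  expect_true(all(resc$zp > 0 & resc$zp < 1))
  body <- samBody(aln)
  expect_true(any(grepl("\tZR:i:", body, fixed = TRUE)))
})

test_that("SAM round-trips through the package reader", {
  set.seed(62)
  panel <- syntheticMitogenome(length = 4000, seed = 62)
  midx <- buildMinimizerIndex(panel, k = 21, w = 5)
  sim <- simulateReads(panel, 50, seed = 63)
  aln <- mapReads(sim$reads, panel, midx)
  f <- tempfile(fileext = ".sam")
  writeSam(aln, panel, f)
  back <- readSam(f)
  expect_identical(back$qname, aln$qname)
  expect_identical(back$flag, aln$flag)
  expect_identical(back$pos, aln$pos)
  expect_identical(back$cigar, aln$cigar)
  expect_identical(back$score, aln$score)
  unlink(f)
})
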