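# Minimizer index construction, the RY rescue index, queries, and
# serialization.

test_that("w = 1 indexes every unambiguous canonical kmer position", {
  set.seed(21)
  panel <- smallPanel(paste0(randomSeq(40), "N", randomSeq(40)))
  idx <- buildMinimizerIndex(panel, k = 5, w = 1)
  s <- as.character(panel@sequences[[1]])
  npos <- nchar(s) - 5L + 1L
  kmers <- substring(s, 1:npos, 5:(npos + 4L))
  valid <- which(!grepl("N", kmers))
  expect_setequal(idx@table$offset, valid - 1L)
})

test_that("minimizer selection equals the brute-force window-scan oracle", {
  set.seed(22)
  cases <- expand.grid(k = c(3L, 7L, 11L), w = c(1L, 2L, 5L))
  for (ci in seq_len(nrow(cases))) {
    k <- cases$k[ci]; w <- cases$w[ci]
    for (rep in 1:3) {
      s <- randomSeq(sample(50:200, 1))
      panel <- smallPanel(s)
      idx <- buildMinimizerIndex(panel, k = k, w = w)
      got <- idx@table[, c("offset", "orient", "key")]
      want <- oracleMinimizers(s, k, w)
      setorder2 <- function(d) d[order(d$offset, d$orient, d$key), ]
      expect_equal(setorder2(as.data.frame(got)), setorder2(want),
                   ignore_attr = TRUE)
    }
  }
})

test_that("sequences shorter than k contribute nothing; empty panel rejected", {
  panel <- smallPanel(randomSeq(10))
  idx <- buildMinimizerIndex(panel, k = 11, w = 2)
  expect_identical(nrow(idx@table), 0L)
  expect_error(buildMinimizerIndex(ReferencePanel(DNAStringSet()), k = 5, w = 2),
               "empty")
  expect_error(buildMinimizerIndex(panel, k = 0, w = 2))
  expect_error(buildMinimizerIndex(panel, k = 5, w = 0))
})

test_that("circular indexing equals linearization extended by k-1 bases", {
  set.seed(23)
  s <- randomSeq(120)
  k <- 7L; w <- 3L
  circ <- buildMinimizerIndex(smallPanel(s, circular = TRUE), k = k, w = w)
  ext <- buildMinimizerIndex(smallPanel(paste0(s, substr(s, 1, k - 1))),
                             k = k, w = w)
  # wrapped offsets reduce modulo length; the extended scan already reports
  # offsets 0..len-1, so the tables agree directly
  expect_identical(as.data.frame(circ@table), as.data.frame(ext@table))
  expect_true(all(circ@table$offset + k <= nchar(s) + k - 1))
})

test_that("rescue index covers every minimizer key and only those", {
  set.seed(24)
  panel <- smallPanel(randomSeq(300))
  midx <- buildMinimizerIndex(panel, k = 9, w = 4)
  ridx <- buildRymerIndex(midx)
  keys <- unique(midx@table$key)
  proj <- kmerToRymer(new("KmerCode", bits = keys,
                          length = rep(9L, length(keys))))@bits
  expect_setequal(unique(ridx@table$rykey), unique(proj))
  expect_true(all(ridx@table$key %in% keys))
  expect_lte(nKeys(ridx), nKeys(midx))
  # every minimizer key is reachable through its projection
  for (i in seq_along(keys))
    expect_true(keys[i] %in% ridx@table$key[ridx@table$rykey == proj[i]])
})

test_that("kmers sharing an RY projection share one rescue entry", {
  # index holding the keys CCC and TTT: both project to YYY, so the rescue
  # index carries a single entry listing both minimizer keys
  keys <- c(encodeKmer("CCC")@bits, encodeKmer("TTT")@bits)
  tab <- data.table::as.data.table(list(key = keys, seq_id = c(1L, 1L),
                                        offset = c(0L, 10L),
                                        orient = c(0L, 0L)))
  midx <- new("MinimizerIndex", params = new("IndexParams", k = 3L, w = 1L),
              table = tab, maxHits = 512L, refNames = "seq1",
              refLengths = 20L, refCircular = FALSE)
  ridx <- buildRymerIndex(midx)
  expect_identical(nKeys(ridx), 1L)
  yyy <- encodeRymer("YYY")@bits
  under <- ridx@table$key[ridx@table$rykey == yyy]
  expect_setequal(under, keys)
})

test_that("self-query finds the true locus; N-reads and strangers find nothing", {
  set.seed(25)
  s <- randomSeq(16000)
  panel <- smallPanel(s)
  midx <- buildMinimizerIndex(panel, k = 29, w = 11)
  read <- substr(s, 1001, 1060)
  hits <- queryMinimizers(midx, read)
  expect_gt(nrow(hits), 0)
  expect_true(any(hits$ref_offset - hits$read_offset == 1000L))
  expect_identical(nrow(queryMinimizers(midx, strrep("N", 60))), 0L)
  # a random 40-mer against 16 kb at k=29: no exact substring, no hits
  repeat {
    stranger <- randomSeq(40)
    if (!grepl(stranger, s, fixed = TRUE) &&
        !grepl(oracleRC(stranger), s, fixed = TRUE)) break
  }
  expect_identical(nrow(queryMinimizers(midx, stranger)), 0L)
})

test_that("RY query rescues transition-mutated kmers but not transversions", {
  set.seed(26)
  s <- randomSeq(400)
  panel <- smallPanel(s)
  midx <- buildMinimizerIndex(panel, k = 11, w = 3)
  ridx <- buildRymerIndex(midx)
  key <- midx@table$key[1]
  km <- decodeKmer(new("KmerCode", bits = key, length = 11L))
  # exact read kmer: candidate list contains the minimizer itself
  res <- queryRymers(ridx, km)
  expect_true(key %in% res$candidate[res$exact])
  # C->T (or fallback transition) mutation: still found via RY space
  ch <- strsplit(km, "")[[1]]
  j <- if (any(ch == "C")) which(ch == "C")[1] else 1L
  ch[j] <- chartr("CGAT", "TAGC", ch[j])
  mut <- paste(ch, collapse = "")
  res2 <- queryRymers(ridx, mut)
  expect_true(key %in% res2$candidate)
  expect_false(any(res2$exact & res2$candidate == key))
  # kmer lookup misses it (unless mutation hit another indexed kmer)
  em <- queryMinimizers(midx, mut)
  expect_false(key %in% em$key)
  # transversion at the same position: candidate absent
  ch2 <- strsplit(km, "")[[1]]
  ch2[j] <- chartr("ACGT", "CATG", ch2[j])
  res3 <- queryRymers(ridx, paste(ch2, collapse = ""))
  expect_false(key %in% res3$candidate)
})

test_that("rescue completeness: all transition neighbours reach their minimizer", {
  # exhaustive on a small panel: every transitions-only neighbour of every
  # indexed minimizer must surface that minimizer as an RY candidate
  set.seed(27)
  panel <- smallPanel(randomSeq(60))
  k <- 6L
  midx <- buildMinimizerIndex(panel, k = k, w = 2)
  ridx <- buildRymerIndex(midx)
  keys <- unique(midx@table$key)
  for (key in keys) {
    km <- decodeKmer(new("KmerCode", bits = key, length = k))
    for (nb in transitionNeighbours(km)) {
      res <- queryRymers(ridx, nb)
      expect_true(key %in% res$candidate,
                  label = sprintf("minimizer %s via neighbour %s", km, nb))
    }
  }
})

test_that("index serialization round-trips and is byte-deterministic", {
  set.seed(28)
  s <- randomSeq(16000)
  panel <- ReferencePanel(c(mt = s), circular = TRUE)
  midx <- buildMinimizerIndex(panel, k = 29, w = 11)
  ridx <- buildRymerIndex(midx)
  fm <- tempfile(fileext = ".mdx"); fr <- tempfile(fileext = ".rdx")
  writeIndex(midx, fm); writeIndex(ridx, fr)
  m2 <- readIndex(fm); r2 <- readIndex(fr)
  expect_identical(as.data.frame(m2@table), as.data.frame(midx@table))
  expect_identical(m2@params@k, midx@params@k)
  expect_identical(m2@refNames, midx@refNames)
  expect_identical(m2@refLengths, midx@refLengths)
  expect_identical(m2@refCircular, midx@refCircular)
  expect_identical(as.data.frame(r2@table), as.data.frame(ridx@table))
  # byte determinism: rebuilding and rewriting gives identical bytes
  fm2 <- tempfile(fileext = ".mdx")
  writeIndex(buildMinimizerIndex(panel, k = 29, w = 11), fm2)
  expect_identical(readBin(fm, "raw", file.size(fm)),
                   readBin(fm2, "raw", file.size(fm2)))
  unlink(c(fm, fr, fm2))
})

test_that("corrupted or truncated index files are rejected with a reason", {
  panel <- smallPanel(randomSeq(200))
  midx <- buildMinimizerIndex(panel, k = 7, w = 2)
  f <- tempfile()
  writeIndex(midx, f)
  bytes <- readBin(f, "raw", file.size(f))
  bad <- bytes; bad[2] <- as.raw(0x58)
  writeBin(bad, f)
  expect_error(readIndex(f), "magic")
  writeBin(bytes[1:20], f)
  expect_error(readIndex(f), "truncated")
  unlink(f)
})

test_that("hit lists beyond maxHits are truncated with a warning", {
  panel <- smallPanel(strrep("ACGT", 50))
  expect_warning(idx <- buildMinimizerIndex(panel, k = 4, w = 1, maxHits = 5),
                 "truncated")
  expect_true(all(table(idx@table$key) <= 5))
})
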