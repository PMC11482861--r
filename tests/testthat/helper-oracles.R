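# Shared fixtures and independent oracles, built in code at test time.

BASES <- c("A", "C", "G", "T")

randomSeq <- function(len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
}

# text-level RY encoding (independent of the bit-level projection)
oracleRY <- function(s) chartr("AGCT", "RRYY", s)

# text-level reverse complement
oracleRC <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""), ""))
}

# TRUE iff a and b differ only by transitions (same purine/pyrimidine class)
transitionsOnly <- function(a, b) {
  oracleRY(a) == oracleRY(b)
}

# Brute-force minimizer selection oracle: enumerates every window, hashes
# both orientations of every kmer through the package's pinned primitives
# (hash64/encodeKmer, themselves pinned against frozen external values),
# and takes per-window minima with the same truncated-window and tie rules
# the scan documents. Returns a data.frame (offset, orient, key).
oracleMinimizers <- function(seq, k, w) {
  n <- nchar(seq)
  npos <- n - k + 1L
  if (npos < 1L) return(data.frame(offset = integer(), orient = integer(),
                                   key = character()))
  kmers <- substring(seq, 1:npos, k:(npos + k - 1L))
  valid <- !grepl("[^ACGT]", kmers)
  hash <- rep(NA_character_, npos)
  orient <- rep(NA_integer_, npos)
  key <- rep(NA_character_, npos)
  for (i in which(valid)) {
    kf <- encodeKmer(kmers[i])@bits
    kr <- encodeKmer(oracleRC(kmers[i]))@bits
    hf <- hash64(kf); hr <- hash64(kr)
    if (hf <= hr) { hash[i] <- hf; key[i] <- kf; orient[i] <- 0L }
    else { hash[i] <- hr; key[i] <- kr; orient[i] <- 1L }
  }
  starts <- if (npos >= w) 1:(npos - w + 1L) else 1L
  wlen <- min(w, npos)
  selected <- logical(npos)
  for (j in starts) {
    span <- j:(j + wlen - 1L)
    hs <- hash[span]
    if (all(is.na(hs))) next
    mn <- min(hs, na.rm = TRUE)
    selected[span[!is.na(hs) & hs == mn]] <- TRUE
  }
  idx <- which(selected)
  data.frame(offset = idx - 1L, orient = orient[idx], key = key[idx],
             stringsAsFactors = FALSE)
}

# all transitions-only neighbours of a kmer string (including itself)
transitionNeighbours <- function(s) {
  ch <- strsplit(s, "")[[1]]
  alt <- chartr("AGCT", "GATC", ch)
  out <- ""
  for (i in seq_along(ch)) {
    out <- c(paste0(out, ch[i]), paste0(out, alt[i]))
    out <- unique(out)
  }
  out
}

# small shared panel builders
smallPanel <- function(seqs, circular = FALSE) {
  names(seqs) <- sprintf("seq%d", seq_along(seqs))
  ReferencePanel(seqs, circular = circular)
}

# effective per-position substitution rates the simulator applies, given
# that fragments are much longer than twice the profile depth: the far
# end's contribution is always the clamped last row.
effectiveAppliedRates <- function(profile) {
  d5 <- nrow(fivePrime(profile)); d3 <- nrow(threePrime(profile))
  ct5 <- fivePrime(profile)[, "C>T"]
  ga3 <- threePrime(profile)[, "G>A"]
  ct3 <- threePrime(profile)[, "C>T"]
  ss <- libraryType(profile) == "single-stranded"
  five <- matrix(0, d5, 2, dimnames = list(NULL, c("C>T", "G>A")))
  three <- matrix(0, d3, 2, dimnames = list(NULL, c("C>T", "G>A")))
  if (ss) {
    five[, "C>T"] <- 1 - (1 - ct5) * (1 - ct3[d3])
    three[, "C>T"] <- 1 - (1 - ct5[d5]) * (1 - ct3)
  } else {
    five[, "C>T"] <- ct5
    three[, "C>T"] <- ct5[d5]
  }
  five[, "G>A"] <- ga3[d3]
  three[, "G>A"] <- ga3
  list(fivePrime = five, threePrime = three)
}
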