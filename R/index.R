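# Reference panels and the paired minimizer / RY rescue indexes.

#' Construct a reference panel
#'
#' @param sequences a named character vector or [Biostrings::DNAStringSet].
#' @param circular logical; recycled per sequence, or a character vector of
#'   sequence names to flag circular.
#' @return a [ReferencePanel-class].
#' @export
ReferencePanel <- function(sequences, circular = FALSE) {
  if (is.character(sequences)) sequences <- DNAStringSet(toupper(sequences))
  if (is.character(circular)) {
    circ <- names(sequences) %in% circular
    missing <- setdiff(circular, names(sequences))
    if (length(missing))
      stop("circular names not in panel: ", paste(missing, collapse = ", "))
  } else {
    circ <- rep_len(as.logical(circular), length(sequences))
  }
  new("ReferencePanel", sequences = sequences, circular = circ)
}

#' Read a reference panel from a multi-FASTA file
#'
#' @param path FASTA file.
#' @param circular character vector of record names to flag circular.
#' @return a [ReferencePanel-class].
#' @export
readPanel <- function(path, circular = character()) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))  # first word of the header
  ReferencePanel(seqs, circular = circular)
}

#' @rdname ReferencePanel
#' @param x,object a [ReferencePanel-class].
#' @export
setGeneric("seqNames", function(x) standardGeneric("seqNames"))

#' @rdname ReferencePanel
#' @export
setMethod("seqNames", "ReferencePanel", function(x) names(x@sequences))

#' @rdname ReferencePanel
#' @export
setGeneric("seqLengths", function(x) standardGeneric("seqLengths"))

#' @rdname ReferencePanel
#' @export
setMethod("seqLengths", "ReferencePanel", function(x) {
  stats::setNames(Biostrings::width(x@sequences), names(x@sequences))
})

#' @rdname ReferencePanel
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @rdname ReferencePanel
#' @export
setMethod("isCircular", "ReferencePanel", function(x) {
  stats::setNames(x@circular, names(x@sequences))
})

setMethod("show", "ReferencePanel", function(object) {
  n <- length(object@sequences)
  cat(sprintf("ReferencePanel of %d sequence%s\n", n, if (n == 1) "" else "s"))
  shown <- min(n, 8L)
  w <- Biostrings::width(object@sequences)
  for (i in seq_len(shown))
    cat(sprintf("  %s: %d bp%s\n", names(object@sequences)[i], w[i],
                if (object@circular[i]) " (circular)" else ""))
  if (n > shown) cat("  ...\n")
})

setMethod("length", "ReferencePanel", function(x) length(x@sequences))

#' Synthetic circular mitogenome-sized reference
#'
#' A seeded pseudorandom circular sequence (default 16,569 bp, GC about
#' 44\%) standing in for a mitochondrial genome so examples and tests are
#' self-contained; real FASTA panels drop in unchanged. The sequence is
#' labelled synthetic in its name.
#'
#' @param length sequence length in bases.
#' @param gc target GC fraction.
#' @param seed integer seed; the sequence is reproducible given the seed.
#' @param name sequence name.
#' @return a single-sequence circular [ReferencePanel-class].
#' @export
syntheticMitogenome <- function(length = 16569L, gc = 0.44, seed = NULL,
                                name = "synthetic_mito") {
  if (!is.null(seed)) set.seed(seed)
  s <- cpp_random_dna(as.integer(length), gc)
  ReferencePanel(stats::setNames(s, name), circular = TRUE)
}

# ---------------------------------------------------------------------------

#' Build the minimizer index over a reference panel
#'
#' For every window of `w` consecutive kmer start positions on each strand
#' of each sequence, the canonical kmer (the orientation with the smaller
#' Wang hash; ties to forward) attaining the window's minimum hash is
#' recorded with all its occurrences. All kmers tying the window minimum
#' are indexed. Kmers overlapping an ambiguous base are never indexed.
#' Circular sequences are indexed on their linearisation extended by a
#' virtual copy of their first k-1 bases. Sequences with at least one but
#' fewer than `w` kmer positions contribute a single truncated window.
#'
#' @param panel a [ReferencePanel-class].
#' @param k minimizer length in bases (1..31).
#' @param w consecutive kmer start positions per window per strand.
#' @param maxHits keys with more occurrences are kept but their hit lists
#'   truncated, with a warning (bounds worst-case behaviour on repeats).
#' @return a [MinimizerIndex-class].
#' @export
buildMinimizerIndex <- function(panel, k = 29L, w = 11L, maxHits = 512L) {
  stopifnot(is(panel, "ReferencePanel"))
  if (length(panel) == 0L) stop("empty reference panel")
  k <- as.integer(k); w <- as.integer(w)
  params <- new("IndexParams", k = k, w = w)  # validity enforces ranges

  pieces <- vector("list", length(panel))
  seqs <- as.character(panel@sequences)
  lens <- Biostrings::width(panel@sequences)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (nchar(s) < k) next  # too short to hold a kmer
    if (panel@circular[i]) s <- paste0(s, substr(s, 1L, k - 1L))
    sc <- as.data.table(cpp_scan_minimizers(s, k, w))
    if (nrow(sc) == 0L) next
    sc[, seq_id := i]
    pieces[[i]] <- sc
  }
  tab <- rbindlist(pieces)
  if (is.null(tab) || nrow(tab) == 0L)
    tab <- as.data.table(list(offset = integer(), orient = integer(),
                              key = character(), seq_id = integer()))
  setcolorder(tab, c("key", "seq_id", "offset", "orient"))
  setorder(tab, key, seq_id, offset, orient)
  nh <- tab[, .N, by = key]
  if (any(nh$N > maxHits)) {
    warning(sum(nh$N > maxHits),
            " key(s) exceeded maxHits = ", maxHits, "; hit lists truncated")
    tab <- tab[, utils::head(.SD, maxHits), by = key]
  }
  setkey(tab, key)
  new("MinimizerIndex", params = params, table = tab,
      maxHits = as.integer(maxHits), refNames = seqNames(panel),
      refLengths = as.integer(lens), refCircular = panel@circular)
}

#' Build the RY rescue index from a minimizer index
#'
#' The rescue index is not built by re-running minimizer selection in RY
#' space (that set can differ); instead the minimizer key set is taken as-is
#' and each key's RY projection becomes a rescue-index key whose payload is
#' the list of minimizer keys projecting to it, guaranteeing that every
#' indexed minimizer is reachable through RY space. Positions are never
#' duplicated here: lookups go back through the minimizer index.
#'
#' @param minidx a [MinimizerIndex-class].
#' @return a [RymerIndex-class] sharing `minidx`'s parameters.
#' @export
buildRymerIndex <- function(minidx) {
  stopifnot(is(minidx, "MinimizerIndex"))
  keys <- unique(minidx@table$key)
  tab <- as.data.table(list(rykey = cpp_kmer_to_rymer(keys, minidx@params@k),
                            key = keys))
  setorder(tab, rykey, key)
  setkey(tab, rykey)
  new("RymerIndex", params = minidx@params, table = tab)
}

#' @rdname buildMinimizerIndex
#' @param x a minimizer or rescue index.
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))
#' @rdname buildMinimizerIndex
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))
#' @rdname buildMinimizerIndex
#' @export
setGeneric("nKeys", function(x) standardGeneric("nKeys"))

#' @rdname buildMinimizerIndex
#' @export
setMethod("kmerSize", "MinimizerIndex", function(x) x@params@k)
#' @rdname buildMinimizerIndex
#' @export
setMethod("kmerSize", "RymerIndex", function(x) x@params@k)
#' @rdname buildMinimizerIndex
#' @export
setMethod("windowSize", "MinimizerIndex", function(x) x@params@w)
#' @rdname buildMinimizerIndex
#' @export
setMethod("windowSize", "RymerIndex", function(x) x@params@w)
#' @rdname buildMinimizerIndex
#' @export
setMethod("nKeys", "MinimizerIndex", function(x) length(unique(x@table$key)))
#' @rdname buildMinimizerIndex
#' @export
setMethod("nKeys", "RymerIndex", function(x) length(unique(x@table$rykey)))

setMethod("show", "MinimizerIndex", function(object) {
  cat(sprintf("MinimizerIndex (k = %d, w = %d)\n",
              object@params@k, object@params@w))
  cat(sprintf("  %d keys, %d hits over %d reference sequence(s)\n",
              nKeys(object), nrow(object@table), length(object@refNames)))
})

setMethod("show", "RymerIndex", function(object) {
  cat(sprintf("RymerIndex (k = %d, w = %d)\n",
              object@params@k, object@params@w))
  cat(sprintf("  %d RY keys backing %d minimizer keys\n",
              nKeys(object), nrow(object@table)))
})

# ---------------------------------------------------------------------------
# queries

#' Query a read against the minimizer index
#'
#' Applies the same (k, w) windowing scheme as indexing to the read and
#' looks up each selected canonical kmer. Read kmers containing ambiguous
#' bases are skipped; an empty result is valid.
#'
#' @param idx a [MinimizerIndex-class].
#' @param read a single read sequence.
#' @return data.frame with one row per (selected window kmer, hit):
#'   read_offset, orient (0 = key equals the read substring, 1 = its
#'   reverse complement), key, seq_id, ref_offset, ref_orient.
#' @export
queryMinimizers <- function(idx, read) {
  stopifnot(is(idx, "MinimizerIndex"), length(read) == 1L)
  win <- as.data.table(cpp_scan_reads(toupper(as.character(read)),
                                      idx@params@k, idx@params@w, FALSE))
  if (nrow(win) == 0L)
    return(data.frame(read_offset = integer(), orient = integer(),
                      key = character(), seq_id = integer(),
                      ref_offset = integer(), ref_orient = integer()))
  tab <- as.data.table(idx@table)
  hits <- tab[win, on = "key", nomatch = NULL, allow.cartesian = TRUE]
  out <- data.frame(read_offset = hits$i.offset, orient = hits$i.orient,
                    key = hits$key, seq_id = hits$seq_id,
                    ref_offset = hits$offset, ref_orient = hits$orient)
  out[order(out$read_offset, out$seq_id, out$ref_offset, out$ref_orient), ,
      drop = FALSE]
}

#' Query a read against the RY rescue index
#'
#' For each window-selected canonical read kmer, looks up its RY projection
#' and returns every minimizer key stored under that RY key, paired with the
#' read's own kmer for later mismatch counting. Candidates equal to the read
#' kmer are the exact-match case (flagged `exact`) and bypass filtering
#' downstream. A read kmer differing from an indexed minimizer only by
#' transitions (e.g. a deaminated C read as T) is found here even though a
#' kmer-space lookup would miss it; any transversion changes the RY key and
#' the candidate is absent.
#'
#' @param ryidx a [RymerIndex-class].
#' @param read a single read sequence.
#' @return data.frame: read_offset, orient, key (read kmer), rykey,
#'   candidate (minimizer key), exact.
#' @export
queryRymers <- function(ryidx, read) {
  stopifnot(is(ryidx, "RymerIndex"), length(read) == 1L)
  win <- as.data.table(cpp_scan_reads(toupper(as.character(read)),
                                      ryidx@params@k, ryidx@params@w, TRUE))
  if (nrow(win) == 0L) {
    out <- data.frame(read_offset = integer(), orient = integer(),
                      key = character(), rykey = character(),
                      candidate = character(), exact = logical())
    attr(out, "k") <- ryidx@params@k
    return(out)
  }
  tab <- as.data.table(ryidx@table)
  # both RY orientations: damage can flip the read kmer's canonical
  # orientation relative to its undamaged form
  k <- ryidx@params@k
  win2 <- copy(win)
  win2[, key := cpp_revcomp_kmer(key, k)]
  win2[, rykey := cpp_revcomp_rymer(rykey, k)]
  win2[, orient := 1L - orient]
  win <- unique(rbind(win, win2))
  cand <- tab[win, on = "rykey", nomatch = NULL, allow.cartesian = TRUE]
  out <- data.frame(read_offset = cand$offset, orient = cand$orient,
                    key = cand$i.key, rykey = cand$rykey,
                    candidate = cand$key,
                    exact = cand$i.key == cand$key)
  out <- out[order(out$read_offset, out$candidate), , drop = FALSE]
  attr(out, "k") <- ryidx@params@k
  out
}

# ---------------------------------------------------------------------------
# serialization: versioned little-endian binary container, magic "RYSEED1",
# keys written in sorted order so output is byte-deterministic.

INDEX_MAGIC <- "RYSEED1"
INDEX_VERSION <- 1L

.hex2raw <- function(h) {
  # n 16-char hex strings -> raw vector of 8n bytes (big-endian byte order)
  if (length(h) == 0L) return(raw())
  starts <- seq(1L, 15L, by = 2L)
  bytes <- vapply(starts, function(s) strtoi(substring(h, s, s + 1L), 16L),
                  integer(length(h)))
  as.raw(t(matrix(bytes, nrow = length(h))))
}

.raw2hex <- function(r) {
  # raw vector (8n bytes) -> n hex strings
  m <- matrix(as.integer(r), nrow = 8L)
  apply(m, 2L, function(b) paste(sprintf("%02x", b), collapse = ""))
}

.writeStr <- function(con, s) {
  b <- charToRaw(s)
  writeBin(length(b), con, size = 4L, endian = "little")
  writeBin(b, con)
}

.readStr <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(n) != 1L) stop("truncated index file: missing string length")
  b <- readBin(con, "raw", n)
  if (length(b) != n) stop("truncated index file: short string")
  rawToChar(b)
}

.readInts <- function(con, n, what = "integer", size = 4L) {
  v <- readBin(con, what, n, size = size, endian = "little")
  if (length(v) != n) stop("truncated index file: expected ", n, " values")
  v
}

#' Serialize an index pair member to disk
#'
#' Versioned little-endian binary container (magic "RYSEED1"); keys and
#' records are written in sorted order, so serialization is deterministic:
#' identical inputs yield byte-identical files. `readIndex` rejects files
#' with a bad magic string, unknown version, or truncation, naming the
#' failure.
#'
#' @param x a [MinimizerIndex-class] or [RymerIndex-class].
#' @param path output file (conventionally `.mdx` for the minimizer index
#'   and `.rdx` for the rescue index).
#' @return `path`, invisibly.
#' @export
writeIndex <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(INDEX_MAGIC), con)
  if (is(x, "MinimizerIndex")) {
    writeBin(as.raw(1L), con)
    writeBin(INDEX_VERSION, con, size = 4L, endian = "little")
    writeBin(c(x@params@k, x@params@w, x@maxHits), con, size = 4L,
             endian = "little")
    writeBin(length(x@refNames), con, size = 4L, endian = "little")
    for (i in seq_along(x@refNames)) {
      .writeStr(con, x@refNames[i])
      writeBin(x@refLengths[i], con, size = 4L, endian = "little")
      writeBin(as.raw(as.integer(x@refCircular[i])), con)
    }
    tab <- as.data.table(x@table)
    setorder(tab, key, seq_id, offset, orient)
    keys <- unique(tab$key)
    writeBin(length(keys), con, size = 4L, endian = "little")
    grp <- tab[, .(n = .N), by = key]
    writeBin(.hex2raw(keys), con)
    writeBin(grp$n, con, size = 4L, endian = "little")
    writeBin(as.integer(rbind(tab$seq_id, tab$offset, tab$orient)), con,
             size = 4L, endian = "little")
  } else if (is(x, "RymerIndex")) {
    writeBin(as.raw(2L), con)
    writeBin(INDEX_VERSION, con, size = 4L, endian = "little")
    writeBin(c(x@params@k, x@params@w), con, size = 4L, endian = "little")
    tab <- as.data.table(x@table)
    setorder(tab, rykey, key)
    keys <- unique(tab$rykey)
    writeBin(length(keys), con, size = 4L, endian = "little")
    grp <- tab[, .(n = .N), by = rykey]
    writeBin(.hex2raw(keys), con)
    writeBin(grp$n, con, size = 4L, endian = "little")
    writeBin(.hex2raw(tab$key), con)
  } else {
    stop("x must be a MinimizerIndex or RymerIndex")
  }
  invisible(path)
}

#' @rdname writeIndex
#' @export
readIndex <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", nchar(INDEX_MAGIC))
  if (length(magic) != nchar(INDEX_MAGIC) ||
      !identical(rawToChar(magic), INDEX_MAGIC))
    stop("not a ryseed index: bad magic string in ", path)
  type <- as.integer(readBin(con, "raw", 1L))
  if (!length(type) || !type %in% c(1L, 2L))
    stop("not a ryseed index: unknown record type")
  version <- .readInts(con, 1L)
  if (version != INDEX_VERSION)
    stop("unsupported index format version ", version)
  if (type == 1L) {
    pkw <- .readInts(con, 3L)
    nseq <- .readInts(con, 1L)
    nms <- character(nseq); lens <- integer(nseq); circ <- logical(nseq)
    for (i in seq_len(nseq)) {
      nms[i] <- .readStr(con)
      lens[i] <- .readInts(con, 1L)
      fl <- readBin(con, "raw", 1L)
      if (length(fl) != 1L) stop("truncated index file: missing circular flag")
      circ[i] <- as.integer(fl) != 0L
    }
    nkeys <- .readInts(con, 1L)
    keyraw <- readBin(con, "raw", 8L * nkeys)
    if (length(keyraw) != 8L * nkeys) stop("truncated index file: key block")
    keys <- if (nkeys > 0L) .raw2hex(keyraw) else character()
    nhits <- .readInts(con, nkeys)
    total <- sum(nhits)
    rec <- .readInts(con, 3L * total)
    m <- matrix(rec, nrow = 3L)
    tab <- as.data.table(list(key = rep(keys, nhits), seq_id = m[1L, ],
                              offset = m[2L, ], orient = m[3L, ]))
    setkey(tab, key)
    new("MinimizerIndex",
        params = new("IndexParams", k = pkw[1L], w = pkw[2L]),
        table = tab, maxHits = pkw[3L], refNames = nms, refLengths = lens,
        refCircular = circ)
  } else {
    pkw <- .readInts(con, 2L)
    nkeys <- .readInts(con, 1L)
    keyraw <- readBin(con, "raw", 8L * nkeys)
    if (length(keyraw) != 8L * nkeys) stop("truncated index file: key block")
    keys <- if (nkeys > 0L) .raw2hex(keyraw) else character()
    nmin <- .readInts(con, nkeys)
    total <- sum(nmin)
    minraw <- readBin(con, "raw", 8L * total)
    if (length(minraw) != 8L * total)
      stop("truncated index file: minimizer-key block")
    tab <- as.data.table(list(
      rykey = rep(keys, nmin),
      key = if (total > 0L) .raw2hex(minraw) else character()))
    setkey(tab, rykey)
    new("RymerIndex", params = new("IndexParams", k = pkw[1L], w = pkw[2L]),
        table = tab)
  }
}
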