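# Seed-and-extend mapping: exact minimizer seeds augmented by rescued RY
# seeds, diagonal clustering, gapless X-drop extension with a banded gapped
# fallback, and SAM-style output.

DEFAULT_SCORING <- list(match = 1L, mismatch = 4L, gapOpen = 6L,
                        gapExtend = 1L, xdrop = 20L, band = 16L)

.scoring <- function(scoring) {
  s <- DEFAULT_SCORING
  s[names(scoring)] <- scoring
  lapply(s, as.integer)
}

# Bulk seed collection across reads. Returns a data.table with one row per
# seed occurrence: read, roff (read offset), rorient (window orientation),
# key, seq_id, goff (reference offset), gorient (hit orientation), rescued,
# posterior.
.collectSeedsBulk <- function(reads, minidx, ryidx = NULL, profile = NULL,
                              config = FilterConfig(), rescue = TRUE) {
  k <- minidx@params@k
  w <- minidx@params@w
  empty <- as.data.table(list(
    read = integer(), roff = integer(), rorient = integer(),
    key = character(), seq_id = integer(), goff = integer(),
    gorient = integer(), rescued = logical(), posterior = numeric()))
  if (length(reads) == 0L) return(empty)
  win <- as.data.table(cpp_scan_reads(reads, k, w, rescue))
  if (nrow(win) == 0L) return(empty)
  setnames(win, c("offset", "orient"), c("roff", "rorient"))
  tab <- as.data.table(minidx@table)

  exact <- tab[win, on = "key", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(exact)) {
    exact <- exact[, .(read, roff, rorient, key, seq_id, goff = offset,
                       gorient = orient, rescued = FALSE, posterior = 1)]
  } else exact <- empty

  if (rescue && !is.null(ryidx)) {
    if (ryidx@params@k != k || ryidx@params@w != w)
      stop("minimizer and rescue index parameters differ")
    if (is.null(profile)) profile <- zeroDamageProfile()
    rytab <- as.data.table(ryidx@table)
    # Query both RY orientations: damage can flip which orientation of a
    # read kmer wins canonicalisation (its hash changes), so the projection
    # of the undamaged canonical form may be the reverse complement of the
    # projection of the damaged one.
    win2 <- copy(win)
    win2[, key := cpp_revcomp_kmer(key, k)]
    win2[, rykey := cpp_revcomp_rymer(rykey, k)]
    win2[, rorient := 1L - rorient]
    ryWin <- unique(rbind(win, win2))
    cand <- rytab[ryWin, on = "rykey", nomatch = NULL, allow.cartesian = TRUE]
    # candidate 'key' column is the minimizer key; the read's own kmer is i.key
    if (nrow(cand)) {
      setnames(cand, c("key", "i.key"), c("candidate", "readkey"))
      cand <- cand[candidate != readkey]  # exact projections seed via kmer space
    }
    if (nrow(cand)) {
      # drop candidates duplicating the read's exact-match seed set
      ek <- unique(exact[, .(read, candidate = key)])
      if (nrow(ek)) cand <- cand[!ek, on = c("read", "candidate")]
    }
    if (nrow(cand)) {
      L <- nchar(reads)[cand$read]
      cmp <- seedComparisons(cand$readkey, cand$candidate, k = k,
                             orient = cand$rorient, readOffset = cand$roff,
                             readLength = L)
      post <- rescuePosterior(cmp, profile, config)
      keep <- post >= config@thresholdJ
      cand <- cand[keep]
      if (nrow(cand)) {
        cand[, posterior := post[keep]]
        hits <- tab[cand, on = c(key = "candidate"), nomatch = NULL,
                    allow.cartesian = TRUE]
        resc <- hits[, .(read, roff, rorient, key, seq_id, goff = offset,
                         gorient = orient, rescued = TRUE, posterior)]
        exact <- rbind(exact, resc)
      }
    }
  }
  setorder(exact, read, roff, seq_id, goff, gorient, rescued)
  exact
}

#' Collect exact and rescued seeds for one read
#'
#' Union of exact minimizer seeds and RY-rescued seeds that survive the
#' Bayesian filter; rescued minimizers duplicating an exact seed are
#' removed, and each rescued seed carries its posterior. With a rescue
#' threshold of 1 or a zero-damage profile the result equals the
#' exact-only seed set.
#'
#' @param read a single read sequence.
#' @param minidx a [MinimizerIndex-class].
#' @param ryidx optional paired [RymerIndex-class]; `NULL` disables rescue.
#' @param profile a [DamageProfile-class] (defaults to zero damage).
#' @param config a [FilterConfig-class].
#' @return data.frame of seeds: read_offset, orient, key, seq_id,
#'   ref_offset, ref_orient, rescued, posterior.
#' @export
collectSeeds <- function(read, minidx, ryidx = NULL, profile = NULL,
                         config = FilterConfig()) {
  s <- .collectSeedsBulk(toupper(as.character(read)), minidx, ryidx, profile,
                         config, rescue = !is.null(ryidx))
  data.frame(read_offset = s$roff, orient = s$rorient, key = s$key,
             seq_id = s$seq_id, ref_offset = s$goff, ref_orient = s$gorient,
             rescued = s$rescued, posterior = s$posterior)
}

#' Group seeds into diagonal clusters
#'
#' Seeds are grouped by (reference sequence, strand) and chained along the
#' alignment diagonal (reference offset minus read offset): seeds whose
#' diagonals are within `band` of a neighbour join the same cluster
#' (single-linkage). Clusters are ranked by their number of distinct read
#' offsets.
#'
#' @param seeds data.frame with columns seq_id, strand, diag and optionally
#'   read and read_offset (as produced internally by [mapReads()], or built
#'   by the caller).
#' @param band diagonal half-width in bases.
#' @return the seeds with an appended `cluster` column; cluster summary in
#'   attribute "clusters" (cluster, read, seq_id, strand, nOffsets).
#' @export
clusterSeeds <- function(seeds, band = 16L) {
  dt <- as.data.table(seeds)
  if (!all(c("seq_id", "strand", "diag") %in% names(dt)))
    stop("seeds must carry seq_id, strand and diag columns")
  if (nrow(dt) == 0L) {
    out <- as.data.frame(dt)
    out$cluster <- integer()
    return(out)
  }
  if (!"read" %in% names(dt)) dt[, read := 1L]
  if (!"read_offset" %in% names(dt)) dt[, read_offset := 0L]
  setorder(dt, read, seq_id, strand, diag)
  grpChange <- c(TRUE, diff(dt$read) != 0 | diff(dt$seq_id) != 0 |
                   diff(dt$strand) != 0)
  gap <- c(0, diff(dt$diag))
  newCluster <- grpChange | gap > band
  dt[, cluster := cumsum(newCluster)]
  summ <- dt[, .(read = read[1L], seq_id = seq_id[1L], strand = strand[1L],
                 nOffsets = uniqueN(read_offset)), by = cluster]
  out <- as.data.frame(dt)
  attr(out, "clusters") <- as.data.frame(summ)
  out
}

#' Map reads against an indexed reference panel
#'
#' Full seed-and-extend pipeline: windowed minimizer seeding, optional
#' Bayesian RY-seed rescue, diagonal clustering, gapless bidirectional
#' X-drop extension from each cluster anchor with a banded gapped fitting
#' fallback, score-floor filtering, and primary-alignment selection with a
#' mapping quality derived from the best and second-best scores.
#'
#' Alignments on circular references may cross the origin: they are
#' computed on the doubled sequence and reported with start reduced modulo
#' the length, tagged `ZC:i:1`. Rescued-seed provenance is carried in
#' `ZR` (count of rescued seeds in the winning cluster) and `ZP` (their
#' minimum posterior).
#'
#' @param reads character vector or `DNAStringSet` of read sequences;
#'   names are used as read identifiers (default read1, read2, ...).
#' @param panel the [ReferencePanel-class] the index was built from.
#' @param minidx a [MinimizerIndex-class].
#' @param ryidx the paired [RymerIndex-class], or `NULL` to disable the
#'   RY rescue path entirely.
#' @param profile a [DamageProfile-class] for the rescue filter.
#' @param config a [FilterConfig-class].
#' @param rescue logical; `FALSE` disables the rescue path even when
#'   `ryidx` is given.
#' @param maxClustersPerRead extension attempts per read.
#' @param scoring list overriding match, mismatch, gapOpen, gapExtend,
#'   xdrop, band (penalties positive).
#' @param scoreFloor fraction of the maximum score below which an
#'   alignment fails: alignments with score < scoreFloor * readLength *
#'   match are discarded.
#' @return data.frame of SAM-style records (one per read; unmapped reads
#'   have flag 4): qname, flag, rname, pos (1-based), mapq, cigar, seq,
#'   score, nm, zr, zp, zc.
#' @export
mapReads <- function(reads, panel, minidx, ryidx = NULL, profile = NULL,
                     config = FilterConfig(), rescue = !is.null(ryidx),
                     maxClustersPerRead = 16L, scoring = list(),
                     scoreFloor = 0.5) {
  stopifnot(is(panel, "ReferencePanel"), is(minidx, "MinimizerIndex"))
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%d", seq_along(reads))
  if (anyNA(reads) || any(reads == ""))
    stop("malformed read record(s): ",
         paste(names(reads)[is.na(reads) | reads == ""], collapse = ", "))
  reads <- toupper(reads)
  sc <- .scoring(scoring)
  k <- minidx@params@k
  if (!identical(seqNames(panel), minidx@refNames))
    stop("panel does not match the index's reference metadata")

  nm <- names(reads)
  L <- nchar(reads)
  unmappedRow <- function(i) {
    data.frame(qname = nm[i], flag = 4L, rname = "*", pos = 0L, mapq = 0L,
               cigar = "*", seq = reads[[i]], score = NA_integer_,
               nm = NA_integer_, zr = NA_integer_, zp = NA_real_,
               zc = NA_integer_, stringsAsFactors = FALSE)
  }

  seeds <- .collectSeedsBulk(unname(reads), minidx, ryidx, profile, config,
                             rescue = rescue && !is.null(ryidx))
  if (nrow(seeds) == 0L) {
    out <- do.call(rbind, lapply(seq_along(reads), unmappedRow))
    rownames(out) <- NULL
    return(out)
  }

  lens <- minidx@refLengths
  circ <- minidx@refCircular
  seeds[, Lr := L[read]]
  seeds[, strand := as.integer(xor(rorient == 1L, gorient == 1L))]
  seeds[, diag := fifelse(strand == 0L, goff - roff, goff - (Lr - roff - k))]
  seeds[, read_offset := roff]
  cs <- clusterSeeds(as.data.frame(seeds), band = sc$band)
  cl <- as.data.table(cs)
  summ <- as.data.table(attr(cs, "clusters"))
  # rank clusters per read and keep the strongest few
  setorder(summ, read, -nOffsets, cluster)
  summ[, rank := seq_len(.N), by = read]
  keepCl <- summ[rank <= maxClustersPerRead, cluster]
  cl <- cl[cluster %in% keepCl]

  # anchor seed per cluster: deterministic first by (read offset, ref offset)
  setorder(cl, cluster, roff, goff, gorient)
  anchors <- cl[, .SD[1L], by = cluster]
  clStats <- cl[, .(zr = sum(rescued),
                    zp = if (any(rescued)) min(posterior[rescued]) else NA_real_),
                by = cluster]
  anchors <- clStats[anchors, on = "cluster"]

  # oriented reads and anchor coordinates
  anchors[, anchorRead := fifelse(strand == 0L, roff, Lr - roff - k)]
  anchors[, anchorRef := as.numeric(goff)]
  # a circular read starting before the origin is shifted one period right
  anchors[, circularRef := circ[seq_id]]
  anchors[, refLen := lens[seq_id]]
  anchors[circularRef & (anchorRef - anchorRead < 0),
          anchorRef := anchorRef + refLen]

  refSeqs <- as.character(panel@sequences)
  extSeqs <- ifelse(circ, paste0(refSeqs, refSeqs), refSeqs)
  orientedRead <- ifelse(anchors$strand == 1L,
                         cpp_revcomp_seq(reads[anchors$read]),
                         reads[anchors$read])
  ext <- as.data.table(cpp_extend_batch(orientedRead, anchors$seq_id, extSeqs,
                                        anchors$anchorRef, anchors$anchorRead,
                                        sc$match, sc$mismatch, sc$gapOpen,
                                        sc$gapExtend, sc$xdrop, sc$band))
  res <- cbind(anchors, ext)
  res[, oseq := orientedRead]
  res[, floorScore := scoreFloor * Lr * sc$match]
  res <- res[ok == TRUE & score >= floorScore]

  out <- vector("list", length(reads))
  if (nrow(res)) {
    res[, posMod := fifelse(circularRef, start %% refLen, start)]
    res[, refSpan := .cigarRefSpan(cigar)]
    res[, wraps := circularRef & (posMod + refSpan > refLen)]
    setorder(res, read, -score, seq_id, posMod, strand)
    for (i in unique(res$read)) {
      ri <- res[read == i]
      best <- ri[1L]
      s2 <- if (nrow(ri) >= 2L) ri$score[2L] else 0L
      mapq <- max(0L, min(60L, as.integer(round(40 * (1 - s2 / best$score)))))
      out[[i]] <- data.frame(
        qname = nm[i], flag = if (best$strand == 1L) 16L else 0L,
        rname = minidx@refNames[best$seq_id], pos = as.integer(best$posMod) + 1L,
        mapq = mapq, cigar = best$cigar, seq = best$oseq,
        score = best$score, nm = best$nm,
        zr = if (best$zr > 0L) as.integer(best$zr) else NA_integer_,
        zp = best$zp, zc = if (isTRUE(best$wraps)) 1L else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_along(reads)) if (is.null(out[[i]])) out[[i]] <- unmappedRow(i)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# reference span consumed by a CIGAR (M and D ops)
.cigarRefSpan <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDS]", cg))[[1]]
    n <- as.integer(sub("[MIDS]$", "", ops))
    op <- substring(ops, nchar(ops))
    sum(n[op %in% c("M", "D")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Map a single read
#'
#' Convenience wrapper around [mapReads()] for one read; reads shorter than
#' the index's k can never seed and are reported unmapped.
#'
#' @inheritParams mapReads
#' @param read one read sequence (optionally named).
#' @return a one-row alignment data.frame (see [mapReads()]).
#' @export
mapRead <- function(read, panel, minidx, ryidx = NULL, profile = NULL,
                    config = FilterConfig(), ...) {
  mapReads(read, panel, minidx, ryidx = ryidx, profile = profile,
           config = config, ...)
}

#' Re-score an alignment's edit script against the reference
#'
#' Walks the CIGAR over the reference and recomputes score and edit
#' distance under the given scheme; used to validate emitted alignments.
#'
#' @param aln one-row alignment data.frame (mapped).
#' @param panel the [ReferencePanel-class].
#' @param scoring scoring overrides as in [mapReads()].
#' @return list with score, nm and read_consumed.
#' @export
rescoreAlignment <- function(aln, panel, scoring = list()) {
  sc <- .scoring(scoring)
  stopifnot(nrow(aln) == 1L, aln$flag != 4L)
  i <- match(aln$rname, seqNames(panel))
  if (is.na(i)) stop("alignment reference not in panel")
  s <- as.character(panel@sequences[[i]])
  if (panel@circular[i]) s <- paste0(s, s)
  cpp_rescore_cigar(toupper(aln$seq), s, as.numeric(aln$pos - 1L), aln$cigar,
                    sc$match, sc$mismatch, sc$gapOpen, sc$gapExtend)
}
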