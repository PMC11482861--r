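# Ancient-DNA read simulator: fragment lengths from an empirical or
# lognormal distribution, strand-resolved deamination per a DamageProfile,
# optional contaminant reads, and a ground-truth table.

#' Fragment length distributions
#'
#' `lognormalFragments` is a truncated, discretised lognormal whose
#' defaults (median 55 bp, range 30-120 bp) emulate the short-fragment
#' shape typical of ancient mitochondrial libraries. `empiricalFragments`
#' takes an explicit length -> probability table, e.g. read from a TSV with
#' columns `length` and `prob`.
#'
#' @param meanlog,sdlog lognormal parameters on the log scale.
#' @param minLen,maxLen inclusive truncation bounds in bases.
#' @return a [FragmentLengthDist-class].
#' @export
lognormalFragments <- function(meanlog = log(55), sdlog = 0.35,
                               minLen = 30L, maxLen = 120L) {
  new("FragmentLengthDist", type = "lognormal", lengths = integer(),
      probs = numeric(), meanlog = meanlog, sdlog = sdlog,
      minLen = as.integer(minLen), maxLen = as.integer(maxLen))
}

#' @rdname lognormalFragments
#' @param lengths fragment lengths, or the path to a two-column TSV.
#' @param probs probabilities summing to 1 (within 1e-9).
#' @export
empiricalFragments <- function(lengths, probs = NULL) {
  if (is.character(lengths) && length(lengths) == 1L) {
    df <- utils::read.delim(lengths)
    if (!all(c("length", "prob") %in% colnames(df)))
      stop("empirical length table needs columns 'length' and 'prob'")
    probs <- df$prob
    lengths <- df$length
  }
  new("FragmentLengthDist", type = "empirical",
      lengths = as.integer(lengths), probs = as.numeric(probs),
      meanlog = NA_real_, sdlog = NA_real_, minLen = min(as.integer(lengths)),
      maxLen = max(as.integer(lengths)))
}

#' @rdname lognormalFragments
#' @param dist a [FragmentLengthDist-class].
#' @param n number of lengths to draw.
#' @export
sampleFragmentLengths <- function(dist, n) {
  stopifnot(is(dist, "FragmentLengthDist"))
  if (dist@type == "empirical")
    return(sample(dist@lengths, n, replace = TRUE, prob = dist@probs))
  out <- integer(0)
  while (length(out) < n) {
    draw <- as.integer(round(rlnorm(n, dist@meanlog, dist@sdlog)))
    out <- c(out, draw[draw >= dist@minLen & draw <= dist@maxLen])
  }
  out[seq_len(n)]
}

setMethod("show", "FragmentLengthDist", function(object) {
  if (object@type == "lognormal")
    cat(sprintf(
      "FragmentLengthDist: lognormal(meanlog %.3f, sdlog %.3f) on [%d, %d]\n",
      object@meanlog, object@sdlog, object@minLen, object@maxLen))
  else
    cat(sprintf("FragmentLengthDist: empirical over %d lengths [%d, %d]\n",
                length(object@lengths), object@minLen, object@maxLen))
})

#' Simulate ancient-DNA reads with ground truth
#'
#' Each endogenous read takes a uniformly placed fragment (uniform start on
#' a uniformly chosen panel sequence; circular sequences may wrap the
#' origin) of length drawn from `dist`, on a Bernoulli(0.5) strand;
#' deamination is then applied per base in sequenced-read orientation:
#' C>T with the 5' profile rate at the base's 5'-distance (single-stranded
#' libraries combine both ends) and G>A with the 3' rate at its
#' 3'-distance, positions beyond the profile depth clamping to the last
#' row. Damage never introduces transversions, so every read's RY encoding
#' equals that of its undamaged source. Contaminants are drawn identically
#' from `contaminantPanel` when given, otherwise as i.i.d. uniform random
#' sequences, and pass through the same damage process.
#'
#' @param panel endogenous [ReferencePanel-class].
#' @param n total number of reads.
#' @param profile a [DamageProfile-class] (its libraryType selects the
#'   damage geometry).
#' @param dist a [FragmentLengthDist-class].
#' @param contaminantFraction fraction of the n reads that are contaminant.
#' @param contaminantPanel optional [ReferencePanel-class] of contaminant
#'   sources (e.g. bacterial genomes).
#' @param errorRate optional uniform per-base sequencing error rate applied
#'   after damage; off (0) by default, matching the filter model's
#'   exclusion of sequencing error.
#' @param seed integer seed; identical inputs and seed give byte-identical
#'   FASTQ and truth files.
#' @return list with `reads` (named character), `truth` (data.frame: id,
#'   class, seq_id, start, end, strand, n_damage_events), and `events`
#'   (data.frame of applied damage events in read orientation: id, pos,
#'   ref_base, read_base).
#' @export
simulateReads <- function(panel, n, profile = damageFixture("zero"),
                          dist = lognormalFragments(),
                          contaminantFraction = 0, contaminantPanel = NULL,
                          errorRate = 0, seed = NULL) {
  stopifnot(is(panel, "ReferencePanel"), is(profile, "DamageProfile"),
            is(dist, "FragmentLengthDist"), n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- as.integer(n)
  nCont <- as.integer(round(n * contaminantFraction))
  nEndo <- n - nCont

  drawFragments <- function(pan, m, tag) {
    lens <- sampleFragmentLengths(dist, m)
    seqLen <- unname(seqLengths(pan))
    circ <- isCircular(pan)
    sidx <- sample.int(length(pan), m, replace = TRUE)
    bad <- !circ[sidx] & lens > seqLen[sidx]
    if (any(bad)) {
      for (j in which(bad)) {
        elig <- which(circ | seqLen >= lens[j])
        if (length(elig) == 0L)
          stop("fragment length ", lens[j],
               " exceeds every linear panel sequence")
        sidx[j] <- elig[sample.int(length(elig), 1L)]
      }
    }
    maxStart <- ifelse(circ[sidx], seqLen[sidx],
                       seqLen[sidx] - lens + 1L)
    start <- as.integer(floor(runif(m) * maxStart))  # 0-based
    seqs <- as.character(pan@sequences)
    doubled <- ifelse(circ, paste0(seqs, seqs), seqs)
    frag <- substring(doubled[sidx], start + 1L, start + lens)
    strand <- ifelse(runif(m) < 0.5, "+", "-")
    frag[strand == "-"] <- cpp_revcomp_seq(frag[strand == "-"])
    list(seq = frag, seq_id = seqNames(pan)[sidx], start = start,
         end = start + lens, strand = strand,
         id = sprintf("%s_%06d", tag, seq_len(m)))
  }

  endo <- drawFragments(panel, nEndo, "endo")
  if (nCont > 0L) {
    if (!is.null(contaminantPanel)) {
      cont <- drawFragments(contaminantPanel, nCont, "cont")
    } else {
      lens <- sampleFragmentLengths(dist, nCont)
      cont <- list(seq = cpp_random_dna(lens, 0.5),
                   seq_id = rep("*", nCont), start = rep(0L, nCont),
                   end = lens, strand = rep("+", nCont),
                   id = sprintf("cont_%06d", seq_len(nCont)))
    }
  } else {
    cont <- list(seq = character(), seq_id = character(), start = integer(),
                 end = integer(), strand = character(), id = character())
  }

  allSeq <- c(endo$seq, cont$seq)
  allId <- c(endo$id, cont$id)
  cls <- c(rep("endogenous", nEndo), rep("contaminant", nCont))

  ss <- profile@libraryType == "single-stranded"
  dmg <- cpp_apply_damage(allSeq, profile@fivePrime[, "C>T"],
                          profile@threePrime[, "G>A"],
                          profile@threePrime[, "C>T"], ss)
  reads <- dmg$seq
  events <- as.data.frame(dmg$events)
  events$id <- allId[events$read]
  events <- events[, c("id", "pos", "ref_base", "read_base")]

  if (errorRate > 0) {
    spl <- strsplit(reads, "", fixed = TRUE)
    reads <- vapply(spl, function(b) {
      hit <- runif(length(b)) < errorRate
      if (any(hit))
        b[hit] <- vapply(b[hit], function(x) {
          sample(setdiff(c("A", "C", "G", "T"), x), 1L)
        }, "")
      paste(b, collapse = "")
    }, "")
  }

  nEvents <- integer(length(allId))
  if (nrow(events) > 0) {
    tb <- table(factor(events$id, levels = allId))
    nEvents <- as.integer(tb)
  }
  truth <- data.frame(id = allId, class = cls,
                      seq_id = c(endo$seq_id, cont$seq_id),
                      start = c(endo$start, cont$start),
                      end = c(endo$end, cont$end),
                      strand = c(endo$strand, cont$strand),
                      n_damage_events = nEvents, stringsAsFactors = FALSE)
  names(reads) <- allId
  list(reads = reads, truth = truth, events = events)
}

#' Read and write simulation truth tables
#'
#' Tab-separated with a fixed header (id, class, seq_id, start, end,
#' strand, n_damage_events); `readTruth` validates the header and rejects
#' malformed rows naming the first offending line.
#'
#' @param truth a truth data.frame from [simulateReads()].
#' @param path TSV file.
#' @return `writeTruth` returns `path` invisibly; `readTruth` the table.
#' @export
writeTruth <- function(truth, path) {
  fwrite(as.data.table(truth), path, sep = "\t", quote = FALSE)
  invisible(path)
}

TRUTH_COLUMNS <- c("id", "class", "seq_id", "start", "end", "strand",
                   "n_damage_events")

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty truth file")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, TRUTH_COLUMNS))
    stop("malformed truth header: expected ",
         paste(TRUTH_COLUMNS, collapse = ", "))
  nf <- lengths(strsplit(lines[-1L], "\t", fixed = TRUE))
  if (any(nf != length(TRUTH_COLUMNS)))
    stop("malformed truth row at line ",
         which(nf != length(TRUTH_COLUMNS))[1L] + 1L)
  df <- as.data.frame(fread(path, sep = "\t", colClasses = list(
    character = c("id", "class", "seq_id", "strand"),
    integer = c("start", "end", "n_damage_events"))))
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$n_damage_events) |
               !df$class %in% c("endogenous", "contaminant") |
               !df$strand %in% c("+", "-"))
  if (length(bad))
    stop("malformed truth row at line ", bad[1L] + 1L)
  df
}

#' Truth-derived alignment records
#'
#' Builds gapless SAM-style records from simulated reads at their true
#' placements (endogenous reads only), for damage-profile estimation
#' independent of any mapper.
#'
#' @param sim result of [simulateReads()].
#' @return alignment data.frame usable by [estimateDamageProfile()].
#' @export
truthToAlignments <- function(sim) {
  tr <- sim$truth
  keep <- tr$class == "endogenous"
  tr <- tr[keep, , drop = FALSE]
  reads <- sim$reads[tr$id]
  minus <- tr$strand == "-"
  seq <- ifelse(minus, cpp_revcomp_seq(reads), reads)  # reference-forward
  data.frame(qname = tr$id, flag = ifelse(minus, 16L, 0L),
             rname = tr$seq_id, pos = tr$start + 1L, mapq = 60L,
             cigar = paste0(nchar(reads), "M"), seq = unname(seq),
             stringsAsFactors = FALSE)
}
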