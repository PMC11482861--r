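# Position-dependent deamination rate matrices: representation, file IO,
# rate lookup, estimation from alignments, and RMSE comparison.

#' @rdname DamageProfile-class
#' @format NULL
#' @export
SUBSTITUTION_TYPES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                        "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

.emptyRateMatrix <- function(depth) {
  matrix(0, nrow = depth, ncol = 12L,
         dimnames = list(NULL, SUBSTITUTION_TYPES))
}

.coerceRateMatrix <- function(m, what) {
  m <- as.matrix(m)
  if (is.null(colnames(m)) || !all(SUBSTITUTION_TYPES %in% colnames(m)))
    stop(what, " must have all 12 substitution columns ",
         "(\"A>C\" ... \"T>G\"); column order is taken from the header")
  m <- m[, SUBSTITUTION_TYPES, drop = FALSE]
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}

#' @rdname DamageProfile-class
#' @param fivePrime,threePrime rate matrices (rows = position from the
#'   respective end, columns the 12 substitution types "X>Y").
#' @param libraryType "double-stranded" (C>T at 5', G>A at 3') or
#'   "single-stranded" (C>T read from both ends' matrices).
#' @export
DamageProfile <- function(fivePrime, threePrime,
                          libraryType = c("double-stranded", "single-stranded")) {
  new("DamageProfile",
      fivePrime = .coerceRateMatrix(fivePrime, "fivePrime"),
      threePrime = .coerceRateMatrix(threePrime, "threePrime"),
      libraryType = match.arg(libraryType))
}

#' @rdname DamageProfile-class
#' @param depth number of positions per end.
#' @export
zeroDamageProfile <- function(depth = 5L,
                              libraryType = "double-stranded") {
  DamageProfile(.emptyRateMatrix(depth), .emptyRateMatrix(depth),
                libraryType = libraryType)
}

#' Shipped damage strata
#'
#' Package-defined damage strata with monotone terminal decay over 5
#' positions, mirroring the usual spectrum from undamaged to heavily
#' deaminated double-stranded libraries plus a mildly damaged
#' single-stranded one:
#' \describe{
#'   \item{zero}{no damage.}
#'   \item{ds-mid}{double-stranded, C>T at 5' and G>A at 3' decaying
#'     0.25, 0.15, 0.08, 0.04, 0.02.}
#'   \item{ds-high}{double-stranded, decaying 0.45, 0.30, 0.18, 0.10, 0.06.}
#'   \item{ss-low}{single-stranded, C>T at both ends decaying
#'     0.08, 0.05, 0.03, 0.02, 0.01; no G>A.}
#' }
#'
#' @param name stratum name.
#' @return a [DamageProfile-class].
#' @export
damageFixture <- function(name = c("zero", "ds-mid", "ds-high", "ss-low")) {
  name <- match.arg(name)
  five <- .emptyRateMatrix(5L)
  three <- .emptyRateMatrix(5L)
  if (name == "ds-high") {
    five[, "C>T"] <- c(0.45, 0.30, 0.18, 0.10, 0.06)
    three[, "G>A"] <- c(0.45, 0.30, 0.18, 0.10, 0.06)
  } else if (name == "ds-mid") {
    five[, "C>T"] <- c(0.25, 0.15, 0.08, 0.04, 0.02)
    three[, "G>A"] <- c(0.25, 0.15, 0.08, 0.04, 0.02)
  } else if (name == "ss-low") {
    five[, "C>T"] <- c(0.08, 0.05, 0.03, 0.02, 0.01)
    three[, "C>T"] <- c(0.08, 0.05, 0.03, 0.02, 0.01)
    return(DamageProfile(five, three, libraryType = "single-stranded"))
  }
  DamageProfile(five, three)
}

#' @rdname DamageProfile-class
#' @param x,object a [DamageProfile-class].
#' @export
setGeneric("fivePrime", function(x) standardGeneric("fivePrime"))
#' @rdname DamageProfile-class
#' @export
setMethod("fivePrime", "DamageProfile", function(x) x@fivePrime)
#' @rdname DamageProfile-class
#' @export
setGeneric("threePrime", function(x) standardGeneric("threePrime"))
#' @rdname DamageProfile-class
#' @export
setMethod("threePrime", "DamageProfile", function(x) x@threePrime)
#' @rdname DamageProfile-class
#' @export
setGeneric("libraryType", function(x) standardGeneric("libraryType"))
#' @rdname DamageProfile-class
#' @export
setMethod("libraryType", "DamageProfile", function(x) x@libraryType)

setMethod("show", "DamageProfile", function(object) {
  cat(sprintf("DamageProfile (%s), depth %d/%d positions\n",
              object@libraryType, nrow(object@fivePrime),
              nrow(object@threePrime)))
  if (nrow(object@fivePrime))
    cat("  5' C>T:", paste(sprintf("%.3f", object@fivePrime[, "C>T"]),
                           collapse = " "), "\n")
  if (nrow(object@threePrime))
    cat("  3' G>A:", paste(sprintf("%.3f", object@threePrime[, "G>A"]),
                           collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# file dialect: tab-separated, header of substitution columns "X>Y" covering
# all 12 off-diagonal pairs (order taken from the header), row i = position i
# from the respective end; one file per end.

#' Read and write damage-profile files
#'
#' @param path5p,path3p per-end TSV files (see Details).
#' @param libraryType library chemistry of the profile.
#' @return `loadDamageProfile` returns a [DamageProfile-class];
#'   `writeDamageProfile` returns the paths invisibly.
#' @details Files are tab-separated with a header naming the 12 substitution
#'   columns "X>Y"; row i (0-based) holds the rates at position i from the
#'   respective fragment end. Rates outside [0,1] and malformed headers are
#'   rejected.
#' @export
loadDamageProfile <- function(path5p, path3p,
                              libraryType = c("double-stranded",
                                              "single-stranded")) {
  readOne <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE)
    if (!all(SUBSTITUTION_TYPES %in% colnames(df)))
      stop("malformed profile header in ", p,
           ": need all 12 substitution columns \"X>Y\"")
    m <- as.matrix(df[, SUBSTITUTION_TYPES, drop = FALSE])
    if (anyNA(m) || !is.numeric(m))
      stop("non-numeric rate in ", p)
    if (any(m < 0) || any(m > 1))
      stop("rate outside [0,1] in ", p)
    m
  }
  DamageProfile(readOne(path5p), readOne(path3p),
                libraryType = match.arg(libraryType))
}

#' @rdname loadDamageProfile
#' @param profile a [DamageProfile-class].
#' @export
writeDamageProfile <- function(profile, path5p, path3p) {
  stopifnot(is(profile, "DamageProfile"))
  writeOne <- function(m, p) {
    df <- as.data.frame(m)
    fwrite(df, p, sep = "\t", quote = FALSE)
  }
  writeOne(profile@fivePrime, path5p)
  writeOne(profile@threePrime, path3p)
  invisible(c(path5p, path3p))
}

# ---------------------------------------------------------------------------

#' Query the deamination rate delta for a substitution at a read position
#'
#' Pure read-back of the profile matrices under the library geometry:
#' C>T is taken from the 5' matrix at the 5'-distance (single-stranded
#' libraries combine both ends' C>T rates as 1-(1-r5)(1-r3)); G>A from the
#' 3' matrix at the 3'-distance; any other substitution returns the 5'
#' matrix rate at the 5'-distance (zero in the shipped fixtures); identical
#' bases return 0. Positions past the last profiled row clamp to the last
#' row by default (residual interior deamination), or return 0 with
#' `beyondDepth = "zero"`.
#'
#' @param profile a [DamageProfile-class].
#' @param posFrom5p,posFrom3p 0-based distances from the read's ends.
#' @param refBase,readBase bases in {A,C,G,T}, read orientation.
#' @param beyondDepth "clamp" (default) or "zero".
#' @return vector of rates in [0,1].
#' @export
deltaRate <- function(profile, posFrom5p, posFrom3p, refBase, readBase,
                      beyondDepth = c("clamp", "zero")) {
  stopifnot(is(profile, "DamageProfile"))
  beyondDepth <- match.arg(beyondDepth)
  refBase <- toupper(refBase); readBase <- toupper(readBase)
  if (!all(refBase %in% c("A", "C", "G", "T")) ||
      !all(readBase %in% c("A", "C", "G", "T")))
    stop("bases must be in {A,C,G,T}")
  n <- max(length(posFrom5p), length(posFrom3p), length(refBase),
           length(readBase))
  posFrom5p <- rep_len(as.integer(posFrom5p), n)
  posFrom3p <- rep_len(as.integer(posFrom3p), n)
  refBase <- rep_len(refBase, n); readBase <- rep_len(readBase, n)
  if (any(posFrom5p < 0) || any(posFrom3p < 0))
    stop("positions must be >= 0")

  lookup <- function(m, pos, col) {
    d <- nrow(m)
    if (d == 0L) return(numeric(length(pos)))
    out <- numeric(length(pos))
    inside <- pos < d
    out[inside] <- m[pos[inside] + 1L, col]
    if (beyondDepth == "clamp") out[!inside] <- m[d, col]
    out
  }

  out <- numeric(n)
  same <- refBase == readBase
  sub <- paste0(refBase, ">", readBase)
  ct <- !same & sub == "C>T"
  ga <- !same & sub == "G>A"
  other <- !same & !ct & !ga
  if (any(ct)) {
    r5 <- lookup(profile@fivePrime, posFrom5p[ct], "C>T")
    if (profile@libraryType == "single-stranded") {
      r3 <- lookup(profile@threePrime, posFrom3p[ct], "C>T")
      out[ct] <- 1 - (1 - r5) * (1 - r3)
    } else {
      out[ct] <- r5
    }
  }
  if (any(ga)) out[ga] <- lookup(profile@threePrime, posFrom3p[ga], "G>A")
  if (any(other)) {
    subs <- sub[other]
    idx <- which(other)
    for (s in unique(subs)) {
      sel <- idx[subs == s]
      out[sel] <- lookup(profile@fivePrime, posFrom5p[sel], s)
    }
  }
  out
}

# ---------------------------------------------------------------------------

#' Estimate a damage profile from alignments
#'
#' Counts substitutions relative to the reference in read (sequenced-strand)
#' orientation: reverse-strand records are complemented and reversed before
#' counting. For each end and position closer than `depth`, the rate of
#' X>Y is count(X>Y) / opportunities(X); positions with zero opportunities
#' report 0. Sequencing error is not modelled (the estimator reports raw
#' mismatch rates).
#'
#' @param alignments a data.frame of primary alignments with columns
#'   qname, flag, rname, pos (1-based), cigar, seq — as returned by
#'   [mapReads()] or [readSam()] — or the path to a SAM file.
#' @param panel the [ReferencePanel-class] the reads were aligned to.
#' @param depth positions per end to profile.
#' @param libraryType recorded in the returned profile.
#' @return a [DamageProfile-class]; the raw counts and opportunities are
#'   attached as attribute "counts".
#' @export
estimateDamageProfile <- function(alignments, panel, depth = 5L,
                                  libraryType = c("double-stranded",
                                                  "single-stranded")) {
  stopifnot(is(panel, "ReferencePanel"))
  libraryType <- match.arg(libraryType)
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- readSam(alignments)
  aln <- as.data.table(alignments)
  aln <- aln[!bitwAnd(aln$flag, 4L) & !bitwAnd(aln$flag, 256L) &
             !bitwAnd(aln$flag, 2048L)]
  prof <- zeroDamageProfile(depth, libraryType)
  if (nrow(aln) == 0L) {
    warning("no usable alignments; returning a zero-opportunity profile")
    attr(prof, "counts") <- NULL
    return(prof)
  }
  refSeqs <- as.character(panel@sequences)
  # doubled circular references let wrapped alignments read past the origin
  ext <- ifelse(panel@circular, paste0(refSeqs, refSeqs), refSeqs)
  ridx <- match(aln$rname, seqNames(panel))
  if (anyNA(ridx))
    stop("alignment references not in panel: ",
         paste(unique(aln$rname[is.na(ridx)]), collapse = ", "))
  res <- cpp_damage_counts(toupper(aln$seq), ridx, ext,
                           as.numeric(aln$pos - 1L), aln$cigar,
                           bitwAnd(aln$flag, 16L) > 0L, as.integer(depth))
  counts <- res$counts  # dims: end(2) x pos(depth) x (from*4+to)(16)
  opps <- res$opps      # dims: end(2) x pos(depth) x from(4)
  bases <- c("A", "C", "G", "T")
  five <- .emptyRateMatrix(depth)
  three <- .emptyRateMatrix(depth)
  for (fi in 1:4) for (ti in 1:4) {
    if (fi == ti) next
    col <- paste0(bases[fi], ">", bases[ti])
    for (end in 1:2) {
      o <- opps[end, , fi]
      cts <- counts[end, , (fi - 1L) * 4L + ti]
      rate <- ifelse(o > 0L, cts / o, 0)
      if (end == 1L) five[, col] <- rate else three[, col] <- rate
    }
  }
  prof <- DamageProfile(five, three, libraryType = libraryType)
  attr(prof, "counts") <- list(counts = counts, opportunities = opps)
  prof
}

#' Root-mean-squared error between two damage profiles
#'
#' The square root of the mean squared difference over all compared cells
#' of both end matrices. Profiles of unequal depth are clamped to the
#' shallower depth before comparison. `cells = "deamination"` restricts the
#' comparison to the C>T and G>A columns.
#'
#' @param a,b [DamageProfile-class] objects.
#' @param cells "all" (default) or "deamination".
#' @return a nonnegative number.
#' @export
profileRMSE <- function(a, b, cells = c("all", "deamination")) {
  stopifnot(is(a, "DamageProfile"), is(b, "DamageProfile"))
  cells <- match.arg(cells)
  cols <- if (cells == "all") SUBSTITUTION_TYPES else c("C>T", "G>A")
  if (!all(cols %in% colnames(a@fivePrime)) ||
      !all(cols %in% colnames(b@fivePrime)))
    stop("incompatible substitution sets")
  d5 <- min(nrow(a@fivePrime), nrow(b@fivePrime))
  d3 <- min(nrow(a@threePrime), nrow(b@threePrime))
  if (d5 == 0L && d3 == 0L) stop("profiles have no comparable positions")
  diffs <- c(
    a@fivePrime[seq_len(d5), cols, drop = FALSE] -
      b@fivePrime[seq_len(d5), cols, drop = FALSE],
    a@threePrime[seq_len(d3), cols, drop = FALSE] -
      b@threePrime[seq_len(d3), cols, drop = FALSE])
  sqrt(mean(diffs^2))
}
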