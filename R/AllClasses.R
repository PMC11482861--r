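# Central S4 containers. 64-bit keys are held as fixed-width 16-character
# lowercase hex strings; R doubles are exact only to 2^53, short of the
# 62 bits a length-31 kmer needs.

setOldClass(c("data.table", "data.frame"))

#' @rdname encodeKmer
#' @export
setClass("KmerCode",
  representation(bits = "character", length = "integer"),
  validity = function(object) {
    if (length(object@bits) != length(object@length))
      return("bits and length must be parallel vectors")
    if (any(object@length < 1L | object@length > 31L))
      return("kmer length must be in 1..31")
    if (any(!grepl("^[0-9a-f]{16}$", object@bits)))
      return("bits must be 16-character lowercase hex")
    # decoding then re-encoding must be the identity (catches stray high bits)
    dec <- cpp_decode_kmer(object@bits, object@length)
    if (any(cpp_encode_kmer(dec) != object@bits))
      return("bits exceed 4^length (non-canonical high bits set)")
    TRUE
  }
)

#' @rdname encodeRymer
#' @export
setClass("RyCode",
  representation(bits = "character", length = "integer"),
  validity = function(object) {
    if (length(object@bits) != length(object@length))
      return("bits and length must be parallel vectors")
    if (any(object@length < 1L | object@length > 62L))
      return("RYmer length must be in 1..62")
    if (any(!grepl("^[0-9a-f]{16}$", object@bits)))
      return("bits must be 16-character lowercase hex")
    dec <- cpp_decode_rymer(object@bits, object@length)
    if (any(cpp_encode_rymer(dec) != object@bits))
      return("bits exceed 2^length (non-canonical high bits set)")
    TRUE
  }
)

#' Indexing parameters shared by a minimizer/rescue index pair
#'
#' @slot k minimizer length in bases (1..31).
#' @slot w number of consecutive kmer start positions per window per strand.
#' @export
setClass("IndexParams",
  representation(k = "integer", w = "integer"),
  validity = function(object) {
    if (length(object@k) != 1L || is.na(object@k) ||
        object@k < 1L || object@k > 31L)
      return("k must be a single integer in 1..31")
    if (length(object@w) != 1L || is.na(object@w) || object@w < 1L)
      return("w must be a single integer >= 1")
    TRUE
  }
)

#' A panel of reference haplotype sequences
#'
#' An ordered collection of named sequences, each optionally flagged
#' circular. Coordinates are 0-based internally and 1-based in SAM output.
#'
#' @slot sequences a [Biostrings::DNAStringSet] with unique names.
#' @slot circular logical vector, one flag per sequence.
#' @export
setClass("ReferencePanel",
  representation(sequences = "DNAStringSet", circular = "logical"),
  validity = function(object) {
    if (length(object@sequences) == 0L) return(TRUE)
    nm <- names(object@sequences)
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
      return("all panel sequences must be named")
    if (anyDuplicated(nm)) return("panel sequence names must be unique")
    if (length(object@circular) != length(object@sequences))
      return("circular must have one flag per sequence")
    TRUE
  }
)

#' Minimizer index over a reference panel
#'
#' Hash-style table mapping canonical minimizer keys to their occurrence
#' hits (sequence, 0-based offset, orientation). Built by
#' [buildMinimizerIndex()].
#'
#' @slot params an [IndexParams-class].
#' @slot table data.table with columns key, seq_id, offset, orient.
#' @slot maxHits per-key hit cap applied at build time.
#' @slot refNames,refLengths,refCircular panel metadata captured at build.
#' @export
setClass("MinimizerIndex",
  representation(params = "IndexParams", table = "data.frame",
                 maxHits = "integer", refNames = "character",
                 refLengths = "integer", refCircular = "logical")
)

#' Rescue index: RY projections of the minimizer keys
#'
#' Maps each distinct RY (purine/pyrimidine) projection of the paired
#' minimizer index's keys back to the minimizer keys that produced it.
#' The payload is a back-pointer: positions are always fetched by a second
#' lookup in the minimizer index. Built by [buildRymerIndex()].
#'
#' @slot params an [IndexParams-class]; must match the paired minimizer index.
#' @slot table data.table with columns rykey, key.
#' @export
setClass("RymerIndex",
  representation(params = "IndexParams", table = "data.frame")
)

#' Position-dependent deamination rate matrices
#'
#' Substitution rates indexed by distance from each fragment end. The 5'
#' matrix drives C-to-T rates, the 3' matrix G-to-A rates (double-stranded
#' geometry); single-stranded libraries read C-to-T from both ends.
#'
#' @slot fivePrime,threePrime numeric matrices, rows = position from the
#'   respective end (0-based), columns the 12 substitution types "X>Y".
#' @slot libraryType "double-stranded" or "single-stranded".
#' @export
setClass("DamageProfile",
  representation(fivePrime = "matrix", threePrime = "matrix",
                 libraryType = "character"),
  validity = function(object) {
    for (m in list(object@fivePrime, object@threePrime)) {
      if (!identical(colnames(m), SUBSTITUTION_TYPES))
        return("matrix columns must be the 12 substitution types X>Y")
      if (nrow(m) > 0 && (any(m < 0) || any(m > 1)))
        return("all rates must lie in [0,1]")
      for (b in c("A", "C", "G", "T")) {
        cols <- grep(paste0("^", b, ">"), colnames(m))
        if (nrow(m) > 0 && any(rowSums(m[, cols, drop = FALSE]) > 1 + 1e-9))
          return(sprintf("rates leaving %s must sum to <= 1 at every position", b))
      }
    }
    if (!object@libraryType %in% c("double-stranded", "single-stranded"))
      return("libraryType must be 'double-stranded' or 'single-stranded'")
    TRUE
  }
)

#' Configuration of the Bayesian seed-rescue filter
#'
#' @slot a,b coefficients of the power-law per-base spurious mismatch rate
#'   p = a * k^b.
#' @slot kCutoff seed lengths at or above this use a flat spurious
#'   likelihood instead of the binomial model.
#' @slot longKConstant the flat spurious likelihood for long seeds.
#' @slot priorV prior probability that an RY-matched, kmer-mismatched seed
#'   is explained by deamination.
#' @slot thresholdJ posterior cutoff; candidates with posterior >= thresholdJ
#'   are rescued.
#' @export
setClass("FilterConfig",
  representation(a = "numeric", b = "numeric", kCutoff = "integer",
                 longKConstant = "numeric", priorV = "numeric",
                 thresholdJ = "numeric"),
  validity = function(object) {
    if (object@priorV < 0 || object@priorV > 1)
      return("priorV must lie in [0,1]")
    if (object@thresholdJ < 0 || object@thresholdJ > 1)
      return("thresholdJ must lie in [0,1]")
    if (object@longKConstant <= 0 || object@longKConstant >= 1)
      return("longKConstant must lie in (0,1)")
    TRUE
  }
)

#' Read-kmer / candidate-minimizer comparisons for the rescue filter
#'
#' Vectorised container: one row per (read kmer, candidate minimizer) pair,
#' with per-base records laid out in read (sequenced-strand) orientation.
#'
#' @slot readKey,candKey hex-encoded kmer keys.
#' @slot k seed length.
#' @slot m transitions-only Hamming mismatch count per pair.
#' @slot readBases,refBases character matrices (pairs x k), read orientation.
#' @slot posFrom5p,posFrom3p integer matrices of per-base distances from the
#'   read's 5' and 3' ends.
#' @slot readLength integer vector of read lengths.
#' @export
setClass("SeedComparisons",
  representation(readKey = "character", candKey = "character", k = "integer",
                 m = "integer", readBases = "matrix", refBases = "matrix",
                 posFrom5p = "matrix", posFrom3p = "matrix",
                 readLength = "integer"),
  validity = function(object) {
    n <- length(object@readKey)
    if (length(object@candKey) != n || length(object@m) != n ||
        length(object@readLength) != n)
      return("parallel slots must have equal length")
    if (n > 0) {
      # every mismatch must be a transition: RY projections identical
      rya <- cpp_kmer_to_rymer(object@readKey, object@k)
      ryb <- cpp_kmer_to_rymer(object@candKey, object@k)
      if (any(rya != ryb))
        return("read and candidate kmers must share their RY projection")
    }
    TRUE
  }
)

#' Confusion counts for the read-mapping classification task
#'
#' Labels follow the benchmark's convention: endogenous reads mapped within
#' tolerance are TP, endogenous reads mapped elsewhere are FP, unmapped
#' endogenous reads are FN; contaminant reads are TN when unmapped and are
#' counted as FN when mapped (set \code{conventionalLabels = TRUE} in
#' [classifyAlignments()] to count mapped contaminants as FP instead).
#'
#' @slot tp,fp,tn,fn the four counts.
#' @slot breakdown list with the per-class components of fn/fp.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer", breakdown = "list")
)

#' Fragment length distribution for the aDNA simulator
#'
#' Either an empirical length->probability table or a truncated discretised
#' lognormal.
#'
#' @slot type "empirical" or "lognormal".
#' @slot lengths,probs the empirical table (empty for lognormal).
#' @slot meanlog,sdlog,minLen,maxLen lognormal parameters.
#' @export
setClass("FragmentLengthDist",
  representation(type = "character", lengths = "integer", probs = "numeric",
                 meanlog = "numeric", sdlog = "numeric", minLen = "integer",
                 maxLen = "integer"),
  validity = function(object) {
    if (!object@type %in% c("empirical", "lognormal"))
      return("type must be 'empirical' or 'lognormal'")
    if (object@type == "empirical") {
      if (length(object@lengths) != length(object@probs))
        return("lengths and probs must be parallel")
      if (any(object@lengths < 1L)) return("all lengths must be >= 1")
      if (abs(sum(object@probs) - 1) > 1e-9)
        return("probabilities must sum to 1 (tolerance 1e-9)")
      if (any(object@probs < 0)) return("probabilities must be nonnegative")
    } else {
      if (object@minLen < 1L) return("minLen must be >= 1")
      if (object@maxLen < object@minLen) return("maxLen must be >= minLen")
    }
    TRUE
  }
)
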