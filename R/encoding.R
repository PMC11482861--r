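# Bit-packed kmer and RYmer encodings plus the index hash function.
#
# Base codes follow the usual packing A=00, C=01, G=10, T=11 with the first
# base in the most significant position, so lexicographic sequence order
# coincides with integer key order. Purines (A,G) are exactly the even
# codes, which makes the RY projection a per-base low-bit extraction.

KEY_BITS <- 62L

#' Width limits of the 62-bit key encodings
#'
#' A 62-bit key holds 31 bases at 2 bits/base in nucleotide space and
#' 62 bases at 1 bit/base in RY space.
#'
#' @return named list with `kmerBases` and `rymerBases`.
#' @export
encodingLimits <- function() {
  list(kmerBases = KEY_BITS %/% 2L, rymerBases = KEY_BITS)
}

#' Shannon information content of a kmer or RYmer
#'
#' A length-k word over an alphabet of size A carries log2(A^k) = k*log2(A)
#' bits when all letters are equiprobable: 2k bits for a nucleotide kmer,
#' k bits for its RY reduction, so the ratio is exactly 2 for every k.
#'
#' @param k word length in bases.
#' @param alphabetSize 4 for nucleotide kmers, 2 for RYmers.
#' @return information content in bits.
#' @export
shannonInformation <- function(k, alphabetSize = 4) {
  stopifnot(all(k >= 1))
  k * log2(alphabetSize)
}

#' Encode nucleotide kmers as bit-packed integer keys
#'
#' Each base maps to a 2-bit code (A=00, C=01, G=10, T=11); codes are
#' concatenated big-endian (first base most significant). Sequences
#' containing ambiguous bases (including N) are rejected, as are lengths
#' outside 1..31.
#'
#' @param seq character vector of sequences over {A,C,G,T}.
#' @return a [KmerCode-class] holding hex-encoded key bits and lengths.
#' @examples
#' encodeKmer("ACGT")  # bits 0b00011011 = 27
#' @export
encodeKmer <- function(seq) {
  seq <- toupper(as.character(seq))
  new("KmerCode", bits = cpp_encode_kmer(seq), length = nchar(seq))
}

#' @rdname encodeKmer
#' @param code a [KmerCode-class].
#' @export
decodeKmer <- function(code) {
  stopifnot(is(code, "KmerCode"))
  cpp_decode_kmer(code@bits, code@length)
}

#' Encode sequences in the reduced purine/pyrimidine (RY) alphabet
#'
#' Purines (A,G) map to bit 0 ("R"), pyrimidines (C,T) to bit 1 ("Y"), one
#' bit per base with the same big-endian order as [encodeKmer()]. The
#' encoding is invariant under any set of transition substitutions
#' (C<->T, G<->A), which is what makes it blind to deamination.
#'
#' @param seq character vector over {A,C,G,T} (R/Y symbols also accepted).
#' @return an [RyCode-class].
#' @examples
#' decodeRymer(encodeRymer("GATC"))  # "RRYY"
#' @export
encodeRymer <- function(seq) {
  seq <- toupper(as.character(seq))
  new("RyCode", bits = cpp_encode_rymer(seq), length = nchar(seq))
}

#' @rdname encodeRymer
#' @param code an [RyCode-class].
#' @export
decodeRymer <- function(code) {
  stopifnot(is(code, "RyCode"))
  cpp_decode_rymer(code@bits, code@length)
}

#' Project a kmer key to its RY key without decoding to text
#'
#' Works at bit level: the low bit of each 2-bit base code is exactly the
#' purine/pyrimidine class, so the projection is a mask-and-compress. The
#' result always equals `encodeRymer(decodeKmer(code))`.
#'
#' @param code a [KmerCode-class].
#' @return an [RyCode-class] of the same length.
#' @export
kmerToRymer <- function(code) {
  stopifnot(is(code, "KmerCode"))
  new("RyCode", bits = cpp_kmer_to_rymer(code@bits, code@length),
      length = code@length)
}

#' @describeIn encodeKmer reverse complement of an encoded kmer.
#' @export
setMethod("reverseComplement", "KmerCode", function(x, ...) {
  new("KmerCode", bits = cpp_revcomp_kmer(x@bits, x@length), length = x@length)
})

#' @describeIn encodeRymer reverse complement in RY space: reverse the bit
#'   order and flip every bit (complementation swaps purine and pyrimidine).
#' @export
setMethod("reverseComplement", "RyCode", function(x, ...) {
  new("RyCode", bits = cpp_revcomp_rymer(x@bits, x@length), length = x@length)
})

#' @describeIn encodeKmer Watson-Crick reverse complement of plain
#'   character sequences.
#' @export
setMethod("reverseComplement", "character", function(x, ...) {
  cpp_revcomp_seq(toupper(x))
})

#' Thomas Wang's 64-bit integer mix
#'
#' The deterministic, invertible 64-bit hash used for minimizer selection.
#' The exact variant (the `~key + (key << 21)` shift/add ladder) is pinned
#' and versioned as part of the index format: indexes are only comparable
#' under a fixed hash.
#'
#' @param x a [KmerCode-class], [RyCode-class], or 16-character hex string.
#' @return hashed keys as 16-character hex strings.
#' @export
hash64 <- function(x) {
  if (is(x, "KmerCode") || is(x, "RyCode")) x <- x@bits
  stopifnot(is.character(x), all(grepl("^[0-9a-f]{16}$", x)))
  cpp_hash64(x)
}

setMethod("show", "KmerCode", function(object) {
  n <- length(object@bits)
  cat(sprintf("KmerCode of %d key%s\n", n, if (n == 1) "" else "s"))
  shown <- min(n, 5L)
  if (shown > 0) {
    sq <- cpp_decode_kmer(object@bits[seq_len(shown)], object@length[seq_len(shown)])
    cat(sprintf("  %s  (0x%s)\n", sq, object@bits[seq_len(shown)]), sep = "")
  }
  if (n > shown) cat("  ...\n")
})

setMethod("show", "RyCode", function(object) {
  n <- length(object@bits)
  cat(sprintf("RyCode of %d key%s\n", n, if (n == 1) "" else "s"))
  shown <- min(n, 5L)
  if (shown > 0) {
    sq <- cpp_decode_rymer(object@bits[seq_len(shown)], object@length[seq_len(shown)])
    cat(sprintf("  %s  (0x%s)\n", sq, object@bits[seq_len(shown)]), sep = "")
  }
  if (n > shown) cat("  ...\n")
})
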