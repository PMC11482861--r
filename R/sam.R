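# Minimal SAM writing/reading for the package's own alignment records.

#' Write alignments as SAM
#'
#' Emits @HD/@SQ/@PG headers and one record per alignment row with NM and
#' AS tags plus the package's ZR (rescued seed count), ZP (minimum rescued
#' posterior) and ZC (origin-crossing) tags where set. Output is
#' deterministic: identical alignment tables yield byte-identical files.
#'
#' @param aln alignment data.frame from [mapReads()].
#' @param panel the [ReferencePanel-class] mapped against (for @SQ lines).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSam <- function(aln, panel, path) {
  stopifnot(is(panel, "ReferencePanel"))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", seqNames(panel),
                      unname(seqLengths(panel))),
              sprintf("@PG\tID:ryseed\tPN:ryseed\tVN:%s",
                      as.character(utils::packageVersion("ryseed"))))
  body <- samBody(aln)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writeSam
#' @export
samBody <- function(aln) {
  n <- nrow(aln)
  if (n == 0L) return(character())
  tags <- character(n)
  mapped <- aln$flag != 4L
  tags[mapped] <- sprintf("\tNM:i:%d\tAS:i:%d", aln$nm[mapped],
                          aln$score[mapped])
  hasZr <- mapped & !is.na(aln$zr)
  tags[hasZr] <- paste0(tags[hasZr],
                        sprintf("\tZR:i:%d\tZP:f:%.6g", aln$zr[hasZr],
                                aln$zp[hasZr]))
  hasZc <- mapped & !is.na(aln$zc)
  tags[hasZc] <- paste0(tags[hasZc], sprintf("\tZC:i:%d", aln$zc[hasZc]))
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
          aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
          aln$seq, tags)
}

#' Read a SAM file written by [writeSam()]
#'
#' Minimal parser for the package's own SAM dialect (header skipped,
#' mandatory fields plus NM/AS/ZR/ZP/ZC tags).
#'
#' @param path SAM file.
#' @return alignment data.frame in the layout of [mapReads()].
#' @export
readSam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(),
                      score = integer(), nm = integer(), zr = integer(),
                      zp = numeric(), zc = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed SAM record at line(s) ",
         paste(utils::head(which(nf < 11L), 5L), collapse = ", "))
  getTag <- function(f, tag) {
    if (length(f) <= 11L) return(NA_character_)
    extra <- f[12:length(f)]
    hit <- extra[startsWith(extra, tag)]
    if (length(hit) == 0L) return(NA_character_)
    sub("^[A-Za-z0-9]{2}:[AifZ]:", "", hit[1L])
  }
  data.frame(
    qname = vapply(fields, `[`, "", 1L),
    flag = as.integer(vapply(fields, `[`, "", 2L)),
    rname = vapply(fields, `[`, "", 3L),
    pos = as.integer(vapply(fields, `[`, "", 4L)),
    mapq = as.integer(vapply(fields, `[`, "", 5L)),
    cigar = vapply(fields, `[`, "", 6L),
    seq = vapply(fields, `[`, "", 10L),
    score = as.integer(vapply(fields, getTag, "", "AS:")),
    nm = as.integer(vapply(fields, getTag, "", "NM:")),
    zr = as.integer(vapply(fields, getTag, "", "ZR:")),
    zp = as.numeric(vapply(fields, getTag, "", "ZP:")),
    zc = as.integer(vapply(fields, getTag, "", "ZC:")),
    stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' Constant "I" base qualities; deterministic output.
#'
#' @param reads named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  if (is.null(names(reads))) names(reads) <- sprintf("read%d", seq_along(reads))
  quals <- strrep("I", nchar(reads))
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", quals), path)
  invisible(path)
}

#' @rdname writeFastq
#' @export
readFastq <- function(path) {
  x <- readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
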