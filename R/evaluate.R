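# Truth-based benchmarking: binary classification of alignments,
# sensitivity/specificity/F1, and two-run comparison reports.

.circDist <- function(a, b, len, circular) {
  d <- abs(a - b)
  ifelse(circular, pmin(d, len - d), d)
}

#' Classify alignments against simulation truth
#'
#' Endogenous reads are positives: a read mapping within `tolerance` bases
#' (inclusive, circular distance on circular references, leftmost
#' coordinate vs truth start) of its true location is a true positive, one
#' mapping anywhere else a false positive, an unmapped one a false
#' negative. Contaminant reads are negatives: true negatives when
#' unmapped; when mapped they are counted as false negatives, matching the
#' benchmark's labeling (set `conventionalLabels = TRUE` to count them as
#' false positives instead). Only primary records are classified.
#'
#' @param alignments alignment data.frame (from [mapReads()] or
#'   [readSam()]) or a SAM path.
#' @param truth truth data.frame from [simulateReads()] or [readTruth()].
#' @param panel the [ReferencePanel-class] (for lengths and circularity).
#' @param tolerance placement tolerance in bases (inclusive).
#' @param conventionalLabels count mapped contaminants as FP instead of FN.
#' @return a [ConfusionCounts-class].
#' @export
classifyAlignments <- function(alignments, truth, panel, tolerance = 50,
                               conventionalLabels = FALSE) {
  stopifnot(is(panel, "ReferencePanel"))
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- readSam(alignments)
  aln <- as.data.frame(alignments)
  if (anyDuplicated(truth$id))
    stop("truth ids must be unique")
  unknown <- setdiff(aln$qname, truth$id)
  if (length(unknown))
    stop("alignment id(s) absent from truth: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  primary <- aln[!bitwAnd(aln$flag, 256L) & !bitwAnd(aln$flag, 2048L), ,
                 drop = FALSE]
  mapped <- primary[!bitwAnd(primary$flag, 4L), , drop = FALSE]
  if (anyDuplicated(mapped$qname))
    stop("truth id(s) with more than one primary alignment: ",
         paste(utils::head(unique(mapped$qname[duplicated(mapped$qname)]), 5L),
               collapse = ", "))

  lens <- seqLengths(panel)
  circ <- isCircular(panel)
  idx <- match(truth$id, mapped$qname)
  isMapped <- !is.na(idx)
  sameRef <- rep(FALSE, nrow(truth))
  within <- rep(FALSE, nrow(truth))
  mi <- idx[isMapped]
  sameRef[isMapped] <- mapped$rname[mi] == truth$seq_id[isMapped]
  ok <- which(isMapped)[sameRef[isMapped]]
  if (length(ok)) {
    ri <- match(truth$seq_id[ok], names(lens))
    d <- .circDist(mapped$pos[idx[ok]] - 1L, truth$start[ok],
                   lens[ri], circ[ri])
    within[ok] <- d <= tolerance
  }

  endo <- truth$class == "endogenous"
  cont <- truth$class == "contaminant"
  tp <- sum(endo & isMapped & within)
  fpEndo <- sum(endo & isMapped & !within)
  fnEndo <- sum(endo & !isMapped)
  tn <- sum(cont & !isMapped)
  contMapped <- sum(cont & isMapped)

  if (conventionalLabels) {
    fp <- fpEndo + contMapped
    fn <- fnEndo
  } else {
    fp <- fpEndo
    fn <- fnEndo + contMapped
  }
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn),
      breakdown = list(endogenousFP = fpEndo, endogenousFN = fnEndo,
                       contaminantMapped = contMapped,
                       nEndogenous = sum(endo), nContaminant = sum(cont),
                       conventionalLabels = conventionalLabels))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %d, FP %d, TN %d, FN %d\n",
              object@tp, object@fp, object@tn, object@fn))
  b <- object@breakdown
  cat(sprintf("  endogenous: %d (FP %d, FN %d); contaminant: %d (mapped %d)\n",
              b$nEndogenous, b$endogenousFP, b$endogenousFN,
              b$nContaminant, b$contaminantMapped))
})

#' Sensitivity, specificity and F1 from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), and F1 the harmonic
#' mean of precision TP/(TP+FP) and recall TP/(TP+FN). Metrics with a zero
#' denominator are reported as NA (undefined), never as 0.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named numeric: sensitivity, specificity, precision, recall, f1.
#' @export
alignmentMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  sens <- rat(tp, tp + fn)
  spec <- rat(tn, tn + fp)
  prec <- rat(tp, tp + fp)
  rec <- rat(tp, tp + fn)
  f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  c(sensitivity = sens, specificity = spec, precision = prec, recall = rec,
    f1 = f1)
}

#' Compare two mapping runs against the same truth
#'
#' Per-run confusion counts and metrics, per-class mapped counts formatted
#' as aligned/total, and run-A-minus-run-B deltas. The two runs must cover
#' the same read universe.
#'
#' @param a,b alignment data.frames or SAM paths.
#' @param truth shared truth table.
#' @param panel the [ReferencePanel-class].
#' @param tolerance,conventionalLabels passed to [classifyAlignments()].
#' @param labels run display names.
#' @return list of class "ryseedRunComparison" with elements runs (per-run
#'   counts, metrics, mappedByClass) and delta.
#' @export
compareRuns <- function(a, b, truth, panel, tolerance = 50,
                        conventionalLabels = FALSE,
                        labels = c("runA", "runB")) {
  if (is.character(a) && length(a) == 1L) a <- readSam(a)
  if (is.character(b) && length(b) == 1L) b <- readSam(b)
  ua <- sort(unique(a$qname)); ub <- sort(unique(b$qname))
  if (!identical(ua, ub))
    stop("mismatched read universes between the two runs")
  one <- function(x) {
    cc <- classifyAlignments(x, truth, panel, tolerance, conventionalLabels)
    mapped <- x[!bitwAnd(x$flag, 4L) & !bitwAnd(x$flag, 256L) &
                !bitwAnd(x$flag, 2048L), , drop = FALSE]
    byClass <- vapply(c("endogenous", "contaminant"), function(cl) {
      ids <- truth$id[truth$class == cl]
      sprintf("%d/%d", sum(mapped$qname %in% ids), length(ids))
    }, "")
    list(counts = cc, metrics = alignmentMetrics(cc), mappedByClass = byClass)
  }
  ra <- one(a); rb <- one(b)
  delta <- list(
    tp = ra$counts@tp - rb$counts@tp,
    fp = ra$counts@fp - rb$counts@fp,
    tn = ra$counts@tn - rb$counts@tn,
    fn = ra$counts@fn - rb$counts@fn,
    metrics = ra$metrics - rb$metrics)
  out <- list(runs = stats::setNames(list(ra, rb), labels), delta = delta)
  class(out) <- "ryseedRunComparison"
  out
}

#' @export
print.ryseedRunComparison <- function(x, ...) {
  for (nm in names(x$runs)) {
    r <- x$runs[[nm]]
    cat(sprintf("%s: TP %d FP %d TN %d FN %d | sens %.4f spec %.4f f1 %.4f\n",
                nm, r$counts@tp, r$counts@fp, r$counts@tn, r$counts@fn,
                r$metrics["sensitivity"], r$metrics["specificity"],
                r$metrics["f1"]))
    cat(sprintf("  mapped endogenous %s, contaminant %s\n",
                r$mappedByClass["endogenous"],
                r$mappedByClass["contaminant"]))
  }
  cat(sprintf("delta (%s - %s): TP %+d FP %+d TN %+d FN %+d\n",
              names(x$runs)[1], names(x$runs)[2], x$delta$tp, x$delta$fp,
              x$delta$tn, x$delta$fn))
  invisible(x)
}
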