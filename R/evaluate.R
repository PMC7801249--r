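#' Metrics from TP/FP/FN counts
#'
#' Sensitivity = TP/(TP+FN); precision = TP/(TP+FP); F1 =
#' 2*TP/(2*TP+FP+FN).  Ratios with zero denominators are defined as 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return one-row data.frame: \code{tp}, \code{fp}, \code{fn},
#'   \code{sensitivity}, \code{precision}, \code{f1}.
#' @export
#' @examples
#' metricsFromCounts(92, 1, 8)
metricsFromCounts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  data.frame(tp = tp, fp = fp, fn = fn, sensitivity = sens,
             precision = prec, f1 = f1)
}

#' Evaluate circRNA predictions against a truth set
#'
#' Predictions and truth are keyed by (chromosome, start, end, strand).
#' A prediction is a true positive when a truth entry matches within
#' \code{tolerance} bp on both coordinates (same chromosome and strand);
#' each truth entry can absorb any number of matching predictions, and
#' unmatched truth entries count as false negatives.
#'
#' @param predictions a \linkS4class{BackspliceSet},
#'   \linkS4class{CircRNASet}, or data.frame with \code{chrom},
#'   \code{start}, \code{end}, \code{strand}.
#' @param truth data.frame in the same shape (e.g.
#'   \code{simTruth(sim)}).
#' @param tolerance coordinate tolerance in bp (default 0 = exact;
#'   +/-5 mirrors the site-adjustment window).
#' @return one-row metrics data.frame (see
#'   \code{\link{metricsFromCounts}}).
#' @export
evaluatePredictions <- function(predictions, truth, tolerance = 0L) {
  pred <- .candFrame(predictions)
  tru <- truth[, c("chrom", "start", "end", "strand")]
  if (tolerance == 0L) {
    pk <- paste(pred$chrom, pred$start, pred$end, pred$strand)
    tk <- paste(tru$chrom, tru$start, tru$end, tru$strand)
    tp <- sum(pk %in% tk)
    fp <- sum(!pk %in% tk)
    fn <- sum(!tk %in% pk)
  } else {
    matched <- logical(nrow(tru))
    isTP <- logical(nrow(pred))
    for (i in seq_len(nrow(pred))) {
      hit <- which(tru$chrom == pred$chrom[i] &
                     tru$strand == pred$strand[i] &
                     abs(tru$start - pred$start[i]) <= tolerance &
                     abs(tru$end - pred$end[i]) <= tolerance)
      if (length(hit)) {
        isTP[i] <- TRUE
        matched[hit] <- TRUE
      }
    }
    tp <- sum(isTP); fp <- sum(!isTP); fn <- sum(!matched)
  }
  metricsFromCounts(tp, fp, fn)
}

#' Simulate a complete benchmark dataset
#'
#' Convenience wrapper: generates genome + annotation with \code{seed}
#' and the reads/alignments/truth with \code{seed + 1}.
#'
#' @param param a \code{\link{simParams}} list.
#' @param seed integer random seed (keep below 2^31 - 2).
#' @return a \linkS4class{CircSimulation}.
#' @export
simulateBenchmark <- function(param = simParams(), seed = 1L) {
  ga <- simulateGenomeAnnotation(param, seed)
  simulateCircReads(ga$genome, ga$models, param, seed + 1L)
}

#' Write a simulation to disk
#'
#' Emits \code{genome.fa}, \code{annotation.gff3}, \code{reads_1.fastq}
#' (and \code{reads_2.fastq} for paired data), \code{alignments.sam} and
#' \code{truth.tsv} into \code{dir}.  Byte-deterministic for a given
#' simulation object.
#'
#' @param sim a \linkS4class{CircSimulation}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gff3 = file.path(dir, "annotation.gff3"),
             fastq1 = file.path(dir, "reads_1.fastq"),
             sam = file.path(dir, "alignments.sam"),
             truth = file.path(dir, "truth.tsv"))
  writeFasta(simGenome(sim), paths[["genome"]])
  writeGFF3(simModels(sim), paths[["gff3"]])
  writeFastq(simReads(sim, 1L), paths[["fastq1"]])
  if (!is.null(simReads(sim, 2L))) {
    paths <- c(paths, fastq2 = file.path(dir, "reads_2.fastq"))
    writeFastq(simReads(sim, 2L), paths[["fastq2"]])
  }
  writeLines(simAlignments(sim), paths[["sam"]])
  .writeTSV(simTruth(sim), paths[["truth"]])
  invisible(paths)
}
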