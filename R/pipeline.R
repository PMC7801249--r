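#' Run the circRNA detection pipeline
#'
#' Chains candidate calling, pseudo-reference verification and
#' full-length sequence extraction: SAM split reads are screened for
#' chiastic junctions, raw reads are re-matched against the junction
#' pseudo-reference, and verified circRNAs get isoform sequences.
#'
#' @param splitReads a \linkS4class{SplitReadSet} or path to a SAM file.
#' @param genome named \code{DNAStringSet} or FASTA path.
#' @param models \linkS4class{GeneModels}, GFF3 path, or \code{NULL}.
#' @param reads named \code{DNAStringSet} or character vector of FASTQ
#'   paths; when \code{NULL} the verification stage is skipped and all
#'   candidates pass through with \code{verified_reads = n_reads}.
#' @param param \code{\link{detectionParams}}.
#' @param flank pseudo-reference flank (default: read length inferred
#'   from the alignments).
#' @param minAnchor,maxMismatch verification thresholds.
#' @param minVerified minimum verified reads (default 2).
#' @return a \linkS4class{CircRNASet}.
#' @export
detectCircRNAs <- function(splitReads, genome, models = NULL,
                           reads = NULL, param = detectionParams(),
                           flank = NULL, minAnchor = 10L,
                           maxMismatch = 2L, minVerified = 2L) {
  if (is.character(splitReads))
    splitReads <- readSplitAlignments(splitReads)
  if (is.character(genome)) genome <- readGenome(genome)
  if (is.character(models)) models <- readGeneModels(models,
                                                     names(genome))
  cands <- callBackspliceJunctions(splitReads, genome, models, param)
  if (is.null(reads)) {
    mcols(cands)$verified_reads <- mcols(cands)$n_reads
    circs <- new("CircRNASet", cands, isoforms = .emptyIsoforms())
  } else {
    if (is.null(flank)) {
      rl <- alignmentSegments(splitReads)$read_length
      flank <- if (length(rl)) max(rl) else 100L
    }
    pref <- buildPseudoRef(genome, cands, flank = flank)
    ver <- verifyJunctions(reads, pref, minAnchor = minAnchor,
                           maxMismatch = maxMismatch)
    circs <- finalizeCircRNAs(cands, ver, minVerified = minVerified)
  }
  extractFullLength(genome, models, circs, tol = param$annotationTol)
}

#' Run the simulated benchmark end to end
#'
#' Simulates a dataset, runs detection + verification on the
#' truth-derived alignments and raw reads, and scores the calls against
#' the truth set.
#'
#' @param param a \code{\link{simParams}} list.
#' @param seed integer seed.
#' @param tolerance evaluation coordinate tolerance (default 0).
#' @param detectParam a \code{\link{detectionParams}} list.
#' @return list with \code{sim} (\linkS4class{CircSimulation}),
#'   \code{circs} (\linkS4class{CircRNASet}) and \code{metrics}
#'   (one-row data.frame).
#' @export
runBenchmark <- function(param = simParams(), seed = 1L,
                         tolerance = 0L,
                         detectParam = detectionParams()) {
  sim <- simulateBenchmark(param, seed)
  dir <- tempfile("backsplice_bench")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  samPath <- file.path(dir, "alignments.sam")
  writeLines(simAlignments(sim), samPath)
  splitReads <- readSplitAlignments(samPath)
  reads <- simReads(sim, 1L)
  if (!is.null(simReads(sim, 2L))) reads <- c(reads, simReads(sim, 2L))
  circs <- detectCircRNAs(splitReads, simGenome(sim), simModels(sim),
                          reads = reads, param = detectParam,
                          flank = param$readLen)
  metrics <- evaluatePredictions(circs, simTruth(sim),
                                 tolerance = tolerance)
  list(sim = sim, circs = circs, metrics = metrics)
}
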