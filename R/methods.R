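# accessor and show methods

#' @rdname backsplice-accessors
#' @export
setMethod("modelExons", "GeneModels", function(x) x@exons)

#' @rdname backsplice-accessors
#' @export
setMethod("modelTranscripts", "GeneModels", function(x) x@transcripts)

setMethod("length", "GeneModels", function(x) nrow(x@transcripts))

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels with", nrow(object@transcripts), "transcripts,",
      length(unique(object@transcripts$gene_id)), "genes,",
      length(object@exons), "exons\n")
})

#' @rdname backsplice-accessors
#' @export
setMethod("alignmentSegments", "SplitReadSet", function(x) x@segments)

#' @rdname backsplice-accessors
#' @export
setMethod("isPaired", "SplitReadSet", function(x) x@paired)

setMethod("length", "SplitReadSet", function(x) {
  if (!nrow(x@segments)) return(0L)
  length(unique(paste(x@segments$read_id, x@segments$mate)))
})

setMethod("show", "SplitReadSet", function(object) {
  cat("SplitReadSet:", length(object), "read ends,",
      nrow(object@segments), "aligned segments,",
      if (object@paired) "paired-end" else "single-end", "\n")
})

#' @rdname backsplice-accessors
#' @export
setMethod("junctionReads", "BackspliceSet",
          function(x) mcols(x)$n_reads)

#' @rdname backsplice-accessors
#' @export
setMethod("spliceSignal", "BackspliceSet", function(x) mcols(x)$signal)

#' @rdname backsplice-accessors
#' @export
setMethod("circType", "BackspliceSet", function(x) mcols(x)$circ_type)

#' @rdname backsplice-accessors
#' @export
setMethod("candidateId", "BackspliceSet", function(x) {
  if (!length(x)) return(character(0))
  .circId(as.character(seqnames(x)), start(x), end(x),
          as.character(strand(x)))
})

setMethod("show", "BackspliceSet", function(object) {
  cat(class(object), "with", length(object), "back-splice junctions\n")
  if (length(object)) {
    cat("  signals:",
        paste(names(table(mcols(object)$signal)),
              table(mcols(object)$signal), sep = "=", collapse = " "), "\n")
    cat("  types:  ",
        paste(names(table(mcols(object)$circ_type)),
              table(mcols(object)$circ_type), sep = "=", collapse = " "),
        "\n")
  }
})

#' @rdname backsplice-accessors
#' @export
setMethod("verifiedReads", "CircRNASet",
          function(x) mcols(x)$verified_reads)

#' @rdname backsplice-accessors
#' @export
setMethod("isoformTable", "CircRNASet", function(x) x@isoforms)

#' @rdname backsplice-accessors
#' @export
setMethod("simTruth", "CircSimulation", function(x) x@truth)

#' @rdname backsplice-accessors
#' @export
setMethod("simGenome", "CircSimulation", function(x) x@genome)

#' @rdname backsplice-accessors
#' @export
setMethod("simModels", "CircSimulation", function(x) x@models)

#' @rdname backsplice-accessors
#' @export
setMethod("simReads", "CircSimulation", function(x, mate = 1L) {
  if (mate == 1L) x@reads1 else x@reads2
})

#' @rdname backsplice-accessors
#' @export
setMethod("simAlignments", "CircSimulation", function(x) x@samLines)

setMethod("show", "CircSimulation", function(object) {
  cat("CircSimulation:", nrow(object@truth), "true circRNAs,",
      sum(object@truth$n_reads), "BSJ read pairs,",
      length(object@reads1), "R1 reads on",
      length(object@genome), "chromosome(s)\n")
})
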