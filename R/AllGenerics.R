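#' @name backsplice-accessors
#' @title Accessors for backsplice classes
#' @description Accessor generics for \linkS4class{GeneModels},
#'   \linkS4class{SplitReadSet}, \linkS4class{BackspliceSet},
#'   \linkS4class{CircRNASet} and \linkS4class{CircSimulation} objects.
#' @param x an object of the documented class.
#' @return the slot or derived value described per method.
NULL

#' @rdname backsplice-accessors
#' @export
setGeneric("modelExons", function(x) standardGeneric("modelExons"))

#' @rdname backsplice-accessors
#' @export
setGeneric("modelTranscripts",
           function(x) standardGeneric("modelTranscripts"))

#' @rdname backsplice-accessors
#' @export
setGeneric("alignmentSegments",
           function(x) standardGeneric("alignmentSegments"))

#' @rdname backsplice-accessors
#' @export
setGeneric("isPaired", function(x) standardGeneric("isPaired"))

#' @rdname backsplice-accessors
#' @export
setGeneric("junctionReads", function(x) standardGeneric("junctionReads"))

#' @rdname backsplice-accessors
#' @export
setGeneric("spliceSignal", function(x) standardGeneric("spliceSignal"))

#' @rdname backsplice-accessors
#' @export
setGeneric("circType", function(x) standardGeneric("circType"))

#' @rdname backsplice-accessors
#' @export
setGeneric("candidateId", function(x) standardGeneric("candidateId"))

#' @rdname backsplice-accessors
#' @export
setGeneric("verifiedReads", function(x) standardGeneric("verifiedReads"))

#' @rdname backsplice-accessors
#' @export
setGeneric("isoformTable", function(x) standardGeneric("isoformTable"))

#' @rdname backsplice-accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname backsplice-accessors
#' @export
setGeneric("simGenome", function(x) standardGeneric("simGenome"))

#' @rdname backsplice-accessors
#' @export
setGeneric("simModels", function(x) standardGeneric("simModels"))

#' @rdname backsplice-accessors
#' @export
setGeneric("simReads", function(x, mate = 1L) standardGeneric("simReads"))

#' @rdname backsplice-accessors
#' @export
setGeneric("simAlignments", function(x) standardGeneric("simAlignments"))
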