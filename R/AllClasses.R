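#' Gene models parsed from a GFF3 annotation
#'
#' Container for exon structures grouped by transcript and gene.  Exons are
#' stored as a \code{GRanges} with \code{transcript_id} and \code{gene_id}
#' metadata columns (1-based inclusive coordinates, sorted by start within
#' each transcript); per-transcript summaries live in the \code{transcripts}
#' slot.
#'
#' @slot exons \code{GRanges} of exons with mcols \code{transcript_id},
#'   \code{gene_id}.
#' @slot transcripts \code{data.frame} with columns \code{transcript_id},
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{start}, \code{end},
#'   \code{n_exons}, \code{flags}.
#' @export
setClass("GeneModels",
  representation(exons = "GRanges", transcripts = "data.frame"))

setValidity("GeneModels", function(object) {
  msg <- character(0)
  need <- c("transcript_id", "gene_id")
  if (!all(need %in% colnames(mcols(object@exons))))
    msg <- c(msg, "exons must carry transcript_id and gene_id mcols")
  needTx <- c("transcript_id", "gene_id", "chrom", "strand",
              "start", "end", "n_exons", "flags")
  if (!all(needTx %in% colnames(object@transcripts)))
    msg <- c(msg, "transcripts table is missing required columns")
  if (length(msg)) msg else TRUE
})

#' Collection of split-read alignments
#'
#' One row of the \code{segments} table is one aligned segment of one read
#' (a primary or supplementary SAM record, or one SA-tag entry rehydrated
#' into read coordinates).  Read intervals are in the original read
#' orientation; reference intervals are 1-based inclusive.
#'
#' @slot segments \code{data.frame} with columns \code{read_id},
#'   \code{mate} (1/2, or 0 for single-end), \code{read_start},
#'   \code{read_end}, \code{chrom}, \code{ref_start}, \code{ref_end},
#'   \code{strand}, \code{nm}, \code{score}, \code{read_length}.
#' @slot paired logical, whether the data are paired-end.
#' @slot nDropped integer, reads dropped at parse time (unmapped or
#'   secondary-only).
#' @export
setClass("SplitReadSet",
  representation(segments = "data.frame", paired = "logical",
                 nDropped = "integer"))

setValidity("SplitReadSet", function(object) {
  need <- c("read_id", "mate", "read_start", "read_end", "chrom",
            "ref_start", "ref_end", "strand", "nm", "score", "read_length")
  if (!all(need %in% colnames(object@segments)))
    return("segments table is missing required columns")
  TRUE
})

#' Back-splice junction candidates
#'
#' A \code{GRanges} subclass in which each range is one putative circRNA:
#' \code{start} is the acceptor coordinate (lower genomic boundary of the
#' circle) and \code{end} the donor coordinate, both 1-based inclusive.
#' Required metadata columns: \code{n_reads} (junction-read count),
#' \code{signal} (splice-signal class, one of GT-AG/GC-AG/AT-AC/none),
#' \code{offset_acceptor}/\code{offset_donor} (site-adjustment offsets,
#' each within +/-5), \code{circ_type} (exonic/intronic/intergenic),
#' \code{flags} (comma-separated), \code{read_ids} (CharacterList),
#' \code{pe_support} (junction reads whose mate is consistent with the
#' circle interval).
#'
#' @export
setClass("BackspliceSet", contains = "GRanges")

setValidity("BackspliceSet", function(object) {
  msg <- character(0)
  need <- c("n_reads", "signal", "offset_acceptor", "offset_donor",
            "circ_type", "flags", "read_ids", "pe_support")
  if (!all(need %in% colnames(mcols(object))))
    msg <- c(msg, paste("missing mcols:",
                        paste(setdiff(need, colnames(mcols(object))),
                              collapse = ", ")))
  if (length(object)) {
    if (any(start(object) >= end(object)))
      msg <- c(msg, "all candidates must satisfy start < end")
    if (length(msg) == 0 && any(mcols(object)$n_reads < 1L))
      msg <- c(msg, "junction-read sets must be non-empty")
    off <- c(mcols(object)$offset_acceptor, mcols(object)$offset_donor)
    if (length(msg) == 0 && any(abs(off) > 5L))
      msg <- c(msg, "site-adjustment offsets must lie in -5..+5")
  }
  if (length(msg)) msg else TRUE
})

#' Verified circRNAs with full-length isoforms
#'
#' Extends \code{\link{BackspliceSet}} with a \code{verified_reads} metadata
#' column (reads confirming the junction in the pseudo-reference screen) and
#' an isoform table.  One circRNA has at least one isoform; exonic isoforms
#' are spliced exon chains, intronic/intergenic isoforms are the genomic
#' span.
#'
#' @slot isoforms \code{DataFrame} with columns \code{circ_id},
#'   \code{isoform} (record id \code{"chrom:start|end(strand)#k"}),
#'   \code{transcript_id} (or \code{"genomic"}), \code{n_exons},
#'   \code{length}, \code{seq}.
#' @export
setClass("CircRNASet", contains = "BackspliceSet",
  representation(isoforms = "DataFrame"))

setValidity("CircRNASet", function(object) {
  if (!"verified_reads" %in% colnames(mcols(object)))
    return("missing mcol verified_reads")
  TRUE
})

setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

#' A simulated circRNA benchmark dataset
#'
#' Bundle produced by \code{\link{simulateBenchmark}}: synthetic genome and
#' annotation, the circRNA truth set, junction-spanning and background
#' reads, and truth-derived split alignments (SAM lines) so the detection
#' pipeline can run without an external aligner.
#'
#' @slot genome named \code{DNAStringSet}.
#' @slot models \code{\link{GeneModels}}.
#' @slot truth \code{data.frame}: \code{circ_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{transcript_id},
#'   \code{n_reads}, \code{spliced_length}.
#' @slot reads1,reads2 named \code{DNAStringSet} (\code{reads2} NULL for
#'   single-end simulations).
#' @slot samLines character vector, one SAM line per element (header
#'   included).
#' @slot params the simulation parameter list used.
#' @export
setClass("CircSimulation",
  representation(genome = "DNAStringSet", models = "GeneModels",
                 truth = "data.frame", reads1 = "DNAStringSet",
                 reads2 = "DNAStringSetOrNULL", samLines = "character",
                 params = "list"))
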