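#' Extract full-length circRNA sequences
#'
#' For an exonic circRNA, every transcript whose exon boundaries match the
#' back-splice site (within \code{tol} bp) contributes one isoform: the
#' concatenation of that transcript's exons lying within the circle
#' interval (only exon regions are extracted; intra-circRNA alternative
#' splicing is not modelled).  Transcripts sharing boundary exons but
#' differing in internal exons therefore yield distinct isoforms;
#' duplicate exon chains are collapsed.  Intronic and intergenic circRNAs
#' (and exonic ones whose matching transcript has no exon inside the
#' interval, flagged \code{genomic_fallback}) get the genomic span as a
#' single isoform.  Minus-strand sequences are reverse-complemented.
#'
#' @param genome named \code{DNAStringSet}.
#' @param models \linkS4class{GeneModels} or \code{NULL}.
#' @param circs a \linkS4class{CircRNASet} (or
#'   \linkS4class{BackspliceSet}).
#' @param tol boundary tolerance in bp (default 5).
#' @return a \linkS4class{CircRNASet} with the isoform table populated
#'   (input candidates are passed through unchanged).
#' @export
extractFullLength <- function(genome, models, circs, tol = 5L) {
  n <- length(circs)
  rows <- list()
  chrom <- as.character(seqnames(circs))
  st <- start(circs); en <- end(circs)
  strnd <- as.character(strand(circs))
  type <- mcols(circs)$circ_type
  flags <- mcols(circs)$flags
  ex <- if (is.null(models)) NULL else modelExons(models)
  for (k in seq_len(n)) {
    id <- .circId(chrom[k], st[k], en[k], strnd[k])
    chains <- list()
    if (!is.null(ex) && identical(type[k], "exonic")) {
      onTx <- as.character(seqnames(ex)) == chrom[k] &
        as.character(strand(ex)) == strnd[k]
      exSub <- ex[onTx]
      txA <- unique(mcols(exSub)$transcript_id[
        abs(start(exSub) - st[k]) <= tol])
      txB <- unique(mcols(exSub)$transcript_id[
        abs(end(exSub) - en[k]) <= tol])
      for (tx in intersect(txA, txB)) {
        exTx <- exSub[mcols(exSub)$transcript_id == tx]
        inside <- start(exTx) >= st[k] - tol & end(exTx) <= en[k] + tol
        exTx <- exTx[inside]
        if (!length(exTx)) next
        exTx <- exTx[order(start(exTx))]
        chainKey <- paste(start(exTx), end(exTx), sep = "-",
                          collapse = ",")
        if (!is.null(chains[[chainKey]])) next
        cs <- .chromString(genome, chrom[k])
        pieces <- .subseqs(cs, start(exTx), end(exTx))
        sq <- paste(pieces, collapse = "")
        if (strnd[k] == "-") sq <- revComp(sq)
        chains[[chainKey]] <- data.frame(
          circ_id = id, transcript_id = tx,
          n_exons = length(exTx), length = nchar(sq), seq = sq,
          stringsAsFactors = FALSE)
      }
      if (length(chains) == 0L)
        flags[k] <- paste0(flags[k],
                           ifelse(nzchar(flags[k]), ",", ""),
                           "genomic_fallback")
    }
    if (length(chains) == 0L) {
      sq <- getSubseq(genome, chrom[k], st[k], en[k])
      if (strnd[k] == "-") sq <- revComp(sq)
      chains[["genomic"]] <- data.frame(
        circ_id = id, transcript_id = "genomic",
        n_exons = 0L, length = nchar(sq), seq = sq,
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, unname(chains))
    tab$isoform <- paste0(id, "#", seq_len(nrow(tab)))
    rows[[k]] <- tab
  }
  iso <- if (length(rows)) do.call(rbind, rows) else NULL
  isoDF <- if (is.null(iso)) .emptyIsoforms() else
    DataFrame(circ_id = iso$circ_id, isoform = iso$isoform,
              transcript_id = iso$transcript_id, n_exons = iso$n_exons,
              length = iso$length, seq = iso$seq)
  gr <- granges(circs)
  mcols(gr) <- mcols(circs)
  mcols(gr)$flags <- flags
  if (!"verified_reads" %in% colnames(mcols(gr)))
    mcols(gr)$verified_reads <- mcols(gr)$n_reads
  .msg("sequence", "%d isoforms for %d circRNAs", nrow(isoDF), n)
  new("CircRNASet", gr, isoforms = isoDF)
}

#' Write circRNA isoform sequences to FASTA
#'
#' One record per isoform, id \code{"chrom:start|end(strand)#k"}.
#'
#' @param circs a \linkS4class{CircRNASet} with isoforms populated.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCircFasta <- function(circs, path) {
  iso <- isoformTable(circs)
  if (nrow(iso) == 0L) {
    con <- file(path, "wt"); close(con)
    return(invisible(path))
  }
  writeFasta(setNames(as.character(iso$seq), iso$isoform), path)
}

#' Write the isoform table to TSV
#'
#' @param circs a \linkS4class{CircRNASet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIsoformTable <- function(circs, path) {
  iso <- as.data.frame(isoformTable(circs))
  .writeTSV(iso[, c("circ_id", "isoform", "transcript_id", "n_exons",
                    "length")], path)
}
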