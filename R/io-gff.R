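#' Read gene models from a GFF3 annotation
#'
#' Parses gene/mRNA/exon features (via \code{rtracklayer}), groups exons
#' per transcript through their \code{Parent} attributes and sorts them by
#' start.  Exons whose Parent cannot be resolved to a transcript are
#' skipped with a warning that reports the count.  Transcripts with no exon
#' features (e.g. CDS-only gene entries) are retained with zero exons and
#' flagged \code{no_exons}.  Transcripts on chromosomes absent from
#' \code{knownChroms} (when given) are flagged \code{unplaced}.
#'
#' @param path path to a GFF3 file.
#' @param knownChroms optional character vector of placed chromosome names
#'   (e.g. \code{names(genome)}).
#' @return a \linkS4class{GeneModels} object.
#' @export
readGeneModels <- function(path, knownChroms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  .buildGeneModels(gr, knownChroms)
}

.firstParent <- function(p) {
  # rtracklayer gives Parent as a CharacterList
  vapply(as.list(p), function(v) if (length(v)) v[[1L]] else NA_character_,
         character(1))
}

.buildGeneModels <- function(gr, knownChroms = NULL) {
  type <- tolower(as.character(gr$type))
  isGene <- type == "gene"
  isTx <- type %in% c("mrna", "transcript")
  isExon <- type == "exon"

  ids <- as.character(gr$ID)
  parents <- if (!is.null(gr$Parent)) .firstParent(gr$Parent)
             else rep(NA_character_, length(gr))

  txIdx <- which(isTx)
  txId <- ids[txIdx]
  # transcripts missing an ID cannot anchor exons; synthesise one
  noId <- is.na(txId) | txId == ""
  txId[noId] <- paste0("tx", txIdx[noId])
  geneOfTx <- parents[txIdx]
  geneOfTx[is.na(geneOfTx)] <- txId[is.na(geneOfTx)]

  tx <- data.frame(
    transcript_id = txId,
    gene_id = geneOfTx,
    chrom = as.character(seqnames(gr))[txIdx],
    strand = as.character(strand(gr))[txIdx],
    start = start(gr)[txIdx],
    end = end(gr)[txIdx],
    n_exons = 0L,
    flags = "",
    stringsAsFactors = FALSE)

  exIdx <- which(isExon)
  exParent <- parents[exIdx]
  resolvable <- exParent %in% tx$transcript_id
  nSkipped <- sum(!resolvable)
  if (nSkipped > 0L)
    warning(nSkipped, " exon feature(s) with unresolvable Parent skipped",
            call. = FALSE)
  exIdx <- exIdx[resolvable]
  exParent <- exParent[resolvable]

  exons <- GRanges(
    seqnames = as.character(seqnames(gr))[exIdx],
    ranges = IRanges(start(gr)[exIdx], end(gr)[exIdx]),
    strand = as.character(strand(gr))[exIdx],
    transcript_id = exParent,
    gene_id = tx$gene_id[match(exParent, tx$transcript_id)])
  ord <- order(mcols(exons)$transcript_id, start(exons))
  exons <- exons[ord]

  cnt <- table(mcols(exons)$transcript_id)
  tx$n_exons <- as.integer(cnt[tx$transcript_id])
  tx$n_exons[is.na(tx$n_exons)] <- 0L
  tx$flags[tx$n_exons == 0L] <- "no_exons"
  if (!is.null(knownChroms)) {
    un <- !(tx$chrom %in% knownChroms)
    tx$flags[un] <- paste0(tx$flags[un],
                           ifelse(nzchar(tx$flags[un]), ",", ""), "unplaced")
  }
  new("GeneModels", exons = exons, transcripts = tx)
}

#' Write gene models to GFF3
#'
#' Deterministic writer (gene, mRNA, exon features; stable ordering) so
#' that identical models produce byte-identical files.
#'
#' @param models a \linkS4class{GeneModels} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGFF3 <- function(models, path) {
  tx <- modelTranscripts(models)
  ex <- modelExons(models)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(tx) == 0L) return(invisible(path))
  tx <- tx[order(tx$chrom, tx$start, tx$transcript_id), , drop = FALSE]
  genes <- tx[!duplicated(tx$gene_id), , drop = FALSE]
  lines <- character(0)
  exChrom <- as.character(seqnames(ex))
  exTx <- mcols(ex)$transcript_id
  for (g in seq_len(nrow(genes))) {
    gid <- genes$gene_id[g]
    sub <- tx[tx$gene_id == gid, , drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\tbacksplice\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      genes$chrom[g], min(sub$start), max(sub$end), genes$strand[g], gid))
    for (t in seq_len(nrow(sub))) {
      tid <- sub$transcript_id[t]
      lines <- c(lines, sprintf(
        "%s\tbacksplice\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        sub$chrom[t], sub$start[t], sub$end[t], sub$strand[t], tid, gid))
      ei <- which(exTx == tid)
      ei <- ei[order(start(ex)[ei])]
      for (k in seq_along(ei)) {
        i <- ei[k]
        lines <- c(lines, sprintf(
          "%s\tbacksplice\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          exChrom[i], start(ex)[i], end(ex)[i],
          as.character(strand(ex))[i], tid, k, tid))
      }
    }
  }
  writeLines(lines, con)
  invisible(path)
}
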