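#' Read a genome (or any DNA) FASTA file
#'
#' Multi-line records are concatenated and uppercased.  Duplicate record
#' names, empty files, files not starting with \code{>}, and records with
#' non-IUPAC characters are rejected with an error naming the offending
#' record.
#'
#' @param path path to a FASTA file.
#' @param rna if \code{TRUE}, U is normalised to T (for mature miRNA or
#'   transcript inputs given at the RNA level).
#' @return a named \code{DNAStringSet}, one element per record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ac", "gt"), fa)
#' as.character(readGenome(fa))
readGenome <- function(path, rna = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop("FASTA format error: empty file: ", path, call. = FALSE)
  if (!startsWith(first, ">"))
    stop("FASTA format error: file does not begin with '>': ", path,
         call. = FALSE)
  raw <- readBStringSet(path)
  if (length(raw) == 0L)
    stop("FASTA format error: no records in ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm))
    stop("FASTA format error: duplicate record name '",
         nm[duplicated(nm)][1L], "' in ", path, call. = FALSE)
  seqs <- toupper(as.character(raw))
  if (rna) seqs <- .normSeq(seqs)
  bad <- grepl("[^ACGTNRYSWKMBDHV]", seqs)
  if (any(bad))
    stop("FASTA format error: non-IUPAC characters in record '",
         nm[bad][1L], "'", call. = FALSE)
  out <- DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Write sequences to FASTA
#'
#' 60-column line wrapping; writing a genome read with
#' \code{\link{readGenome}} reproduces it record for record.
#'
#' @param seqs named \code{DNAStringSet} or named character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, filepath = path, width = 60L)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Qualities are not retained: downstream junction verification is
#' quality-agnostic (ungapped mismatch counting).
#'
#' @param path path to an uncompressed FASTQ file.
#' @return named \code{DNAStringSet} of reads.
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readDNAStringSet(path, format = "fastq")
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param seqs named \code{DNAStringSet} or named character vector.
#' @param path output path.
#' @param quality a single quality character used for every base
#'   (simulated reads carry no calibrated qualities).
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(seqs, path, quality = "I") {
  seqs <- as.character(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("read", seq_along(seqs))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(seqs)) {
    quals <- vapply(nchar(seqs), function(n)
      paste(rep(quality, n), collapse = ""), character(1))
    writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n", quals), con)
  }
  invisible(path)
}
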