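# shared internal helpers: coordinates are 1-based inclusive everywhere;
# BED-style 0-based half-open only at writer boundaries.

`%||%` <- function(a, b) if (is.null(a)) b else a

.isVerbose <- function() isTRUE(getOption("backsplice.verbose", TRUE))

.msg <- function(stage, fmt, ...) {
  if (.isVerbose())
    message(sprintf("INFO [%s] %s", stage, sprintf(fmt, ...)))
  invisible(NULL)
}

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around
#' \code{Biostrings::reverseComplement}.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements, same length as \code{x}.
#' @export
#' @examples
#' revComp(c("ACGT", "GGAT"))
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(reverseComplement(DNAStringSet(x)))
}

# vectorised substring extraction from one chromosome; out-of-range
# coordinates are clipped and the short result returned (callers that need
# strict behaviour check lengths themselves).
.subseqs <- function(chromStr, starts, ends) {
  n <- nchar(chromStr)
  s <- pmax(1L, as.integer(starts))
  e <- pmin(n, as.integer(ends))
  out <- character(length(s))
  ok <- s <= e
  out[ok] <- substring(chromStr, s[ok], e[ok])
  out
}

# genome accessor: genome is a named DNAStringSet
.chromString <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not present in the genome", call. = FALSE)
  as.character(genome[[chrom]])
}

#' Extract a genomic subsequence
#'
#' Returns \code{genome[[chrom]][start..end]} using 1-based inclusive
#' coordinates; the result has length \code{end - start + 1}.
#'
#' @param genome named \code{DNAStringSet} as returned by
#'   \code{\link{readGenome}}.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @return character scalar.
#' @export
getSubseq <- function(genome, chrom, start, end) {
  if (start < 1 || end < start)
    stop("invalid coordinates: start=", start, " end=", end, call. = FALSE)
  cs <- .chromString(genome, chrom)
  if (end > nchar(cs))
    stop("coordinates beyond chromosome '", chrom, "' length ",
         nchar(cs), call. = FALSE)
  substring(cs, start, end)
}

# TSV with a commented header line (the common output dialect of this package)
.writeTSV <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(colnames(df), collapse = "\t")), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.readTSV <- function(path) {
  hdr <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)[[1L]]
  df <- tryCatch(
    read.table(path, sep = "\t", comment.char = "#", header = FALSE,
               stringsAsFactors = FALSE, quote = ""),
    error = function(e) as.data.frame(setNames(rep(list(character(0)), length(cols)), cols)))
  if (ncol(df) == length(cols)) colnames(df) <- cols
  df
}

# candidate identity key used everywhere: "chrom:start|end(strand)"
.circId <- function(chrom, start, end, strand) {
  sprintf("%s:%d|%d(%s)", chrom, as.integer(start), as.integer(end), strand)
}

# normalise an RNA/DNA sequence to uppercase DNA alphabet (U -> T)
.normSeq <- function(x) gsub("U", "T", toupper(x), fixed = TRUE)
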