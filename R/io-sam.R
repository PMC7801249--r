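#' Parse a CIGAR string
#'
#' Operations are restricted to \code{M I D N S H = X}.  The read span is
#' the number of read bases the CIGAR accounts for
#' (\code{M,I,S,=,X}); the reference span covers \code{M,D,N,=,X}.  Hard
#' clips consume neither.
#'
#' @param cigar a single CIGAR string.
#' @return list with \code{ops} (data.frame of \code{len}, \code{op} in
#'   order), \code{read_span} and \code{ref_span}.
#' @export
#' @examples
#' parseCigar("50S50M")$read_span  # 100
parseCigar <- function(cigar) {
  if (length(cigar) != 1L || is.na(cigar) || cigar == "" || cigar == "*")
    stop("CIGAR parse error: empty or missing CIGAR", call. = FALSE)
  if (!grepl("^([0-9]+[MIDNSH=X])+$", cigar))
    stop("CIGAR parse error: unknown operation in '", cigar, "'",
         call. = FALSE)
  tok <- strsplit(gsub("([MIDNSH=X])", "\\1 ", cigar), " ", fixed = TRUE)[[1L]]
  op <- substr(tok, nchar(tok), nchar(tok))
  len <- as.integer(substr(tok, 1L, nchar(tok) - 1L))
  list(ops = data.frame(len = len, op = op, stringsAsFactors = FALSE),
       read_span = sum(len[op %in% c("M", "I", "S", "=", "X")]),
       ref_span = sum(len[op %in% c("M", "D", "N", "=", "X")]))
}

# vectorised CIGAR bookkeeping for the SAM reader.
# Returns lead/trail clips (stored-orientation), query bases aligned
# (M,I,=,X), reference span and total read length (hard clips rehydrated).
.cigarInfo <- function(cig) {
  bad <- !grepl("^([0-9]+[MIDNSH=X])+$", cig)
  if (any(bad))
    stop("CIGAR parse error: unknown operation in '", cig[bad][1L], "'",
         call. = FALSE)
  clipNum <- function(x, pat, grp) {
    out <- integer(length(x))
    has <- grepl(pat, x)
    out[has] <- as.integer(sub(pat, grp, x[has]))
    out
  }
  leadH <- clipNum(cig, "^(\\d+)H.*$", "\\1")
  rest <- sub("^\\d+H", "", cig)
  leadS <- clipNum(rest, "^(\\d+)S.*$", "\\1")
  trailH <- clipNum(cig, "^.*?(\\d+)H$", "\\1")
  rest2 <- sub("\\d+H$", "", cig)
  trailS <- clipNum(rest2, "^.*?(\\d+)S$", "\\1")
  toks <- strsplit(gsub("([MIDNSH=X])", "\\1 ", cig), " ", fixed = TRUE)
  idx <- rep(seq_along(toks), lengths(toks))
  tok <- unlist(toks, use.names = FALSE)
  op <- substr(tok, nchar(tok), nchar(tok))
  len <- as.integer(substr(tok, 1L, nchar(tok) - 1L))
  zero <- integer(length(cig))
  sumBy <- function(w) {
    if (!any(w)) return(zero)
    s <- rowsum(len[w], idx[w])
    out <- zero
    out[as.integer(rownames(s))] <- as.integer(s)
    out
  }
  qAligned <- sumBy(op %in% c("M", "I", "=", "X"))
  refSpan <- sumBy(op %in% c("M", "D", "N", "=", "X"))
  data.frame(leadClip = leadH + leadS, trailClip = trailH + trailS,
             qAligned = qAligned, refSpan = refSpan,
             readLength = leadH + leadS + qAligned + trailS + trailH)
}

# stored-orientation clips -> read interval in the original read orientation
.readInterval <- function(info, strandChar) {
  rs <- ifelse(strandChar == "+", info$leadClip + 1L, info$trailClip + 1L)
  data.frame(read_start = rs, read_end = rs + info$qAligned - 1L)
}

#' Load split-read alignments from a SAM file
#'
#' Reads a text SAM file and decomposes every mapped read end into ordered
#' alignment segments.  Supplementary alignments are accepted both as
#' separate records and through the standard \code{SA} tag; hard-clipped
#' records are rehydrated into read coordinates from the clip lengths, so
#' both encodings yield identical segments (duplicates are collapsed).
#' Unmapped records and secondary alignments (flag 0x100) are dropped.
#' Per-segment mismatch counts come from the \code{NM} tag and alignment
#' scores from the \code{AS} tag; when \code{AS} is absent the score falls
#' back to the aligned read length minus the mismatch count.
#'
#' @param path path to a SAM file with a header containing at least one
#'   \code{@SQ} line.
#' @return a \linkS4class{SplitReadSet}.
#' @export
readSplitAlignments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  isHdr <- startsWith(lines, "@")
  if (!any(startsWith(lines, "@SQ")))
    stop("SAM error: missing header sequence dictionary (@SQ lines) in ",
         path, call. = FALSE)
  recIdx <- which(!isHdr & nzchar(lines))
  if (length(recIdx) == 0L)
    return(new("SplitReadSet",
               segments = .emptySegments(), paired = FALSE, nDropped = 0L))
  fields <- strsplit(lines[recIdx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("SAM error: truncated record at line ", recIdx[nf < 11L][1L],
         call. = FALSE)
  f <- function(i) vapply(fields, `[[`, character(1), i)
  qname <- f(1L); flag <- as.integer(f(2L)); rname <- f(3L)
  pos <- as.integer(f(4L)); cigar <- f(6L)
  tagstr <- vapply(fields, function(v)
    paste(v[-seq_len(11L)], collapse = "\t"), character(1))

  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  keep <- !unmapped & !secondary & cigar != "*"
  nDropped <- sum(unmapped)
  pairedFlag <- bitwAnd(flag, 1L) > 0L
  paired <- any(pairedFlag)
  if (!any(keep))
    return(new("SplitReadSet", segments = .emptySegments(),
               paired = paired, nDropped = nDropped))

  tagInt <- function(tags, key) {
    pat <- paste0(".*", key, ":i:(-?\\d+).*")
    has <- grepl(paste0(key, ":i:"), tags, fixed = TRUE)
    out <- rep(NA_integer_, length(tags))
    out[has] <- as.integer(sub(pat, "\\1", tags[has]))
    out
  }
  qn <- qname[keep]; fl <- flag[keep]; rn <- rname[keep]
  ps <- pos[keep]; cg <- cigar[keep]; tg <- tagstr[keep]
  nm <- tagInt(tg, "NM"); as_ <- tagInt(tg, "AS")
  mate <- ifelse(bitwAnd(fl, 1L) == 0L, 0L,
                 ifelse(bitwAnd(fl, 64L) > 0L, 1L, 2L))
  strand <- ifelse(bitwAnd(fl, 16L) > 0L, "-", "+")
  info <- .cigarInfo(cg)
  ri <- .readInterval(info, strand)
  seg <- data.frame(
    read_id = qn, mate = mate,
    read_start = ri$read_start, read_end = ri$read_end,
    chrom = rn, ref_start = ps, ref_end = ps + info$refSpan - 1L,
    strand = strand,
    nm = ifelse(is.na(nm), 0L, nm),
    score = ifelse(is.na(as_), info$qAligned - ifelse(is.na(nm), 0L, nm),
                   as_),
    read_length = info$readLength,
    stringsAsFactors = FALSE)

  # rehydrate SA-tag entries (for inputs whose supplementary alignments are
  # encoded only in the tag)
  hasSA <- grepl("SA:Z:", tg, fixed = TRUE)
  if (any(hasSA)) {
    sa <- sub("^.*SA:Z:([^\t]+).*$", "\\1", tg[hasSA])
    ent <- strsplit(sa, ";", fixed = TRUE)
    n <- lengths(ent)
    src <- rep(which(hasSA), n)
    parts <- strsplit(unlist(ent, use.names = FALSE), ",", fixed = TRUE)
    ok <- lengths(parts) == 6L
    parts <- parts[ok]; src <- src[ok]
    if (length(parts)) {
      g <- function(i) vapply(parts, `[[`, character(1), i)
      saCig <- g(4L); saStrand <- g(3L)
      saInfo <- .cigarInfo(saCig)
      saRi <- .readInterval(saInfo, saStrand)
      saNm <- suppressWarnings(as.integer(g(6L)))
      saNm[is.na(saNm)] <- 0L
      saSeg <- data.frame(
        read_id = qn[src], mate = mate[src],
        read_start = saRi$read_start, read_end = saRi$read_end,
        chrom = g(1L), ref_start = as.integer(g(2L)),
        ref_end = as.integer(g(2L)) + saInfo$refSpan - 1L,
        strand = saStrand, nm = saNm,
        score = saInfo$qAligned - saNm,
        read_length = saInfo$readLength,
        stringsAsFactors = FALSE)
      seg <- rbind(seg, saSeg)
    }
  }

  key <- paste(seg$read_id, seg$mate, seg$read_start, seg$read_end,
               seg$chrom, seg$ref_start, seg$ref_end, seg$strand,
               sep = "\r")
  seg <- seg[!duplicated(key), , drop = FALSE]
  seg <- seg[order(seg$read_id, seg$mate, seg$read_start,
                   seg$ref_start), , drop = FALSE]
  rownames(seg) <- NULL
  .msg("load_split_reads", "%d segments from %d read ends (%d paired)",
       nrow(seg), length(unique(paste(seg$read_id, seg$mate))),
       sum(pairedFlag[keep] & !duplicated(paste(qn, mate))))
  new("SplitReadSet", segments = seg, paired = paired,
      nDropped = nDropped)
}

.emptySegments <- function() {
  data.frame(read_id = character(0), mate = integer(0),
             read_start = integer(0), read_end = integer(0),
             chrom = character(0), ref_start = integer(0),
             ref_end = integer(0), strand = character(0),
             nm = integer(0), score = numeric(0),
             read_length = integer(0), stringsAsFactors = FALSE)
}
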