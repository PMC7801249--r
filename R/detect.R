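#' Detection parameters
#'
#' Screening thresholds for back-splice junction calling.  The length
#' thresholds reflect the size distribution of plant circRNAs: candidates
#' above \code{defaultLength} (20 kb) are kept but flagged \code{long},
#' candidates above \code{maxLength} (100 kb) are removed.  Both are
#' applied to the genomic span (the quantity known before annotation); the
#' spliced length is recorded separately on the isoform table.  Strict
#' per-segment criteria (at most \code{maxMismatch} mismatches, alignment
#' score at least \code{minScoreFrac} of the aligned segment length) guard
#' against false positives from repetitive sequence and mapping errors in
#' high-copy-number plant genomes.
#'
#' @param defaultLength genomic span (bp) above which a candidate is
#'   flagged \code{long} (default 20000).
#' @param maxLength maximum genomic span (bp, default 100000).
#' @param maxShift maximum back-splice site adjustment (bp, default 5).
#' @param minJunctionReads minimum junction-read support (default 2).
#' @param maxMismatch maximum mismatches per alignment segment (default 2).
#' @param minScoreFrac minimum alignment score as a fraction of the
#'   aligned segment length (default 0.8).
#' @param requirePaired require paired-end consistency for at least one
#'   supporting read; \code{NA} (default) enables it automatically when
#'   the data are paired-end.
#' @param maxSegmentOverlap tolerated read-coordinate overlap (bp) between
#'   the two segments of a split read (default 5; mappers often re-align a
#'   few bases on both sides).  Larger overlaps mark the read ambiguous.
#' @param matePad slack (bp) around the circle interval when testing mate
#'   placement (default 5).
#' @param annotationTol tolerance (bp) for matching candidate boundaries
#'   to annotated exon boundaries (default 5).
#' @return a named list of class \code{backsplice_params}.
#' @export
detectionParams <- function(defaultLength = 20000L, maxLength = 100000L,
                            maxShift = 5L, minJunctionReads = 2L,
                            maxMismatch = 2L, minScoreFrac = 0.8,
                            requirePaired = NA, maxSegmentOverlap = 5L,
                            matePad = 5L, annotationTol = 5L) {
  stopifnot(defaultLength > 0, defaultLength <= maxLength,
            minJunctionReads >= 1, maxShift >= 0, minScoreFrac >= 0)
  structure(list(defaultLength = as.integer(defaultLength),
                 maxLength = as.integer(maxLength),
                 maxShift = as.integer(maxShift),
                 minJunctionReads = as.integer(minJunctionReads),
                 maxMismatch = as.integer(maxMismatch),
                 minScoreFrac = minScoreFrac,
                 requirePaired = requirePaired,
                 maxSegmentOverlap = as.integer(maxSegmentOverlap),
                 matePad = as.integer(matePad),
                 annotationTol = as.integer(annotationTol)),
            class = "backsplice_params")
}

# per-read chiastic geometry over a segment table (vectorised).
# Returns one row per qualifying read end: read_id, mate, chrom, start,
# end, strand.
.chiasticFromSegments <- function(seg, param) {
  if (!nrow(seg)) {
    return(data.frame(read_id = character(0), mate = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  segLen <- seg$read_end - seg$read_start + 1L
  ok <- seg$nm <= param$maxMismatch &
    seg$score >= param$minScoreFrac * segLen
  seg <- seg[ok, , drop = FALSE]
  key <- paste(seg$read_id, seg$mate, sep = "\r")
  cnt <- table(key)
  two <- names(cnt)[cnt == 2L]
  seg <- seg[key %in% two, , drop = FALSE]
  if (!nrow(seg)) {
    return(data.frame(read_id = character(0), mate = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  o <- order(paste(seg$read_id, seg$mate, sep = "\r"), seg$read_start)
  seg <- seg[o, , drop = FALSE]
  i <- seq(1L, nrow(seg), by = 2L)  # earlier-in-read segment
  j <- i + 1L                       # later-in-read segment
  overlap <- seg$read_end[i] - seg$read_start[j] + 1L
  sameChrom <- seg$chrom[i] == seg$chrom[j]
  sameStrand <- seg$strand[i] == seg$strand[j]
  okPair <- (overlap <= param$maxSegmentOverlap) & sameChrom & sameStrand
  plus <- seg$strand[i] == "+"
  chi <- ifelse(plus,
                seg$ref_start[i] > seg$ref_end[j],  # earlier maps downstream
                seg$ref_end[i] < seg$ref_start[j])  # mirrored on minus
  s <- ifelse(plus, seg$ref_start[j], seg$ref_start[i])
  e <- ifelse(plus, seg$ref_end[i], seg$ref_end[j])
  sel <- okPair & chi & s < e
  data.frame(read_id = seg$read_id[i][sel], mate = seg$mate[i][sel],
             chrom = seg$chrom[i][sel],
             start = as.integer(s[sel]), end = as.integer(e[sel]),
             strand = seg$strand[i][sel], stringsAsFactors = FALSE)
}

#' Chiastic junction test for one split read
#'
#' A back-splice joins a downstream donor to an upstream acceptor, so a
#' junction-spanning read aligns in two chiastic segments: the part earlier
#' in the read maps strictly downstream (on the plus strand; mirrored on
#' the minus strand) of the later part, on the same chromosome and strand.
#' Colinear splits (ordinary splice junctions), cross-chromosome and
#' cross-strand splits yield no candidate.
#'
#' @param splitRead a \linkS4class{SplitReadSet} or segment
#'   \code{data.frame} holding the segments of a single read end.
#' @param param a \code{\link{detectionParams}} list.
#' @return a one-row data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{strand}) or \code{NULL} when the read is not chiastic.
#' @export
chiasticCandidate <- function(splitRead, param = detectionParams()) {
  seg <- if (is(splitRead, "SplitReadSet")) alignmentSegments(splitRead)
         else splitRead
  if (length(unique(paste(seg$read_id, seg$mate))) > 1L)
    stop("chiasticCandidate expects the segments of a single read end",
         call. = FALSE)
  out <- .chiasticFromSegments(seg, param)
  if (nrow(out) == 0L) NULL else out[, c("chrom", "start", "end", "strand")]
}

# complement-and-reverse of a dinucleotide vector (fast path)
.revcomp2 <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  paste0(substr(comp, 2L, 2L), substr(comp, 1L, 1L))
}

.SIGNALS <- c(GTAG = "GT-AG", GCAG = "GC-AG", ATAC = "AT-AC")

#' Classify the splice signal of back-splice sites
#'
#' On the plus strand the donor-side dinucleotide is
#' \code{genome[end+1..end+2]} and the acceptor-side dinucleotide is
#' \code{genome[start-2..start-1]}; the pair (donor, acceptor) is
#' classified as GT-AG or GC-AG (U2 major spliceosome) or AT-AC (U12 minor
#' spliceosome), otherwise \code{none}.  On the minus strand the same test
#' is applied to the reverse complement with donor/acceptor roles
#' mirrored.  Junctions at a chromosome edge get signal \code{none}.
#'
#' @param genome named \code{DNAStringSet}.
#' @param chrom,start,end,strand candidate coordinates (vectorised;
#'   1-based inclusive, \code{start < end}).
#' @return character vector of signal classes.
#' @export
checkSpliceSignal <- function(genome, chrom, start, end, strand) {
  n <- length(chrom)
  out <- rep("none", n)
  if (n == 0L) return(out)
  start <- as.integer(start); end <- as.integer(end)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (!ch %in% names(genome)) next
    cs <- .chromString(genome, ch)
    len <- nchar(cs)
    s <- start[idx]; e <- end[idx]
    inRange <- s - 2L >= 1L & e + 2L <= len
    up <- ifelse(inRange, substring(cs, s - 2L, s - 1L), "NN")
    dn <- ifelse(inRange, substring(cs, e + 1L, e + 2L), "NN")
    plus <- strand[idx] == "+"
    donor <- ifelse(plus, dn, .revcomp2(up))
    acceptor <- ifelse(plus, up, .revcomp2(dn))
    cls <- .SIGNALS[paste0(donor, acceptor)]
    out[idx] <- ifelse(is.na(cls), "none", cls)
  }
  out
}

#' Adjust a back-splice site towards a canonical splice signal
#'
#' Alternative donor/acceptor usage near canonical sites is common, so a
#' candidate without a canonical signal is searched over acceptor/donor
#' offset pairs within \code{maxShift} (default +/-5 bp) in increasing
#' total shift; ties on total shift are broken by signal priority
#' (GT-AG > GC-AG > AT-AC), then by the smaller donor offset.  If no
#' offset pair yields a canonical signal the site is returned unchanged
#' with class \code{none}.
#'
#' @param genome named \code{DNAStringSet}.
#' @param chrom,start,end,strand one candidate site.
#' @param maxShift maximum absolute offset per boundary (default 5).
#' @return list with \code{start}, \code{end}, \code{offset_acceptor},
#'   \code{offset_donor}, \code{signal}.
#' @export
adjustBackspliceSite <- function(genome, chrom, start, end, strand,
                                 maxShift = 5L) {
  grid <- expand.grid(ds = -maxShift:maxShift, de = -maxShift:maxShift)
  ns <- start + grid$ds
  ne <- end + grid$de
  valid <- ns < ne & ns > 2L
  cls <- rep("none", nrow(grid))
  cls[valid] <- checkSpliceSignal(genome, rep(chrom, sum(valid)),
                                  ns[valid], ne[valid],
                                  rep(strand, sum(valid)))
  hit <- which(cls != "none")
  if (!length(hit)) {
    return(list(start = start, end = end, offset_acceptor = 0L,
                offset_donor = 0L, signal = "none"))
  }
  # acceptor offset is the shift of the acceptor coordinate (start on the
  # plus strand, end on the minus strand); donor likewise
  da <- if (strand == "+") grid$ds[hit] else grid$de[hit]
  dd <- if (strand == "+") grid$de[hit] else grid$ds[hit]
  prio <- match(cls[hit], c("GT-AG", "GC-AG", "AT-AC"))
  best <- hit[order(abs(da) + abs(dd), prio, abs(dd), dd, da)][1L]
  list(start = as.integer(start + grid$ds[best]),
       end = as.integer(end + grid$de[best]),
       offset_acceptor = as.integer(
         if (strand == "+") grid$ds[best] else grid$de[best]),
       offset_donor = as.integer(
         if (strand == "+") grid$de[best] else grid$ds[best]),
       signal = cls[best])
}

#' Test paired-end consistency of a junction read
#'
#' For a back-splice read from a circRNA the mate is drawn from the
#' circle, so it must align within the (padded) circle interval on the
#' same chromosome, on the strand opposite the junction read (FR
#' library).  Single-end data are vacuously consistent.
#'
#' @param chrom,start,end candidate circle interval.
#' @param readStrand alignment strand of the junction read.
#' @param mateSegments segment \code{data.frame} of the mate (zero rows
#'   when the mate is unmapped).
#' @param pad interval padding in bp (default 5).
#' @param singleEnd set \code{TRUE} for single-end data.
#' @return logical scalar.
#' @export
pairedEndConsistent <- function(chrom, start, end, readStrand,
                                mateSegments, pad = 5L,
                                singleEnd = FALSE) {
  if (singleEnd) return(TRUE)
  if (is.null(mateSegments) || nrow(mateSegments) == 0L) return(FALSE)
  all(mateSegments$chrom == chrom &
        mateSegments$ref_start >= start - pad &
        mateSegments$ref_end <= end + pad &
        mateSegments$strand != readStrand)
}

#' Classify circRNA type against gene models
#'
#' A candidate is \code{exonic} when one transcript (on the candidate
#' strand) has an exon starting at the candidate start and an exon ending
#' at the candidate end, both within the tolerance; \code{intronic} when
#' the interval lies wholly inside one intron of some transcript; and
#' \code{intergenic} otherwise.  Without an annotation every candidate is
#' \code{intergenic}.
#'
#' @param models a \linkS4class{GeneModels} object or \code{NULL}.
#' @param chrom,start,end,strand candidate coordinates (vectorised).
#' @param tol boundary-matching tolerance in bp (default 5).
#' @return character vector of types.
#' @export
classifyCircType <- function(models, chrom, start, end, strand, tol = 5L) {
  n <- length(chrom)
  out <- rep("intergenic", n)
  if (n == 0L || is.null(models)) return(out)
  ex <- modelExons(models)
  exChrom <- as.character(seqnames(ex))
  exStrand <- as.character(strand(ex))
  exTx <- mcols(ex)$transcript_id
  exS <- start(ex); exE <- end(ex)
  introns <- .modelIntrons(models)
  candGR <- GRanges(chrom, IRanges(start, end))
  inIntron <- rep(FALSE, n)
  if (length(introns)) {
    hits <- findOverlaps(candGR, introns, type = "within")
    inIntron[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  for (k in seq_len(n)) {
    onChr <- exChrom == chrom[k] & exStrand == strand[k]
    txA <- exTx[onChr & abs(exS - start[k]) <= tol]
    txB <- exTx[onChr & abs(exE - end[k]) <= tol]
    if (length(intersect(txA, txB))) {
      out[k] <- "exonic"
    } else if (inIntron[k]) {
      out[k] <- "intronic"
    }
  }
  out
}

# introns of all transcripts as a GRanges
.modelIntrons <- function(models) {
  ex <- modelExons(models)
  if (!length(ex)) return(GRanges())
  tx <- mcols(ex)$transcript_id
  o <- order(tx, start(ex))
  s <- start(ex)[o]; e <- end(ex)[o]; t <- tx[o]
  chr <- as.character(seqnames(ex))[o]
  i <- which(t[-1] == t[-length(t)])
  if (!length(i)) return(GRanges())
  is_ <- e[i] + 1L; ie <- s[i + 1L] - 1L
  keep <- is_ <= ie
  GRanges(chr[i][keep], IRanges(is_[keep], ie[keep]))
}

.emptyBackspliceSet <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(n_reads = integer(0), signal = character(0),
                         offset_acceptor = integer(0),
                         offset_donor = integer(0),
                         circ_type = character(0), flags = character(0),
                         read_ids = CharacterList(),
                         pe_support = integer(0))
  new("BackspliceSet", gr)
}

#' Call back-splice junction candidates from split reads
#'
#' Runs the full candidate-calling path: per-read chiastic geometry with
#' strict segment screening, splice-signal classification with back-splice
#' site adjustment (within +/- \code{maxShift} bp), strand resolution by
#' signal (libraries are effectively unstranded at the cDNA level, so a
#' candidate whose alignment strand shows no signal while the opposite
#' strand does is flipped and flagged), pooling of reads by adjusted site,
#' paired-end consistency, length screening, and annotation typing.
#' Splice signal and annotation are used as complementary evidence: a
#' candidate is retained when it has a canonical signal or when its
#' boundaries match annotated exon boundaries of one transcript.
#'
#' @param splitReads a \linkS4class{SplitReadSet}.
#' @param genome named \code{DNAStringSet}; when \code{NULL}, signal
#'   classification and site adjustment are skipped.
#' @param models a \linkS4class{GeneModels} annotation or \code{NULL}.
#' @param param a \code{\link{detectionParams}} list.
#' @return a \linkS4class{BackspliceSet}, sorted by position.
#' @export
callBackspliceJunctions <- function(splitReads, genome = NULL,
                                    models = NULL,
                                    param = detectionParams()) {
  seg <- alignmentSegments(splitReads)
  cand <- .chiasticFromSegments(seg, param)
  .msg("detect", "%d chiastic read ends from %d read ends",
       nrow(cand), length(splitReads))
  if (nrow(cand) == 0L) return(.emptyBackspliceSet())

  # resolve each distinct raw site once, then pool reads by adjusted site
  rawKey <- paste(cand$chrom, cand$start, cand$end, cand$strand,
                  sep = "\r")
  uk <- !duplicated(rawKey)
  sites <- cand[uk, c("chrom", "start", "end", "strand")]
  sites$signal <- "none"
  sites$offset_acceptor <- 0L
  sites$offset_donor <- 0L
  sites$flag <- ""
  if (!is.null(genome)) {
    sites$signal <- checkSpliceSignal(genome, sites$chrom, sites$start,
                                      sites$end, sites$strand)
    todo <- which(sites$signal == "none")
    if (length(todo) && !is.null(models)) {
      # annotation anchoring: a signal-less site whose boundaries match
      # exon boundaries of one transcript is accepted as-is (signal and
      # annotation are complementary evidence); adjustment is reserved
      # for sites supported by neither
      type0 <- classifyCircType(models, sites$chrom[todo],
                                sites$start[todo], sites$end[todo],
                                sites$strand[todo], param$annotationTol)
      anchored <- todo[type0 == "exonic"]
      sites$flag[anchored] <- "annotation_anchored"
      todo <- todo[type0 != "exonic"]
    }
    if (length(todo)) {
      flipStrand <- ifelse(sites$strand[todo] == "+", "-", "+")
      flip0 <- checkSpliceSignal(genome, sites$chrom[todo],
                                 sites$start[todo], sites$end[todo],
                                 flipStrand)
      for (ii in seq_along(todo)) {
        k <- todo[ii]
        if (flip0[ii] != "none") {
          # exact signal on the opposite strand beats an adjusted one on
          # the alignment strand (cDNA second-strand reads)
          sites$strand[k] <- flipStrand[ii]
          sites$signal[k] <- flip0[ii]
          sites$flag[k] <- "strand_flipped"
          next
        }
        adj <- adjustBackspliceSite(genome, sites$chrom[k],
                                    sites$start[k], sites$end[k],
                                    sites$strand[k], param$maxShift)
        if (adj$signal != "none") {
          sites$start[k] <- adj$start; sites$end[k] <- adj$end
          sites$offset_acceptor[k] <- adj$offset_acceptor
          sites$offset_donor[k] <- adj$offset_donor
          sites$signal[k] <- adj$signal
          sites$flag[k] <- "site_adjusted"
          next
        }
        adjF <- adjustBackspliceSite(genome, sites$chrom[k],
                                     sites$start[k], sites$end[k],
                                     flipStrand[ii], param$maxShift)
        if (adjF$signal != "none") {
          sites$strand[k] <- flipStrand[ii]
          sites$start[k] <- adjF$start; sites$end[k] <- adjF$end
          sites$offset_acceptor[k] <- adjF$offset_acceptor
          sites$offset_donor[k] <- adjF$offset_donor
          sites$signal[k] <- adjF$signal
          sites$flag[k] <- "strand_flipped,site_adjusted"
        }
      }
    }
  }

  m <- match(rawKey, rawKey[uk])
  cand$start <- sites$start[m]; cand$end <- sites$end[m]
  cand$strand <- sites$strand[m]
  cand$signal <- sites$signal[m]
  cand$offset_acceptor <- sites$offset_acceptor[m]
  cand$offset_donor <- sites$offset_donor[m]
  cand$flag <- sites$flag[m]

  adjKey <- paste(cand$chrom, cand$start, cand$end, cand$strand,
                  sep = "\r")
  grp <- split(seq_len(nrow(cand)), adjKey)
  first <- vapply(grp, `[[`, integer(1), 1L)
  agg <- cand[first, , drop = FALSE]
  agg$n_reads <- lengths(grp)
  readsOf <- lapply(grp, function(i)
    unique(paste0(cand$read_id[i], "/", cand$mate[i])))
  agg$flag <- vapply(grp, function(i) {
    f <- unique(cand$flag[i]); f <- f[nzchar(f)]
    paste(sort(unique(unlist(strsplit(f, ",")))), collapse = ",")
  }, character(1))

  # paired-end consistency: at least one supporting read whose mate lies
  # inside the padded circle interval
  singleEnd <- !isPaired(splitReads)
  requirePE <- if (is.na(param$requirePaired)) !singleEnd
               else param$requirePaired && !singleEnd
  segKey <- paste(seg$read_id, seg$mate, sep = "\r")
  segByRead <- split(seq_len(nrow(seg)), segKey)
  agg$pe_support <- vapply(seq_len(nrow(agg)), function(k) {
    i <- grp[[k]]
    if (singleEnd) return(length(i))
    ok <- vapply(i, function(r) {
      mateKey <- paste(cand$read_id[r], 3L - cand$mate[r], sep = "\r")
      rows <- segByRead[[mateKey]]
      pairedEndConsistent(agg$chrom[k], agg$start[k], agg$end[k],
                          cand$strand[r],
                          if (is.null(rows)) NULL
                          else seg[rows, , drop = FALSE],
                          pad = param$matePad)
    }, logical(1))
    sum(ok)
  }, integer(1))

  agg$circ_type <- classifyCircType(models, agg$chrom, agg$start, agg$end,
                                    agg$strand, param$annotationTol)
  if (is.null(models))
    agg$flag <- paste0(agg$flag,
                       ifelse(nzchar(agg$flag), ",", ""), "no_annotation")

  span <- agg$end - agg$start + 1L
  keep <- span <= param$maxLength & agg$n_reads >= param$minJunctionReads
  if (requirePE) keep <- keep & agg$pe_support >= 1L
  if (!is.null(genome)) {
    evid <- agg$signal != "none"
    if (!is.null(models)) evid <- evid | agg$circ_type == "exonic"
    keep <- keep & evid
  }
  long <- span > param$defaultLength
  agg$flag[long] <- paste0(agg$flag[long],
                           ifelse(nzchar(agg$flag[long]), ",", ""), "long")
  .msg("detect", "%d candidate sites -> %d retained after filters",
       nrow(agg), sum(keep))
  sel <- which(keep)
  sel <- sel[order(agg$chrom[sel], agg$start[sel], agg$end[sel])]
  agg <- agg[sel, , drop = FALSE]

  gr <- GRanges(agg$chrom, IRanges(agg$start, agg$end),
                strand = agg$strand)
  mcols(gr) <- DataFrame(
    n_reads = agg$n_reads,
    signal = agg$signal,
    offset_acceptor = agg$offset_acceptor,
    offset_donor = agg$offset_donor,
    circ_type = agg$circ_type,
    flags = agg$flag,
    read_ids = CharacterList(readsOf[sel]),
    pe_support = agg$pe_support)
  new("BackspliceSet", gr)
}

#' Write back-splice candidates to TSV or BED
#'
#' The TSV uses 1-based inclusive coordinates with a commented header
#' line; BED6 output converts to 0-based half-open coordinates at this
#' writer boundary only (score column = junction reads).
#'
#' @param x a \linkS4class{BackspliceSet} (or \linkS4class{CircRNASet}).
#' @param path output path.
#' @param format \code{"tsv"} or \code{"bed"}.
#' @return \code{path}, invisibly.
#' @export
writeBacksplices <- function(x, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  chrom <- as.character(seqnames(x))
  df <- data.frame(chrom = chrom, start = start(x), end = end(x),
                   strand = as.character(strand(x)),
                   junction_reads = mcols(x)$n_reads,
                   signal = mcols(x)$signal,
                   circ_type = mcols(x)$circ_type,
                   flags = mcols(x)$flags,
                   stringsAsFactors = FALSE)
  if ("verified_reads" %in% colnames(mcols(x)))
    df$verified_reads <- mcols(x)$verified_reads
  if (format == "tsv") return(.writeTSV(df, path))
  bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = .circId(df$chrom, df$start, df$end, df$strand),
                    score = df$junction_reads, strand = df$strand)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(bed))
    write.table(bed, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}
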