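#' Build the pseudo-reference of back-splice junction flanks
#'
#' For every candidate, the junction sequence is the donor-side flank
#' (last \code{f} bases of the circle) followed by the acceptor-side flank
#' (first \code{f} bases), where \code{f = min(flank, circle span)} (no
#' wrap-around).  Minus-strand entries are reverse-complemented.  The seam
#' sits between positions \code{f} and \code{f+1}.
#'
#' @param genome named \code{DNAStringSet}.
#' @param candidates a \linkS4class{BackspliceSet} (or data.frame with
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}).
#' @param flank flank length in bp; the read length is the natural choice
#'   (a junction-spanning read cannot need more).
#' @return data.frame with columns \code{id}, \code{seq}, \code{seam},
#'   \code{flank}, \code{flagged}.
#' @export
buildPseudoRef <- function(genome, candidates, flank = 100L) {
  df <- .candFrame(candidates)
  n <- nrow(df)
  out <- data.frame(id = character(n), seq = character(n),
                    seam = integer(n), flank = integer(n),
                    flagged = logical(n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  out$id <- .circId(df$chrom, df$start, df$end, df$strand)
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    cs <- .chromString(genome, ch)
    s <- df$start[idx]; e <- df$end[idx]
    f <- pmin(as.integer(flank), e - s + 1L)
    donorSide <- .subseqs(cs, e - f + 1L, e)
    acceptorSide <- .subseqs(cs, s, s + f - 1L)
    truncated <- nchar(donorSide) < f | nchar(acceptorSide) < f
    seqs <- paste0(donorSide, acceptorSide)
    minus <- df$strand[idx] == "-"
    seqs[minus] <- revComp(seqs[minus])
    out$seq[idx] <- seqs
    out$seam[idx] <- nchar(donorSide)
    out$flank[idx] <- f
    out$flagged[idx] <- truncated
  }
  out
}

#' Write a pseudo-reference to FASTA
#'
#' @param entries data.frame from \code{\link{buildPseudoRef}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePseudoRef <- function(entries, path) {
  writeFasta(setNames(entries$seq, entries$id), path)
}

#' Verify junction candidates by re-screening raw reads
#'
#' Plays the role of the second alignment: raw reads are matched against
#' the pseudo-reference with an internal seed-and-extend, ungapped
#' matcher.  A read verifies an entry iff (in either orientation) it
#' aligns to the junction sequence spanning the seam with at least
#' \code{minAnchor} bases on each side and at most \code{maxMismatch}
#' mismatches inside the seam-centered \code{2*minAnchor} window.
#' Anchoring uses exact \code{seedLen}-mer seeding restricted to the
#' seam-spanning region of each entry.  Each read counts at most once per
#' entry.
#'
#' @param reads named \code{DNAStringSet} (or character vector of FASTQ
#'   paths).
#' @param entries pseudo-reference data.frame from
#'   \code{\link{buildPseudoRef}}.
#' @param minAnchor minimum bases on each side of the seam (default 10).
#' @param maxMismatch maximum mismatches in the seam window (default 2).
#' @param seedLen exact seed length (default 20).
#' @return list with \code{results} (per read-entry match: \code{id},
#'   \code{read_id}, \code{orientation}, \code{left_anchor},
#'   \code{right_anchor}, \code{mismatches}) and \code{counts}
#'   (per entry: \code{id}, \code{verified_reads}).
#' @export
verifyJunctions <- function(reads, entries, minAnchor = 10L,
                            maxMismatch = 2L, seedLen = 20L) {
  if (is.character(reads)) {
    reads <- do.call(c, lapply(reads, readFastq))
  }
  readSeq <- as.character(reads)
  readId <- names(reads) %||% paste0("read", seq_along(readSeq))
  results <- data.frame(id = character(0), read_id = character(0),
                        orientation = character(0),
                        left_anchor = integer(0),
                        right_anchor = integer(0),
                        mismatches = integer(0), stringsAsFactors = FALSE)
  counts <- data.frame(id = entries$id,
                       verified_reads = integer(nrow(entries)),
                       stringsAsFactors = FALSE)
  if (nrow(entries) == 0L || length(readSeq) == 0L)
    return(list(results = results, counts = counts))

  # seam-spanning seed k-mers of every entry
  seedTab <- .seamSeeds(entries, seedLen)
  if (nrow(seedTab) == 0L)
    return(list(results = results, counts = counts))
  uniqSeeds <- unique(seedTab$kmer)
  seedOf <- split(seq_len(nrow(seedTab)), seedTab$kmer)

  hits <- vector("list", 2L)
  for (oi in 1:2) {
    sq <- if (oi == 1L) readSeq else revComp(readSeq)
    hits[[oi]] <- .seedHits(sq, uniqSeeds, seedLen)
    if (nrow(hits[[oi]])) hits[[oi]]$orientation <-
        if (oi == 1L) "fwd" else "rev"
  }
  hits <- rbind(hits[[1L]], hits[[2L]])
  if (nrow(hits) == 0L)
    return(list(results = results, counts = counts))

  # expand seed hits to (read, entry, offset) anchorings
  perHit <- seedOf[hits$kmer]
  reps <- lengths(perHit)
  hIdx <- rep(seq_len(nrow(hits)), reps)
  rows <- unlist(perHit, use.names = FALSE)
  expand <- data.frame(read = hits$read[hIdx], pos = hits$pos[hIdx],
                       orientation = hits$orientation[hIdx],
                       entry = seedTab$entry[rows],
                       epos = seedTab$pos[rows],
                       stringsAsFactors = FALSE)
  # offset o: read base j aligns entry position o + j
  expand$offset <- expand$epos - expand$pos
  key <- paste(expand$read, expand$entry, expand$orientation,
               expand$offset, sep = "\r")
  expand <- expand[!duplicated(key), , drop = FALSE]

  ok <- logical(nrow(expand))
  leftA <- integer(nrow(expand)); rightA <- integer(nrow(expand))
  mm <- integer(nrow(expand))
  for (h in seq_len(nrow(expand))) {
    e <- expand$entry[h]
    f <- entries$seam[e]
    entrySeq <- entries$seq[e]
    rs <- if (expand$orientation[h] == "fwd") readSeq[expand$read[h]]
          else revComp(readSeq[expand$read[h]])
    L <- nchar(rs)
    o <- expand$offset[h]
    la <- min(f - o, L)              # read bases on/left of the seam
    ra <- min(nchar(entrySeq), o + L) - f  # read bases right of the seam
    leftA[h] <- max(0L, la); rightA[h] <- max(0L, ra)
    if (la < minAnchor || ra < minAnchor) next
    # mismatches inside the seam-centered window
    ws <- f - minAnchor + 1L; we <- f + minAnchor
    rw <- substring(rs, ws - o, we - o)
    ew <- substring(entrySeq, ws, we)
    d <- sum(utf8ToInt(rw) != utf8ToInt(ew))
    mm[h] <- d
    ok[h] <- d <= maxMismatch
  }
  expand <- cbind(expand, left_anchor = leftA, right_anchor = rightA,
                  mismatches = mm, ok = ok)
  good <- expand[expand$ok, , drop = FALSE]
  # one verification per (read, entry)
  good <- good[!duplicated(paste(good$read, good$entry, sep = "\r")), ,
               drop = FALSE]
  results <- data.frame(id = entries$id[good$entry],
                        read_id = readId[good$read],
                        orientation = good$orientation,
                        left_anchor = good$left_anchor,
                        right_anchor = good$right_anchor,
                        mismatches = good$mismatches,
                        stringsAsFactors = FALSE)
  cnt <- table(factor(good$entry, levels = seq_len(nrow(entries))))
  counts$verified_reads <- as.integer(cnt)
  .msg("verify", "%d of %d entries verified by >=1 read",
       sum(counts$verified_reads > 0L), nrow(entries))
  list(results = results, counts = counts)
}

# seam-spanning seedLen-mers for each pseudoRef entry
.seamSeeds <- function(entries, seedLen) {
  out <- vector("list", nrow(entries))
  for (e in seq_len(nrow(entries))) {
    f <- entries$seam[e]
    len <- nchar(entries$seq[e])
    from <- max(1L, f - seedLen + 2L)
    to <- min(f, len - seedLen + 1L)
    if (to < from) { out[[e]] <- NULL; next }
    pos <- from:to
    out[[e]] <- data.frame(entry = e, pos = pos,
                           kmer = substring(entries$seq[e], pos,
                                            pos + seedLen - 1L),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out) %||% data.frame(entry = integer(0), pos = integer(0),
                                      kmer = character(0))
}

# all (read, pos) where a read carries one of the seed k-mers, vectorised
# over reads in chunks
.seedHits <- function(sq, uniqSeeds, seedLen) {
  res <- list()
  n <- length(sq)
  chunk <- 5000L
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(n, lo + chunk - 1L)
    idx <- lo:hi
    L <- nchar(sq[idx])
    nk <- pmax(0L, L - seedLen + 1L)
    rd <- rep(idx, nk)
    pos <- unlist(lapply(nk, function(k) seq_len(k)), use.names = FALSE)
    if (!length(rd)) next
    km <- substring(sq[rd], pos, pos + seedLen - 1L)
    isHit <- km %in% uniqSeeds
    if (any(isHit))
      res[[length(res) + 1L]] <- data.frame(read = rd[isHit],
                                            pos = pos[isHit],
                                            kmer = km[isHit],
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, res) %||% data.frame(read = integer(0), pos = integer(0),
                                      kmer = character(0))
}

#' Finalize verified circRNAs
#'
#' Keeps candidates whose verified read count reaches \code{minVerified},
#' attaches the counts, and returns a \linkS4class{CircRNASet} in stable
#' (chromosome, start) order.  Isoform sequences are added separately by
#' \code{\link{extractFullLength}}.
#'
#' @param candidates a \linkS4class{BackspliceSet}.
#' @param verification result of \code{\link{verifyJunctions}}.
#' @param minVerified minimum verified reads (default 2).
#' @return a \linkS4class{CircRNASet} (isoform table empty).
#' @export
finalizeCircRNAs <- function(candidates, verification, minVerified = 2L) {
  counts <- verification$counts
  ids <- if (length(candidates))
    .circId(as.character(seqnames(candidates)), start(candidates),
            end(candidates), as.character(strand(candidates)))
    else character(0)
  v <- counts$verified_reads[match(ids, counts$id)]
  v[is.na(v)] <- 0L
  keep <- v >= minVerified
  .msg("verify", "%d of %d candidates verified (>=%d reads)",
       sum(keep), length(candidates), minVerified)
  gr <- candidates[keep]
  mcols(gr)$verified_reads <- v[keep]
  o <- order(as.character(seqnames(gr)), start(gr))
  gr <- gr[o]
  new("CircRNASet", gr, isoforms = .emptyIsoforms())
}

.emptyIsoforms <- function() {
  DataFrame(circ_id = character(0), isoform = character(0),
            transcript_id = character(0), n_exons = integer(0),
            length = integer(0), seq = character(0))
}

# normalise candidate input to a plain data.frame
.candFrame <- function(candidates) {
  if (is(candidates, "GRanges")) {
    data.frame(chrom = as.character(seqnames(candidates)),
               start = start(candidates), end = end(candidates),
               strand = as.character(strand(candidates)),
               stringsAsFactors = FALSE)
  } else {
    as.data.frame(candidates)[, c("chrom", "start", "end", "strand")]
  }
}
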