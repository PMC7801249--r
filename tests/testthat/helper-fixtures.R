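# fixtures and independent oracles used across the test files.
# Everything is built in code; no binary data.

options(backsplice.verbose = FALSE)

# ---- tiny builders -------------------------------------------------------

toyGenome <- function(seqs) {
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

# gene models from a list of transcripts:
# list(tx1 = list(chrom=, strand=, gene=, exons=matrix(start,end)))
toyModels <- function(txs) {
  rows <- lapply(names(txs), function(tid) {
    t <- txs[[tid]]
    data.frame(chrom = t$chrom, start = t$exons[, 1], end = t$exons[, 2],
               strand = t$strand, transcript_id = tid,
               gene_id = t$gene %||% paste0("g_", tid),
               stringsAsFactors = FALSE)
  })
  ex <- do.call(rbind, rows)
  exons <- GenomicRanges::GRanges(ex$chrom,
                                  IRanges::IRanges(ex$start, ex$end),
                                  strand = ex$strand,
                                  transcript_id = ex$transcript_id,
                                  gene_id = ex$gene_id)
  o <- order(ex$transcript_id, ex$start)
  exons <- exons[o]
  tx <- do.call(rbind, lapply(names(txs), function(tid) {
    t <- txs[[tid]]
    data.frame(transcript_id = tid, gene_id = t$gene %||% paste0("g_", tid),
               chrom = t$chrom, strand = t$strand,
               start = min(t$exons[, 1]), end = max(t$exons[, 2]),
               n_exons = nrow(t$exons), flags = "",
               stringsAsFactors = FALSE)
  }))
  new("GeneModels", exons = exons, transcripts = tx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# segment rows for a synthetic split read
segRow <- function(read_id, mate, rs, re, chrom, gs, ge, strand,
                   nm = 0L, score = NULL, read_length = 100L) {
  data.frame(read_id = read_id, mate = mate, read_start = rs,
             read_end = re, chrom = chrom, ref_start = gs, ref_end = ge,
             strand = strand, nm = nm,
             score = score %||% (re - rs + 1L - nm),
             read_length = read_length, stringsAsFactors = FALSE)
}

splitReadSet <- function(seg, paired = FALSE) {
  new("SplitReadSet", segments = seg, paired = paired, nDropped = 0L)
}

# ---- independent oracles -------------------------------------------------

# brute-force CIGAR interpreter: walk operation by operation
oracleCigarSpans <- function(cigar) {
  chars <- strsplit(cigar, "")[[1]]
  readSpan <- 0L; refSpan <- 0L; num <- 0L
  for (ch in chars) {
    if (grepl("[0-9]", ch)) {
      num <- num * 10L + as.integer(ch)
    } else {
      if (ch %in% c("M", "I", "S", "=", "X")) readSpan <- readSpan + num
      if (ch %in% c("M", "D", "N", "=", "X")) refSpan <- refSpan + num
      num <- 0L
    }
  }
  list(read_span = readSpan, ref_span = refSpan)
}

# exhaustive hypergeometric upper tail from the pmf via choose()
oracleHyperSF <- function(k, N, K, n) {
  i <- 0:min(K, n)
  pmf <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sum(pmf[i >= k])
}

# brute-force miRNA-alignment enumeration: all alignments with at most
# one bulge event per side (miRNA bulge anywhere, target bulge strictly
# internal), same penalty convention as the scorer.
oracleScore <- function(mirna, window, param = mirnaParams()) {
  m <- strsplit(gsub("U", "T", toupper(mirna)), "")[[1]]
  w <- rev(strsplit(gsub("U", "T", toupper(window)), "")[[1]])
  M <- length(m); W <- length(w)
  mult <- function(i) if (i >= param$doubledRegion[1] &&
                            i <= param$doubledRegion[2])
    param$doubledFactor else 1
  pairPen <- function(a, b, i) {
    wc <- c(A = "T", C = "G", G = "C", T = "A")
    base <- if (b == wc[[a]]) 0
            else if ((a == "G" && b == "T") || (a == "T" && b == "G"))
              param$guPenalty
            else param$mismatchPenalty
    base * mult(i)
  }
  best <- Inf
  rec <- function(i, j, usedMB, usedTB, acc) {
    if (acc >= best) return()
    if (i == M && j == W) { best <<- min(best, acc); return() }
    if (i < M && j < W)
      rec(i + 1, j + 1, usedMB, usedTB,
          acc + pairPen(m[i + 1], w[j + 1], i + 1))
    if (!usedMB) {
      pen <- 0
      for (L in 1:param$maxBulge) {
        if (i + L > M) break
        pen <- pen + param$bulgePenalty * mult(i + L)
        rec(i + L, j, TRUE, usedTB, acc + pen)
      }
    }
    if (!usedTB && i >= 1 && i < M) {
      unit <- param$bulgePenalty * mult(min(i + 1, M))
      for (L in 1:param$maxBulge) {
        if (j + L > W) break
        rec(i, j + L, usedMB, TRUE, acc + L * unit)
      }
    }
  }
  rec(0, 0, FALSE, FALSE, 0)
  best
}

# brute-force junction enumeration: match every read (both orientations)
# against all junction windows by exact two-part string matching
oracleJunctions <- function(genome, reads, minSplit = 10L) {
  res <- list()
  chromStrs <- lapply(as.list(genome), as.character)
  findAll <- function(chrom, pat) {
    hits <- gregexpr(pat, chromStrs[[chrom]], fixed = TRUE)[[1]]
    if (hits[1] == -1) integer(0) else as.integer(hits)
  }
  for (rs in as.character(reads)) {
    L <- nchar(rs)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(rs)))
    for (a in minSplit:(L - minSplit)) {
      p1 <- substr(rs, 1, a); p2 <- substr(rs, a + 1, L)
      q1 <- substr(rc, 1, L - a); q2 <- substr(rc, L - a + 1, L)
      for (chrom in names(chromStrs)) {
        # plus strand: earlier part strictly downstream of later part
        for (s1 in findAll(chrom, p1)) {
          for (s2 in findAll(chrom, p2)) {
            if (s1 > s2 + nchar(p2) - 1)
              res[[length(res) + 1L]] <-
                c(chrom, s2, s1 + nchar(p1) - 1L, "+")
          }
        }
        # minus strand: original read part1 = revcomp of q2, maps at q2
        # matches; part1 must be strictly upstream of part2
        for (s2 in findAll(chrom, q2)) {       # part1 of original read
          for (s1 in findAll(chrom, q1)) {     # part2 of original read
            if (s2 + nchar(q2) - 1 < s1)
              res[[length(res) + 1L]] <-
                c(chrom, s2, s1 + nchar(q1) - 1L, "-")
          }
        }
      }
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  df <- unique(as.data.frame(do.call(rbind, res),
                             stringsAsFactors = FALSE))
  colnames(df) <- c("chrom", "start", "end", "strand")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}

# brute-force verification: scan every alignment offset of a read
# against an entry (no seeding) and apply the seam-window rule
oracleVerify <- function(readSeq, entrySeq, seam, minAnchor = 10L,
                         maxMismatch = 2L) {
  tryOne <- function(rs) {
    L <- nchar(rs)
    for (o in (-L + 1):(nchar(entrySeq))) {
      la <- min(seam - o, L)
      ra <- min(nchar(entrySeq), o + L) - seam
      if (la < minAnchor || ra < minAnchor) next
      ws <- seam - minAnchor + 1; we <- seam + minAnchor
      if (ws - o < 1 || we - o > L) next
      rw <- substr(rs, ws - o, we - o)
      ew <- substr(entrySeq, ws, we)
      if (sum(utf8ToInt(rw) != utf8ToInt(ew)) <= maxMismatch)
        return(TRUE)
    }
    FALSE
  }
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(readSeq)))
  tryOne(readSeq) || tryOne(rc)
}

# small standard simulation used by several files (error-free)
smallSim <- function(seed = 5L, ...) {
  p <- simParams(nChrom = 1L, chromLen = 120000L, nGenes = 40L,
                 nCirc = 10L, nBsjReads = 200L, nBackground = 80L, ...)
  simulateBenchmark(p, seed = seed)
}

simSplitReads <- function(sim) {
  f <- tempfile(fileext = ".sam")
  writeLines(simAlignments(sim), f)
  on.exit(unlink(f))
  readSplitAlignments(f)
}

candKeys <- function(x) {
  if (is(x, "GRanges"))
    paste(as.character(GenomicRanges::seqnames(x)),
          GenomicRanges::start(x), GenomicRanges::end(x),
          as.character(GenomicRanges::strand(x)))
  else paste(x$chrom, x$start, x$end, x$strand)
}
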