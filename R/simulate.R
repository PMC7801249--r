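#' Simulation parameters
#'
#' Defaults encode the benchmark design this package is calibrated
#' against: 200 circRNAs supported by 6000 back-splice junction read
#' pairs, paired-end 100 bp reads, plus an equal number of linear
#' background fragments, on a ~2 Mb multi-gene synthetic genome whose
#' introns carry canonical splice signals (a small fraction GC-AG and
#' AT-AC).
#'
#' @param nChrom number of chromosomes (default 4).
#' @param chromLen chromosome length in bp (default 500000).
#' @param nGenes total genes, placed without overlap (default 500).
#' @param exonsPerGene length-2 range of exons per gene (default 4..8).
#' @param exonLen length-2 range of exon lengths (default 80..300).
#' @param intronLen length-2 range of intron lengths (default 60..200).
#' @param intergenic length-2 range of gaps between genes (default
#'   200..500).
#' @param gcagFrac,atacFrac fraction of introns with GC-AG / AT-AC
#'   signals (defaults 0.05 and 0.02).
#' @param nCirc number of true circRNAs (default 200).
#' @param nBsjReads total back-splice junction read (pairs) (default
#'   6000), distributed multinomially with a floor of 2 per circle.
#' @param readLen read length (default 100).
#' @param paired paired-end flag (default TRUE).
#' @param insertMean,insertSd fragment length distribution (250/25).
#' @param errorRate per-base substitution error rate (default 0).
#' @param nBackground linear background fragments (default 6000).
#' @param singleExonCirc restrict circles to single exons (no spliced
#'   junction inside the circle; default FALSE).
#' @param minAnchor minimum read bases on each side of the seam for a
#'   simulated BSJ read (default 10).
#' @return named list of class \code{backsplice_params}.
#' @export
simParams <- function(nChrom = 4L, chromLen = 500000L, nGenes = 500L,
                      exonsPerGene = c(4L, 8L), exonLen = c(80L, 300L),
                      intronLen = c(60L, 200L),
                      intergenic = c(200L, 500L), gcagFrac = 0.05,
                      atacFrac = 0.02, nCirc = 200L, nBsjReads = 6000L,
                      readLen = 100L, paired = TRUE, insertMean = 250,
                      insertSd = 25, errorRate = 0,
                      nBackground = 6000L, singleExonCirc = FALSE,
                      minAnchor = 10L) {
  stopifnot(nChrom >= 1, chromLen > 0, nGenes >= 0,
            nBsjReads >= 2 * nCirc, readLen > 2 * minAnchor,
            errorRate >= 0, errorRate < 1)
  structure(list(nChrom = as.integer(nChrom),
                 chromLen = as.integer(chromLen),
                 nGenes = as.integer(nGenes),
                 exonsPerGene = as.integer(exonsPerGene),
                 exonLen = as.integer(exonLen),
                 intronLen = as.integer(intronLen),
                 intergenic = as.integer(intergenic),
                 gcagFrac = gcagFrac, atacFrac = atacFrac,
                 nCirc = as.integer(nCirc),
                 nBsjReads = as.integer(nBsjReads),
                 readLen = as.integer(readLen), paired = paired,
                 insertMean = insertMean, insertSd = insertSd,
                 errorRate = errorRate,
                 nBackground = as.integer(nBackground),
                 singleExonCirc = singleExonCirc,
                 minAnchor = as.integer(minAnchor)),
            class = "backsplice_params")
}

# run expr under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.rint <- function(n, range) {
  if (range[1] >= range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

#' Simulate a multi-gene genome and its annotation
#'
#' Generates random chromosomes and places non-overlapping genes (one
#' transcript each, random strand).  Every intron is written with
#' canonical boundary dinucleotides on the transcribed strand (GT..AG by
#' default, a configurable fraction GC-AG and AT-AC), and the outer
#' boundaries of terminal exons also receive GT/AG context so that every
#' exon-boundary pair is a splice-signal-bearing back-splice site.
#' Deterministic under \code{seed}.
#'
#' @param param a \code{\link{simParams}} list.
#' @param seed integer random seed.
#' @return list with \code{genome} (named \code{DNAStringSet}) and
#'   \code{models} (\linkS4class{GeneModels}).
#' @export
simulateGenomeAnnotation <- function(param = simParams(), seed = 1L) {
  .withSeed(seed, {
    chromNames <- sprintf("chr%d", seq_len(param$nChrom))
    chroms <- lapply(seq_len(param$nChrom), function(i)
      sample(c("A", "C", "G", "T"), param$chromLen, replace = TRUE))
    names(chroms) <- chromNames

    exS <- list(); exE <- list(); exTx <- list(); exGene <- list()
    txRows <- list()
    ci <- 1L
    pos <- .rint(1L, param$intergenic) + 3L
    for (g in seq_len(max(0L, param$nGenes))) {
      nEx <- .rint(1L, param$exonsPerGene)
      eLens <- .rint(nEx, param$exonLen)
      iLens <- if (nEx > 1L) .rint(nEx - 1L, param$intronLen)
               else integer(0)
      geneLen <- sum(eLens) + sum(iLens)
      while (pos + geneLen + 3L > param$chromLen) {
        ci <- ci + 1L
        if (ci > param$nChrom)
          stop("genes do not fit on the simulated chromosomes; ",
               "increase chromLen or reduce nGenes", call. = FALSE)
        pos <- .rint(1L, param$intergenic) + 3L
      }
      strand <- sample(c("+", "-"), 1L)
      starts <- integer(nEx); ends <- integer(nEx)
      p <- pos
      for (k in seq_len(nEx)) {
        starts[k] <- p; ends[k] <- p + eLens[k] - 1L
        p <- ends[k] + 1L + if (k < nEx) iLens[k] else 0L
      }
      gid <- sprintf("gene%04d", g)
      tid <- sprintf("tx%04d", g)
      exS[[g]] <- starts; exE[[g]] <- ends
      exTx[[g]] <- rep(tid, nEx); exGene[[g]] <- rep(gid, nEx)
      txRows[[g]] <- data.frame(
        transcript_id = tid, gene_id = gid, chrom = chromNames[ci],
        strand = strand, start = starts[1L], end = ends[nEx],
        n_exons = nEx, flags = "", stringsAsFactors = FALSE)

      # plant splice signals on the transcribed strand
      v <- chroms[[ci]]
      plant <- function(at, dinuc) {
        v[at] <<- substr(dinuc, 1L, 1L)
        v[at + 1L] <<- substr(dinuc, 2L, 2L)
      }
      if (nEx > 1L) {
        sigs <- sample(c("GT-AG", "GC-AG", "AT-AC"), nEx - 1L,
                       replace = TRUE,
                       prob = c(1 - param$gcagFrac - param$atacFrac,
                                param$gcagFrac, param$atacFrac))
        for (k in seq_len(nEx - 1L)) {
          D <- substr(sigs[k], 1L, 2L)
          A <- substr(sigs[k], 4L, 5L)
          iStart <- ends[k] + 1L; iEnd <- starts[k + 1L] - 1L
          if (strand == "+") {
            plant(iStart, D)
            plant(iEnd - 1L, A)
          } else {
            plant(iEnd - 1L, revComp(D))
            plant(iStart, revComp(A))
          }
        }
      }
      # terminal boundaries: GT/AG context outside the gene span
      if (strand == "+") {
        plant(starts[1L] - 2L, "AG")
        plant(ends[nEx] + 1L, "GT")
      } else {
        plant(starts[1L] - 2L, revComp("GT"))   # AC
        plant(ends[nEx] + 1L, revComp("AG"))    # CT
      }
      chroms[[ci]] <- v
      pos <- ends[nEx] + 1L + .rint(1L, param$intergenic) + 3L
    }

    genome <- DNAStringSet(vapply(chroms, paste, character(1),
                                  collapse = ""))
    names(genome) <- chromNames
    tx <- do.call(rbind, txRows) %||% data.frame(
      transcript_id = character(0), gene_id = character(0),
      chrom = character(0), strand = character(0), start = integer(0),
      end = integer(0), n_exons = integer(0), flags = character(0),
      stringsAsFactors = FALSE)
    exons <- if (nrow(tx)) GRanges(
      rep(tx$chrom, tx$n_exons),
      IRanges(unlist(exS), unlist(exE)),
      strand = rep(tx$strand, tx$n_exons),
      transcript_id = unlist(exTx), gene_id = unlist(exGene))
      else GRanges(transcript_id = character(0), gene_id = character(0))
    models <- new("GeneModels", exons = exons, transcripts = tx)
    list(genome = genome, models = models)
  })
}

# per-transcript cache: ascending exon table, tx-coordinate ->
# genomic-position array (tx 5'->3'), spliced sequence
.txData <- function(genome, models) {
  tx <- modelTranscripts(models)
  ex <- modelExons(models)
  exTx <- mcols(ex)$transcript_id
  chromCache <- lapply(as.list(genome), as.character)
  out <- vector("list", nrow(tx))
  names(out) <- tx$transcript_id
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    idx <- which(exTx == tid)
    idx <- idx[order(start(ex)[idx])]
    s <- start(ex)[idx]; e <- end(ex)[idx]
    gpos <- unlist(lapply(seq_along(s), function(k) s[k]:e[k]),
                   use.names = FALSE)
    cs <- chromCache[[tx$chrom[i]]]
    sq <- paste(substring(cs, s, e), collapse = "")
    if (tx$strand[i] == "-") {
      gpos <- rev(gpos)
      sq <- revComp(sq)
    }
    out[[i]] <- list(transcript_id = tid, chrom = tx$chrom[i],
                     strand = tx$strand[i], exStart = s, exEnd = e,
                     gpos = gpos, seq = sq, splicedLen = length(gpos),
                     cum = cumsum(e - s + 1L))
  }
  out
}

# maximal colinear runs in a monotone genomic-position vector ->
# ascending blocks (gstart, gend)
.blocksFromPositions <- function(g) {
  n <- length(g)
  if (n == 1L) return(cbind(gstart = g, gend = g))
  step <- if (g[2L] >= g[1L]) 1L else -1L
  br <- which(diff(g) != step)
  starts <- c(1L, br + 1L); ends <- c(br, n)
  gs <- pmin(g[starts], g[ends]); ge <- pmax(g[starts], g[ends])
  o <- order(gs)
  cbind(gstart = gs[o], gend = ge[o])
}

# one SAM alignment "part": read interval (original orientation),
# ascending genomic blocks, strand, chrom
.makePart <- function(txd, txFrom, txTo, readStart, readEnd, sense) {
  g <- txd$gpos[txFrom:txTo]
  strand <- if (sense) txd$strand else if (txd$strand == "+") "-" else "+"
  list(read_start = as.integer(readStart), read_end = as.integer(readEnd),
       blocks = .blocksFromPositions(g), strand = strand,
       chrom = txd$chrom)
}

.cigarOf <- function(part, readLen, clipChar) {
  b <- part$blocks
  w <- b[, "gend"] - b[, "gstart"] + 1L
  gaps <- if (nrow(b) > 1L) b[-1L, "gstart"] - b[-nrow(b), "gend"] - 1L
          else integer(0)
  body <- paste0(w[1L], "M")
  if (length(gaps))
    body <- paste0(body,
                   paste0(gaps, "N", w[-1L], "M", collapse = ""))
  lead <- if (part$strand == "+") part$read_start - 1L
          else readLen - part$read_end
  trail <- readLen - (part$read_end - part$read_start + 1L) - lead
  paste0(if (lead > 0L) paste0(lead, clipChar) else "", body,
         if (trail > 0L) paste0(trail, clipChar) else "")
}

# SAM records for one read end consisting of 1-2 parts
.samForRead <- function(qname, parts, seqFull, errPos, paired, mate1,
                        mateStrand, matePos, mateChrom, readLen) {
  nmOf <- vapply(parts, function(p)
    sum(errPos >= p$read_start & p$read_end >= errPos), integer(1))
  lens <- vapply(parts, function(p) p$read_end - p$read_start + 1L,
                 integer(1))
  primary <- which.max(lens)
  saStr <- vapply(seq_along(parts), function(k) {
    p <- parts[[k]]
    sprintf("%s,%d,%s,%s,60,%d", p$chrom, p$blocks[1L, "gstart"],
            p$strand, .cigarOf(p, readLen,
                               if (k == primary) "S" else "H"), nmOf[k])
  }, character(1))
  recs <- character(length(parts))
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    isSupp <- k != primary
    flag <- 0L
    if (paired) {
      flag <- flag + 1L + 2L + if (mate1) 64L else 128L
      if (mateStrand == "-") flag <- flag + 32L
    }
    if (p$strand == "-") flag <- flag + 16L
    if (isSupp) flag <- flag + 2048L
    stored <- if (p$strand == "+") seqFull else revComp(seqFull)
    if (isSupp) {
      lead <- if (p$strand == "+") p$read_start - 1L
              else readLen - p$read_end
      stored <- substr(stored, lead + 1L,
                       lead + (p$read_end - p$read_start + 1L))
    }
    qual <- strrep("I", nchar(stored))
    tags <- sprintf("NM:i:%d\tAS:i:%d", nmOf[k],
                    lens[k] - 5L * nmOf[k])
    if (length(parts) > 1L)
      tags <- paste0(tags, "\tSA:Z:",
                     paste0(saStr[-k], ";", collapse = ""))
    rnext <- if (paired) "=" else "*"
    pnext <- if (paired) matePos else 0L
    recs[k] <- paste(qname, flag, p$chrom, p$blocks[1L, "gstart"], 60L,
                     .cigarOf(p, readLen, if (isSupp) "H" else "S"),
                     rnext, pnext, 0L, stored, qual, tags, sep = "\t")
  }
  recs
}

# apply substitution errors at positions errPos of seq
.applyErrors <- function(seq, errPos) {
  if (!length(errPos)) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  for (p in errPos) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- alt[sample.int(3L, 1L)]
  }
  paste(ch, collapse = "")
}

# split a tx interval (RNA coordinates of one read end) into SAM parts,
# representing linear junction-crossing reads as colinear split records
# when both sides are long enough (a chimeric-aware mapper splits rather
# than writing N across its primary segment boundary)
.linearParts <- function(txd, a, b, sense, splitMin = 15L) {
  L <- b - a + 1L
  g <- txd$gpos[a:b]
  blocks <- .blocksFromPositions(g)
  if (nrow(blocks) >= 2L) {
    # split at the first junction (in tx coordinates) if both sides
    # are >= splitMin
    step <- if (g[2L] >= g[1L]) 1L else -1L
    br <- which(diff(g) != step)[1L]
    if (!is.na(br) && br >= splitMin && (L - br) >= splitMin) {
      if (sense) {
        return(list(.makePart(txd, a, a + br - 1L, 1L, br, sense),
                    .makePart(txd, a + br, b, br + 1L, L, sense)))
      } else {
        # antisense: read base 1 corresponds to tx coordinate b
        return(list(.makePart(txd, a + br, b, 1L, L - br, sense),
                    .makePart(txd, a, a + br - 1L, L - br + 1L, L,
                              sense)))
      }
    }
  }
  list(.makePart(txd, a, b, 1L, L, sense))
}

#' Simulate circRNA reads and truth-derived split alignments
#'
#' Chooses \code{nCirc} transcripts, defines one circle per transcript
#' over an exon-boundary pair, distributes \code{nBsjReads} fragments
#' multinomially (floor 2 per circle), and synthesises paired-end
#' fragments from the circularised spliced sequence such that read 1
#' spans the back-splice seam with at least \code{minAnchor} bases on
#' each side (mates are drawn from inside the circle and may themselves
#' wrap the seam).  Linear background fragments are drawn from the
#' remaining transcripts.  Substitution errors are applied at
#' \code{errorRate}.  Besides FASTQ-ready reads, the simulator emits the
#' split alignments a chimeric-aware spliced mapper would produce
#' (primary + hard-clipped supplementary records with SA tags, NM/AS
#' tags, N operations across introns), so the detection pipeline can run
#' with no external aligner.
#'
#' @param genome named \code{DNAStringSet} from
#'   \code{\link{simulateGenomeAnnotation}}.
#' @param models matching \linkS4class{GeneModels}.
#' @param param a \code{\link{simParams}} list.
#' @param seed integer random seed.
#' @return a \linkS4class{CircSimulation}.
#' @export
simulateCircReads <- function(genome, models, param = simParams(),
                              seed = 1L) {
  .withSeed(seed, {
    txd <- .txData(genome, models)
    readLen <- param$readLen
    minCirc <- readLen + 2L * param$minAnchor
    # valid exon-boundary pairs per transcript
    pairsOf <- lapply(txd, function(t) {
      nEx <- length(t$exStart)
      cum <- t$cum
      res <- list()
      for (i in seq_len(nEx)) {
        jset <- if (param$singleExonCirc) i else i:nEx
        for (j in jset) {
          sl <- cum[j] - (if (i > 1L) cum[i - 1L] else 0L)
          if (sl >= minCirc) res[[length(res) + 1L]] <- c(i, j, sl)
        }
      }
      res
    })
    eligible <- names(txd)[lengths(pairsOf) > 0L &
                             vapply(txd, function(t)
                               length(t$exStart), integer(1)) >=
                             (if (param$singleExonCirc) 1L else 2L)]
    if (length(eligible) < param$nCirc)
      stop("not enough eligible transcripts for ", param$nCirc,
           " circRNAs (", length(eligible), " available)", call. = FALSE)
    circTx <- sample(eligible, param$nCirc)

    truth <- data.frame(circ_id = sprintf("circ%04d",
                                          seq_len(param$nCirc)),
                        chrom = "", start = 0L, end = 0L, strand = "",
                        transcript_id = circTx, n_reads = 0L,
                        spliced_length = 0L, stringsAsFactors = FALSE)
    circInfo <- vector("list", param$nCirc)
    for (c in seq_len(param$nCirc)) {
      t <- txd[[circTx[c]]]
      pr <- pairsOf[[circTx[c]]]
      pick <- pr[[sample.int(length(pr), 1L)]]
      i <- pick[1L]; j <- pick[2L]
      # exon indices are in ascending genomic order; tx-coordinate
      # boundaries depend on strand
      if (t$strand == "+") {
        csT <- (if (i > 1L) t$cum[i - 1L] else 0L) + 1L
        ceT <- t$cum[j]
      } else {
        nEx <- length(t$exStart)
        widths <- t$exEnd - t$exStart + 1L
        cumR <- cumsum(rev(widths))
        ri <- nEx - j + 1L; rj <- nEx - i + 1L
        csT <- (if (ri > 1L) cumR[ri - 1L] else 0L) + 1L
        ceT <- cumR[rj]
      }
      S <- ceT - csT + 1L
      circSeq <- substr(t$seq, csT, ceT)
      truth$chrom[c] <- t$chrom
      truth$start[c] <- t$exStart[i]
      truth$end[c] <- t$exEnd[j]
      truth$strand[c] <- t$strand
      truth$spliced_length[c] <- S
      circInfo[[c]] <- list(t = t, csT = csT, ceT = ceT, S = S,
                            seq2x = paste0(circSeq, circSeq))
    }
    extra <- param$nBsjReads - 2L * param$nCirc
    alloc <- rep(2L, param$nCirc)
    if (extra > 0L)
      alloc <- alloc + as.integer(stats::rmultinom(
        1L, extra, rep(1 / param$nCirc, param$nCirc)))
    truth$n_reads <- alloc

    sam <- list(); r1 <- list(); r2 <- list()
    nm1 <- list(); nm2 <- list()
    recIdx <- 0L
    emit <- function(lines) {
      recIdx <<- recIdx + 1L
      sam[[recIdx]] <<- lines
    }
    errPositions <- function() {
      if (param$errorRate <= 0) return(integer(0))
      ne <- rbinom(1L, readLen, param$errorRate)
      if (ne == 0L) integer(0) else sort(sample.int(readLen, ne))
    }

    for (c in seq_len(param$nCirc)) {
      info <- circInfo[[c]]
      t <- info$t; S <- info$S; csT <- info$csT
      for (r in seq_len(alloc[c])) {
        qname <- sprintf("%s_r%04d", truth$circ_id[c], r)
        a <- sample(param$minAnchor:(readLen - param$minAnchor), 1L)
        fs <- S - a + 1L
        flenMax <- S + a - 1L
        flen <- round(rnorm(1L, param$insertMean, param$insertSd))
        flen <- max(readLen + 10L, min(flenMax, flen))
        if (!param$paired) flen <- readLen
        fe <- fs + flen - 1L

        # R1: sense, spans the seam
        e1 <- errPositions()
        seq1 <- .applyErrors(substr(info$seq2x, fs, fs + readLen - 1L),
                             e1)
        parts1 <- .circleParts(t, csT, S, fs, fs + readLen - 1L,
                               sense = TRUE, readLen)
        # R2: antisense from the fragment end
        if (param$paired) {
          e2 <- errPositions()
          seq2raw <- substr(info$seq2x, fe - readLen + 1L, fe)
          seq2 <- .applyErrors(revComp(seq2raw), e2)
          parts2 <- .circleParts(t, csT, S, fe - readLen + 1L, fe,
                                 sense = FALSE, readLen)
          p1 <- parts1[[which.max(vapply(parts1, function(p)
            p$read_end - p$read_start + 1L, integer(1)))]]
          p2 <- parts2[[which.max(vapply(parts2, function(p)
            p$read_end - p$read_start + 1L, integer(1)))]]
          emit(.samForRead(qname, parts1, seq1, e1, TRUE, TRUE,
                           p2$strand, p2$blocks[1L, "gstart"],
                           p2$chrom, readLen))
          emit(.samForRead(qname, parts2, seq2, e2, TRUE, FALSE,
                           p1$strand, p1$blocks[1L, "gstart"],
                           p1$chrom, readLen))
          r2[[length(r2) + 1L]] <- setNames(seq2, qname)
        } else {
          emit(.samForRead(qname, parts1, seq1, e1, FALSE, TRUE,
                           "+", 0L, "*", readLen))
        }
        r1[[length(r1) + 1L]] <- setNames(seq1, qname)
      }
    }

    # linear background fragments from non-circle transcripts
    bgTx <- setdiff(names(txd), circTx)
    bgTx <- bgTx[vapply(txd[bgTx], function(t)
      t$splicedLen >= readLen + 10L, logical(1))]
    if (param$nBackground > 0L && length(bgTx) > 0L) {
      picks <- sample(bgTx, param$nBackground, replace = TRUE)
      for (b in seq_len(param$nBackground)) {
        t <- txd[[picks[b]]]
        qname <- sprintf("bg_%06d", b)
        flen <- round(rnorm(1L, param$insertMean, param$insertSd))
        flen <- max(readLen, min(t$splicedLen, flen))
        if (!param$paired) flen <- readLen
        fs <- sample.int(t$splicedLen - flen + 1L, 1L)
        fe <- fs + flen - 1L
        e1 <- errPositions()
        seq1 <- .applyErrors(substr(t$seq, fs, fs + readLen - 1L), e1)
        parts1 <- .linearParts(t, fs, fs + readLen - 1L, sense = TRUE)
        if (param$paired) {
          e2 <- errPositions()
          seq2 <- .applyErrors(revComp(substr(t$seq, fe - readLen + 1L,
                                              fe)), e2)
          parts2 <- .linearParts(t, fe - readLen + 1L, fe,
                                 sense = FALSE)
          p1 <- parts1[[1L]]; p2 <- parts2[[1L]]
          emit(.samForRead(qname, parts1, seq1, e1, TRUE, TRUE,
                           p2$strand, p2$blocks[1L, "gstart"],
                           p2$chrom, readLen))
          emit(.samForRead(qname, parts2, seq2, e2, TRUE, FALSE,
                           p1$strand, p1$blocks[1L, "gstart"],
                           p1$chrom, readLen))
          r2[[length(r2) + 1L]] <- setNames(seq2, qname)
        } else {
          emit(.samForRead(qname, parts1, seq1, e1, FALSE, TRUE,
                           "+", 0L, "*", readLen))
        }
        r1[[length(r1) + 1L]] <- setNames(seq1, qname)
      }
    }

    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                        width(genome)),
                "@PG\tID:backsplice-sim\tPN:backsplice-sim")
    samLines <- c(header, unlist(sam, use.names = FALSE))
    reads1 <- DNAStringSet(unlist(r1))
    reads2 <- if (param$paired) DNAStringSet(unlist(r2)) else NULL
    .msg("simulate", "%d circRNAs, %d BSJ fragments, %d background",
         param$nCirc, sum(alloc), param$nBackground)
    new("CircSimulation", genome = genome, models = models,
        truth = truth, reads1 = reads1, reads2 = reads2,
        samLines = samLines, params = unclass(param))
  })
}

# parts of a read covering circle-unrolled interval [u1, u2]
# (1 <= u1 <= 2S, interval crosses the seam at most once); sense reads
# run 5'->3' along the circle RNA, antisense reads the reverse
.circleParts <- function(txd, csT, S, u1, u2, sense, readLen) {
  # unrolled pieces, split at the seam (between S and S+1)
  pieces <- if (u2 <= S || u1 > S) list(c(u1, u2))
            else list(c(u1, S), c(S + 1L, u2))
  parts <- list()
  for (pc in pieces) {
    pu1 <- pc[1L]; pu2 <- pc[2L]
    x <- ((pu1 - 1L) %% S) + 1L          # circle coordinates
    y <- x + (pu2 - pu1)
    if (sense) {
      rs <- pu1 - u1 + 1L; re <- pu2 - u1 + 1L
    } else {
      rs <- u2 - pu2 + 1L; re <- u2 - pu1 + 1L
    }
    parts[[length(parts) + 1L]] <-
      .makePart(txd, csT + x - 1L, csT + y - 1L, rs, re, sense)
  }
  parts[order(vapply(parts, `[[`, integer(1), "read_start"))]
}
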