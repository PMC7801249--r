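#' miRNA interaction parameters
#'
#' Penalty scheme and rules for plant miRNA target prediction.  Cleavage
#' sites are scored with the standard plant penalty convention: mismatch
#' 1, G:U wobble 0.5, bulged nucleotide 1, all doubled over miRNA
#' positions 2-13 (the 5' pairing region that directs cleavage); a site
#' is reported when its minimal score over alignments (at most one bulge
#' per side) falls below \code{scoreCutoff} (default 3).  Endogenous
#' target mimics are called by three rules: perfect Watson-Crick pairing
#' at miRNA positions \code{mimicSeed} (2-8), a bulge of
#' \code{mimicBulgeLen} (1-5) unpaired target nucleotides opposite miRNA
#' positions \code{mimicBulgeRegion} (9-11, the cleavage-blocking bulge)
#' with no other bulge, and at most \code{mimicMaxLoose} combined
#' mismatches plus G:U pairs over the remaining positions.  These encode
#' the standard target-mimic criteria of the plant literature and are
#' fully configurable.
#'
#' @param scoreCutoff cleavage score cutoff (default 3).
#' @param mismatchPenalty,guPenalty,bulgePenalty per-position penalties.
#' @param doubledRegion length-2 integer, miRNA positions with doubled
#'   penalties (default 2..13).
#' @param doubledFactor penalty multiplier in that region (default 2).
#' @param maxBulge maximum bulge length in nucleotides (default 5).
#' @param mimicSeed positions requiring perfect pairing for mimics.
#' @param mimicBulgeRegion miRNA positions opposite the mimic bulge.
#' @param mimicBulgeLen allowed mimic bulge lengths.
#' @param mimicMaxLoose maximum mismatches + G:U pairs outside the seed.
#' @return named list of class \code{backsplice_params}.
#' @export
mirnaParams <- function(scoreCutoff = 3, mismatchPenalty = 1,
                        guPenalty = 0.5, bulgePenalty = 1,
                        doubledRegion = c(2L, 13L), doubledFactor = 2,
                        maxBulge = 5L, mimicSeed = c(2L, 8L),
                        mimicBulgeRegion = c(9L, 11L),
                        mimicBulgeLen = c(1L, 5L), mimicMaxLoose = 4L) {
  stopifnot(scoreCutoff > 0, mismatchPenalty >= 0, guPenalty >= 0,
            bulgePenalty >= 0, maxBulge >= 1)
  structure(list(scoreCutoff = scoreCutoff,
                 mismatchPenalty = mismatchPenalty,
                 guPenalty = guPenalty, bulgePenalty = bulgePenalty,
                 doubledRegion = as.integer(doubledRegion),
                 doubledFactor = doubledFactor,
                 maxBulge = as.integer(maxBulge),
                 mimicSeed = as.integer(mimicSeed),
                 mimicBulgeRegion = as.integer(mimicBulgeRegion),
                 mimicBulgeLen = as.integer(mimicBulgeLen),
                 mimicMaxLoose = as.integer(mimicMaxLoose)),
            class = "backsplice_params")
}

#' Score one miRNA-target window
#'
#' Aligns the miRNA antiparallel to the window (T and U are equivalent;
#' sequences are normalised on entry) with a small dynamic program
#' allowing at most one bulge per side, and returns the minimal penalty
#' score with its per-position pairing string (\code{|} Watson-Crick,
#' \code{o} G:U, \code{x} mismatch, \code{-} bulge).
#'
#' @param mirna mature miRNA sequence, 5' to 3'.
#' @param window target site sequence, 5' to 3'; its length must lie
#'   within the miRNA length +/- \code{maxBulge}.
#' @param param a \code{\link{mirnaParams}} list.
#' @return list with \code{score} and \code{pairing}.
#' @export
#' @examples
#' scoreSite("AAGCUGCCAGCAUGAUCUGA",
#'           as.character(Biostrings::reverseComplement(
#'             Biostrings::DNAStringSet("AAGCTGCCAGCATGATCTGA"))))
scoreSite <- function(mirna, window, param = mirnaParams()) {
  m <- .normSeq(mirna); w <- .normSeq(window)
  M <- nchar(m); W <- nchar(w)
  if (W < M - param$maxBulge || W > M + param$maxBulge)
    stop("window length ", W, " outside miRNA length +/- maxBulge",
         call. = FALSE)
  # antiparallel: reverse the window so its first base faces miRNA pos 1
  res <- .cppMirnaAlign(m, .strrev(w), TRUE,
                        param$mismatchPenalty, param$guPenalty,
                        param$bulgePenalty, param$doubledFactor,
                        param$doubledRegion[1], param$doubledRegion[2],
                        param$maxBulge)
  list(score = res$score, pairing = res$pairing)
}

.strrev <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

.asSeqVector <- function(x) {
  if (is(x, "XStringSet")) x <- as.character(x)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  .normSeq(x)
}

#' Scan targets for miRNA cleavage sites
#'
#' Every window of every target is scored against every miRNA (the
#' miRNA 5' end pairing the 3' end of the site); sites scoring below the
#' cutoff are reported, with overlapping sites of the same miRNA on the
#' same target collapsed to the best-scoring one.  circRNA targets are
#' scanned on the circularised sequence, so a site may wrap the
#' back-splice seam (reported with \code{end < start}).
#'
#' @param mirnas named character vector or \code{DNAStringSet} of mature
#'   miRNA sequences (5' to 3'; U allowed).
#' @param targets named character vector or \code{DNAStringSet}.
#' @param param a \code{\link{mirnaParams}} list.
#' @param circular logical, recycled over targets: scan on the
#'   circularised sequence.
#' @return data.frame: \code{mirna}, \code{target}, \code{start},
#'   \code{end}, \code{kind} (\code{"cleavage"}), \code{score},
#'   \code{pairing}.
#' @export
scanTargets <- function(mirnas, targets, param = mirnaParams(),
                        circular = FALSE) {
  mirnas <- .asSeqVector(mirnas)
  targets <- .asSeqVector(targets)
  circular <- rep_len(circular, length(targets))
  out <- list()
  for (ti in seq_along(targets)) {
    tlen <- nchar(targets[ti])
    for (mi in seq_along(mirnas)) {
      m <- mirnas[mi]
      M <- nchar(m)
      tseq <- targets[ti]
      if (circular[ti] && tlen > 1L) {
        ext <- min(M + param$maxBulge - 1L, tlen)
        tseq <- paste0(tseq, substr(targets[ti], 1L, ext))
      }
      hits <- .cppScanTarget(m, tseq, param$scoreCutoff,
                             param$mismatchPenalty, param$guPenalty,
                             param$bulgePenalty, param$doubledFactor,
                             param$doubledRegion[1],
                             param$doubledRegion[2], param$maxBulge)
      if (nrow(hits) == 0L) next
      df <- data.frame(end = as.integer(hits[, "end"]),
                       site_len = as.integer(hits[, "site_len"]),
                       score = hits[, "score"])
      df$start <- df$end - df$site_len + 1L
      if (circular[ti]) {
        # de-duplicate by modular start position
        modStart <- ((df$start - 1L) %% tlen) + 1L
        df <- df[order(df$score, df$start), , drop = FALSE]
        df <- df[!duplicated(modStart[order(df$score, df$start)]), ,
                 drop = FALSE]
        df <- df[df$start <= tlen, , drop = FALSE]
      }
      if (nrow(df) == 0L) next
      df <- .collapseOverlaps(df)
      pair <- vapply(seq_len(nrow(df)), function(k) {
        win <- substr(tseq, df$start[k], df$end[k])
        .cppMirnaAlign(m, .strrev(win), TRUE, param$mismatchPenalty,
                       param$guPenalty, param$bulgePenalty,
                       param$doubledFactor, param$doubledRegion[1],
                       param$doubledRegion[2], param$maxBulge)$pairing
      }, character(1))
      out[[length(out) + 1L]] <- data.frame(
        mirna = names(mirnas)[mi], target = names(targets)[ti],
        start = ((df$start - 1L) %% tlen) + 1L,
        end = ((df$end - 1L) %% tlen) + 1L,
        kind = "cleavage", score = df$score, pairing = pair,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||% .emptySites()
  rownames(res) <- NULL
  res
}

.emptySites <- function() {
  data.frame(mirna = character(0), target = character(0),
             start = integer(0), end = integer(0), kind = character(0),
             score = numeric(0), pairing = character(0),
             stringsAsFactors = FALSE)
}

# greedy collapse of overlapping hits (df has start/end/score in
# extended coordinates) to the best-scoring representative
.collapseOverlaps <- function(df) {
  df <- df[order(df$score, df$start), , drop = FALSE]
  kept <- logical(0)
  ks <- integer(0); ke <- integer(0)
  sel <- integer(0)
  for (k in seq_len(nrow(df))) {
    if (!length(sel) ||
        all(df$end[k] < ks | df$start[k] > ke)) {
      sel <- c(sel, k)
      ks <- c(ks, df$start[k]); ke <- c(ke, df$end[k])
    }
  }
  df[sort(sel), , drop = FALSE]
}

# pairing classes of one miRNA base against a vector of target bases
.pairClassVec <- function(mBase, tBases) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  out <- integer(length(tBases))  # 0 mism, 1 GU, 2 WC
  out[tBases == wc[[mBase]]] <- 2L
  if (mBase == "G") out[tBases == "T"] <- 1L
  if (mBase == "T") out[tBases == "G"] <- 1L
  out[tBases == ""] <- -1L  # out of range
  out
}

#' Detect endogenous target-mimic (miRNA sponge) sites
#'
#' Applies the three mimic rules (see \code{\link{mirnaParams}}): perfect
#' seed pairing at miRNA positions 2-8, a single bulge of 1-5 target
#' nucleotides opposite miRNA positions 9-11, and at most 4 combined
#' mismatches plus G:U pairs over the remaining positions.
#'
#' @inheritParams scanTargets
#' @return data.frame in the same shape as \code{\link{scanTargets}},
#'   with \code{kind = "mimic"}; \code{score} is the penalty score of the
#'   bulged alignment.
#' @export
detectTargetMimics <- function(mirnas, targets, param = mirnaParams(),
                               circular = FALSE) {
  mirnas <- .asSeqVector(mirnas)
  targets <- .asSeqVector(targets)
  circular <- rep_len(circular, length(targets))
  seedPos <- param$mimicSeed[1]:param$mimicSeed[2]
  insPoints <- param$mimicBulgeRegion[1]:(param$mimicBulgeRegion[2] - 1L)
  bulgeLens <- param$mimicBulgeLen[1]:param$mimicBulgeLen[2]
  dbl <- param$doubledRegion
  out <- list()
  for (ti in seq_along(targets)) {
    tlen <- nchar(targets[ti])
    for (mi in seq_along(mirnas)) {
      m <- mirnas[mi]
      M <- nchar(m)
      tseq <- targets[ti]
      if (circular[ti] && tlen > 1L)
        tseq <- paste0(tseq, substr(targets[ti], 1L,
                                    min(M + param$maxBulge - 1L, tlen)))
      N <- nchar(tseq)
      mChars <- strsplit(m, "")[[1L]]
      best <- NULL
      for (b in bulgeLens) {
        for (ins in insPoints) {
          # site end q: miRNA position 1 pairs target base q
          q <- seq_len(N)
          lenSite <- M + b
          valid <- q - lenSite + 1L >= 1L
          if (circular[ti]) valid <- valid & q - lenSite + 1L <= tlen
          cls <- matrix(-1L, nrow = M, ncol = N)
          for (i in seq_len(M)) {
            tpos <- q - (i - 1L) - ifelse(i > ins, b, 0L)
            tb <- ifelse(tpos >= 1L & tpos <= N,
                         substring(tseq, tpos, tpos), "")
            cls[i, ] <- .pairClassVec(mChars[i], tb)
          }
          seedOK <- colSums(cls[seedPos, , drop = FALSE] == 2L) ==
            length(seedPos)
          others <- setdiff(seq_len(M), seedPos)
          loose <- colSums(cls[others, , drop = FALSE] != 2L)
          inRange <- colSums(cls == -1L) == 0L
          hit <- which(valid & inRange & seedOK &
                         loose <= param$mimicMaxLoose)
          for (h in hit) {
            pen <- .mimicPenalty(cls[, h], ins, b, param)
            rec <- data.frame(
              mirna = names(mirnas)[mi], target = names(targets)[ti],
              start = ((h - lenSite) %% tlen) + 1L,
              end = ((h - 1L) %% tlen) + 1L,
              kind = "mimic", score = pen,
              pairing = .mimicPairing(cls[, h], ins, b),
              stringsAsFactors = FALSE)
            best[[length(best) + 1L]] <- rec
          }
        }
      }
      if (length(best)) {
        df <- do.call(rbind, best)
        df <- df[!duplicated(paste(df$start, df$end)), , drop = FALSE]
        df <- df[order(df$score, df$start), , drop = FALSE]
        # collapse overlapping mimic calls to the best-scoring one
        sel <- integer(0); ks <- integer(0); ke <- integer(0)
        for (k in seq_len(nrow(df))) {
          if (!length(sel) || all(df$end[k] < ks | df$start[k] > ke)) {
            sel <- c(sel, k); ks <- c(ks, df$start[k])
            ke <- c(ke, df$end[k])
          }
        }
        out[[length(out) + 1L]] <- df[sort(sel), , drop = FALSE]
      }
    }
  }
  res <- do.call(rbind, out) %||% .emptySites()
  rownames(res) <- NULL
  res
}

.mimicPenalty <- function(cls, ins, b, param) {
  M <- length(cls)
  mult <- ifelse(seq_len(M) >= param$doubledRegion[1] &
                   seq_len(M) <= param$doubledRegion[2],
                 param$doubledFactor, 1)
  pen <- sum(ifelse(cls == 2L, 0,
                    ifelse(cls == 1L, param$guPenalty,
                           param$mismatchPenalty)) * mult)
  bulgeMult <- if (ins + 1L >= param$doubledRegion[1] &&
                     ins + 1L <= param$doubledRegion[2])
    param$doubledFactor else 1
  pen + b * param$bulgePenalty * bulgeMult
}

.mimicPairing <- function(cls, ins, b) {
  sym <- ifelse(cls == 2L, "|", ifelse(cls == 1L, "o", "x"))
  paste0(paste(sym[seq_len(ins)], collapse = ""),
         paste(rep("-", b), collapse = ""),
         paste(sym[(ins + 1L):length(sym)], collapse = ""))
}

#' Predict miRNA sites on a set of targets (cleavage + mimic)
#'
#' Runs \code{\link{scanTargets}} and \code{\link{detectTargetMimics}}
#' and makes the classification exclusive per (miRNA, position): a
#' cleavage call at coordinates identical to a mimic call is dropped
#' (the cleavage-blocking bulge takes precedence).
#'
#' @inheritParams scanTargets
#' @return combined site data.frame.
#' @export
predictMirnaSites <- function(mirnas, targets, param = mirnaParams(),
                              circular = FALSE) {
  cleav <- scanTargets(mirnas, targets, param, circular)
  mim <- detectTargetMimics(mirnas, targets, param, circular)
  if (nrow(mim) && nrow(cleav)) {
    keyM <- paste(mim$mirna, mim$target, mim$start, mim$end)
    keyC <- paste(cleav$mirna, cleav$target, cleav$start, cleav$end)
    cleav <- cleav[!keyC %in% keyM, , drop = FALSE]
  }
  res <- rbind(cleav, mim)
  rownames(res) <- NULL
  .msg("mirna", "%d cleavage + %d mimic sites",
       sum(res$kind == "cleavage"), sum(res$kind == "mimic"))
  res
}

#' Write miRNA site predictions to TSV
#'
#' @param sites data.frame from \code{\link{predictMirnaSites}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMirnaSites <- function(sites, path) .writeTSV(sites, path)
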