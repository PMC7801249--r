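# plant miRNA target scoring, scanning and target-mimic rules

rcOf <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

mir21 <- "TCGGACCAGGCTTCATTCCCC"  # 21 nt, arbitrary plant-like miRNA

test_that("penalty scoring follows the plant convention", {
  targ <- rcOf(mir21)
  expect_equal(scoreSite(mir21, targ)$score, 0)
  expect_equal(scoreSite(mir21, targ)$pairing, strrep("|", 21))

  # G:U at miRNA position 15 (outside the doubled region): 0.5
  t15 <- targ
  i <- nchar(targ) - 14L  # target base opposite miRNA position 15
  stopifnot(substr(mir21, 15, 15) %in% c("A", "C"))
  # make a G:U pair: miRNA T pairs G / miRNA G pairs T; position 15
  # of this miRNA is "T"? choose position with T or G
  # (position 15 of mir21 is "A": use position 16, which is "T")
  i16 <- nchar(targ) - 15L
  substr(t15, i16, i16) <- "G"
  expect_equal(scoreSite(mir21, t15)$score, 0.5)

  # mismatch at miRNA position 5 (doubled): 2.0
  t5 <- targ
  i5 <- nchar(targ) - 4L
  old <- substr(t5, i5, i5)
  substr(t5, i5, i5) <- setdiff(c("A", "C"), c(old,
    chartr("ACGT", "TGCA", substr(mir21, 5, 5))))[1]
  expect_equal(scoreSite(mir21, t5)$score, 2)

  # U and T are equivalent
  expect_equal(scoreSite(gsub("T", "U", mir21),
                         gsub("T", "U", targ))$score, 0)

  # window length outside miRNA +/- maxBulge errors
  expect_error(scoreSite(mir21, substr(targ, 1, 10)), "window")
})

test_that("any single mismatch strictly increases a zero score", {
  targ <- rcOf(mir21)
  for (i in seq_len(nchar(targ))) {
    t2 <- targ
    old <- substr(t2, i, i)
    # substitute with a base that neither WC- nor GU-pairs
    mPos <- nchar(targ) - i + 1L
    mBase <- substr(mir21, mPos, mPos)
    badBases <- setdiff(c("A", "C", "G", "T"),
                        c(old, switch(mBase, G = "T", T = "G",
                                      character(0))))
    substr(t2, i, i) <- badBases[1]
    expect_gt(scoreSite(mir21, t2)$score, 0)
  }
})

test_that("scorer equals brute-force alignment enumeration", {
  set.seed(99)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:30) {
    M <- sample(18:22, 1)
    m <- paste(sample(bases, M, TRUE), collapse = "")
    # windows: mutated complements and random sequences, lengths
    # within the bulge envelope
    W <- M + sample(-3:3, 1)
    w <- if (rep %% 2) {
      base <- rcOf(m)
      if (W >= M) paste0(substr(base, 1, 5),
                         paste(sample(bases, W - M, TRUE),
                               collapse = ""),
                         substr(base, 6, M))
      else paste0(substr(base, 1, 3), substr(base, 3 + (M - W) + 1, M))
    } else paste(sample(bases, W, TRUE), collapse = "")
    got <- scoreSite(m, w)$score
    want <- oracleScore(m, w)
    expect_equal(got, want, info = paste(m, w))
  }
})

test_that("target scanning reports sub-cutoff sites and collapses
          overlaps", {
  set.seed(12)
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  targ <- paste0(filler(40), rcOf(mir21), filler(40))
  hits <- scanTargets(c(m = mir21), c(t = targ))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 41L)
  expect_equal(hits$end, 41L + 20L)
  expect_equal(hits$score, 0)
  expect_equal(hits$kind, "cleavage")

  # a target with no sub-cutoff windows yields nothing
  none <- scanTargets(c(m = mir21), c(t = filler(80)))
  expect_equal(nrow(none), 0L)
})

test_that("circular targets are scanned across the seam", {
  set.seed(13)
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  lin <- paste0(filler(30), rcOf(mir21), filler(30))
  # rotate so the site straddles position 1
  rot <- paste0(substr(lin, 42, nchar(lin)), substr(lin, 1, 41))
  linHit <- scanTargets(c(m = mir21), c(t = lin))
  expect_equal(nrow(linHit), 1L)
  circHit <- scanTargets(c(m = mir21), c(t = rot), circular = TRUE)
  expect_equal(nrow(circHit), 1L)
  expect_true(circHit$end < circHit$start)  # wrapped site
  expect_equal(circHit$score, 0)
  # without circular scanning the wrapped site is invisible
  expect_equal(nrow(scanTargets(c(m = mir21), c(t = rot))), 0L)
})

test_that("target mimics require the 9-11 bulge and perfect seed", {
  set.seed(14)
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  base <- rcOf(mir21)
  M <- nchar(mir21)
  # 3-nt bulge opposite miRNA positions 9-11: insert after the target
  # base pairing position 10 (positions counted from the 3' end of the
  # site)
  ins <- function(seqs, at, s) paste0(substr(s, 1, at),
                                      seqs, substr(s, at + 1, nchar(s)))
  mimicCore <- ins("TTT", M - 9L, base)
  targ <- paste0(filler(25), mimicCore, filler(25))
  mm <- detectTargetMimics(c(m = mir21), c(t = targ))
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$kind, "mimic")
  expect_match(mm$pairing, "\\|{8,}-{3}")

  # a perfect complement is a cleavage site, not a mimic
  perfect <- paste0(filler(25), base, filler(25))
  expect_equal(nrow(detectTargetMimics(c(m = mir21),
                                       c(t = perfect))), 0L)

  # bulge opposite the seed (positions 4-6) is rejected
  seedBulge <- paste0(filler(25), ins("TTT", M - 4L, base), filler(25))
  expect_equal(nrow(detectTargetMimics(c(m = mir21),
                                       c(t = seedBulge))), 0L)

  # seed mismatch is rejected even with a correct bulge
  broken <- mimicCore
  j <- nchar(broken) - 3L  # pairs miRNA position 4 (within seed 2-8)
  old <- substr(broken, j, j)
  substr(broken, j, j) <- setdiff(c("A", "C", "G", "T"), old)[1]
  targ2 <- paste0(filler(25), broken, filler(25))
  expect_equal(nrow(detectTargetMimics(c(m = mir21), c(t = targ2))),
               0L)
})

test_that("the cleavage/mimic classification is exclusive per site", {
  set.seed(15)
  filler <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
  base <- rcOf(mir21)
  M <- nchar(mir21)
  mimicCore <- paste0(substr(base, 1, M - 10L), "A",
                      substr(base, M - 9L, M))  # 1-nt bulge opp. 10-11
  targ <- paste0(filler(25), mimicCore, filler(25), base, filler(25))
  sites <- predictMirnaSites(c(m = mir21), c(t = targ))
  key <- paste(sites$start, sites$end)
  expect_equal(anyDuplicated(key), 0L)
  expect_setequal(unique(sites$kind), c("cleavage", "mimic"))
})
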