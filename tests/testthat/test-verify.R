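# pseudo-reference construction and junction verification

test_that("pseudoRef entries are donor flank + acceptor flank", {
  g <- toyGenome(c(c1 = "AAACCCGGGTTT"))
  cand <- data.frame(chrom = "c1", start = 4L, end = 9L, strand = "+")
  pr <- buildPseudoRef(g, cand, flank = 3L)
  expect_equal(pr$seq, "GGGCCC")
  expect_equal(pr$seam, 3L)
  expect_equal(nchar(pr$seq), 2L * pr$flank)
  expect_equal(pr$id, "c1:4|9(+)")

  # flank capped at the circle size
  cand2 <- data.frame(chrom = "c1", start = 4L, end = 7L, strand = "+")
  pr2 <- buildPseudoRef(g, cand2, flank = 100L)
  expect_equal(pr2$flank, 4L)
  expect_equal(nchar(pr2$seq), 8L)

  # minus strand entry is the reverse complement
  candM <- data.frame(chrom = "c1", start = 4L, end = 9L, strand = "-")
  prM <- buildPseudoRef(g, candM, flank = 3L)
  expect_equal(prM$seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GGGCCC"))))
})

test_that("verification enforces seam anchors and mismatch cap", {
  set.seed(31)
  chrom <- paste(sample(c("A", "C", "G", "T"), 600, TRUE),
                 collapse = "")
  g <- toyGenome(c(c1 = chrom))
  cand <- data.frame(chrom = "c1", start = 101L, end = 400L,
                     strand = "+")
  pr <- buildPseudoRef(g, cand, flank = 50L)
  seam <- pr$seam
  # read = the seam-centered 2x10 window: verified with 0 mismatches
  win <- substr(pr$seq, seam - 9L, seam + 10L)
  v <- verifyJunctions(Biostrings::DNAStringSet(c(ok = win)), pr)
  expect_equal(v$counts$verified_reads, 1L)
  expect_equal(v$results$mismatches, 0L)

  # reverse-complement orientation also verifies
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(win)))
  v2 <- verifyJunctions(Biostrings::DNAStringSet(c(rc = rc)), pr)
  expect_equal(v2$counts$verified_reads, 1L)

  # 3 substitutions in the seam window: rejected (cap 2)
  bad <- win
  flip <- function(s, i) {
    old <- substr(s, i, i)
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), old)[1]
    s
  }
  # place errors outside the seed region 1..20? the seam window is
  # exactly the check window, so hit positions 2, 5, 18
  for (i in c(2L, 5L, 18L)) bad <- flip(bad, i)
  v3 <- verifyJunctions(Biostrings::DNAStringSet(c(bad = bad)), pr)
  expect_equal(v3$counts$verified_reads, 0L)

  # read entirely donor-side of the seam: right anchor 0, rejected
  donorOnly <- substr(pr$seq, seam - 29L, seam)
  v4 <- verifyJunctions(Biostrings::DNAStringSet(c(d = donorOnly)), pr)
  expect_equal(v4$counts$verified_reads, 0L)
})

test_that("seeded verifier agrees with a brute-force all-window scan", {
  set.seed(77)
  for (rep in 1:5) {
    chrom <- paste(sample(c("A", "C", "G", "T"), 800, TRUE),
                   collapse = "")
    g <- toyGenome(c(c1 = chrom))
    cand <- data.frame(chrom = "c1", start = 201L, end = 500L,
                       strand = sample(c("+", "-"), 1))
    pr <- buildPseudoRef(g, cand, flank = 60L)  # entry length 120
    # reads: seam-spanning windows at several offsets, a colinear
    # genomic read, and a random read
    reads <- c(
      substr(pr$seq, pr$seam - 39L, pr$seam + 20L),
      substr(pr$seq, pr$seam - 10L, pr$seam + 49L),
      substr(chrom, 300, 359),
      paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""))
    names(reads) <- paste0("r", seq_along(reads))
    v <- verifyJunctions(Biostrings::DNAStringSet(reads), pr)
    got <- names(reads) %in% v$results$read_id
    want <- vapply(reads, oracleVerify, logical(1),
                   entrySeq = pr$seq, seam = pr$seam)
    expect_equal(unname(got), unname(want))
  }
})

test_that("finalize keeps candidates at the verified-read threshold", {
  gr <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(c(100L, 500L), c(300L, 900L)),
    strand = "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    n_reads = c(5L, 4L), signal = "GT-AG",
    offset_acceptor = 0L, offset_donor = 0L, circ_type = "exonic",
    flags = "", read_ids = IRanges::CharacterList(list("a", "b")),
    pe_support = c(5L, 4L))
  cands <- new("BackspliceSet", gr)
  ver <- list(counts = data.frame(
    id = c("c1:100|300(+)", "c1:500|900(+)"),
    verified_reads = c(5L, 1L)))
  out <- finalizeCircRNAs(cands, ver, minVerified = 2L)
  expect_equal(length(out), 1L)
  expect_equal(verifiedReads(out), 5L)
  # verified set is a subset of the candidate set
  expect_true(all(candKeys(out) %in% candKeys(cands)))
  # empty candidate input gives empty output
  empty <- finalizeCircRNAs(cands[0], list(counts = data.frame(
    id = character(0), verified_reads = integer(0))), 2L)
  expect_equal(length(empty), 0L)
})

test_that("simulated junctions with >=2 error-free reads all verify", {
  sim <- smallSim(seed = 23L)
  sr <- simSplitReads(sim)
  cands <- callBackspliceJunctions(sr, simGenome(sim), simModels(sim))
  pr <- buildPseudoRef(simGenome(sim), cands, flank = 100L)
  reads <- c(simReads(sim, 1L), simReads(sim, 2L))
  ver <- verifyJunctions(reads, pr)
  circs <- finalizeCircRNAs(cands, ver, minVerified = 2L)
  tru <- simTruth(sim)
  expect_true(all(tru$n_reads >= 2L))
  tk <- paste(tru$chrom, tru$start, tru$end, tru$strand)
  expect_true(all(tk %in% candKeys(circs)))
  # verification never creates candidates
  expect_true(all(candKeys(circs) %in% candKeys(cands)))
})
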