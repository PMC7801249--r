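# chiastic junction calling and plant-specific screening

test_that("chiastic geometry calls back-splices and rejects colinear", {
  # chiastic: earlier part of the read maps downstream
  seg <- rbind(segRow("r1", 0L, 1L, 50L, "c1", 1000L, 1049L, "+"),
               segRow("r1", 0L, 51L, 100L, "c1", 200L, 249L, "+"))
  cand <- chiasticCandidate(seg)
  expect_equal(cand$start, 200L)
  expect_equal(cand$end, 1049L)
  expect_equal(cand$strand, "+")

  # colinear split = ordinary splice junction
  seg2 <- rbind(segRow("r1", 0L, 1L, 50L, "c1", 200L, 249L, "+"),
                segRow("r1", 0L, 51L, 100L, "c1", 1000L, 1049L, "+"))
  expect_null(chiasticCandidate(seg2))

  # cross-chromosome excluded
  seg3 <- rbind(segRow("r1", 0L, 1L, 50L, "c1", 1000L, 1049L, "+"),
                segRow("r1", 0L, 51L, 100L, "c2", 200L, 249L, "+"))
  expect_null(chiasticCandidate(seg3))

  # cross-strand excluded
  seg4 <- rbind(segRow("r1", 0L, 1L, 50L, "c1", 1000L, 1049L, "+"),
                segRow("r1", 0L, 51L, 100L, "c1", 200L, 249L, "-"))
  expect_null(chiasticCandidate(seg4))

  # minus strand mirror: earlier part maps upstream
  seg5 <- rbind(segRow("r1", 0L, 1L, 50L, "c1", 200L, 249L, "-"),
                segRow("r1", 0L, 51L, 100L, "c1", 1000L, 1049L, "-"))
  cand5 <- chiasticCandidate(seg5)
  expect_equal(cand5$start, 200L)
  expect_equal(cand5$end, 1049L)
  expect_equal(cand5$strand, "-")
})

test_that("segment quality and overlap rules gate junction calling", {
  p <- detectionParams()
  # too many mismatches on one segment
  seg <- rbind(segRow("r1", 0L, 1L, 50L, "c1", 1000L, 1049L, "+", nm = 3L),
               segRow("r1", 0L, 51L, 100L, "c1", 200L, 249L, "+"))
  expect_null(chiasticCandidate(seg, p))
  # low alignment score
  seg2 <- rbind(segRow("r1", 0L, 1L, 50L, "c1", 1000L, 1049L, "+",
                       score = 30),
                segRow("r1", 0L, 51L, 100L, "c1", 200L, 249L, "+"))
  expect_null(chiasticCandidate(seg2, p))
  # 5 bp read overlap tolerated, 6 bp not
  seg3 <- rbind(segRow("r1", 0L, 1L, 52L, "c1", 1000L, 1051L, "+"),
                segRow("r1", 0L, 48L, 100L, "c1", 200L, 252L, "+"))
  expect_false(is.null(chiasticCandidate(seg3, p)))
  seg4 <- rbind(segRow("r1", 0L, 1L, 53L, "c1", 1000L, 1052L, "+"),
                segRow("r1", 0L, 47L, 100L, "c1", 200L, 253L, "+"))
  expect_null(chiasticCandidate(seg4, p))
})

test_that("splice signals classify on both strands and at edges", {
  # circle c1:10..20 with AG upstream and GT downstream
  s <- paste0(strrep("T", 7), "AG",           # 8..9 acceptor context
              strrep("C", 11),                # 10..20 circle
              "GT", strrep("T", 7))           # 21..22 donor
  g <- toyGenome(c(c1 = s))
  expect_equal(checkSpliceSignal(g, "c1", 10L, 20L, "+"), "GT-AG")
  # same fixture reverse-complemented is the minus-strand mirror
  L <- nchar(s)
  g2 <- toyGenome(c(c1 = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))))
  expect_equal(checkSpliceSignal(g2, "c1", L - 20L + 1L, L - 10L + 1L,
                                 "-"), "GT-AG")
  # GC-AG and AT-AC classes
  substr(s, 21, 22) <- "GC"
  expect_equal(checkSpliceSignal(toyGenome(c(c1 = s)), "c1", 10L, 20L,
                                 "+"), "GC-AG")
  s2 <- paste0(strrep("T", 7), "AC", strrep("C", 11), "AT",
               strrep("T", 7))
  expect_equal(checkSpliceSignal(toyGenome(c(c1 = s2)), "c1", 10L, 20L,
                                 "+"), "AT-AC")
  # non-canonical flanks
  s3 <- paste0(strrep("T", 9), strrep("C", 11), strrep("C", 9))
  expect_equal(checkSpliceSignal(toyGenome(c(c1 = s3)), "c1", 10L, 20L,
                                 "+"), "none")
  # chromosome edge: no exception, class none
  expect_equal(checkSpliceSignal(g, "c1", 1L, 20L, "+"), "none")
})

test_that("site adjustment finds the nearest canonical signal", {
  # GT-AG present only at donor offset +2
  s <- paste0(strrep("T", 7), "AG",            # acceptor at start 10
              strrep("C", 13),                 # circle 10..22
              "GT", strrep("T", 7))            # donor signal after 22
  g <- toyGenome(c(c1 = s))
  expect_equal(checkSpliceSignal(g, "c1", 10L, 20L, "+"), "none")
  adj <- adjustBackspliceSite(g, "c1", 10L, 20L, "+")
  expect_equal(adj$start, 10L)
  expect_equal(adj$end, 22L)
  expect_equal(adj$offset_donor, 2L)
  expect_equal(adj$offset_acceptor, 0L)
  expect_equal(adj$signal, "GT-AG")

  # exhaustive scan over the 121 offset pairs agrees
  grid <- expand.grid(da = -5:5, dd = -5:5)
  cls <- checkSpliceSignal(g, rep("c1", nrow(grid)), 10L + grid$da,
                           20L + grid$dd, rep("+", nrow(grid)))
  hits <- grid[cls != "none", ]
  expect_true(all(abs(hits$da) + abs(hits$dd) >= 2))
  expect_true(any(hits$da == 0 & hits$dd == 2))

  # signal already present: zero-shift identity
  adj0 <- adjustBackspliceSite(g, "c1", 10L, 22L, "+")
  expect_equal(adj0$offset_acceptor, 0L)
  expect_equal(adj0$offset_donor, 0L)
  expect_equal(adj0$signal, "GT-AG")

  # no signal anywhere in +/-5: unchanged, class none
  g3 <- toyGenome(c(c1 = strrep("T", 60)))
  adj3 <- adjustBackspliceSite(g3, "c1", 20L, 40L, "+")
  expect_equal(adj3$signal, "none")
  expect_equal(adj3$start, 20L)
  expect_equal(adj3$end, 40L)
})

test_that("paired-end consistency tests mate placement", {
  mate <- segRow("r1", 2L, 1L, 100L, "c1", 500L, 599L, "-")
  expect_true(pairedEndConsistent("c1", 200L, 1049L, "+", mate))
  far <- segRow("r1", 2L, 1L, 100L, "c1", 11000L, 11099L, "-")
  expect_false(pairedEndConsistent("c1", 200L, 1049L, "+", far))
  wrongChrom <- segRow("r1", 2L, 1L, 100L, "c2", 500L, 599L, "-")
  expect_false(pairedEndConsistent("c1", 200L, 1049L, "+", wrongChrom))
  expect_true(pairedEndConsistent("c1", 200L, 1049L, "+", NULL,
                                  singleEnd = TRUE))
  expect_false(pairedEndConsistent("c1", 200L, 1049L, "+", NULL))
})

test_that("length thresholds remove >100 kb and flag >20 kb spans", {
  reads <- function(id, s, e, n) {
    do.call(rbind, lapply(seq_len(n), function(i) rbind(
      segRow(paste0(id, i), 0L, 1L, 50L, "c1", e - 49L, e, "+"),
      segRow(paste0(id, i), 0L, 51L, 100L, "c1", s, s + 49L, "+"))))
  }
  seg <- rbind(reads("big", 1000L, 151000L, 3L),    # span 150001: drop
               reads("long", 1000L, 26000L, 3L),    # span 25001: flag
               reads("few", 40000L, 41000L, 1L))    # 1 read: drop
  sr <- splitReadSet(seg)
  out <- callBackspliceJunctions(sr)   # no genome: geometry+counts only
  expect_equal(length(out), 1L)
  expect_equal(GenomicRanges::start(out), 1000L)
  expect_equal(GenomicRanges::end(out), 26000L)
  expect_match(S4Vectors::mcols(out)$flags, "long")
  expect_equal(junctionReads(out), 3L)
})

test_that("candidate monotonicity in the junction-read threshold", {
  sim <- smallSim(seed = 9L)
  sr <- simSplitReads(sim)
  prev <- NULL
  for (mr in 1:3) {
    out <- callBackspliceJunctions(
      sr, simGenome(sim), simModels(sim),
      detectionParams(minJunctionReads = mr))
    if (!is.null(prev)) expect_true(all(candKeys(out) %in% prev))
    prev <- candKeys(out)
  }
})

test_that("candidates satisfy the structural invariants", {
  sim <- smallSim(seed = 13L)
  sr <- simSplitReads(sim)
  out <- callBackspliceJunctions(sr, simGenome(sim), simModels(sim))
  expect_true(all(GenomicRanges::start(out) < GenomicRanges::end(out)))
  expect_true(all(GenomicRanges::width(out) <=
                    detectionParams()$maxLength))
  expect_true(all(junctionReads(out) >= 2L))
  mc <- S4Vectors::mcols(out)
  expect_true(all(abs(mc$offset_acceptor) <= 5L))
  expect_true(all(abs(mc$offset_donor) <= 5L))
  expect_true(validObject(out))
})

test_that("strand symmetry: mirrored genome gives mirrored candidates", {
  sim <- smallSim(seed = 17L)
  sr <- simSplitReads(sim)
  g <- simGenome(sim)
  out <- callBackspliceJunctions(sr, g, NULL,
                                 detectionParams(requirePaired = FALSE))
  L <- Biostrings::width(g)[1]
  gm <- Biostrings::reverseComplement(g)
  names(gm) <- names(g)
  seg <- alignmentSegments(sr)
  segM <- seg
  segM$ref_start <- L - seg$ref_end + 1L
  segM$ref_end <- L - seg$ref_start + 1L
  segM$strand <- ifelse(seg$strand == "+", "-", "+")
  srM <- splitReadSet(segM, paired = isPaired(sr))
  outM <- callBackspliceJunctions(srM, gm, NULL,
                                  detectionParams(requirePaired = FALSE))
  mirrored <- paste(as.character(GenomicRanges::seqnames(out)),
                    L - GenomicRanges::end(out) + 1L,
                    L - GenomicRanges::start(out) + 1L,
                    ifelse(as.character(GenomicRanges::strand(out)) ==
                             "+", "-", "+"))
  expect_setequal(candKeys(outM), mirrored)
})

test_that("circRNA typing follows exon boundaries and introns", {
  m <- toyModels(list(
    t1 = list(chrom = "c1", strand = "+",
              exons = cbind(c(100L, 400L, 800L, 1200L),
                            c(200L, 600L, 1000L, 1400L)))))
  # boundaries of exon 2 start / exon 3 end (within tolerance)
  expect_equal(classifyCircType(m, "c1", 402L, 998L, "+"), "exonic")
  # wholly inside intron 1
  expect_equal(classifyCircType(m, "c1", 250L, 350L, "+"), "intronic")
  # outside any gene
  expect_equal(classifyCircType(m, "c1", 5000L, 6000L, "+"),
               "intergenic")
  # strand mismatch is not exonic
  expect_equal(classifyCircType(m, "c1", 400L, 1000L, "-"),
               "intergenic")
  # no annotation
  expect_equal(classifyCircType(NULL, "c1", 400L, 1000L, "+"),
               "intergenic")
})
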