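# synthetic-data generator and evaluation metrics

test_that("simulation is byte-deterministic under a fixed seed", {
  p <- simParams(nChrom = 1L, chromLen = 60000L, nGenes = 20L,
                 nCirc = 5L, nBsjReads = 60L, nBackground = 30L,
                 errorRate = 0.01)
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulation(simulateBenchmark(p, seed = 42L), d1)
  writeSimulation(simulateBenchmark(p, seed = 42L), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a different seed changes the output
  d3 <- tempfile()
  writeSimulation(simulateBenchmark(p, seed = 43L), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "genome.fa"))),
    unname(tools::md5sum(file.path(d3, "genome.fa")))))
})

test_that("every simulated intron carries a canonical splice signal", {
  ga <- simulateGenomeAnnotation(
    simParams(nChrom = 1L, chromLen = 80000L, nGenes = 25L,
              gcagFrac = 0.2, atacFrac = 0.1), seed = 3L)
  ex <- modelExons(ga$models)
  tx <- modelTranscripts(ga$models)
  chromStr <- as.character(ga$genome[[1]])
  ok <- c("GT-AG", "GC-AG", "AT-AC")
  for (tid in tx$transcript_id) {
    sub <- ex[S4Vectors::mcols(ex)$transcript_id == tid]
    sub <- sub[order(GenomicRanges::start(sub))]
    strand <- tx$strand[tx$transcript_id == tid]
    n <- length(sub)
    if (n < 2) next
    for (k in seq_len(n - 1)) {
      iStart <- GenomicRanges::end(sub)[k] + 1L
      iEnd <- GenomicRanges::start(sub)[k + 1] - 1L
      din <- c(substr(chromStr, iStart, iStart + 1L),
               substr(chromStr, iEnd - 1L, iEnd))
      if (strand == "-") din <- rev(revComp(din))
      expect_true(paste0(substr(din[1], 1, 2), "-",
                         din[2]) %in% ok,
                  info = paste(tid, k))
    }
  }
})

test_that("zero genes still yields a genome; missing fit errors", {
  ga <- simulateGenomeAnnotation(
    simParams(nChrom = 1L, chromLen = 5000L, nGenes = 0L), seed = 1L)
  expect_equal(length(ga$genome), 1L)
  expect_equal(length(ga$models), 0L)
  expect_error(simulateGenomeAnnotation(
    simParams(nChrom = 1L, chromLen = 4000L, nGenes = 10L), seed = 1L),
    "fit")
})

test_that("read totals are conserved with a floor of two per circle", {
  sim <- smallSim(seed = 19L)
  tru <- simTruth(sim)
  expect_equal(sum(tru$n_reads), 200L)
  expect_true(all(tru$n_reads >= 2L))
  # every circle contributes chiastic read groups to the SAM
  sr <- simSplitReads(sim)
  seg <- alignmentSegments(sr)
  for (i in seq_len(nrow(tru))) {
    own <- seg[startsWith(seg$read_id, paste0(tru$circ_id[i], "_r")) &
                 seg$mate == 1L, ]
    nSplit <- sum(table(own$read_id) == 2L)
    expect_gte(nSplit, 2L)
  }
})

test_that("error-free BSJ reads match their pseudoRef junction window",
          {
  sim <- smallSim(seed = 29L)
  tru <- simTruth(sim)
  pr <- buildPseudoRef(simGenome(sim), tru, flank = 100L)
  reads <- as.character(simReads(sim, 1L))
  isBsj <- grepl("^circ", names(simReads(sim, 1L)))
  circOf <- sub("_r\\d+$", "", names(simReads(sim, 1L)))
  hit <- 0L
  for (i in which(isBsj)) {
    e <- match(circOf[i], tru$circ_id)
    entry <- pr$seq[e]
    # exonic circles: only the seam-proximal part of the read must
    # match the genomic pseudoRef; check the seam window
    expect_true(oracleVerify(reads[i], entry, pr$seam[e]),
                info = names(reads)[i])
    hit <- hit + 1L
  }
  expect_gt(hit, 0L)
})

test_that("metric formulas reproduce the worked example and oracle", {
  m <- metricsFromCounts(92, 1, 8)
  expect_equal(m$sensitivity, 0.92)
  expect_equal(m$precision, 92 / 93, tolerance = 1e-12)
  expect_equal(m$f1, 184 / 193, tolerance = 1e-12)

  # degenerate inputs
  empty <- metricsFromCounts(0, 0, 10)
  expect_equal(c(empty$sensitivity, empty$precision, empty$f1),
               c(0, 0, 0))

  # randomized sets vs direct set arithmetic
  set.seed(20)
  for (rep in 1:20) {
    keys <- sprintf("c1:%d|%d(+)", 1:30, 101:130)
    tru <- data.frame(chrom = "c1", start = 1:30, end = 101:130,
                      strand = "+")[sample(30, 12), ]
    prd <- data.frame(chrom = "c1", start = 1:30, end = 101:130,
                      strand = "+")[sample(30, 15), ]
    m <- evaluatePredictions(prd, tru)
    tk <- paste(tru$start, tru$end)
    pk <- paste(prd$start, prd$end)
    expect_equal(m$tp, length(intersect(pk, tk)))
    expect_equal(m$fp, length(setdiff(pk, tk)))
    expect_equal(m$fn, length(setdiff(tk, pk)))
  }
})

test_that("perfect predictions give unit metrics; tolerance matching
          works", {
  tru <- data.frame(chrom = "c1", start = c(100L, 500L),
                    end = c(300L, 900L), strand = "+")
  m <- evaluatePredictions(tru, tru)
  expect_equal(c(m$sensitivity, m$precision, m$f1), c(1, 1, 1))
  off <- tru; off$start <- off$start + 3L
  expect_equal(evaluatePredictions(off, tru)$tp, 0L)
  expect_equal(evaluatePredictions(off, tru, tolerance = 5L)$tp, 2)
})
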