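# hypergeometric testing, BH adjustment, ceRNA pairs and network export

test_that("hypergeomSF matches closed forms and boundary cases", {
  expect_equal(hypergeomSF(0, 30, 10, 5), 1)
  expect_equal(hypergeomSF(5, 10, 5, 5), 1 / 252)
  expect_equal(hypergeomSF(6, 10, 5, 5), 0)
  expect_error(hypergeomSF(1, 10, 12, 5), "invalid")
  expect_error(hypergeomSF(-1, 10, 5, 5), "non-negative")
})

test_that("hypergeomSF agrees with exhaustive enumeration and phyper", {
  set.seed(8)
  for (rep in 1:200) {
    N <- sample(1:60, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:(min(K, n) + 1), 1)
    got <- hypergeomSF(k, N, K, n)
    expect_equal(got, oracleHyperSF(k, N, K, n), tolerance = 1e-12)
    expect_equal(got, phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric pmf sums to 1 and the tail is monotone", {
  for (N in c(5L, 17L, 40L, 60L)) {
    for (K in c(0L, N %/% 3, N)) {
      for (n in c(1L, N %/% 2, N)) {
        i <- 0:min(K, n)
        pmf <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
        expect_equal(sum(pmf), 1, tolerance = 1e-9)
        sf <- hypergeomSF(0:(min(K, n) + 1L), N, K, n)
        expect_true(all(diff(sf) <= 1e-12))
      }
    }
  }
})

test_that("BH adjustment: worked example, permutation invariance", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  set.seed(9)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  # step-up output is monotone after sorting
  q <- bhAdjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

siteDF <- function(target, mirnas) {
  data.frame(mirna = mirnas, target = target, start = 1L, end = 21L,
             kind = "cleavage", score = 0, pairing = "",
             stringsAsFactors = FALSE)
}

test_that("ceRNA pairs reproduce the hypergeometric example", {
  mirs <- paste0("miR", 1:10)
  circSites <- siteDF("circA", mirs[1:5])
  mrnaSites <- siteDF("geneX", mirs[1:5])
  pairs <- buildCernaPairs(circSites, mrnaSites, universe = mirs)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$k, 5L)
  expect_equal(pairs$N, 10L)
  expect_equal(pairs$p, 1 / 252, tolerance = 1e-12)
  expect_equal(pairs$q, pairs$p)
  expect_equal(pairs$shared_mirnas,
               paste(sort(mirs[1:5]), collapse = ","))
})

test_that("pairs without shared miRNAs are not tested; empty universe
          errors", {
  circSites <- siteDF("circA", c("miR1", "miR2"))
  mrnaSites <- siteDF("geneX", c("miR3", "miR4"))
  pairs <- buildCernaPairs(circSites, mrnaSites,
                           universe = paste0("miR", 1:6), alpha = 1)
  expect_equal(nrow(pairs), 0L)
  expect_error(buildCernaPairs(circSites, mrnaSites,
                               universe = character(0)), "universe")
})

test_that("pair grid p-values equal brute-force recomputation", {
  set.seed(10)
  mirs <- paste0("miR", 1:12)
  circSites <- do.call(rbind, lapply(paste0("circ", 1:3), function(cc)
    siteDF(cc, sample(mirs, sample(3:8, 1)))))
  mrnaSites <- do.call(rbind, lapply(paste0("g", 1:3), function(gg)
    siteDF(gg, sample(mirs, sample(3:8, 1)))))
  pairs <- buildCernaPairs(circSites, mrnaSites, universe = mirs,
                           alpha = 1)
  for (i in seq_len(nrow(pairs))) {
    cSet <- unique(circSites$mirna[circSites$target ==
                                     pairs$circ_id[i]])
    gSet <- unique(mrnaSites$mirna[mrnaSites$target ==
                                     pairs$mrna_id[i]])
    k <- length(intersect(cSet, gSet))
    expect_equal(pairs$k[i], k)
    expect_equal(pairs$p[i],
                 oracleHyperSF(k, 12, length(cSet), length(gSet)),
                 tolerance = 1e-12)
    expect_true(pairs$k[i] <= min(pairs$K[i], pairs$n[i]))
  }
  # invariants on the retained table
  expect_true(all(pairs$p > 0 & pairs$p <= 1))
  expect_true(all(pairs$q >= pairs$p - 1e-12))
})

test_that("network export writes typed edges deterministically", {
  pairs <- data.frame(circ_id = "circA", mrna_id = "geneX", k = 2L,
                      K = 2L, n = 2L, N = 10L, p = 0.01, q = 0.01,
                      shared_mirnas = "miR1,miR2",
                      stringsAsFactors = FALSE)
  sif <- tempfile(fileext = ".sif")
  exportNetwork(pairs, sif, "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), 4L)  # 2 circ-miR + 2 miR-mRNA
  expect_setequal(lines, c("circA binds miR1", "circA binds miR2",
                           "miR1 targets geneX",
                           "miR2 targets geneX"))
  # deterministic re-export
  sif2 <- tempfile(fileext = ".sif")
  exportNetwork(pairs, sif2, "sif")
  expect_identical(readLines(sif), readLines(sif2))
  # nodes are exactly the ids of retained pairs and shared miRNAs
  tsv <- tempfile(fileext = ".tsv")
  exportNetwork(pairs, tsv, "tsv")
  tab <- read.table(tsv, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  expect_setequal(unique(c(tab$V1, tab$V4)),
                  c("circA", "miR1", "miR2", "geneX"))
  # empty pairs: empty SIF, header-only TSV
  empty <- pairs[0, ]
  exportNetwork(empty, sif, "sif")
  expect_equal(length(readLines(sif)), 0L)
  exportNetwork(empty, tsv, "tsv")
  expect_equal(length(readLines(tsv)), 1L)
  expect_match(readLines(tsv), "^#")
})
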