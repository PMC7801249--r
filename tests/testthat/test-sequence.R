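# full-length circRNA sequence extraction

mkCircSet <- function(chrom, start, end, strand, type) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    n_reads = 3L, signal = "GT-AG", offset_acceptor = 0L,
    offset_donor = 0L, circ_type = type, flags = "",
    read_ids = IRanges::CharacterList(list("r")), pe_support = 3L,
    verified_reads = 3L)
  new("CircRNASet", new("BackspliceSet", gr),
      isoforms = backsplice:::.emptyIsoforms())
}

test_that("exonic isoforms splice exons and skip introns", {
  set.seed(3)
  chrom <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                 collapse = "")
  g <- toyGenome(c(c1 = chrom))
  # exons 100 nt and 150 nt with a 500 nt intron
  m <- toyModels(list(t1 = list(chrom = "c1", strand = "+",
                                exons = cbind(c(101L, 701L),
                                              c(200L, 850L)))))
  circ <- mkCircSet("c1", 101L, 850L, "+", "exonic")
  out <- extractFullLength(g, m, circ)
  iso <- isoformTable(out)
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$length, 250L)
  expect_equal(iso$n_exons, 2L)
  # brute-force cut-and-join on the genome string
  expect_equal(as.character(iso$seq),
               paste0(substr(chrom, 101, 200), substr(chrom, 701, 850)))
  expect_equal(iso$isoform, "c1:101|850(+)#1")
})

test_that("shared boundary exons with a differing internal exon give
          two isoforms", {
  set.seed(4)
  chrom <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                 collapse = "")
  g <- toyGenome(c(c1 = chrom))
  m <- toyModels(list(
    t1 = list(chrom = "c1", strand = "+", gene = "g1",
              exons = cbind(c(101L, 701L, 1401L),
                            c(200L, 800L, 1500L))),
    t2 = list(chrom = "c1", strand = "+", gene = "g1",
              exons = cbind(c(101L, 1401L), c(200L, 1500L)))))
  circ <- mkCircSet("c1", 101L, 1500L, "+", "exonic")
  out <- extractFullLength(g, m, circ)
  iso <- isoformTable(out)
  expect_equal(nrow(iso), 2L)
  expect_setequal(iso$length, c(300L, 200L))
  expect_equal(anyDuplicated(iso$isoform), 0L)
})

test_that("intergenic circles fall back to the genomic span", {
  set.seed(5)
  chrom <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE),
                 collapse = "")
  g <- toyGenome(c(c1 = chrom))
  circ <- mkCircSet("c1", 200L, 1049L, "+", "intergenic")
  out <- extractFullLength(g, NULL, circ)
  iso <- isoformTable(out)
  expect_equal(iso$length, 850L)
  expect_equal(iso$transcript_id, "genomic")
  expect_equal(as.character(iso$seq), substr(chrom, 200, 1049))
})

test_that("minus-strand extraction is the reverse complement of the
          plus-strand mirror", {
  set.seed(6)
  chrom <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                 collapse = "")
  g <- toyGenome(c(c1 = chrom))
  ex <- cbind(c(101L, 701L), c(200L, 850L))
  mPlus <- toyModels(list(t1 = list(chrom = "c1", strand = "+",
                                    exons = ex)))
  mMinus <- toyModels(list(t1 = list(chrom = "c1", strand = "-",
                                     exons = ex)))
  plus <- isoformTable(extractFullLength(
    g, mPlus, mkCircSet("c1", 101L, 850L, "+", "exonic")))
  minus <- isoformTable(extractFullLength(
    g, mMinus, mkCircSet("c1", 101L, 850L, "-", "exonic")))
  expect_equal(as.character(minus$seq),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(as.character(plus$seq)))))
})

test_that("circRNA FASTA writer emits one record per isoform", {
  set.seed(7)
  chrom <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE),
                 collapse = "")
  g <- toyGenome(c(c1 = chrom))
  circ <- mkCircSet("c1", 200L, 1049L, "+", "intergenic")
  out <- extractFullLength(g, NULL, circ)
  fa <- tempfile(fileext = ".fa")
  writeCircFasta(out, fa)
  back <- readGenome(fa)
  expect_equal(length(back), 1L)
  expect_equal(names(back), "c1:200|1049(+)#1")
  # empty set gives an empty file with no records
  writeCircFasta(mkCircSet("c1", 1L, 10L, "+", "exonic")[0], fa)
  expect_equal(length(readLines(fa)), 0L)
})
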