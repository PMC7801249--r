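#' Pipeline configuration
#'
#' Builds the flat configuration used by \code{\link{runPipeline}} and
#' the command-line interface: every tunable of the detection,
#' verification, miRNA, ceRNA/GO and simulation stages with its module
#' default, plus input/output paths.  Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return named list of class \code{backsplice_config}.
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    genome = NULL, gff3 = NULL, sam = NULL, fastq1 = NULL,
    fastq2 = NULL, mirna = NULL, mrna = NULL, gene2go = NULL,
    obo = NULL, out_dir = ".", seed = 1L, verbose = TRUE,
    # detection
    default_length = 20000L, max_length = 100000L, max_shift = 5L,
    min_reads = 2L, max_mismatch = 2L, min_score_frac = 0.8,
    # verification
    flank = NULL, min_anchor = 10L, verify_max_mismatch = 2L,
    min_verified = 2L,
    # miRNA / ceRNA / GO
    score_cutoff = 3, alpha = 0.05,
    # evaluation
    tolerance = 0L,
    # simulation
    sim_n_circ = 200L, sim_n_bsj_reads = 6000L, sim_read_len = 100L,
    sim_error_rate = 0, sim_n_background = 6000L, sim_paired = TRUE,
    sim_n_chrom = 4L, sim_chrom_len = 500000L, sim_n_genes = 500L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  defaults[names(over)] <- over
  structure(defaults, class = "backsplice_config")
}

#' Read a key: value configuration file
#'
#' Flat YAML-compatible subset: one \code{key: value} pair per line,
#' \code{#} comments allowed.  Values are coerced from the defaults'
#' types; unknown keys are rejected.
#'
#' @param path path to the configuration file.
#' @return a \code{\link{pipelineConfig}} list.
#' @export
readConfigFile <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl(":", lines, fixed = TRUE)
  if (any(bad))
    stop("configuration parse error at line: '", lines[bad][1L], "'",
         call. = FALSE)
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  parsed <- lapply(vals, function(v) {
    if (v %in% c("true", "TRUE", "yes")) return(TRUE)
    if (v %in% c("false", "FALSE", "no")) return(FALSE)
    if (v %in% c("null", "NULL", "~", "")) return(NULL)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  })
  names(parsed) <- keys
  do.call(pipelineConfig, parsed)
}

#' Run pipeline stages from a configuration
#'
#' Chains the four analysis stages as inputs allow: circRNA detection
#' (SAM + genome, annotation optional) with pseudo-reference
#' verification (FASTQ optional) and full-length extraction; miRNA
#' interaction prediction on the circRNA isoforms (miRNA FASTA);
#' ceRNA-pair testing and network export (mRNA FASTA); GO-based
#' function assignment (gene2go table).  Stage outputs are written
#' under \code{out_dir}; record counts are logged per stage.
#'
#' @param config a \code{\link{pipelineConfig}} list.
#' @return invisible list of in-memory stage results.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  options(backsplice.verbose = isTRUE(config$verbose))
  outDir <- config$out_dir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  if (is.null(config$sam) || is.null(config$genome))
    stop("usage error: detection requires --sam and --genome",
         call. = FALSE)
  genome <- readGenome(config$genome)
  models <- if (!is.null(config$gff3))
    readGeneModels(config$gff3, names(genome)) else NULL
  param <- detectionParams(defaultLength = config$default_length,
                           maxLength = config$max_length,
                           maxShift = config$max_shift,
                           minJunctionReads = config$min_reads,
                           maxMismatch = config$max_mismatch,
                           minScoreFrac = config$min_score_frac)
  reads <- c(config$fastq1, config$fastq2)
  circs <- detectCircRNAs(config$sam, genome, models,
                          reads = if (length(reads)) reads else NULL,
                          param = param, flank = config$flank,
                          minAnchor = config$min_anchor,
                          maxMismatch = config$verify_max_mismatch,
                          minVerified = config$min_verified)
  writeBacksplices(circs, file.path(outDir, "circrnas.tsv"))
  writeBacksplices(circs, file.path(outDir, "circrnas.bed"),
                   format = "bed")
  writeCircFasta(circs, file.path(outDir, "circrnas.fa"))
  writeIsoformTable(circs, file.path(outDir, "isoforms.tsv"))
  res <- list(circs = circs)

  if (!is.null(config$mirna) && length(circs)) {
    mirnas <- readGenome(config$mirna, rna = TRUE)
    iso <- isoformTable(circs)
    circSeqs <- setNames(as.character(iso$seq), iso$circ_id)
    circSeqs <- circSeqs[!duplicated(names(circSeqs))]
    mparam <- mirnaParams(scoreCutoff = config$score_cutoff)
    circSites <- predictMirnaSites(mirnas, circSeqs, mparam,
                                   circular = TRUE)
    writeMirnaSites(circSites, file.path(outDir, "circ_mirna_sites.tsv"))
    res$circSites <- circSites
    if (!is.null(config$mrna)) {
      mrnas <- readGenome(config$mrna, rna = TRUE)
      mrnaSites <- scanTargets(mirnas, mrnas, mparam)
      writeMirnaSites(mrnaSites,
                      file.path(outDir, "mrna_mirna_sites.tsv"))
      pairs <- buildCernaPairs(circSites, mrnaSites,
                               universe = names(mirnas),
                               alpha = config$alpha)
      writeCernaPairs(pairs, file.path(outDir, "cerna_pairs.tsv"))
      exportNetwork(pairs, file.path(outDir, "network.sif"),
                    format = "sif")
      exportNetwork(pairs, file.path(outDir, "network.tsv"),
                    format = "tsv")
      res$pairs <- pairs
      if (!is.null(config$gene2go)) {
        g2g <- readGeneGO(config$gene2go)
        obo <- if (!is.null(config$obo)) readOBO(config$obo) else NULL
        go <- annotateCircGO(pairs, g2g, obo, alpha = config$alpha)
        writeCircGO(go, file.path(outDir, "circ_go.tsv"))
        res$go <- go
      }
    }
  }
  invisible(res)
}
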