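#' Read a gene-to-GO annotation table
#'
#' Two-column tab-delimited input (gene id, GO term id); extra columns
#' are ignored, comment lines (\code{#}) skipped.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns \code{gene}, \code{term}.
#' @export
readGeneGO <- function(path) {
  df <- read.table(path, sep = "\t", comment.char = "#", header = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L)
    stop("gene2go file must have at least 2 tab-separated columns",
         call. = FALSE)
  out <- unique(data.frame(gene = as.character(df[[1L]]),
                           term = as.character(df[[2L]]),
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Read a minimal OBO ontology
#'
#' Parses only \code{id}, \code{name} and \code{is_a} from \code{[Term]}
#' stanzas; that is all the ancestor propagation needs.
#'
#' @param path path to an OBO file.
#' @return list with \code{terms} (data.frame \code{id}, \code{name})
#'   and \code{parents} (named list of is_a parent ids).
#' @export
readOBO <- function(path) {
  lines <- readLines(path)
  ids <- character(0); nms <- character(0)
  parents <- list()
  cur <- NULL
  inTerm <- FALSE
  for (ln in lines) {
    if (ln == "[Term]") { inTerm <- TRUE; cur <- NULL; next }
    if (grepl("^\\[", ln)) { inTerm <- FALSE; cur <- NULL; next }
    if (!inTerm) next
    if (startsWith(ln, "id: ")) {
      cur <- sub("^id: ", "", ln)
      ids <- c(ids, cur); nms <- c(nms, "")
      parents[[cur]] <- character(0)
    } else if (!is.null(cur) && startsWith(ln, "name: ")) {
      nms[length(nms)] <- sub("^name: ", "", ln)
    } else if (!is.null(cur) && startsWith(ln, "is_a: ")) {
      p <- sub("^is_a: ", "", ln)
      p <- sub("\\s*!.*$", "", p)
      parents[[cur]] <- c(parents[[cur]], p)
    }
  }
  list(terms = data.frame(id = ids, name = nms,
                          stringsAsFactors = FALSE),
       parents = parents)
}

# transitive closure over is_a: term -> all ancestors incl. itself
.termAncestors <- function(obo) {
  anc <- new.env(parent = emptyenv())
  getAnc <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    anc[[t]] <- t  # break cycles defensively
    ps <- obo$parents[[t]]
    res <- t
    for (p in ps) res <- union(res, getAnc(p))
    anc[[t]] <- res
    res
  }
  for (t in names(obo$parents)) getAnc(t)
  anc
}

#' Propagate GO annotations to ancestor terms
#'
#' Direct annotation to a child term counts for all its \code{is_a}
#' ancestors (the true-path rule).
#'
#' @param gene2go data.frame from \code{\link{readGeneGO}}.
#' @param obo ontology from \code{\link{readOBO}}.
#' @return propagated \code{gene}, \code{term} data.frame.
#' @export
propagateGO <- function(gene2go, obo) {
  anc <- .termAncestors(obo)
  rows <- lapply(seq_len(nrow(gene2go)), function(i) {
    t <- gene2go$term[i]
    terms <- if (!is.null(anc[[t]])) anc[[t]] else t
    data.frame(gene = gene2go$gene[i], term = terms,
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Assign candidate functions to circRNAs by GO enrichment of ceRNA
#' partners
#'
#' For every circRNA, the partner set is the mRNAs of its retained ceRNA
#' pairs.  Each GO term annotated to at least one partner is tested for
#' enrichment against the background of all annotated genes
#' (hypergeometric upper tail), p-values are BH-adjusted per circRNA,
#' and terms with \code{q <= alpha} are reported as the circRNA's
#' potential functions.  With an ontology, annotations are propagated to
#' ancestors before testing.
#'
#' @param pairs ceRNA pairs from \code{\link{buildCernaPairs}}.
#' @param gene2go data.frame from \code{\link{readGeneGO}}.
#' @param obo optional ontology from \code{\link{readOBO}}.
#' @param alpha FDR threshold (default 0.05).
#' @return named list (one element per circRNA with partners) of
#'   data.frames: \code{term}, \code{name}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p}, \code{q}.
#' @export
annotateCircGO <- function(pairs, gene2go, obo = NULL, alpha = 0.05) {
  if (!is.null(obo)) gene2go <- propagateGO(gene2go, obo)
  geneTerms <- split(gene2go$term, gene2go$gene)
  termGenes <- split(gene2go$gene, gene2go$term)
  background <- names(geneTerms)
  N <- length(background)
  termName <- if (!is.null(obo))
    setNames(obo$terms$name, obo$terms$id) else character(0)
  out <- list()
  for (ci in unique(pairs$circ_id)) {
    partners <- unique(pairs$mrna_id[pairs$circ_id == ci])
    partners <- intersect(partners, background)
    n <- length(partners)
    if (n == 0L) { out[[ci]] <- .emptyGOResult(); next }
    terms <- sort(unique(unlist(geneTerms[partners], use.names = FALSE)))
    res <- lapply(terms, function(t) {
      K <- length(termGenes[[t]])
      k <- length(intersect(termGenes[[t]], partners))
      data.frame(term = t,
                 name = if (t %in% names(termName)) termName[[t]] else "",
                 k = k, K = K, n = n, N = N,
                 p = hypergeomSF(k, N, K, n), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, res)
    df$q <- bhAdjust(df$p)
    df <- df[df$q <= alpha, , drop = FALSE]
    df <- df[order(df$p, df$term), , drop = FALSE]
    rownames(df) <- NULL
    out[[ci]] <- df
  }
  out
}

.emptyGOResult <- function() {
  data.frame(term = character(0), name = character(0), k = integer(0),
             K = integer(0), n = integer(0), N = integer(0),
             p = numeric(0), q = numeric(0), stringsAsFactors = FALSE)
}

#' Write per-circRNA GO results to TSV
#'
#' One table with a leading \code{circ_id} column.
#'
#' @param goResults list from \code{\link{annotateCircGO}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCircGO <- function(goResults, path) {
  rows <- lapply(names(goResults), function(ci) {
    df <- goResults[[ci]]
    if (nrow(df) == 0L) return(NULL)
    cbind(data.frame(circ_id = ci, stringsAsFactors = FALSE), df)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- cbind(data.frame(circ_id = character(0)), .emptyGOResult())
  .writeTSV(tab, path)
}
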