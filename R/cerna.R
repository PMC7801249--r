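#' Hypergeometric survival function P(X >= k)
#'
#' Upper tail of the hypergeometric distribution for the shared-miRNA
#' test: from a universe of \code{N} miRNAs of which \code{K} hit the
#' circRNA, \code{n} draws (miRNAs hitting the mRNA) share \code{k}.
#' Computed by summing the probability mass in log space (via
#' \code{lchoose}) for numerical stability; \code{P(X >= 0) = 1} and
#' \code{P(X >= k) = 0} for \code{k > min(K, n)}.
#'
#' @param k observed overlap (vectorised).
#' @param N universe size.
#' @param K successes in the universe.
#' @param n number of draws.
#' @return numeric vector of upper-tail probabilities.
#' @export
#' @examples
#' hypergeomSF(5, 10, 5, 5)  # 1/252
hypergeomSF <- function(k, N, K, n) {
  if (length(N) != 1L || length(K) != 1L || length(n) != 1L)
    stop("N, K, n must be scalars", call. = FALSE)
  if (is.na(N) || is.na(K) || is.na(n) || N < 0 || K < 0 || n < 0 ||
      K > N || n > N)
    stop("invalid hypergeometric parameters: need 0 <= K, n <= N",
         call. = FALSE)
  if (any(is.na(k)) || any(k < 0))
    stop("k must be non-negative", call. = FALSE)
  vapply(k, function(kk) {
    hi <- min(K, n)
    if (kk <= 0) return(1)
    if (kk > hi) return(0)
    i <- kk:hi
    lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    mx <- max(lp)
    min(1, exp(mx + log(sum(exp(lp - mx)))))
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' \code{stats::p.adjust}).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same order as \code{p}.
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Test circRNA-mRNA pairs for shared-miRNA enrichment
#'
#' For every circRNA-mRNA pair sharing at least one miRNA, the overlap of
#' their miRNA sets is tested against the hypergeometric null (universe =
#' all scanned miRNAs); p-values are BH-adjusted across all tested pairs
#' and pairs with \code{q <= alpha} are retained as ceRNA pairs.
#'
#' @param circSites site data.frame for circRNA targets (from
#'   \code{\link{predictMirnaSites}} or \code{\link{scanTargets}}).
#' @param mrnaSites site data.frame for mRNA targets.
#' @param universe character vector of all miRNA ids scanned (or a single
#'   integer giving the universe size).
#' @param alpha FDR threshold (default 0.05).
#' @param method multiple-testing method: \code{"BH"} (default),
#'   \code{"bonferroni"} or \code{"none"}.
#' @return data.frame: \code{circ_id}, \code{mrna_id}, \code{k},
#'   \code{K}, \code{n}, \code{N}, \code{p}, \code{q},
#'   \code{shared_mirnas} (comma-separated).
#' @export
buildCernaPairs <- function(circSites, mrnaSites, universe,
                            alpha = 0.05, method = c("BH", "bonferroni",
                                                     "none")) {
  method <- match.arg(method)
  if (missing(universe) || length(universe) == 0L)
    stop("empty miRNA universe", call. = FALSE)
  N <- if (is.numeric(universe) && length(universe) == 1L)
    as.integer(universe) else length(unique(universe))
  if (N < 1L) stop("empty miRNA universe", call. = FALSE)
  circSets <- lapply(split(circSites$mirna, circSites$target), unique)
  mrnaSets <- lapply(split(mrnaSites$mirna, mrnaSites$target), unique)
  rows <- list()
  for (ci in names(circSets)) {
    for (gi in names(mrnaSets)) {
      shared <- intersect(circSets[[ci]], mrnaSets[[gi]])
      if (length(shared) == 0L) next
      K <- length(circSets[[ci]]); n <- length(mrnaSets[[gi]])
      k <- length(shared)
      rows[[length(rows) + 1L]] <- data.frame(
        circ_id = ci, mrna_id = gi, k = k, K = K, n = n, N = N,
        p = hypergeomSF(k, N, K, n),
        shared_mirnas = paste(sort(shared), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(circ_id = character(0), mrna_id = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      shared_mirnas = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df$q <- switch(method,
                 BH = bhAdjust(df$p),
                 bonferroni = p.adjust(df$p, "bonferroni"),
                 none = df$p)
  df <- df[df$q <= alpha, , drop = FALSE]
  df <- df[order(df$p, df$circ_id, df$mrna_id),
           c("circ_id", "mrna_id", "k", "K", "n", "N", "p", "q",
             "shared_mirnas")]
  rownames(df) <- NULL
  .msg("cerna", "%d ceRNA pairs retained at q <= %g", nrow(df), alpha)
  df
}

#' Export a circRNA-miRNA-mRNA network
#'
#' Writes the network implied by the retained ceRNA pairs: for each
#' pair's shared miRNAs, an edge circRNA-miRNA (relation \code{binds})
#' and an edge miRNA-mRNA (relation \code{targets}).  SIF output loads
#' directly in Cytoscape; TSV output is an edge table with typed nodes.
#' Ordering is deterministic, so identical input re-exports
#' byte-identically.
#'
#' @param pairs data.frame from \code{\link{buildCernaPairs}}.
#' @param path output path.
#' @param format \code{"sif"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(pairs, path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  edges <- .networkEdges(pairs)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "sif") {
    if (nrow(edges))
      writeLines(paste(edges$source, edges$relation, edges$target), con)
  } else {
    writeLines("#source\tsource_type\trelation\ttarget\ttarget_type",
               con)
    if (nrow(edges))
      write.table(edges[, c("source", "source_type", "relation",
                            "target", "target_type")],
                  con, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
  }
  invisible(path)
}

.networkEdges <- function(pairs) {
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    mirs <- strsplit(pairs$shared_mirnas[i], ",", fixed = TRUE)[[1L]]
    for (m in mirs) {
      rows[[length(rows) + 1L]] <- data.frame(
        source = c(pairs$circ_id[i], m),
        source_type = c("circRNA", "miRNA"),
        relation = c("binds", "targets"),
        target = c(m, pairs$mrna_id[i]),
        target_type = c("miRNA", "mRNA"), stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, rows) %||%
    data.frame(source = character(0), source_type = character(0),
               relation = character(0), target = character(0),
               target_type = character(0), stringsAsFactors = FALSE)
  edges <- unique(edges)
  edges[order(edges$relation, edges$source, edges$target), ,
        drop = FALSE]
}

#' Write ceRNA pairs to TSV
#'
#' @param pairs data.frame from \code{\link{buildCernaPairs}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCernaPairs <- function(pairs, path) .writeTSV(pairs, path)
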