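# Turning fitted edge distributions into reportable maintainer networks:
# top-edge truncation by cumulative probability, Jensen-Shannon similarity,
# enrichment queries, gene assignment, and the hub-bias diagnostic.

#' Extract a CMN subgraph from a fitted edge distribution
#'
#' Edges are ranked by probability (descending, ties broken by token id);
#' the shortest prefix whose cumulative probability reaches `coverage` forms
#' the CMN. A coverage of 0.4-0.5 is the recommended operating range; 1.0
#' keeps every edge with positive probability.
#'
#' @param fit a `cmn_fit`, or a named numeric probability vector over edges.
#' @param k CMN index (required when `fit` is a `cmn_fit`).
#' @param coverage cumulative-probability target in (0, 1\].
#' @return an object of class `cmn`: `edges` (data frame edge / proteinA /
#'   proteinB / probability / cumulative), `nodes`, `beta`, `order`.
#' @export
extract_cmn <- function(fit, k = NULL, coverage = 0.5) {
  stopifnot(coverage > 0, coverage <= 1)
  if (inherits(fit, "cmn_fit")) {
    stopifnot(!is.null(k), k >= 1, k <= fit$K)
    beta <- fit$beta[k, ]
  } else {
    beta <- fit
    if (is.null(names(beta))) names(beta) <- as.character(seq_along(beta))
  }
  ord <- order(-beta, seq_along(beta))
  cum <- cumsum(beta[ord])
  n_sel <- if (coverage == 1) sum(beta > 0) else which(cum >= coverage)[1]
  sel <- ord[seq_len(n_sel)]
  lab <- names(beta)[sel]
  halves <- strsplit(lab, "|", fixed = TRUE)
  edges <- data.frame(edge = lab,
                      proteinA = vapply(halves, `[[`, character(1), 1),
                      proteinB = vapply(halves, function(h)
                        if (length(h) > 1) h[2] else h[1], character(1)),
                      probability = unname(beta[sel]),
                      cumulative = unname(cum[seq_len(n_sel)]),
                      stringsAsFactors = FALSE)
  structure(list(index = k, coverage = coverage, edges = edges,
                 nodes = unique(c(edges$proteinA, edges$proteinB)),
                 beta = beta, order = ord),
            class = "cmn")
}

#' @export
print.cmn <- function(x, ...) {
  cat("CMN", if (!is.null(x$index)) x$index else "", ": ",
      nrow(x$edges), " edges over ", length(x$nodes),
      " proteins (coverage ", x$coverage, ")\n", sep = "")
  print(utils::head(x$edges[, c("edge", "probability", "cumulative")], 10),
        row.names = FALSE)
  if (nrow(x$edges) > 10) cat("  ...\n")
  invisible(x)
}

#' Jensen-Shannon similarity between two edge distributions
#'
#' `sim(p, q) = 1 - JS(p, q)` with
#' `JS(p, q) = (D(p, m) + D(q, m)) / 2`, `m = (p + q) / 2`, and KL terms in
#' base-2 logarithms (so the similarity lies exactly in \[0, 1\]); the
#' convention `0 * log(0 / x) = 0` applies.
#'
#' @param p,q probability vectors over the same vocabulary (each sums to 1).
#' @return similarity in \[0, 1\]; 1 for identical distributions, 0 for
#'   disjoint supports.
#' @export
cmn_similarity <- function(p, q) {
  if (length(p) != length(q)) stop("vocabulary mismatch", call. = FALSE)
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q)))
    stop("vocabulary mismatch", call. = FALSE)
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  js <- (kl(p) + kl(q)) / 2
  1 - min(max(js, 0), 1)
}

#' Pairwise CMN similarity matrix
#' @param fit a `cmn_fit`, or a K x V matrix of edge distributions (rows).
#' @return symmetric K x K matrix of Jensen-Shannon similarities, unit
#'   diagonal.
#' @export
similarity_matrix <- function(fit) {
  beta <- if (inherits(fit, "cmn_fit")) fit$beta else fit
  k <- nrow(beta)
  sim <- diag(1, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        sim[i, j] <- sim[j, i] <- cmn_similarity(beta[i, ], beta[j, ])
      }
    }
  }
  dimnames(sim) <- list(rownames(beta), rownames(beta))
  if (is.null(rownames(beta)))
    dimnames(sim) <- rep(list(paste0("CMN", seq_len(k))), 2)
  sim
}

#' Interactions dominated by one CMN
#'
#' Returns the interactions whose mixing proportion for CMN `k` exceeds
#' `min_enrichment` (strictly).
#'
#' @param theta interactions x CMNs proportion matrix (or a `cmn_fit`).
#' @param k CMN index.
#' @param min_enrichment strict lower bound on theta (default 0.5).
#' @return character vector of interaction ids.
#' @export
top_interactions <- function(theta, k, min_enrichment = 0.5) {
  if (inherits(theta, "cmn_fit")) theta <- theta$theta
  rownames(theta)[theta[, k] > min_enrichment]
}

#' Genes controlled by a CMN
#'
#' For every interaction enriched for CMN `k` (see [top_interactions]),
#' scans a window of `window` bp around both anchor centers and returns the
#' genes whose annotation interval overlaps either window by at least 1 bp.
#'
#' @param interactions a `cmn_interactions` data frame.
#' @param genes gene annotation data frame with columns `chrom`, `start`,
#'   `end`, `name` (e.g. from a BED4 file via `read_bed3`-style parsing).
#' @param theta interactions x CMNs matrix (or `cmn_fit`).
#' @param k CMN index.
#' @param window half-width around each anchor center (default 2500 bp).
#' @param min_enrichment strict theta cutoff (default 0.5).
#' @return sorted character vector of unique gene names.
#' @export
assign_genes <- function(interactions, genes, theta, k,
                         window = 2500, min_enrichment = 0.5) {
  ids <- top_interactions(theta, k, min_enrichment)
  sel <- interactions[interactions$id %in% ids, , drop = FALSE]
  if (!nrow(sel)) return(character(0))
  hits <- character(0)
  for (i in seq_len(nrow(sel))) {
    for (side in 1:2) {
      chrom <- sel[[paste0("chrom", side)]][i]
      w <- anchor_window(sel[[paste0("start", side)]][i],
                         sel[[paste0("end", side)]][i], window)
      same <- genes$chrom == chrom
      ov <- same & .overlaps(genes$start, genes$end, w$start, w$end)
      hits <- c(hits, genes$name[ov])
    }
  }
  sort(unique(hits))
}

#' Hub-bias diagnostic for a CMN
#'
#' Correlates each CMN protein's degree inside the truncated CMN subgraph
#' with its degree in the background reference PPI. High correlation flags
#' CMNs that may be artifacts of shortest paths attracted to hub proteins.
#'
#' @param cmn a `cmn` object (see [extract_cmn]).
#' @param ref the reference PPI (igraph).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return the correlation coefficient.
#' @export
degree_bias <- function(cmn, ref, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(cmn, "cmn"))
  nodes <- intersect(cmn$nodes, igraph::V(ref)$name)
  if (length(nodes) < 3) stop("degree_bias needs >= 3 CMN nodes in the ",
                              "reference PPI", call. = FALSE)
  sub <- igraph::graph_from_edgelist(
    as.matrix(cmn$edges[, c("proteinA", "proteinB")]), directed = FALSE)
  d_cmn <- igraph::degree(sub)[nodes]
  d_ref <- igraph::degree(ref)[nodes]
  if (stats::sd(d_cmn) == 0 || stats::sd(d_ref) == 0) {
    stop("degree correlation undefined: constant degrees", call. = FALSE)
  }
  stats::cor(d_cmn, d_ref, method = method)
}
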