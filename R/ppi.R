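# Context-specific reference PPI: physical interactions restricted to
# nuclear proteins whose genes are co-expressed. Co-expression follows the
# weighted-network recipe: |Pearson correlation|^soft_power adjacency,
# unsigned topological overlap, median-connectivity node filter, then
# binarization at adjacency_cutoff.

#' Soft-threshold co-expression adjacency
#'
#' Raises the absolute Pearson correlation between gene expression profiles
#' to the power `soft_power` (the weighted co-expression "soft threshold";
#' typical values 5-6 in breast / erythroleukemia cell-line data).
#'
#' @param expr numeric matrix, genes in rows, >= 3 sample columns.
#' @param soft_power exponent >= 1 applied to |correlation|.
#' @return symmetric matrix of weights in \[0,1\] with zero diagonal.
#' @export
soft_threshold_adjacency <- function(expr, soft_power) {
  stopifnot(is.matrix(expr), soft_power >= 1)
  if (ncol(expr) < 3) stop("need >= 3 samples for correlation", call. = FALSE)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression for gene: ", rownames(expr)[sds == 0][1],
         call. = FALSE)
  }
  w <- abs(stats::cor(t(expr)))^soft_power
  diag(w) <- 0
  w
}

#' Unsigned topological overlap matrix
#'
#' `TOM_ij = (sum_u w_iu w_uj + w_ij) / (min(k_i, k_j) + 1 - w_ij)` with
#' `k_i = sum_u w_iu`; diagonal 1. Measures how much two nodes share
#' neighbourhoods in the weighted co-expression graph.
#'
#' @param w symmetric weight matrix, zero diagonal, entries in \[0,1\].
#' @return TOM matrix, entries in \[0,1\].
#' @export
topological_overlap <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (any(abs(diag(w)) > 0)) stop("weight matrix must have zero diagonal",
                                  call. = FALSE)
  k <- rowSums(w)
  num <- w %*% w + w
  den <- outer(k, k, pmin) + 1 - w
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(w)
  tom
}

#' Drop low-connectivity genes
#'
#' Node connectivity is the TOM row sum (diagonal excluded). Genes whose
#' connectivity falls below the given quantile of all connectivities (the
#' median by default) are removed; ties at the threshold are retained.
#'
#' @param tom topological overlap matrix.
#' @param connectivity_quantile quantile in (0,1), default 0.5.
#' @return character vector of retained gene names.
#' @export
filter_low_connectivity <- function(tom, connectivity_quantile = 0.5) {
  stopifnot(connectivity_quantile > 0, connectivity_quantile < 1)
  conn <- rowSums(tom) - diag(tom)
  thr <- stats::quantile(conn, connectivity_quantile, names = FALSE)
  rownames(tom)[conn >= thr]
}

#' Co-expression configuration
#' @param soft_power soft-threshold exponent (>= 1).
#' @param connectivity_quantile connectivity filter quantile, default 0.5.
#' @param adjacency_cutoff binarization cutoff on the soft-power adjacency,
#'   default 0.5.
#' @param connectivity_on `"tom"` (default) or `"adjacency"`: which row sums
#'   define connectivity for the quantile filter.
#' @return a list of class `coexpression_config`.
#' @export
coexpression_config <- function(soft_power = 5, connectivity_quantile = 0.5,
                                adjacency_cutoff = 0.5,
                                connectivity_on = c("tom", "adjacency")) {
  stopifnot(soft_power >= 1,
            connectivity_quantile > 0, connectivity_quantile < 1,
            adjacency_cutoff > 0, adjacency_cutoff < 1)
  structure(list(soft_power = soft_power,
                 connectivity_quantile = connectivity_quantile,
                 adjacency_cutoff = adjacency_cutoff,
                 connectivity_on = match.arg(connectivity_on)),
            class = "coexpression_config")
}

#' Build the context-specific reference PPI
#'
#' Restricts a physical PPI to nuclear proteins, computes the soft-threshold
#' co-expression network on the genes shared with the expression matrix,
#' filters low-connectivity genes, binarizes the adjacency at
#' `adjacency_cutoff`, and keeps only the physical edges whose endpoints are
#' co-expressed. Isolated nodes are dropped. Filtering never adds edges.
#'
#' @param ppi physical PPI (igraph, e.g. from [read_ppi]).
#' @param expr expression matrix (genes x samples); gene names must match
#'   protein names.
#' @param nuclear character vector of nuclear-localized proteins, or `NULL`
#'   to skip the localization filter.
#' @param cfg a [coexpression_config].
#' @return the reference PPI as an igraph graph.
#' @export
build_reference <- function(ppi, expr, nuclear = NULL,
                            cfg = coexpression_config()) {
  stopifnot(inherits(cfg, "coexpression_config"))
  nodes <- igraph::V(ppi)$name
  if (!is.null(nuclear)) nodes <- intersect(nodes, nuclear)
  g <- igraph::induced_subgraph(ppi, intersect(igraph::V(ppi)$name, nodes))
  genes <- intersect(igraph::V(g)$name, rownames(expr))
  if (length(genes) < 3) stop("fewer than 3 PPI proteins have expression data",
                              call. = FALSE)
  w <- soft_threshold_adjacency(expr[genes, , drop = FALSE], cfg$soft_power)
  tom <- topological_overlap(w)
  kept <- if (cfg$connectivity_on == "tom") {
    filter_low_connectivity(tom, cfg$connectivity_quantile)
  } else {
    conn <- rowSums(w)
    thr <- stats::quantile(conn, cfg$connectivity_quantile, names = FALSE)
    rownames(w)[conn >= thr]
  }
  w <- w[kept, kept, drop = FALSE]
  el <- igraph::as_edgelist(g)
  ok <- el[, 1] %in% kept & el[, 2] %in% kept
  ok[ok] <- w[cbind(el[ok, 1], el[ok, 2])] >= cfg$adjacency_cutoff
  if (!any(ok)) stop("reference PPI is empty; loosen adjacency_cutoff or ",
                     "soft_power", call. = FALSE)
  ref <- igraph::graph_from_edgelist(el[ok, , drop = FALSE], directed = FALSE)
  igraph::simplify(ref)
}
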