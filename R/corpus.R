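# From loops to bags of edges: each ChIA-PET interaction recruits the TFs
# whose peaks fall in a window around its two anchor centers; every
# cross-anchor TF pair is connected through ALL unweighted shortest paths in
# the reference PPI, and each reference edge is counted once per shortest
# path that traverses it. The resulting multisets of edges ("bags") form the
# corpus handed to the HDP.

#' Window around the center of a genomic interval
#'
#' Peak recruitment and gene assignment both look at a fixed flank around
#' the anchor center: `c = floor((start + end) / 2)`, window
#' `[max(0, c - flank), c + flank)`.
#'
#' @param start,end 0-based half-open interval coordinates (vectorized).
#' @param flank half-width in bp (> 0).
#' @return a list with vectors `start` and `end`.
#' @export
anchor_window <- function(start, end, flank) {
  if (any(flank <= 0)) stop("flank must be > 0", call. = FALSE)
  ctr <- (start + end) %/% 2
  list(start = pmax(0L, ctr - as.integer(flank)),
       end = ctr + as.integer(flank))
}

# half-open interval overlap of >= 1 bp
.overlaps <- function(s1, e1, s2, e2) pmax(s1, s2) < pmin(e1, e2)

peak_hits_window <- function(peaks_tf, chrom, wstart, wend) {
  same <- peaks_tf$chrom == chrom
  any(same & .overlaps(peaks_tf$start[same], peaks_tf$end[same], wstart, wend))
}

#' TFs recruited at the two anchors of an interaction
#'
#' A TF is assigned to an anchor when any of its peaks overlaps the anchor's
#' center window by at least 1 bp (half-open semantics).
#'
#' @param interaction one row of a `cmn_interactions` data frame.
#' @param peaks a `cmn_peaks` list from [read_peaks].
#' @param flank window half-width in bp (default 1500, the typical enhancer
#'   size).
#' @return list with character vectors `tfs_A` and `tfs_B`.
#' @export
assign_tfs <- function(interaction, peaks, flank = 1500) {
  wA <- anchor_window(interaction$start1, interaction$end1, flank)
  wB <- anchor_window(interaction$start2, interaction$end2, flank)
  tfs <- names(peaks)
  hitA <- vapply(peaks, peak_hits_window, logical(1),
                 interaction$chrom1, wA$start, wA$end)
  hitB <- vapply(peaks, peak_hits_window, logical(1),
                 interaction$chrom2, wB$start, wB$end)
  list(tfs_A = tfs[hitA], tfs_B = tfs[hitB])
}

# BFS from src over an adjacency list; returns geodesic distances and
# shortest-path counts (sigma) to every node. adj: list of integer vectors.
bfs_sigma <- function(adj, n, src) {
  dist <- rep.int(NA_integer_, n)
  sigma <- numeric(n)
  dist[src] <- 0L
  sigma[src] <- 1
  frontier <- src
  d <- 0L
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (is.na(dist[v])) {
          dist[v] <- d + 1L
          nxt <- c(nxt, v)
          sigma[v] <- sigma[v] + sigma[u]
        } else if (dist[v] == d + 1L) {
          sigma[v] <- sigma[v] + sigma[u]
        }
      }
    }
    frontier <- unique(nxt)
    d <- d + 1L
  }
  list(dist = dist, sigma = sigma)
}

graph_adjacency_list <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (r in seq_len(nrow(el))) {
    u <- el[r, 1]; v <- el[r, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  list(adj = adj, el = el, names = igraph::V(g)$name, n = n)
}

#' Count shortest paths through each edge between two nodes
#'
#' For an unweighted graph, every edge (u,v) lying on a geodesic from `s` to
#' `t` (i.e. `d(s,u) + 1 + d(v,t) = d(s,t)`) is counted
#' `sigma_s(u) * sigma_t(v)` times — exactly the number of distinct shortest
#' s-t paths that traverse it.
#'
#' @param g igraph graph.
#' @param s,t node names.
#' @return named numeric vector: `"A|B"` edge keys to path counts (empty if
#'   `s == t` or no path exists).
#' @export
shortest_path_edge_counts <- function(g, s, t) {
  ga <- graph_adjacency_list(g)
  si <- match(s, ga$names); ti <- match(t, ga$names)
  if (is.na(si) || is.na(ti)) stop("node not in graph", call. = FALSE)
  if (si == ti) return(stats::setNames(numeric(0), character(0)))
  bs <- bfs_sigma(ga$adj, ga$n, si)
  if (is.na(bs$dist[ti])) return(stats::setNames(numeric(0), character(0)))
  bt <- bfs_sigma(ga$adj, ga$n, ti)
  .edge_counts_pair(ga, bs, bt, bs$dist[ti])
}

.edge_counts_pair <- function(ga, bs, bt, dst) {
  el <- ga$el
  u <- el[, 1]; v <- el[, 2]
  fwd <- !is.na(bs$dist[u]) & !is.na(bt$dist[v]) &
    bs$dist[u] + 1L + bt$dist[v] == dst
  rev <- !is.na(bs$dist[v]) & !is.na(bt$dist[u]) &
    bs$dist[v] + 1L + bt$dist[u] == dst
  cnt <- numeric(nrow(el))
  cnt[fwd] <- cnt[fwd] + bs$sigma[u[fwd]] * bt$sigma[v[fwd]]
  cnt[rev] <- cnt[rev] + bs$sigma[v[rev]] * bt$sigma[u[rev]]
  keep <- cnt > 0
  nm <- edge_key(ga$names[u[keep]], ga$names[v[keep]])
  stats::setNames(cnt[keep], nm)
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Local PPI network of one interaction as a bag of edges
#'
#' Connects every TF recruited at anchor A to every TF recruited at anchor B
#' through all shortest paths in the reference PPI; the multiplicity of each
#' reference edge is the number of shortest paths traversing it, summed over
#' cross-anchor pairs. TFs absent from the reference are dropped; a TF bound
#' on both sides contributes only through pairs with the other side (the
#' zero-length self pair has no edges).
#'
#' @param tfs_A,tfs_B character vectors of TFs at the two anchors.
#' @param ref reference PPI (igraph).
#' @return named numeric vector of edge-key counts (possibly empty).
#' @export
build_local_network <- function(tfs_A, tfs_B, ref) {
  ga <- graph_adjacency_list(ref)
  A <- unique(match(tfs_A, ga$names)); A <- A[!is.na(A)]
  B <- unique(match(tfs_B, ga$names)); B <- B[!is.na(B)]
  if (!length(A) || !length(B)) return(stats::setNames(numeric(0), character(0)))
  bfsA <- lapply(A, function(s) bfs_sigma(ga$adj, ga$n, s))
  bfsB <- lapply(B, function(t) bfs_sigma(ga$adj, ga$n, t))
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      if (A[i] == B[j]) next
      dst <- bfsA[[i]]$dist[B[j]]
      if (is.na(dst)) next
      cnt <- .edge_counts_pair(ga, bfsA[[i]], bfsB[[j]], dst)
      for (e in names(cnt)) {
        acc[[e]] <- (if (is.null(acc[[e]])) 0 else acc[[e]]) + cnt[[e]]
      }
    }
  }
  keys <- ls(acc)
  stats::setNames(vapply(keys, function(e) acc[[e]], numeric(1)), keys)
}

new_corpus <- function(vocabulary, bags, info = list()) {
  stopifnot(is.data.frame(vocabulary),
            all(c("token_id", "proteinA", "proteinB") %in% names(vocabulary)))
  if (any(lengths(bags) == 0)) stop("corpus must not contain empty bags",
                                    call. = FALSE)
  tok <- unlist(lapply(bags, names), use.names = FALSE)
  if (!all(as.integer(tok) %in% vocabulary$token_id)) {
    stop("bag token outside vocabulary", call. = FALSE)
  }
  structure(list(vocabulary = vocabulary, bags = bags, info = info),
            class = "cmn_corpus")
}

edge_labels <- function(vocabulary) {
  edge_key(vocabulary$proteinA, vocabulary$proteinB)
}

#' @export
print.cmn_corpus <- function(x, ...) {
  sizes <- vapply(x$bags, sum, numeric(1))
  cat("Bag-of-edges corpus: ", length(x$bags), " interactions, ",
      nrow(x$vocabulary), " edge tokens\n", sep = "")
  cat("  tokens per bag: median ", stats::median(sizes),
      " [", min(sizes), "-", max(sizes), "]\n", sep = "")
  if (!is.null(x$info$dropped_empty)) {
    cat("  interactions dropped (empty local network): ",
        x$info$dropped_empty, "\n", sep = "")
  }
  invisible(x)
}

#' Build the bag-of-edges corpus for a set of interactions
#'
#' Runs [assign_tfs] and [build_local_network] over every interaction and
#' assembles the shared vocabulary of observed reference-PPI edges.
#' Interactions recruiting no TF on either side, or whose local network is
#' empty (no connected cross-anchor pair), are dropped and counted.
#'
#' @param interactions a `cmn_interactions` data frame.
#' @param peaks a `cmn_peaks` list.
#' @param ref reference PPI (igraph).
#' @param flank anchor-window half-width in bp (default 1500).
#' @return a `cmn_corpus`: vocabulary (token_id, proteinA, proteinB), named
#'   list of bags (token_id -> count), and provenance info.
#' @export
build_corpus <- function(interactions, peaks, ref, flank = 1500) {
  raw <- vector("list", nrow(interactions))
  for (i in seq_len(nrow(interactions))) {
    tf <- assign_tfs(interactions[i, ], peaks, flank)
    raw[[i]] <- build_local_network(tf$tfs_A, tf$tfs_B, ref)
  }
  names(raw) <- interactions$id
  keep <- lengths(raw) > 0
  dropped <- sum(!keep)
  raw <- raw[keep]
  if (!length(raw)) stop("all interactions produced empty local networks",
                         call. = FALSE)
  keys <- sort(unique(unlist(lapply(raw, names), use.names = FALSE)))
  vocab <- data.frame(token_id = seq_along(keys),
                      proteinA = sub("\\|.*$", "", keys),
                      proteinB = sub("^.*\\|", "", keys),
                      stringsAsFactors = FALSE)
  bags <- lapply(raw, function(bag) {
    stats::setNames(as.integer(bag), as.character(match(names(bag), keys)))
  })
  new_corpus(vocab, bags,
             info = list(flank = flank, dropped_empty = dropped,
                         n_input = nrow(interactions)))
}

#' Remove over- and under-represented edges from a corpus
#'
#' Edges appearing in more than `max_frac` (hub/shortest-path artifacts) or
#' fewer than `min_frac` (noise) of the bags — strict inequalities on both
#' sides — are removed from every bag and from the vocabulary, which is
#' re-indexed densely. Bags emptied by the filter are dropped and counted.
#'
#' @param corpus a `cmn_corpus`.
#' @param min_frac minimum document frequency (default 0.05).
#' @param max_frac maximum document frequency (default 0.80).
#' @return the filtered `cmn_corpus`; `info$token_map` maps old to new
#'   token ids, `info$dropped_bags` counts emptied bags.
#' @export
filter_outlier_edges <- function(corpus, min_frac = 0.05, max_frac = 0.80) {
  stopifnot(min_frac >= 0, max_frac <= 1, min_frac < max_frac)
  nbags <- length(corpus$bags)
  tok <- unlist(lapply(corpus$bags, names), use.names = FALSE)
  df_count <- table(factor(as.integer(tok),
                           levels = corpus$vocabulary$token_id))
  df <- as.numeric(df_count) / nbags
  keep_tok <- df >= min_frac & df <= max_frac
  old_ids <- corpus$vocabulary$token_id[keep_tok]
  token_map <- stats::setNames(seq_along(old_ids), as.character(old_ids))
  vocab <- corpus$vocabulary[keep_tok, , drop = FALSE]
  vocab$token_id <- seq_len(nrow(vocab))
  rownames(vocab) <- NULL
  bags <- lapply(corpus$bags, function(bag) {
    ok <- names(bag) %in% names(token_map)
    bag <- bag[ok]
    names(bag) <- as.character(token_map[names(bag)])
    bag
  })
  empty <- lengths(bags) == 0
  bags <- bags[!empty]
  if (!length(bags)) stop("outlier filtering emptied every bag; loosen ",
                          "min_frac/max_frac", call. = FALSE)
  info <- corpus$info
  info$min_frac <- min_frac
  info$max_frac <- max_frac
  info$token_map <- token_map
  info$dropped_bags <- sum(empty)
  new_corpus(vocab, bags, info)
}

# expand a corpus into per-document streams of 0-based token ids (count c
# becomes c independent occurrences, in token-id order)
corpus_to_docs <- function(corpus) {
  lapply(corpus$bags, function(bag) {
    ids <- as.integer(names(bag))
    o <- order(ids)
    rep.int(ids[o] - 1L, as.integer(bag)[o])
  })
}

corpus_checksum <- function(corpus) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_corpus(corpus, tmp)
  paste(unname(tools::md5sum(paste0(tmp, c("_vocab.tsv", "_bags.tsv")))),
        collapse = "-")
}
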