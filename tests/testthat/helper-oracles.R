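# Independent oracles and fixture builders shared across the test files.

# --- brute-force oracles -----------------------------------------------------

# count shortest s-t paths through each edge by enumerating ALL shortest
# paths with igraph (independent of the BFS sigma implementation)
enum_edge_counts <- function(g, s, t) {
  if (s == t) return(stats::setNames(numeric(0), character(0)))
  sp <- suppressWarnings(
    igraph::all_shortest_paths(g, from = s, to = t)$res)
  acc <- list()
  for (p in sp) {
    nm <- igraph::V(g)$name[as.integer(p)]
    if (length(nm) < 2) next
    for (i in seq_len(length(nm) - 1)) {
      key <- paste(sort(nm[i:(i + 1)]), collapse = "|")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + 1
    }
  }
  if (!length(acc)) return(stats::setNames(numeric(0), character(0)))
  unlist(acc)
}

# upper-tail hypergeometric by exhaustive subset enumeration:
# draw `draws` elements from a population of `pop` of which `succ` are
# successes; P(X >= c) by enumerating every subset
enum_hyper_tail <- function(pop, succ, draws, c) {
  subsets <- utils::combn(pop, draws)
  hits <- colSums(subsets <= succ)   # successes are elements 1..succ
  mean(hits >= c)
}

# step-up BH computed literally from the definition
bh_by_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# TOM by literal double loop over the stated formula
tom_by_hand <- function(w) {
  n <- nrow(w)
  k <- rowSums(w)
  tom <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- sum(w[i, ] * w[, j]) + w[i, j]
      tom[i, j] <- num / (min(k[i], k[j]) + 1 - w[i, j])
    }
  }
  dimnames(tom) <- dimnames(w)
  tom
}

# one-vs-rest AUC from the rank definition (Mann-Whitney), midranks for ties
auc_by_rank <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

random_connected_graph <- function(n, p = 0.35) {
  repeat {
    m <- matrix(stats::runif(n * n) < p, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    el <- which(m, arr.ind = TRUE)
    if (nrow(el) == 0) next
    g <- igraph::graph_from_edgelist(
      cbind(paste0("n", el[, 1]), paste0("n", el[, 2])), directed = FALSE)
    if (igraph::is_connected(g)) return(g)
  }
}

# --- fixture builders --------------------------------------------------------

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# small corpus with explicit bags (list of named count vectors over 1..V)
manual_corpus <- function(bags, V) {
  vocab <- cmnet:::synthetic_vocabulary(V)
  names(bags) <- sprintf("I%03d", seq_along(bags))
  cmnet:::new_corpus(vocab, lapply(bags, function(b) {
    stats::setNames(as.integer(b), names(b))
  }), info = list())
}

# corpus of `n` identical single-token bags
degenerate_corpus <- function(n, V = 5) {
  manual_corpus(rep(list(c("1" = 1L)), n), V)
}
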