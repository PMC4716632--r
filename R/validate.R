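# Significance machinery: hypergeometric edge-overlap test between
# networks, the TF observed-proportion permutation test, generic gene-set
# overlap, BH correction, CMN label mapping and multi-class ROC, and the
# full input-randomization permutation test for CMNs.

.edge_set <- function(x) {
  if (inherits(x, "cmn")) return(unique(x$edges$edge))
  unique(as.character(x))
}

.edge_nodes <- function(edges) {
  unique(unlist(strsplit(edges, "|", fixed = TRUE), use.names = FALSE))
}

#' Hypergeometric overlap p-value between two networks
#'
#' With M the number of distinct proteins in the union of the two edge sets,
#' there are `E = M(M-1)/2` possible edges. The upper-tail probability of
#' observing at least `c = |N1 intersect N2|` common edges when two edge
#' sets of the given sizes are drawn from those E edges is returned.
#'
#' @param n1,n2 edge sets: character vectors of `"A|B"` keys or `cmn`
#'   objects.
#' @return the p-value.
#' @export
network_overlap_pvalue <- function(n1, n2) {
  e1 <- .edge_set(n1); e2 <- .edge_set(n2)
  if (!length(e1) || !length(e2)) stop("edge sets must be non-empty",
                                       call. = FALSE)
  M <- length(unique(c(.edge_nodes(e1), .edge_nodes(e2))))
  E <- M * (M - 1) / 2
  cc <- length(intersect(e1, e2))
  stats::phyper(cc - 1, length(e1), E - length(e1), length(e2),
                lower.tail = FALSE)
}

#' Hypergeometric gene-set overlap p-value
#'
#' Upper-tail probability of drawing at least `|hits intersect annotated|`
#' annotated elements when `|hits|` elements are drawn from the universe.
#' Used for concept / co-factor list enrichment of CMN proteins.
#'
#' @param hits character vector of the query set (subset of `universe`).
#' @param annotated character vector of the annotated set (subset of
#'   `universe`).
#' @param universe character vector of all eligible elements.
#' @return the p-value.
#' @export
hypergeom_overlap <- function(hits, annotated, universe) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  hits <- unique(hits); annotated <- unique(annotated)
  if (!all(hits %in% universe) || !all(annotated %in% universe)) {
    stop("hits and annotated must be subsets of the universe", call. = FALSE)
  }
  cc <- length(intersect(hits, annotated))
  stats::phyper(cc - 1, length(annotated),
                length(universe) - length(annotated), length(hits),
                lower.tail = FALSE)
}

#' Benjamini-Hochberg correction
#' @param pvals numeric vector of p-values in \[0,1\].
#' @return adjusted p-values in the input order.
#' @export
bh_correct <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

interactions_with_signal <- function(interactions, peaks_tf, flank) {
  vapply(seq_len(nrow(interactions)), function(i) {
    wA <- anchor_window(interactions$start1[i], interactions$end1[i], flank)
    wB <- anchor_window(interactions$start2[i], interactions$end2[i], flank)
    peak_hits_window(peaks_tf, interactions$chrom1[i], wA$start, wA$end) ||
      peak_hits_window(peaks_tf, interactions$chrom2[i], wB$start, wB$end)
  }, logical(1))
}

#' Observed-proportion test for TF enrichment
#'
#' For a set of interactions claimed to be maintained by networks containing
#' a TF, the observed proportion OP is the fraction whose anchor windows
#' truly contain the TF's ChIP-seq signal. The null distribution draws the
#' same number of interactions uniformly (without replacement) from the full
#' ChIA-PET set; the empirical p-value uses the add-one estimator
#' `(1 + #\{null OP >= OP\}) / (n_perm + 1)`.
#'
#' @param claimed character vector of claimed interaction ids.
#' @param peaks_tf data frame of the TF's peaks (`chrom`, `start`, `end`).
#' @param interactions the full `cmn_interactions` set.
#' @param flank anchor-window half-width (default 1500).
#' @param n_perm null draws (default 500).
#' @param seed optional integer seed.
#' @return list with `OP`, `p`, and the vector of null OP values.
#' @export
tf_enrichment_test <- function(claimed, peaks_tf, interactions,
                               flank = 1500, n_perm = 500, seed = NULL) {
  stopifnot(length(claimed) > 0, n_perm >= 1)
  if (!all(claimed %in% interactions$id)) {
    stop("claimed ids not all present in the interaction set", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  has <- interactions_with_signal(interactions, peaks_tf, flank)
  names(has) <- interactions$id
  op <- mean(has[claimed])
  n <- length(claimed)
  null_op <- vapply(seq_len(n_perm), function(i) {
    mean(has[sample.int(nrow(interactions), n)])
  }, numeric(1))
  list(OP = op, p = (1 + sum(null_op >= op)) / (n_perm + 1),
       null = null_op)
}

#' Map planted CMNs to inferred CMNs
#'
#' `f(k)` is the inferred CMN of maximum Jensen-Shannon similarity to
#' planted CMN `k`; ties resolve to the lowest inferred index. Several
#' planted CMNs may map to one inferred CMN (a merge).
#'
#' @param original K x V matrix of planted edge distributions (or
#'   `cmn_fit`).
#' @param inferred K' x V matrix of inferred edge distributions (or
#'   `cmn_fit`).
#' @return list with integer vector `f` and the similarity value per
#'   original CMN (`sim`).
#' @export
map_cmns <- function(original, inferred) {
  ob <- if (inherits(original, "cmn_fit")) original$beta else original
  ib <- if (inherits(inferred, "cmn_fit")) inferred$beta else inferred
  if (ncol(ob) != ncol(ib)) stop("vocabulary mismatch", call. = FALSE)
  f <- integer(nrow(ob)); s <- numeric(nrow(ob))
  for (k in seq_len(nrow(ob))) {
    sims <- vapply(seq_len(nrow(ib)), function(x)
      cmn_similarity(ob[k, ], ib[x, ]), numeric(1))
    f[k] <- which.max(sims)            # lowest index on ties
    s[k] <- sims[f[k]]
  }
  list(f = f, sim = s)
}

#' Multi-class ROC AUC of CMN re-assignment
#'
#' Remaps the planted per-interaction labels through the CMN mapping `f`
#' and scores each class by the corresponding column of the mixing
#' proportions; the macro average of one-vs-rest AUCs is returned. Classes
#' absent after mapping are excluded.
#'
#' @param true_labels integer vector of planted CMN labels per interaction.
#' @param theta interactions x inferred-CMNs proportion matrix (or
#'   `cmn_fit`).
#' @param f integer mapping from planted to inferred indices (from
#'   [map_cmns]).
#' @return the macro-averaged AUC.
#' @export
multiclass_auc <- function(true_labels, theta, f) {
  if (inherits(theta, "cmn_fit")) theta <- theta$theta
  mapped <- f[true_labels]
  classes <- sort(unique(mapped))
  classes <- classes[classes >= 1 & classes <= ncol(theta)]
  if (length(classes) < 2) {
    stop("multi-class AUC undefined: fewer than 2 classes after mapping",
         call. = FALSE)
  }
  aucs <- vapply(classes, function(cl) {
    as.numeric(pROC::auc(response = factor(mapped == cl,
                                           levels = c(FALSE, TRUE)),
                         predictor = theta[, cl],
                         direction = "<", quiet = TRUE))
  }, numeric(1))
  mean(aucs)
}

shuffle_peaks <- function(peaks, chrom_sizes) {
  out <- lapply(peaks, function(d) {
    if (!nrow(d)) return(d)
    len <- d$end - d$start
    maxs <- chrom_sizes[d$chrom] - len
    d$start <- as.integer(floor(stats::runif(nrow(d), 0, pmax(maxs, 1))))
    d$end <- d$start + len
    d
  })
  structure(out, class = "cmn_peaks")
}

shuffle_anchors <- function(interactions) {
  perm <- sample.int(nrow(interactions))
  interactions[, c("chrom2", "start2", "end2")] <-
    interactions[perm, c("chrom2", "start2", "end2")]
  interactions
}

default_chrom_sizes <- function(interactions, peaks) {
  ends <- c(stats::setNames(interactions$end1, interactions$chrom1),
            stats::setNames(interactions$end2, interactions$chrom2),
            unlist(lapply(peaks, function(d)
              stats::setNames(d$end, d$chrom))))
  tapply(ends, names(ends), max) * 1.05
}

#' Input-randomization permutation test for CMNs
#'
#' Re-shuffles the TF binding positions (uniform re-placement on their
#' chromosome, lengths preserved) and the anchor pairings, rebuilds the
#' corpus against the *same* reference PPI and thresholds, and re-infers
#' CMNs. An observed CMN that null runs repeatedly reproduce (best
#' edge-overlap p below 0.05 in more than `alpha` of the iterations) is
#' flagged non-significant: its edges come from the background PPI (hub
#' attraction of shortest paths) rather than from the chromatin data.
#'
#' @param fit the observed `cmn_fit`.
#' @param interactions,peaks,ref the pipeline inputs used for `fit`.
#' @param flank,min_frac,max_frac corpus-construction parameters (must match
#'   the observed run).
#' @param coverage CMN truncation coverage (default 0.5).
#' @param n_perm permutation iterations (default 1000; small values are
#'   usable for pilots).
#' @param null_sweeps Gibbs sweeps for null fits (reduced relative to the
#'   observed fit; recorded in the result).
#' @param alpha flagging level (default 0.05).
#' @param chrom_sizes named vector of chromosome lengths; inferred from the
#'   inputs when `NULL`.
#' @param seed optional integer seed.
#' @return list with per-CMN data frame `table` (`frac_reproduced`,
#'   `significant`), the n_perm x K matrix `null_min_p` of per-iteration
#'   best overlap p-values, and the count of degenerate null corpora.
#' @export
permutation_cmn_test <- function(fit, interactions, peaks, ref,
                                 flank = 1500, min_frac = 0.05,
                                 max_frac = 0.80, coverage = 0.5,
                                 n_perm = 1000, null_sweeps = 100,
                                 alpha = 0.05, chrom_sizes = NULL,
                                 seed = NULL) {
  stopifnot(inherits(fit, "cmn_fit"), n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chrom_sizes)) {
    chrom_sizes <- default_chrom_sizes(interactions, peaks)
  }
  obs <- lapply(seq_len(fit$K), function(k)
    .edge_set(extract_cmn(fit, k, coverage)))
  null_min_p <- matrix(NA_real_, n_perm, fit$K)
  degenerate <- 0L
  for (it in seq_len(n_perm)) {
    pk <- shuffle_peaks(peaks, chrom_sizes)
    ia <- shuffle_anchors(interactions)
    nf <- tryCatch({
      corp <- build_corpus(ia, pk, ref, flank)
      corp <- filter_outlier_edges(corp, min_frac, max_frac)
      cmn_fit(corp, eta = fit$config$eta, gamma = fit$config$gamma,
              alpha = fit$config$alpha, sweeps = null_sweeps)
    }, error = function(e) NULL)
    if (is.null(nf)) {
      degenerate <- degenerate + 1L
      next
    }
    null_edges <- lapply(seq_len(nf$K), function(k)
      .edge_set(extract_cmn(nf, k, coverage)))
    for (k in seq_len(fit$K)) {
      ps <- vapply(null_edges, function(ne)
        network_overlap_pvalue(obs[[k]], ne), numeric(1))
      null_min_p[it, k] <- min(ps)
    }
  }
  valid <- stats::complete.cases(null_min_p)
  frac <- if (any(valid)) {
    colMeans(null_min_p[valid, , drop = FALSE] < 0.05)
  } else rep(0, fit$K)   # no null run reconstructed anything
  tab <- data.frame(cmn = seq_len(fit$K),
                    frac_reproduced = frac,
                    significant = frac <= alpha)
  list(table = tab, null_min_p = null_min_p, degenerate = degenerate,
       n_perm = n_perm, null_sweeps = null_sweeps, alpha = alpha)
}
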