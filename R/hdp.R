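# Fitting interface for the hierarchical Dirichlet process over bags of
# edges, plus posterior summaries. The sampler itself lives in
# src/hdp_gibbs.cpp.

#' Fit chromatin maintainer networks by hierarchical Dirichlet process
#'
#' Runs a collapsed direct-assignment Gibbs sampler over the bag-of-edges
#' corpus. The number of CMNs is not fixed in advance: tokens may open new
#' components under the stick-breaking global measure, so K grows (and
#' shrinks) with the data. All tokens start in a single CMN; burn-in
#' resamples the global stick weights after every `resample_every` documents,
#' subsequent sweeps once per sweep.
#'
#' @param corpus a `cmn_corpus` (see [build_corpus], [sample_corpus]).
#' @param eta symmetric Dirichlet parameter of the base measure over edge
#'   tokens; small values (default 0.01) give sparse edge-per-CMN
#'   distributions, larger values more uniform ones and fewer CMNs.
#' @param gamma concentration of the global measure G0 (default 1); values
#'   above 1 spread mass over more CMNs.
#' @param alpha per-interaction concentration (default 1); larger values let
#'   one interaction draw from more CMNs.
#' @param sweeps post-burn-in Gibbs sweeps (default 1000).
#' @param burnin_sweeps burn-in sweeps with within-sweep stick resampling
#'   (default 1).
#' @param resample_every during burn-in, resample the global weights after
#'   this many documents (default 10).
#' @param seed integer seed; fits are bit-reproducible given (corpus, seed).
#' @return an object of class `cmn_fit` with components `K`, `beta` (K x V
#'   CMN edge distributions), `theta` (interactions x K mixing proportions),
#'   `counts`, `z`, `global_weights`, `k_trace`, `vocabulary`, `config`.
#' @seealso [extract_cmn], [similarity_matrix], [sparsity_metrics]
#' @export
cmn_fit <- function(corpus, eta = 0.01, gamma = 1, alpha = 1,
                    sweeps = 1000, burnin_sweeps = 1, resample_every = 10,
                    seed = NULL) {
  stopifnot(inherits(corpus, "cmn_corpus"),
            eta > 0, gamma > 0, alpha > 0, sweeps >= 1,
            burnin_sweeps >= 1, resample_every >= 1)
  if (!length(corpus$bags)) stop("empty corpus", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  docs <- corpus_to_docs(corpus)
  V <- nrow(corpus$vocabulary)
  res <- hdp_gibbs_cpp(docs, V, eta, gamma, alpha,
                       as.integer(burnin_sweeps), as.integer(sweeps),
                       as.integer(resample_every))
  K <- res$K
  labels <- edge_labels(corpus$vocabulary)
  beta <- posterior_beta(res$n_ke, eta)
  dimnames(beta) <- list(paste0("CMN", seq_len(K)), labels)
  sizes <- vapply(docs, length, numeric(1))
  g <- res$g
  theta <- posterior_theta(res$n_jk, sizes, alpha, g, res$g_u)
  dimnames(theta) <- list(names(corpus$bags), paste0("CMN", seq_len(K)))
  structure(list(
    K = K,
    beta = beta,
    theta = theta,
    counts = list(n_ke = res$n_ke, n_k = res$n_k, n_jk = res$n_jk),
    z = stats::setNames(res$z, names(corpus$bags)),
    global_weights = c(g, unallocated = res$g_u),
    k_trace = res$k_trace,
    vocabulary = corpus$vocabulary,
    corpus_checksum = corpus_checksum(corpus),
    config = list(eta = eta, gamma = gamma, alpha = alpha, sweeps = sweeps,
                  burnin_sweeps = burnin_sweeps,
                  resample_every = resample_every,
                  seed = if (is.null(seed)) NA_integer_ else seed),
    call = match.call()
  ), class = "cmn_fit")
}

#' CMN edge distributions from assignment counts
#'
#' Dirichlet-smoothed posterior mean: `beta_k(e) = (n_ke + eta) / (n_k + V
#' eta)` with `n_k = sum_e n_ke` and V the vocabulary size. Each row sums
#' to 1.
#'
#' @param n_ke K x V matrix of token-to-CMN assignment counts.
#' @param eta base-measure Dirichlet parameter.
#' @return K x V matrix of edge probabilities.
#' @export
posterior_beta <- function(n_ke, eta) {
  n_ke <- as.matrix(n_ke)
  (n_ke + eta) / (rowSums(n_ke) + ncol(n_ke) * eta)
}

#' Per-interaction CMN proportions from assignment counts
#'
#' `theta_j(k) = (n_jk + alpha g_k) / (size_j + alpha (1 - g_new))`,
#' renormalized so each row sums to 1; `g` are the global stick weights and
#' `g_new` the unallocated mass.
#'
#' @param n_jk J x K matrix of per-document CMN counts.
#' @param sizes document sizes (`rowSums(n_jk)`).
#' @param alpha per-document concentration.
#' @param g stick weights of the K active CMNs.
#' @param g_new unallocated stick mass.
#' @return J x K matrix of mixing proportions.
#' @export
posterior_theta <- function(n_jk, sizes, alpha, g, g_new) {
  n_jk <- as.matrix(n_jk)
  theta <- sweep(n_jk, 2, alpha * g, "+") / (sizes + alpha * (1 - g_new))
  theta / rowSums(theta)
}

#' Per-CMN edge distributions
#' @param object a `cmn_fit`.
#' @param ... unused.
#' @return the K x V matrix of CMN edge probabilities (rows sum to 1).
#' @export
coef.cmn_fit <- function(object, ...) object$beta

#' Per-interaction CMN assignment
#'
#' @param object a `cmn_fit`.
#' @param type `"theta"` for the full mixing-proportion matrix, `"label"`
#'   for the index of the dominant CMN per interaction.
#' @param ... unused.
#' @export
predict.cmn_fit <- function(object, type = c("theta", "label"), ...) {
  type <- match.arg(type)
  if (type == "theta") return(object$theta)
  stats::setNames(max.col(object$theta, ties.method = "first"),
                  rownames(object$theta))
}

#' @export
print.cmn_fit <- function(x, ...) {
  cat("Hierarchical Dirichlet process CMN fit\n")
  cat("  ", nrow(x$theta), " interactions, ", ncol(x$beta),
      " edge tokens, K = ", x$K, " CMNs\n", sep = "")
  cat("  eta = ", x$config$eta, ", gamma = ", x$config$gamma,
      ", alpha = ", x$config$alpha, ", sweeps = ", x$config$sweeps,
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.cmn_fit <- function(object, threshold = 1e-3, ...) {
  sp <- sparsity_metrics(object, threshold = threshold)
  sizes <- object$counts$n_k
  out <- list(K = object$K,
              cmn_tokens = sizes,
              sparsity = sp,
              k_trace_tail = utils::tail(object$k_trace, 10),
              config = object$config)
  class(out) <- "summary.cmn_fit"
  out
}

#' @export
print.summary.cmn_fit <- function(x, ...) {
  cat("CMN fit summary: K =", x$K, "\n")
  cat("  tokens per CMN:", paste(x$cmn_tokens, collapse = " "), "\n")
  cat(sprintf("  edge-level sparsity %.3f | doc-level sparsity %.3f | mean CMNs/doc %.2f\n",
              x$sparsity$edge_level, x$sparsity$doc_level,
              x$sparsity$mean_cmns_per_doc))
  cat("  K over last sweeps:", paste(x$k_trace_tail, collapse = " "), "\n")
  invisible(x)
}

#' Heat map of pairwise CMN similarities
#' @param x a `cmn_fit`.
#' @param ... passed to [graphics::image].
#' @export
plot.cmn_fit <- function(x, ...) {
  sim <- similarity_matrix(x)
  k <- nrow(sim)
  graphics::image(seq_len(k), seq_len(k), t(sim[k:1, , drop = FALSE]),
                  zlim = c(0, 1), xlab = "CMN", ylab = "CMN",
                  main = "CMN similarity (1 - Jensen-Shannon)",
                  axes = FALSE, ...)
  graphics::axis(1, at = seq_len(k), labels = colnames(sim))
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(sim)))
  invisible(sim)
}

#' Simulate corpora from a fitted model
#'
#' Draws new bag-of-edges corpora using the fitted CMN edge distributions
#' as planted components (see [sample_corpus]).
#'
#' @param object a `cmn_fit`.
#' @param nsim number of corpora.
#' @param seed optional integer seed.
#' @param n_interactions interactions per corpus (default: as fitted).
#' @param size_range bag-size range, default 10-200 edges.
#' @param ... unused.
#' @return a list of `nsim` simulation results (corpus + truth).
#' @export
simulate.cmn_fit <- function(object, nsim = 1, seed = NULL,
                             n_interactions = nrow(object$theta),
                             size_range = c(10, 200), ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, sample_corpus(n_interactions, object$beta,
                                size_range = size_range,
                                mixing_alpha = object$config$alpha,
                                vocabulary = object$vocabulary),
            simplify = FALSE)
}

#' Sparsity diagnostics of a fit
#'
#' Reports the fraction of CMN-edge cells with probability below
#' `threshold` (edge-level sparsity), the mean fraction of CMNs below
#' `threshold` per interaction (document-level sparsity), K, and the mean
#' number of CMNs with at least one token per interaction.
#'
#' @param fit a `cmn_fit`.
#' @param threshold probability cutoff (default 1e-3).
#' @return list with `edge_level`, `doc_level`, `K`, `mean_cmns_per_doc`.
#' @export
sparsity_metrics <- function(fit, threshold = 1e-3) {
  stopifnot(inherits(fit, "cmn_fit"))
  list(edge_level = mean(fit$beta < threshold),
       doc_level = mean(rowMeans(fit$theta < threshold)),
       K = fit$K,
       mean_cmns_per_doc = mean(rowSums(fit$counts$n_jk >= 1)))
}
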