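# Synthetic data: planted-CMN corpora for parameter-recovery studies and
# full genomic fixtures (anchors, peaks, PPI, expression, nuclear list) so
# every pipeline stage runs without external downloads.

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

synthetic_vocabulary <- function(vocab_size) {
  data.frame(token_id = seq_len(vocab_size),
             proteinA = sprintf("P%04d", 2 * seq_len(vocab_size) - 1),
             proteinB = sprintf("P%04d", 2 * seq_len(vocab_size)),
             stringsAsFactors = FALSE)
}

#' Draw planted CMN edge distributions
#'
#' Each planted CMN is a Dirichlet draw over the edge vocabulary. In
#' disjoint mode each CMN receives an exclusive vocabulary block (vocab
#' split into K contiguous chunks), giving a sharp, fully checkable
#' recovery regime.
#'
#' @param K number of planted CMNs (>= 1).
#' @param vocab_size vocabulary size (>= K).
#' @param concentration symmetric Dirichlet parameter (default 0.1; small
#'   values concentrate each CMN on few edges).
#' @param disjoint give each CMN an exclusive vocabulary block.
#' @param seed optional integer seed.
#' @return K x vocab_size matrix of edge distributions (rows sum to 1).
#' @export
make_planted_cmns <- function(K, vocab_size, concentration = 0.1,
                              disjoint = FALSE, seed = NULL) {
  stopifnot(K >= 1, vocab_size >= K, concentration > 0)
  if (!is.null(seed)) set.seed(seed)
  beta <- matrix(0, K, vocab_size)
  if (disjoint) {
    bounds <- floor(seq(0, vocab_size, length.out = K + 1))
    for (k in seq_len(K)) {
      idx <- (bounds[k] + 1):bounds[k + 1]
      beta[k, idx] <- rdirichlet(1, rep(concentration, length(idx)))
    }
  } else {
    beta[] <- rdirichlet(K, rep(concentration, vocab_size))
  }
  rownames(beta) <- paste0("CMN", seq_len(K))
  beta
}

#' Sample a bag-of-edges corpus from planted CMNs
#'
#' Per interaction: mixing proportions are drawn from a symmetric
#' Dirichlet(`mixing_alpha`) over the planted CMNs, the bag size uniformly
#' from `size_range` (endpoints inclusive), and each edge slot first draws
#' a CMN indicator from the proportions, then an edge from that CMN's
#' distribution. `dominant_only = TRUE` draws all edges from the
#' highest-proportion CMN instead.
#'
#' @param n_interactions number of interactions (>= 1).
#' @param betas K x V matrix of planted edge distributions.
#' @param size_range integer range of edges per bag, default `c(10, 200)`.
#' @param mixing_alpha Dirichlet parameter for the per-interaction CMN
#'   profile (default 1: uniform over the simplex).
#' @param dominant_only sample every edge from the dominant CMN.
#' @param vocabulary optional vocabulary data frame; synthesized when
#'   `NULL`.
#' @param seed optional integer seed.
#' @return list of class `cmn_sim`: `corpus` (a `cmn_corpus`) and `truth`
#'   (planted `betas`, per-interaction `proportions` and dominant `labels`).
#' @export
sample_corpus <- function(n_interactions, betas, size_range = c(10, 200),
                          mixing_alpha = 1, dominant_only = FALSE,
                          vocabulary = NULL, seed = NULL) {
  stopifnot(n_interactions >= 1, is.matrix(betas),
            length(size_range) == 2, size_range[1] >= 1,
            size_range[1] <= size_range[2])
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(betas); V <- ncol(betas)
  if (is.null(vocabulary)) vocabulary <- synthetic_vocabulary(V)
  props <- rdirichlet(n_interactions, rep(mixing_alpha, K))
  sizes <- sample.int(size_range[2] - size_range[1] + 1L, n_interactions,
                      replace = TRUE) + size_range[1] - 1L
  labels <- max.col(props, ties.method = "first")
  bags <- vector("list", n_interactions)
  for (j in seq_len(n_interactions)) {
    zi <- if (dominant_only) rep.int(labels[j], sizes[j])
          else sample.int(K, sizes[j], replace = TRUE, prob = props[j, ])
    tok <- vapply(zi, function(k)
      sample.int(V, 1, prob = betas[k, ]), integer(1))
    tab <- tabulate(tok, nbins = V)
    nz <- which(tab > 0)
    bags[[j]] <- stats::setNames(tab[nz], as.character(nz))
  }
  names(bags) <- sprintf("SIM%05d", seq_len(n_interactions))
  corpus <- new_corpus(vocabulary, bags,
                       info = list(simulated = TRUE, K_true = K,
                                   size_range = size_range,
                                   mixing_alpha = mixing_alpha,
                                   dominant_only = dominant_only))
  structure(list(corpus = corpus,
                 truth = list(betas = betas, proportions = props,
                              labels = labels, sizes = sizes)),
            class = "cmn_sim")
}

#' Subsample a corpus (library-complexity simulation)
#'
#' Keeps a uniform sample (without replacement) of `ceiling(fraction * n)`
#' bags; the vocabulary is unchanged.
#'
#' @param corpus a `cmn_corpus`.
#' @param fraction in (0, 1\].
#' @param seed optional integer seed.
#' @return the subsampled `cmn_corpus`.
#' @export
subsample_corpus <- function(corpus, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(corpus$bags)
  keep <- sort(sample.int(n, ceiling(fraction * n)))
  new_corpus(corpus$vocabulary, corpus$bags[keep],
             info = c(corpus$info, list(subsample_fraction = fraction)))
}

#' Write a full synthetic genomic fixture
#'
#' Emulates the pipeline's real inputs: random anchor pairs on a synthetic
#' chromosome; per-TF peaks placed near the anchor centers of the
#' interactions belonging to each TF's module, with a configurable hit
#' probability; a planted-module PPI (dense within modules, sparse
#' between); expression with correlated blocks matching the modules; and a
#' nuclear whitelist. All files use the package's text dialects and
#' round-trip through the readers.
#'
#' @param dir output directory (created if needed).
#' @param n_interactions number of interactions (default 60).
#' @param n_tfs number of TFs (default 6), assigned round-robin to modules.
#' @param n_modules planted PPI modules (default 2).
#' @param module_size proteins per module, TFs included (default 15).
#' @param p_within,p_between edge probabilities inside / between modules.
#' @param hit_prob probability that a module TF leaves a peak at an anchor
#'   of a module interaction (default 0.9).
#' @param peak_jitter max distance of the peak from the anchor center.
#' @param peak_size peak width in bp.
#' @param anchor_size anchor width in bp.
#' @param chrom_len synthetic chromosome length.
#' @param n_samples expression samples (default 20).
#' @param noise_sd within-block expression noise (default 0.2; block signal
#'   has unit variance, so blocks correlate at about 0.96).
#' @param seed optional integer seed.
#' @return list with the file `paths` and the planted `truth` (module of
#'   each protein and interaction).
#' @export
make_genomic_fixture <- function(dir, n_interactions = 60, n_tfs = 6,
                                 n_modules = 2, module_size = 15,
                                 p_within = 0.3, p_between = 0.02,
                                 hit_prob = 0.9, peak_jitter = 500,
                                 peak_size = 200, anchor_size = 2000,
                                 chrom_len = 2e6, n_samples = 20,
                                 noise_sd = 0.2, seed = NULL) {
  stopifnot(n_tfs >= n_modules,
            module_size >= 2 * ceiling(n_tfs / n_modules))
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  n_cof <- n_modules * module_size - n_tfs
  cofs <- sprintf("CF%03d", seq_len(n_cof))
  proteins <- c(tfs, cofs)
  module <- stats::setNames(
    c(rep_len(seq_len(n_modules), n_tfs),
      rep_len(seq_len(n_modules), n_cof)), proteins)

  # planted-module PPI; TFs are never linked directly (co-factors mediate),
  # so cross-anchor shortest paths traverse the module's co-factor edges
  is_tf <- stats::setNames(proteins %in% tfs, proteins)
  a <- character(0); b <- character(0)
  np <- length(proteins)
  for (i in seq_len(np - 1)) {
    for (j in seq(i + 1, np)) {
      if (is_tf[i] && is_tf[j]) next
      p <- if (module[i] == module[j]) p_within else p_between
      if (stats::runif(1) < p) {
        a <- c(a, proteins[i]); b <- c(b, proteins[j])
      }
    }
  }
  # guarantee connectivity inside each module with a TF/co-factor
  # alternating chain
  for (m in seq_len(n_modules)) {
    mem <- proteins[module == m]
    mem <- mem[order(!is_tf[mem])]        # TFs first
    ntf <- sum(is_tf[mem])
    chain <- c(rbind(mem[seq_len(ntf)],
                     mem[ntf + seq_len(ntf)]),
               mem[-seq_len(2 * ntf)])    # TF, CF, TF, CF, ..., rest
    a <- c(a, chain[-length(chain)]); b <- c(b, chain[-1])
  }
  ppi_path <- file.path(dir, "ppi.tsv")
  utils::write.table(unique(data.frame(a, b)), ppi_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  # interactions: each belongs to one module
  imod <- rep_len(seq_len(n_modules), n_interactions)
  c1 <- as.integer(stats::runif(n_interactions, anchor_size,
                                chrom_len - anchor_size))
  c2 <- as.integer(stats::runif(n_interactions, anchor_size,
                                chrom_len - anchor_size))
  inter <- data.frame(
    id = sprintf("INT%04d", seq_len(n_interactions)),
    chrom1 = "chrS", start1 = c1 - anchor_size %/% 2L,
    end1 = c1 + anchor_size %/% 2L,
    chrom2 = "chrS", start2 = c2 - anchor_size %/% 2L,
    end2 = c2 + anchor_size %/% 2L, stringsAsFactors = FALSE)
  class(inter) <- c("cmn_interactions", "data.frame")
  bedpe_path <- file.path(dir, "interactions.bedpe")
  write_interactions(inter, bedpe_path)

  # peaks: module TFs hit the anchors of module interactions
  peak_paths <- character(0)
  for (tf in tfs) {
    rows <- list()
    for (i in seq_len(n_interactions)) {
      if (module[tf] != imod[i]) next
      for (ctr in c(c1[i], c2[i])) {
        if (stats::runif(1) < hit_prob) {
          s <- ctr + as.integer(stats::runif(1, -peak_jitter, peak_jitter)) -
            peak_size %/% 2L
          rows[[length(rows) + 1]] <- data.frame(
            chrom = "chrS", start = max(0L, s),
            end = max(0L, s) + peak_size)
        }
      }
    }
    p <- file.path(dir, paste0("peaks_", tf, ".bed"))
    peaks_df <- if (length(rows)) do.call(rbind, rows)
                else data.frame(chrom = character(), start = integer(),
                                end = integer())
    utils::write.table(peaks_df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    peak_paths <- c(peak_paths, stats::setNames(p, tf))
  }

  # expression: one latent signal per module, high within-block correlation
  signal <- matrix(stats::rnorm(n_modules * n_samples), n_modules)
  expr <- t(vapply(proteins, function(pr)
    signal[module[pr], ] + stats::rnorm(n_samples, sd = noise_sd),
    numeric(n_samples)))
  colnames(expr) <- sprintf("S%02d", seq_len(n_samples))
  expr_path <- file.path(dir, "expression.tsv")
  utils::write.table(data.frame(gene = proteins, expr), expr_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)

  nuclear_path <- file.path(dir, "nuclear.txt")
  writeLines(proteins, nuclear_path)

  list(paths = list(interactions = bedpe_path, peaks = peak_paths,
                    ppi = ppi_path, expression = expr_path,
                    nuclear = nuclear_path),
       truth = list(protein_module = module, interaction_module = imod,
                    tfs = tfs))
}
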