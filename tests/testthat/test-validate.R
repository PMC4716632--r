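test_that("network edge-overlap p-value matches closed cases and enumeration", {
  # identical 2-edge networks over 3 nodes: M=3, E=3, c=2 -> 1/3
  n1 <- c("a|b", "b|c")
  expect_equal(network_overlap_pvalue(n1, n1), 1 / 3, tolerance = 1e-12)

  # disjoint node sets: c = 0 -> p = 1
  expect_equal(network_overlap_pvalue(c("a|b"), c("x|y")), 1)

  expect_error(network_overlap_pvalue(character(0), n1), "non-empty")

  # random small cases vs exhaustive subset enumeration (population <= 10):
  # condition on N1 fixed; the tail probability over draws of N2
  set.seed(17)
  for (rep in 1:15) {
    M <- sample(3:5, 1)
    nodes <- letters[1:M]
    all_edges <- apply(utils::combn(nodes, 2), 2, paste, collapse = "|")
    E <- length(all_edges)
    s1 <- sample(E, sample(1:E, 1))
    s2 <- sample(E, sample(1:E, 1))
    e1 <- all_edges[s1]; e2 <- all_edges[s2]
    cc <- length(intersect(e1, e2))
    # enumeration: reorder so successes (edges of e1) come first
    oracle <- enum_hyper_tail(E, length(s1), length(s2), cc)
    # only comparable when both node sets span all M nodes
    M_obs <- length(unique(unlist(strsplit(c(e1, e2), "|", fixed = TRUE))))
    if (M_obs == M) {
      expect_equal(network_overlap_pvalue(e1, e2), oracle, tolerance = 1e-12)
    }
  }
})

test_that("gene-set overlap p-value is exactly hypergeometric", {
  universe <- paste0("g", 1:10)
  annotated <- universe[1:5]
  hits <- universe[1:5]
  expect_equal(hypergeom_overlap(hits, annotated, universe), 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeom_overlap(universe[6:8], annotated, universe) <= 1, TRUE)
  expect_equal(hypergeom_overlap(universe[6:10], annotated, universe), 1)
  expect_error(hypergeom_overlap("x", "y", character(0)), "empty universe")
  expect_error(hypergeom_overlap("zz", annotated, universe), "subsets")

  set.seed(23)
  for (rep in 1:15) {
    N <- sample(5:15, 1)
    uni <- paste0("e", seq_len(N))
    ann <- sample(uni, sample(1:N, 1))
    hit <- sample(uni, sample(1:N, 1))
    cc <- length(intersect(hit, ann))
    oracle <- enum_hyper_tail(N, length(ann), length(hit), cc)
    expect_equal(hypergeom_overlap(hit, ann, uni), oracle, tolerance = 1e-12)
  }
})

test_that("BH correction matches the step-up definition", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_correct(0.2), 0.2)
  expect_equal(bh_correct(rep(0.4, 5)), rep(0.4, 5))
  expect_error(bh_correct(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (rep in 1:20) {
    p <- stats::runif(sample(1:12, 1))
    expect_equal(bh_correct(p), bh_by_hand(p), tolerance = 1e-12)
  }
})

op_fixture <- function(n_all = 200, n_claimed = 20, signal_on_claimed_only = TRUE) {
  starts <- seq(10000L, by = 100000L, length.out = n_all)
  inter <- data.frame(id = sprintf("I%03d", seq_len(n_all)),
                      chrom1 = "chr1", start1 = starts, end1 = starts + 400L,
                      chrom2 = "chr2", start2 = starts, end2 = starts + 400L,
                      stringsAsFactors = FALSE)
  class(inter) <- c("cmn_interactions", "data.frame")
  claimed <- inter$id[seq_len(n_claimed)]
  rows <- if (signal_on_claimed_only) seq_len(n_claimed) else seq_len(n_all)
  peaks <- data.frame(chrom = "chr1", start = starts[rows] + 150L,
                      end = starts[rows] + 250L)
  list(inter = inter, claimed = claimed, peaks = peaks)
}

test_that("observed-proportion TF test separates signal from background", {
  fx <- op_fixture()
  res <- tf_enrichment_test(fx$claimed, fx$peaks, fx$inter, flank = 1500,
                            n_perm = 99, seed = 1)
  expect_equal(res$OP, 1)
  # no null draw of 20 from 200 can reach OP = 1 when only the 20 claimed
  # interactions carry signal (P(all 20 signal) astronomically small)
  expect_equal(res$p, 1 / 100)

  # ubiquitous signal: OP = 1 and every null draw ties -> p = 1
  fx2 <- op_fixture(signal_on_claimed_only = FALSE)
  res2 <- tf_enrichment_test(fx2$claimed, fx2$peaks, fx2$inter,
                             n_perm = 50, seed = 2)
  expect_equal(res2$OP, 1)
  expect_equal(res2$p, 1)

  expect_error(tf_enrichment_test(c("nope"), fx$peaks, fx$inter), "claimed")
})

test_that("CMN mapping takes the most similar inferred component", {
  set.seed(6)
  beta <- make_planted_cmns(3, 30, disjoint = TRUE)
  ident <- map_cmns(beta, beta)
  expect_equal(ident$f, 1:3)
  expect_equal(ident$sim, rep(1, 3))

  # merge CMNs 1 and 2: both originals map to the merged component
  merged <- rbind((beta[1, ] + beta[2, ]) / 2, beta[3, ])
  m <- map_cmns(beta, merged)
  expect_equal(m$f, c(1, 1, 2))

  single <- beta[1, , drop = FALSE]
  expect_equal(map_cmns(beta, single)$f, c(1, 1, 1))
})

test_that("multi-class AUC matches rank computation and handles limits", {
  # perfect assignment
  theta <- diag(3)[c(1, 2, 3, 1, 2, 3), ]
  labels <- c(1, 2, 3, 1, 2, 3)
  expect_equal(multiclass_auc(labels, theta, f = 1:3), 1)

  # 6-interaction case vs one-vs-rest AUCs from the rank definition
  set.seed(14)
  th <- cmnet:::rdirichlet(6, c(1, 1))
  lab <- c(1, 1, 2, 2, 1, 2)
  expected <- mean(c(auc_by_rank(th[, 1], lab == 1),
                     auc_by_rank(th[, 2], lab == 2)))
  expect_equal(multiclass_auc(lab, th, f = 1:2), expected, tolerance = 1e-12)

  # uniform scores give chance-level AUC
  uni <- matrix(1 / 3, 60, 3)
  lab3 <- rep(1:3, 20)
  expect_equal(multiclass_auc(lab3, uni, f = 1:3), 0.5)

  # single class after mapping is undefined
  expect_error(multiclass_auc(lab3, uni, f = c(1, 1, 1)), "fewer than 2")

  # invariance under consistent relabeling
  th2 <- th[, c(2, 1)]     # swap columns; map labels accordingly
  expect_equal(multiclass_auc(lab, th2, f = c(2, 1)),
               multiclass_auc(lab, th, f = 1:2), tolerance = 1e-12)
})

test_that("input randomization flags hub artifacts and keeps planted CMNs", {
  # hub fixture: every TF's peaks cover the whole (tiny) chromosome and
  # every shortest path runs through one hub protein, so shuffled binding
  # sites rebuild the same hub-dominated star network every time
  starts <- seq(1000L, by = 3000L, length.out = 12)
  inter <- data.frame(id = sprintf("H%02d", 1:12),
                      chrom1 = "chrH", start1 = starts, end1 = starts + 400L,
                      chrom2 = "chrH", start2 = rev(starts),
                      end2 = rev(starts) + 400L, stringsAsFactors = FALSE)
  class(inter) <- c("cmn_interactions", "data.frame")
  tf_names <- paste0("T", 1:8)
  pk <- structure(
    stats::setNames(lapply(tf_names, function(t)
      data.frame(chrom = "chrH", start = 0L, end = 40000L)), tf_names),
    class = "cmn_peaks")
  ref <- ppi_graph(rep("HUB", 8), tf_names)
  corp <- filter_outlier_edges(build_corpus(inter, pk, ref), 0, 1)
  fit <- cmn_fit(corp, sweeps = 30, seed = 2)
  res <- permutation_cmn_test(fit, inter, pk, ref, min_frac = 0,
                              max_frac = 1, coverage = 0.9, n_perm = 5,
                              null_sweeps = 20, seed = 9)
  expect_true(all(!res$table$significant))

  # planted fixture: peaks sit only near true anchors on a long chromosome;
  # random placement cannot reconstruct the observed networks
  fxdir <- tempfile()
  fx <- make_genomic_fixture(fxdir, n_interactions = 24, n_tfs = 4,
                             n_modules = 2, module_size = 6, hit_prob = 1,
                             seed = 33)
  inter2 <- read_interactions(fx$paths$interactions)
  pk2 <- read_peaks(fx$paths$peaks)
  ref2 <- read_ppi(fx$paths$ppi)
  corp2 <- filter_outlier_edges(build_corpus(inter2, pk2, ref2), 0.05, 0.95)
  fit2 <- cmn_fit(corp2, sweeps = 50, seed = 3)
  res2 <- permutation_cmn_test(fit2, inter2, pk2, ref2, min_frac = 0.05,
                               max_frac = 0.95, n_perm = 5, null_sweeps = 20,
                               seed = 10)
  expect_true(any(res2$table$significant))
  expect_error(permutation_cmn_test(fit2, inter2, pk2, ref2, n_perm = 0))
})
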