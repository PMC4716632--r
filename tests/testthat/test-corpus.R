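test_that("anchor windows center on the interval and clamp at zero", {
  w <- anchor_window(100L, 200L, 1500)           # center 150
  expect_equal(w$start, 0L)
  expect_equal(w$end, 1650L)
  w2 <- anchor_window(10000L, 11000L, 500)       # center 10500
  expect_equal(w2$start, 10000L)
  expect_equal(w2$end, 11000L)
  expect_error(anchor_window(0L, 10L, 0), "flank")
})

test_that("TF assignment uses half-open >= 1 bp overlap on windows", {
  inter <- data.frame(id = "I1", chrom1 = "chr1", start1 = 100L, end1 = 200L,
                      chrom2 = "chr2", start2 = 500L, end2 = 700L)
  pk <- structure(list(
    hit  = data.frame(chrom = "chr1", start = 150L, end = 160L),
    edge = data.frame(chrom = "chr1", start = 1650L, end = 1700L),  # abuts
    far  = data.frame(chrom = "chr9", start = 1L, end = 2L)),
    class = "cmn_peaks")
  tf <- assign_tfs(inter, pk, flank = 1500)
  expect_equal(tf$tfs_A, "hit")   # window [0,1650): 1650 start excluded
  expect_length(tf$tfs_B, 0)
})

test_that("edge counts equal all-shortest-path enumeration on canonical graphs", {
  # diamond: A-C-B and A-D-B
  g <- ppi_graph(c("A", "C", "A", "D"), c("C", "B", "D", "B"))
  cnt <- shortest_path_edge_counts(g, "A", "B")
  expect_equal(sort(names(cnt)), c("A|C", "A|D", "B|C", "B|D"))
  expect_true(all(cnt == 1))

  # 4-cycle
  cyc <- ppi_graph(c("A", "B", "C", "D"), c("B", "C", "D", "A"))
  cc <- shortest_path_edge_counts(cyc, "A", "C")
  expect_true(all(cc[c("A|B", "B|C", "A|D", "C|D")] == 1))

  # path graph
  pg <- ppi_graph(c("A", "B"), c("B", "C"))
  expect_equal(shortest_path_edge_counts(pg, "A", "C"),
               c("A|B" = 1, "B|C" = 1))

  expect_length(shortest_path_edge_counts(pg, "A", "A"), 0)

  disc <- ppi_graph(c("A", "C"), c("B", "D"))
  expect_length(shortest_path_edge_counts(disc, "A", "C"), 0)
})

test_that("sigma-product counting matches enumeration on random graphs", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    g <- random_connected_graph(n)
    nodes <- sample(igraph::V(g)$name, 2)
    mine <- shortest_path_edge_counts(g, nodes[1], nodes[2])
    oracle <- enum_edge_counts(g, nodes[1], nodes[2])
    expect_equal(mine[order(names(mine))], oracle[order(names(oracle))])
  }
})

test_that("local networks sum path counts over cross-anchor pairs", {
  g <- ppi_graph(c("A", "C", "A", "D"), c("C", "B", "D", "B"))
  bag <- build_local_network("A", "B", g)
  expect_true(all(bag[c("A|C", "B|C", "A|D", "B|D")] == 1))

  # direct edge
  direct <- ppi_graph("A", "B")
  expect_equal(build_local_network("A", "B", direct), c("A|B" = 1))

  # total token count = sum over pairs of (#paths x path length)
  set.seed(7)
  gg <- random_connected_graph(9)
  nm <- igraph::V(gg)$name
  A <- nm[1:3]; B <- nm[4:6]
  bag2 <- build_local_network(A, B, gg)
  expected <- 0
  for (s in A) for (t in B) {
    if (s == t) next
    expected <- expected + sum(enum_edge_counts(gg, s, t))
  }
  expect_equal(sum(bag2), expected)

  # TF bound on both anchors: self pair contributes nothing
  path <- ppi_graph(c("A", "B"), c("B", "C"))
  both <- build_local_network(c("A"), c("A", "C"), path)
  expect_equal(sum(both), 2)  # only A->C

  # disconnected pair and TFs absent from the reference give empty bags
  disc <- ppi_graph(c("A", "X"), c("B", "Y"))
  expect_length(build_local_network("A", "X", disc), 0)
  expect_length(build_local_network("Z", "A", disc), 0)
})

test_that("outlier filtering enforces strict document-frequency bounds", {
  # 100 bags: token 1 in 85 (df 0.85 removed), token 2 in 4 (df 0.04
  # removed), tokens 3 and 4 in 60 each (kept), token 5 in exactly 80
  # (kept: df = 0.80 is not > 0.80); every bag retains a kept token
  bags <- lapply(1:100, function(i) {
    b <- c()
    if (i <= 85) b <- c(b, "1" = 1L)
    if (i <= 4)  b <- c(b, "2" = 1L)
    if (i <= 60) b <- c(b, "3" = 1L)
    if (i >= 41) b <- c(b, "4" = 1L)
    if (i <= 80) b <- c(b, "5" = 1L)
    b
  })
  corp <- manual_corpus(bags, V = 5)
  filt <- filter_outlier_edges(corp, 0.05, 0.80)
  kept_edges <- cmnet:::edge_labels(filt$vocabulary)
  all_edges <- cmnet:::edge_labels(corp$vocabulary)
  expect_setequal(kept_edges, all_edges[c(3, 4, 5)])
  expect_equal(filt$vocabulary$token_id, seq_len(nrow(filt$vocabulary)))
  expect_equal(filt$info$dropped_bags, 0)

  # identity thresholds leave the corpus unchanged
  same <- filter_outlier_edges(corp, 0, 1)
  expect_equal(same$bags, corp$bags)
  expect_equal(same$vocabulary, corp$vocabulary)

  # idempotence
  twice <- filter_outlier_edges(filt, 0.05, 0.80)
  expect_equal(twice$bags, filt$bags)
  expect_equal(twice$vocabulary$token_id, filt$vocabulary$token_id)

  # bags holding only removed tokens are dropped and counted
  bags2 <- c(rep(list(c("1" = 1L, "2" = 1L)), 30), rep(list(c("1" = 1L)), 22))
  corp2 <- manual_corpus(bags2, V = 2)
  filt2 <- filter_outlier_edges(corp2, 0.05, 0.80)  # token 1 df=1 removed
  expect_equal(filt2$info$dropped_bags, 22)
  expect_length(filt2$bags, 30)

  expect_error(filter_outlier_edges(corp2, 0.9, 0.95), "emptied")
  expect_error(filter_outlier_edges(corp, 0.5, 0.5))
})

test_that("corpus construction drops empty interactions and indexes tokens", {
  inter <- read_interactions(write_lines_tmp(c(
    "chr1\t1000\t1400\tchr1\t50000\t50400\tA1",
    "chr1\t2000\t2400\tchr1\t60000\t60400\tA2",
    "chr9\t1000\t1400\tchr9\t2000\t2400\tA3")))   # no peaks on chr9
  pk <- structure(list(
    T1 = data.frame(chrom = "chr1", start = c(1100L, 2100L), end = c(1200L, 2200L)),
    T2 = data.frame(chrom = "chr1", start = c(50100L, 60100L), end = c(50200L, 60200L))),
    class = "cmn_peaks")
  ref <- ppi_graph(c("T1", "X"), c("X", "T2"))
  corp <- build_corpus(inter, pk, ref, flank = 1500)
  expect_length(corp$bags, 2)
  expect_equal(corp$info$dropped_empty, 1)
  expect_setequal(cmnet:::edge_labels(corp$vocabulary), c("T1|X", "T2|X"))
  expect_true(all(unlist(corp$bags) >= 1))
})
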