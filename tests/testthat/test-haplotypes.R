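meta2pop <- function(ids, pops) {
  data.frame(sample_id = ids, population = pops,
             lineage = ifelse(pops == "P1", "north", "south"))
}

test_that("haplotype collapsing groups identical sequences and counts by population", {
  seqs <- c(s1 = "AAAA", s2 = "AAAT", s3 = "AAAA", s4 = "TTTT", s5 = "AAAT")
  a <- make_alignment(seqs, meta2pop(names(seqs), c("P1", "P1", "P2", "P2", "P2")))
  ht <- collapseHaplotypes(a)
  expect_equal(length(hapSequences(ht)), 3L)
  expect_equal(sum(hapCounts(ht)), 5L)
  expect_equal(hapLabels(ht), c("H01", "H02", "H03"))
  # labels in first-observed order
  expect_equal(unname(hapSequences(ht)), c("AAAA", "AAAT", "TTTT"))
  expect_equal(unname(hapCounts(ht)["H01", ]), c(P1 = 1L, P2 = 1L),
               ignore_attr = TRUE)

  all_same <- make_alignment(c(a = "GGGG", b = "GGGG"),
                             meta2pop(c("a", "b"), c("P1", "P1")))
  expect_equal(length(hapSequences(collapseHaplotypes(all_same))), 1L)

  expect_error(collapseHaplotypes(make_alignment(seqs),
                                  meta2pop("s1", "P1")), "without metadata")
})

test_that("collapsing is invariant to sample order up to label permutation", {
  set.seed(3)
  seqs <- setNames(sample(c("AAAA", "AAAT", "ATTT"), 12, TRUE),
                   paste0("s", 1:12))
  meta <- meta2pop(names(seqs), rep(c("P1", "P2"), 6))
  ht1 <- collapseHaplotypes(make_alignment(seqs, meta))
  perm <- sample(12)
  ht2 <- collapseHaplotypes(make_alignment(seqs[perm], meta))
  key <- function(h) {
    k <- hapCounts(h)[order(hapSequences(h)), , drop = FALSE]
    rownames(k) <- unname(sort(hapSequences(h)))
    k
  }
  expect_equal(key(ht1), key(ht2))
})

test_that("hammingMatrix counts differing sites", {
  d <- hammingMatrix(c(a = "AAA", b = "AAT", c = "AAA"))
  expect_equal(d["a", "b"], 1L)
  expect_equal(d["a", "c"], 0L)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("median-joining network solves the star and square cases", {
  star <- make_haplotable(c("AAAA", "TAAA", "ATAA", "AATA"))
  net <- medianJoiningNetwork(star)
  expect_equal(sum(networkNodes(net)$median), 0L)
  expect_equal(nrow(networkEdges(net)), 3L)
  expect_true(all(networkEdges(net)$steps == 1L))

  square <- make_haplotable(c("AA", "TA", "AT", "TT"))
  net2 <- medianJoiningNetwork(square)
  ed <- networkEdges(net2)
  expect_equal(nrow(ed), 4L)               # 4-cycle of unit edges
  expect_true(all(ed$steps == 1L))
  deg <- table(c(ed$from, ed$to))
  expect_true(all(deg == 2L))
  expect_equal(sum(networkNodes(net2)$median), 0L)
})

test_that("median vectors are inferred where a missing haplotype ties groups", {
  # three observed haplotypes pairwise 2 steps apart whose majority
  # consensus is unsampled: one median of degree 3 must appear
  trio <- make_haplotable(c("TAAA", "ATAA", "AATA"))
  net <- medianJoiningNetwork(trio)
  nd <- networkNodes(net)
  expect_equal(sum(nd$median), 1L)
  expect_equal(nd$sequence[nd$median], "AAAA")
  ed <- networkEdges(net)
  mv <- nd$label[nd$median]
  expect_equal(sum(ed$from == mv | ed$to == mv), 3L)
})

test_that("with no medians added the network equals the minimum-spanning network", {
  set.seed(11)
  for (rep in 1:4) {
    seqs <- unique(replicate(6, paste0(sample(c("A", "T"), 8, TRUE),
                                       collapse = "")))
    ht <- make_haplotable(seqs)
    net <- medianJoiningNetwork(ht)
    d <- hammingMatrix(hapSequences(ht))
    # every MST's edges are a subset of the network (check via total weight:
    # an MST built on the network's edge set must reach the matrix MST weight)
    g_full <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                                  mode = "undirected")
    w_mst <- sum(igraph::E(igraph::mst(g_full))$weight)
    g_net <- asIgraph(net)
    obs_nodes <- networkNodes(net)$label[!networkNodes(net)$median]
    w_net_mst <- sum(igraph::E(igraph::mst(g_net, weights =
                                             igraph::E(g_net)$steps))$weight)
    if (sum(networkNodes(net)$median) == 0)
      expect_equal(w_net_mst, w_mst)
    # path-length lower bound: network distance >= Hamming distance
    sp <- igraph::distances(g_net, weights = igraph::E(g_net)$steps)
    expect_true(all(sp[obs_nodes, obs_nodes] >= d[obs_nodes, obs_nodes]))
  }
})

test_that("network writers produce readable files", {
  ht <- make_haplotable(c("AAAA", "TAAA", "ATAA"))
  net <- medianJoiningNetwork(ht)
  gml <- tempfile(fileext = ".graphml")
  writeGraphML(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(networkNodes(net)))
  nex <- tempfile(fileext = ".nex")
  writeNexusHaplotypes(ht, nex)
  expect_true(any(grepl("BEGIN TRAITS", readLines(nex))))
  tsv <- tempfile(fileext = ".tsv")
  writeHaplotypeTable(ht, tsv)
  expect_equal(nrow(read.delim(tsv)), ncol(hapCounts(ht)))
})
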