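test_that("haplotype diversity matches the closed form and its edge cases", {
  expect_equal(haplotypeDiversity(c(4, 1, 1))$Hd, 0.6)
  expect_equal(round(haplotypeDiversity(c(4, 1, 1))$Hd_sd, 1), 0.2)
  expect_equal(haplotypeDiversity(c(3, 1, 1))$Hd, 0.7)
  expect_equal(haplotypeDiversity(c(10))$Hd, 0)          # single haplotype
  expect_equal(haplotypeDiversity(rep(1, 7))$Hd, 1)      # all distinct
  expect_error(haplotypeDiversity(c(1)), "at least 2")
})

test_that("nucleotide diversity is the mean pairwise p-distance", {
  expect_equal(nucleotideDiversity(c("ACGT", "ACGT"))$pi, 0)
  expect_equal(nucleotideDiversity(c(strrep("A", 100),
                                     paste0("T", strrep("A", 99))))$pi, 0.01)
  expect_equal(nucleotideDiversity(c("AAAA", "AAAT", "AATT"))$pi,
               (1 + 2 + 1) / 3 / 4)
  expect_error(nucleotideDiversity("ACGT"), "at least 2")
})

test_that("TN93 distances agree with the ape implementation", {
  set.seed(42)
  anc <- sample(c("A", "C", "G", "T"), 200, TRUE,
                prob = c(0.35, 0.15, 0.15, 0.35))
  seqs <- replicate(6, {
    s <- anc
    hit <- sample(200, 12)
    s[hit] <- sample(c("A", "C", "G", "T"), 12, TRUE)
    paste0(s, collapse = "")
  })
  names(seqs) <- paste0("s", 1:6)
  d <- tamuraNeiDistance(seqs)
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "TN93", base.freq = NULL))
  expect_equal(unname(d), unname(ref), tolerance = 1e-6)
})

test_that("TN93 distances are symmetric, zero on identical pairs, >= p-distance", {
  seqs <- c(a = "AAAAACCCCC", b = "AAAAACCCCC", c = "AAGAACCTCC")
  # short sequences can saturate a TN93 term; the p-distance fallback warns
  d <- suppressWarnings(tamuraNeiDistance(seqs))
  expect_equal(d["a", "b"], 0)
  expect_true(isSymmetric(d))
  p <- hammingMatrix(seqs) / 10
  expect_true(all(d >= p - 1e-12))
})

test_that("AMOVA recovers the fixed-difference and null extremes", {
  seqs <- setNames(c(rep("AAA", 5), rep("AAT", 5)), paste0("s", 1:10))
  d <- hammingMatrix(seqs)
  pop <- rep(c("P1", "P2"), each = 5)
  r <- amova(d, pop, nperm = 99, seed = 1)
  expect_equal(unname(r$indices["FST"]), 1)
  expect_equal(sum(r$table$df[1:2]), 9)
  expect_equal(r$table$percent[3], 100)

  set.seed(8)
  seqs2 <- setNames(sample(c("AAA", "AAT", "ATT", "TTT"), 40, TRUE),
                    paste0("s", 1:40))
  r2 <- amova(hammingMatrix(seqs2), rep(c("P1", "P2"), 20), nperm = 199,
              seed = 2)
  expect_lt(abs(r2$indices["FST"]), 0.15)
  expect_gt(r2$pvalues["FST"], 0.05)
})

test_that("single-population AMOVA puts all variance within populations", {
  seqs <- setNames(c("AAA", "AAT", "ATT", "TTT"), paste0("s", 1:4))
  r <- amova(hammingMatrix(seqs), rep("P1", 4), nperm = 19, seed = 1)
  expect_equal(unname(r$indices["FST"]), 0)
  expect_equal(r$table$percent[1], 100)
})

test_that("two-level AMOVA decomposition is internally consistent", {
  set.seed(5)
  seqs <- setNames(c(rep("AAAA", 6), rep("TTAA", 6), rep("TTTT", 6)),
                   paste0("s", 1:18))
  pop <- rep(c("P1", "P2", "P3", "P4", "P5", "P6"), each = 3)
  grp <- rep(c("G1", "G2", "G3"), each = 6)
  r <- amova(hammingMatrix(seqs), pop, grp, nperm = 99, seed = 1)
  expect_equal(sum(r$table$df[1:3]), 17)
  expect_equal(r$table$percent[4], 100)
  v <- r$table$variance
  expect_equal(unname(r$indices["FCT"]), v[1] / v[4])
  expect_equal(unname(r$indices["FSC"]), v[2] / (v[2] + v[3]))
  expect_equal(unname(r$indices["FST"]), (v[1] + v[2]) / v[4])
})

test_that("pairwise FST equals the two-population AMOVA", {
  seqs <- setNames(c(rep("AAA", 4), rep("AAT", 4), rep("TTT", 4)),
                   paste0("s", 1:12))
  d <- hammingMatrix(seqs)
  pop <- rep(c("P1", "P2", "P3"), each = 4)
  pf <- pairwiseFst(d, pop, nperm = 19, seed = 1)
  expect_equal(pf$fst["P1", "P2"],
               unname(amova(d[1:8, 1:8], pop[1:8], nperm = 19,
                            seed = 1)$indices["FST"]))
  expect_equal(pf$fst["P1", "P3"], 1)      # fully fixed difference
  expect_equal(pf$fst["P1", "P1"], 0)
})

test_that("NST collapses to GST for equidistant haplotypes", {
  ht <- table1Fixture()
  k <- length(hapSequences(ht))
  eq <- matrix(3, k, k, dimnames = list(hapLabels(ht), hapLabels(ht)))
  diag(eq) <- 0
  suppressMessages(r <- gstNst(ht, dist = eq, nperm = 99, seed = 1))
  expect_equal(r$G_ST, r$N_ST)
})

test_that("GST is ~0 for identical population frequency vectors", {
  seqs <- stats::setNames(c("AAAA", "AATT", "TTTT"), c("H01", "H02", "H03"))
  cts <- matrix(c(4L, 2L, 2L, 4L, 2L, 2L), 3, 2,
                dimnames = list(names(seqs), c("P1", "P2")))
  ht <- new("HaplotypeTable", sequences = seqs, counts = cts,
            lineages = character(0))
  r <- gstNst(ht, nperm = 99, seed = 1)
  # the unbiased estimator is slightly negative (small-sample correction)
  expect_lt(abs(r$G_ST), 0.1)
  # monomorphic data is an error
  mono <- new("HaplotypeTable",
              sequences = stats::setNames("AAAA", "H01"),
              counts = matrix(c(3L, 3L), 1, 2,
                              dimnames = list("H01", c("P1", "P2"))),
              lineages = character(0))
  expect_error(gstNst(mono, nperm = 9, seed = 1), "monomorphic")
})

test_that("gstNst permutation null keeps observed NST in the body", {
  # random assignment of haplotype identities: p should not be extreme
  set.seed(14)
  k <- 12
  seqs <- stats::setNames(
    unique(replicate(k, paste0(sample(c("A", "T"), 12, TRUE), collapse = ""))),
    NULL)
  k <- length(seqs)
  names(seqs) <- sprintf("H%02d", seq_len(k))
  cts <- matrix(rpois(k * 4, 2) + 1L, k, 4,
                dimnames = list(names(seqs), paste0("P", 1:4)))
  ht <- new("HaplotypeTable", sequences = seqs, counts = cts,
            lineages = character(0))
  r <- gstNst(ht, nperm = 199, seed = 3)
  expect_gt(r$p_NST, 0.02)
})

test_that("Mantel IBD behaves on exact and permuted inputs", {
  set.seed(2)
  k <- 6
  geo <- as.matrix(dist(cbind(runif(k), runif(k))))
  rownames(geo) <- colnames(geo) <- paste0("P", 1:k)
  r <- mantelIBD(geo, geo, nperm = 99, seed = 1)
  expect_equal(r$r, 1)
  # r invariant under a joint relabelling of both matrices
  perm <- sample(k)
  gen <- as.matrix(dist(runif(k)))
  rownames(gen) <- colnames(gen) <- paste0("P", 1:k)
  r1 <- mantelIBD(gen, geo, nperm = 49, seed = 1)
  r2 <- mantelIBD(gen[perm, perm], geo[perm, perm], nperm = 49, seed = 1)
  expect_equal(r1$r, r2$r)
  expect_error(mantelIBD(geo[1:2, 1:2], geo[1:2, 1:2], nperm = 9, seed = 1),
               "at least 3")
})

test_that("great-circle and planar population distances are available", {
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     population = c("P1", "P1", "P2", "P3"),
                     lineage = "x",
                     lat = c(20, 20, 21, 22), lon = c(-98, -98, -98, -98))
  gc <- geographicDistance(meta)
  pl <- geographicDistance(meta, method = "planar")
  expect_equal(dim(gc), c(3, 3))
  expect_equal(pl["P1", "P2"], 1)
  expect_equal(gc["P1", "P2"], 111.19, tolerance = 0.01)  # ~1 degree of latitude
})
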