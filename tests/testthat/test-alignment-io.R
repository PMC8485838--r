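test_that("readAlignment round-trips and sanitises input", {
  a <- make_alignment(c(s1 = "acgtacgtaa", s2 = "ACGTACGTAA", s3 = "ACGUACGUAA"))
  expect_s4_class(a, "HaploAlignment")
  expect_equal(alnLength(a), 10L)
  expect_equal(sampleIDs(a), c("s1", "s2", "s3"))
  # lower case and U are normalised, so all three are identical
  expect_equal(length(unique(as.character(a@seqs))), 1L)
})

test_that("readAlignment rejects malformed input", {
  expect_error(readAlignment(write_fasta(c(a = "ACGTACGTA", b = "ACGTACGTAA"))),
               "ragged")
  expect_error(readAlignment(write_fasta(c(a = "ACGT", a = "ACGT"))),
               "duplicate")
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(readAlignment(empty), "empty")
  expect_error(readAlignment(write_fasta(c(a = "ACXT", b = "ACGT"))),
               "illegal")
  expect_error(readAlignment(tempfile()), "not found")
})

test_that("concatenation records tiling partitions and checks sample sets", {
  a1 <- make_alignment(c(x = "AAAAA", y = "CCCCC"))
  a2 <- make_alignment(c(y = "GGGGG", x = "TTTTT"))
  cc <- concatenateAlignments(list(r1 = a1, r2 = a2))
  expect_equal(alnLength(cc), 10L)
  p <- partitions(cc)
  expect_equal(nrow(p), 2L)
  expect_equal(p$start, c(1L, 6L))
  expect_equal(p$end, c(5L, 10L))
  # per-sample region order: x gets AAAAA then TTTTT
  expect_equal(as.character(cc@seqs[["x"]]), "AAAAATTTTT")
  a3 <- make_alignment(c(z = "AAAAA", w = "CCCCC"))
  expect_error(concatenateAlignments(list(a1, a3)), "mismatched")
  expect_error(concatenateAlignments(list()), "empty")
})

test_that("four-region concatenation reproduces the cpDNA spans", {
  lens <- c(`trnT-trnL` = 744, `trnK5-matk` = 789, `rpl32-trnL` = 624,
            `trnS-trnG` = 702)
  regs <- lapply(lens, function(L)
    make_alignment(c(s1 = strrep("A", L), s2 = strrep("C", L))))
  cc <- concatenateAlignments(regs)
  p <- partitions(cc)
  expect_equal(p$start, c(1L, 745L, 1534L, 2158L))
  expect_equal(p$end, c(744L, 1533L, 2157L, 2859L))
  expect_equal(alnLength(cc), 2859L)
  # spans tile [1, length] without overlap
  expect_equal(unlist(Map(seq, p$start, p$end), use.names = FALSE),
               seq_len(alnLength(cc)))
})

test_that("complete-column filtering drops gaps/ambiguity and classifies sites", {
  a <- make_alignment(c(s1 = "AAAGA-", s2 = "AAAGAC", s3 = "TATGNC",
                        s4 = "TAAGAC"))
  f <- filterCompleteColumns(a)
  # col 5 has N, col 6 has -, both removed
  expect_equal(alnLength(f$alignment), 4L)
  expect_equal(f$map$original, 1:4)
  sc <- f$siteClasses
  expect_equal(sc@complete, 1:4)
  expect_equal(sc@polymorphic, c(1L, 3L))   # {A,A,T,T} and {A,A,T,A}
  expect_equal(sc@informative, 1L)          # {A,A,T,T}
  expect_equal(sc@singleton, 3L)            # {A,A,T,A}
  # idempotence
  f2 <- filterCompleteColumns(f$alignment)
  expect_equal(as.character(f2$alignment@seqs), as.character(f$alignment@seqs))
  expect_equal(f2$siteClasses@polymorphic, c(1L, 3L))
  expect_error(filterCompleteColumns(make_alignment(c(a = "-N", b = "A-"))),
               "no complete columns")
})

test_that("two-sequence alignments have no parsimony-informative sites", {
  for (k in 1:5) {
    set.seed(k)
    s <- replicate(2, paste0(sample(c("A", "C", "G", "T"), 30, TRUE),
                             collapse = ""))
    f <- filterCompleteColumns(make_alignment(c(a = s[1], b = s[2])))
    expect_length(f$siteClasses@informative, 0L)
  }
})

test_that("metadata reading validates structure and ranges", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = c("s1", "s2", "s3"),
                   population = c("P1", "P1", "P2"),
                   lineage = c("north", "north", "south"),
                   lat = c(20, 20.1, 18), lon = c(-98, -98, -96))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- readSampleMetadata(tsv)
  expect_equal(nrow(m), 3L)
  df_bad <- df; df_bad$lat[1] <- 200
  write.table(df_bad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSampleMetadata(tsv), "latitude")
  df_bad <- df; df_bad$lineage[2] <- "south"
  write.table(df_bad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSampleMetadata(tsv), "more than one lineage")
  write.table(df[, 1:2], tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSampleMetadata(tsv), "missing columns")
})

test_that("metadata attachment requires every sample and reports extras", {
  a <- make_alignment(c(s1 = "ACGT", s2 = "ACGT"))
  meta <- data.frame(sample_id = c("s1", "s2", "zz"),
                     population = "P1", lineage = "north")
  expect_message(sampleData(a) <- meta, "unknown sample ids")
  expect_equal(nrow(sampleData(a)), 2L)
  expect_error(sampleData(a) <- meta[1, ], "missing for samples")
})
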