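# in-code fixtures shared across test files

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

make_alignment <- function(seqs, meta = NULL) {
  a <- readAlignment(write_fasta(seqs))
  if (!is.null(meta)) sampleData(a) <- meta
  a
}

make_haplotable <- function(seqs, counts = NULL, pops = "P1") {
  labels <- sprintf("H%02d", seq_along(seqs))
  if (is.null(counts))
    counts <- matrix(1L, length(seqs), length(pops),
                     dimnames = list(labels, pops))
  new("HaplotypeTable", sequences = stats::setNames(seqs, labels),
      counts = counts, lineages = character(0))
}

# printed per-population haplotype diversities of the 20-population design
# (rows with n >= 2), to 2 decimals as published
TABLE1_HD <- c(FO = 1, SI = 0.83, CS = 1, JH = 1, TL = 0.9, MO = 0.9,
               HA = 0.8, TU = 0.6, MM = 1, GO = 0.93, CI = 0.87, AC = 1,
               MA = 1, MY = 1, CP = 1, FXC = 1, ZA = 0.9, SC = 0.7)
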