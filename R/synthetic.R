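#' @include abc.R
NULL

# per-population sample sizes mimicking the study design: 4 northern, 15
# central and 1 southern population (17 / 74 / 5 individuals)
.STUDY_POPS <- list(
  north = c(FO = 3, SI = 4, CS = 4, JH = 6),
  central = c(TL = 5, MO = 7, HA = 6, TU = 6, MM = 6, GO = 6, CI = 6,
              TLA = 1, MI = 1, AC = 9, MA = 5, MY = 5, CP = 4, FXC = 2,
              ZA = 5),
  south = c(SC = 5))

# synthetic population centroids (decimal degrees) along the Sierra Madre
# Oriental gradient; jittered deterministically per population
.STUDY_COORDS <- function(pops) {
  anchor <- list(north = c(21.8, -99.2), central = c(20.2, -98.2),
                 south = c(17.6, -96.5))
  out <- lapply(names(pops), function(g) {
    k <- length(pops[[g]])
    data.frame(population = names(pops[[g]]),
               lineage = g,
               lat = anchor[[g]][1] + seq(-0.6, 0.6, length.out = max(k, 2))[seq_len(k)],
               lon = anchor[[g]][2] + seq(-0.5, 0.5, length.out = max(k, 2))[seq_len(k)])
  })
  do.call(rbind, out)
}

#' Study-shaped synthetic dataset
#'
#' Simulates one dataset under a demographic scenario and dresses it as a
#' field study: samples are split into populations (by contiguous blocks in
#' sample order) with sizes mimicking the real sampling design, given
#' synthetic coordinates, and optionally written as FASTA + metadata TSV +
#' a JSON manifest of the true parameters.
#'
#' @param scenario Scenario id (default 2).
#' @param params Named parameter vector. The defaults state a history that
#'   reproduces the study's observed diversity scales: current sizes 6e4
#'   (prior-midpoint scale), ancestral size 2e4 (the bottleneck behind the
#'   inferred pre-LGM expansion), t2 = 2e4 generations (~200 ka, the skyline
#'   expansion onset) and t1 = 3500 generations (~35 ka, the inferred
#'   north/central divergence), r = 0.5.
#' @param sample_sizes Per-group sizes (default `c(17, 74, 5)`).
#' @param pops Per-group named vectors of population sizes (default the
#'   20-population study layout); must sum to `sample_sizes`.
#' @param L Locus length (default 2858).
#' @param spec A [priorSpec].
#' @param seed Mandatory RNG seed.
#' @param out_dir Optional directory to write `alignment.fasta`,
#'   `metadata.tsv` and `truth.json`.
#' @return A list with `alignment` (a [HaploAlignment] with metadata),
#'   `metadata` and `truth`.
#' @export
generateStudyLike <- function(scenario = 2, params = NULL,
                              sample_sizes = c(17, 74, 5),
                              pops = .STUDY_POPS, L = 2858,
                              spec = priorSpec(), seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(params))
    params <- stats::setNames(c(2e4, 6e4, 6e4, 6e4, 3500, 2e4,
                                if (scenario == 5) 0.5 else NA),
                              .ABC_PARAM_NAMES)
  sizes <- vapply(pops, sum, numeric(1))
  if (!all(sizes == sample_sizes))
    stop("population sizes do not sum to the group sample sizes")
  set.seed(seed)
  a <- simulateDataset(scenario, params, sample_sizes, L, spec, full = TRUE)
  meta <- sampleData(a)
  popvec <- unlist(lapply(names(pops), function(g) rep(names(pops[[g]]), pops[[g]])))
  meta$population <- popvec
  coords <- .STUDY_COORDS(pops)
  meta$lat <- coords$lat[match(meta$population, coords$population)]
  meta$lon <- coords$lon[match(meta$population, coords$population)]
  sampleData(a) <- meta
  truth <- list(scenario = scenario, params = as.list(params[!is.na(params)]),
                sample_sizes = sample_sizes, L = L, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeAlignment(a, file.path(out_dir, "alignment.fasta"))
    utils::write.table(meta, file.path(out_dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(alignment = a, metadata = meta, truth = truth)
}

# Table-1 haplotype listing of the study (population x haplotype counts)
.TABLE1 <- list(
  FO = c(H18 = 1, H20 = 1, H21 = 1),
  SI = c(H31 = 2, H46 = 1, H47 = 1),
  CS = c(H01 = 1, H02 = 1, H18 = 1, H19 = 1),
  JH = c(H18 = 1, H20 = 1, H29 = 1, H30 = 1, H31 = 1, H32 = 1),
  TL = c(H02 = 2, H12 = 1, H35 = 1, H48 = 1),
  MO = c(H03 = 2, H25 = 1, H26 = 1, H35 = 2, H38 = 1),
  HA = c(H03 = 3, H26 = 1, H27 = 1, H28 = 1),
  TU = c(H03 = 4, H12 = 1, H49 = 1),
  MM = c(H02 = 1, H03 = 1, H15 = 1, H25 = 1, H35 = 1, H37 = 1),
  GO = c(H02 = 2, H03 = 1, H15 = 1, H24 = 1, H25 = 1),
  CI = c(H03 = 2, H11 = 2, H12 = 1, H13 = 1),
  TLA = c(H10 = 1),
  MI = c(H36 = 1),
  AC = c(H01 = 1, H02 = 1, H03 = 1, H04 = 1, H05 = 1, H06 = 1, H07 = 1,
         H08 = 1, H09 = 1),
  MA = c(H03 = 1, H12 = 1, H33 = 1, H34 = 1, H35 = 1),
  MY = c(H03 = 1, H39 = 1, H40 = 1, H41 = 1, H42 = 1),
  CP = c(H14 = 1, H15 = 1, H16 = 1, H17 = 1),
  FXC = c(H22 = 1, H23 = 1),
  ZA = c(H02 = 1, H03 = 2, H12 = 1, H35 = 1),
  SC = c(H43 = 3, H44 = 1, H45 = 1))

.TABLE1_LINEAGE <- c(FO = "north", SI = "north", CS = "north", JH = "north",
                     TL = "central", MO = "central", HA = "central",
                     TU = "central", MM = "central", GO = "central",
                     CI = "central", TLA = "central", MI = "central",
                     AC = "central", MA = "central", MY = "central",
                     CP = "central", FXC = "central", ZA = "central",
                     SC = "south")

#' Published haplotype-count configuration as a fixture
#'
#' Returns the exact per-population haplotype counts of the 20-population /
#' 96-individual study design as a [HaplotypeTable]. The sequences are
#' synthetic placeholders (a star: every haplotype one step from H01), which
#' is sufficient for frequency-based statistics such as haplotype diversity
#' but carries no claim about the real sequences.
#'
#' @return A [HaplotypeTable] with 49 haplotypes over 96 individuals.
#' @export
table1Fixture <- function() {
  labels <- sprintf("H%02d", 1:49)
  L <- 50
  seqs <- vapply(1:49, function(i) {
    s <- rep("A", L)
    if (i > 1) s[i] <- "T"
    paste0(s, collapse = "")
  }, character(1))
  names(seqs) <- labels
  cts <- matrix(0L, 49, length(.TABLE1),
                dimnames = list(labels, names(.TABLE1)))
  for (p in names(.TABLE1)) cts[names(.TABLE1[[p]]), p] <- .TABLE1[[p]]
  new("HaplotypeTable", sequences = seqs, counts = cts,
      lineages = .TABLE1_LINEAGE)
}
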