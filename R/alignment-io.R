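#' @include AllGenerics.R
NULL

.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

.hamming <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(x != y)
}

.sanitize_seqs <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  x <- gsub("?", "N", x, fixed = TRUE)
  bad <- grepl(paste0("[^ACGT", paste(.IUPAC_AMBIG, collapse = ""), "-]"), x)
  if (any(bad))
    stop("illegal characters in sequence(s): ",
         paste(names(x)[bad], collapse = ", "))
  x
}

.new_alignment <- function(seqs, partitions = NULL, sampleData = NULL) {
  if (is.null(partitions))
    partitions <- data.frame(region = character(), start = integer(),
                             end = integer())
  if (is.null(sampleData))
    sampleData <- data.frame(sample_id = character(), population = character(),
                             lineage = character())
  new("HaploAlignment", seqs = Biostrings::DNAStringSet(seqs),
      partitions = partitions, sampleData = sampleData)
}

#' Read an aligned FASTA file
#'
#' Reads a multi-record aligned FASTA into a [HaploAlignment]. Sequences are
#' upper-cased, `U` is mapped to `T` and `?` to `N`; ragged (unequal-length)
#' inputs, duplicate ids, empty files and non-nucleotide characters are
#' rejected.
#'
#' @param path Path to an aligned FASTA file.
#' @return A [HaploAlignment].
#' @export
readAlignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA: ", path)
  ids <- names(raw)
  # keep the id part only (up to first whitespace), preserved verbatim
  ids <- sub("[ \t].*$", "", ids)
  if (anyDuplicated(ids)) stop("duplicate ids in ", path)
  x <- as.character(raw)
  names(x) <- ids
  if (length(unique(nchar(x))) != 1L)
    stop("ragged alignment: records differ in length")
  .new_alignment(.sanitize_seqs(x))
}

#' Write a HaploAlignment to FASTA
#'
#' @param a A [HaploAlignment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(a, path) {
  Biostrings::writeXStringSet(a@seqs, path)
  invisible(path)
}

#' Concatenate per-region alignments into one matrix
#'
#' Joins alignments of the same sample set column-wise (in the order given),
#' recording each region's 1-based column span in `partitions`.
#'
#' @param alignments Named list of [HaploAlignment] objects sharing an
#'   identical sample-id set; names become region names.
#' @return A [HaploAlignment] whose length is the sum of the input lengths.
#' @export
concatenateAlignments <- function(alignments) {
  if (length(alignments) == 0L) stop("empty input list")
  if (is.null(names(alignments)) || any(names(alignments) == ""))
    names(alignments) <- paste0("region", seq_along(alignments))
  ids <- sampleIDs(alignments[[1]])
  for (a in alignments[-1])
    if (!setequal(ids, sampleIDs(a)))
      stop("mismatched sample sets across regions")
  lens <- vapply(alignments, alnLength, integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  seqs <- vapply(alignments, function(a) {
    s <- as.character(a@seqs)
    unname(s[match(ids, sampleIDs(a))])
  }, character(length(ids)))
  if (is.null(dim(seqs))) seqs <- matrix(seqs, nrow = length(ids))
  out <- apply(seqs, 1L, paste0, collapse = "")
  names(out) <- ids
  .new_alignment(out,
                 partitions = data.frame(region = names(alignments),
                                         start = starts, end = as.integer(ends)))
}

.site_classes <- function(mat, original_idx) {
  n <- nrow(mat)
  poly <- integer(0)
  info <- integer(0)
  for (j in seq_len(ncol(mat))) {
    tab <- table(mat[, j])
    if (length(tab) >= 2L) {
      poly <- c(poly, j)
      if (sum(tab >= 2L) >= 2L) info <- c(info, j)
    }
  }
  new("SiteClasses",
      complete = as.integer(original_idx),
      polymorphic = as.integer(original_idx[poly]),
      informative = as.integer(original_idx[info]),
      singleton = as.integer(setdiff(original_idx[poly], original_idx[info])))
}

#' Remove columns with gaps, missing or ambiguous bases (complete deletion)
#'
#' Keeps only columns in which every sequence has one of A/C/G/T, the
#' "complete deletion" treatment of gaps and missing data. Site classes
#' (polymorphic, parsimony-informative, singleton) are computed on the
#' filtered matrix but reported in the original 1-based column coordinates.
#'
#' @param a A [HaploAlignment].
#' @return A list with elements `alignment` (the filtered [HaploAlignment]),
#'   `siteClasses` (a [SiteClasses]) and `map` (a `data.frame` with columns
#'   `original`, `filtered`).
#' @export
filterCompleteColumns <- function(a) {
  mat <- seqMatrix(a)
  ok <- apply(mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  keep <- which(ok)
  if (length(keep) == 0L) stop("no complete columns remain after filtering")
  fmat <- mat[, keep, drop = FALSE]
  seqs <- apply(fmat, 1L, paste0, collapse = "")
  names(seqs) <- sampleIDs(a)
  out <- .new_alignment(seqs, sampleData = a@sampleData)
  list(alignment = out,
       siteClasses = .site_classes(fmat, keep),
       map = data.frame(original = keep, filtered = seq_along(keep)))
}

#' Read a sample metadata table
#'
#' Reads a TSV with columns `sample_id`, `population`, `lineage` and optional
#' `lat`, `lon`. Coordinates are checked for valid ranges and every population
#' code must map to exactly one lineage.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with one row per sample.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "population", "lineage")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop("duplicate sample ids in metadata")
  map <- unique(m[, c("population", "lineage")])
  dup <- map$population[duplicated(map$population)]
  if (length(dup))
    stop("population(s) mapped to more than one lineage: ",
         paste(unique(dup), collapse = ", "))
  if ("lat" %in% names(m) && any(!is.na(m$lat) & abs(m$lat) > 90))
    stop("latitude outside [-90, 90]")
  if ("lon" %in% names(m) && any(!is.na(m$lon) & abs(m$lon) > 180))
    stop("longitude outside [-180, 180]")
  m
}

#' Write site classes as a TSV report
#'
#' @param sc A [SiteClasses].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSiteClasses <- function(sc, path) {
  df <- data.frame(column = sc@complete,
                   class = ifelse(sc@complete %in% sc@informative, "informative",
                           ifelse(sc@complete %in% sc@singleton, "singleton",
                                  "monomorphic")))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
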