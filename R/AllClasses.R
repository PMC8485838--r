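#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
#' @importFrom Rcpp sourceCpp
#' @useDynLib cpPhylogeo, .registration = TRUE
NULL

#' Aligned cpDNA matrix with sample metadata
#'
#' Container for an aligned multi-sequence nucleotide matrix. Sequences are
#' stored as a [Biostrings::DNAStringSet] of equal width; optional `partitions`
#' record which 1-based column span each concatenated region occupies, and
#' `sampleData` holds per-sample population/lineage assignments and
#' coordinates.
#'
#' @slot seqs A `DNAStringSet`, all of identical width, named by sample id.
#' @slot partitions `data.frame` with columns `region`, `start`, `end`
#'   (1-based inclusive); zero rows when the alignment is a single region.
#' @slot sampleData `data.frame` with columns `sample_id`, `population`,
#'   `lineage` and optional `lat`, `lon`; zero rows until metadata is attached.
#' @export
setClass("HaploAlignment",
  representation(seqs = "DNAStringSet", partitions = "data.frame",
                 sampleData = "data.frame"))

setValidity("HaploAlignment", function(object) {
  s <- object@seqs
  if (length(s) == 0L) return("alignment has no sequences")
  w <- Biostrings::width(s)
  if (length(unique(w)) != 1L) return("ragged alignment: sequences differ in length")
  if (w[1] == 0L) return("alignment has zero columns")
  ids <- names(s)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) return("sequences must be named by sample id")
  if (anyDuplicated(ids)) return("duplicate sample ids")
  p <- object@partitions
  if (nrow(p)) {
    if (!all(c("region", "start", "end") %in% names(p)))
      return("partitions need columns region/start/end")
    if (any(p$start > p$end) || any(p$start < 1L) || any(p$end > w[1]))
      return("partition spans outside [1, length]")
  }
  m <- object@sampleData
  if (nrow(m) && !all(c("sample_id", "population", "lineage") %in% names(m)))
    return("sampleData needs sample_id/population/lineage columns")
  TRUE
})

#' Haplotype-by-population count table
#'
#' Unique (gap-free) sequences with labels `H01`, `H02`, ... in order of first
#' occurrence, and a haplotype x population matrix of individual counts.
#'
#' @slot sequences Named character vector of distinct haplotype sequences.
#' @slot counts Integer matrix, rows = haplotypes, columns = populations.
#' @slot lineages Named character vector mapping population code to lineage
#'   (may be empty).
#' @export
setClass("HaplotypeTable",
  representation(sequences = "character", counts = "matrix",
                 lineages = "character"))

setValidity("HaplotypeTable", function(object) {
  seqs <- object@sequences
  cts <- object@counts
  if (length(seqs) == 0L) return("no haplotypes")
  if (anyDuplicated(seqs)) return("haplotype sequences must be pairwise distinct")
  if (nrow(cts) != length(seqs)) return("counts rows must match haplotypes")
  if (!identical(rownames(cts), names(seqs))) return("counts rownames must equal haplotype labels")
  if (any(cts < 0) || any(cts != round(cts))) return("counts must be non-negative integers")
  if (any(rowSums(cts) < 1)) return("every haplotype must be observed at least once")
  if (length(object@lineages) &&
      !all(colnames(cts) %in% names(object@lineages)))
    return("every population must have a lineage when lineages are given")
  TRUE
})

#' Median-joining haplotype network
#'
#' Nodes are observed haplotypes plus inferred median vectors (flagged by
#' `median = TRUE`); each edge records the Hamming distance (mutation steps)
#' between its endpoint sequences.
#'
#' @slot nodes `data.frame` with columns `label`, `sequence`, `median`, `n`
#'   (total individuals carrying the haplotype; 0 for medians).
#' @slot edges `data.frame` with columns `from`, `to`, `steps`.
#' @slot epsilon Relaxation parameter used when the network was built.
#' @export
setClass("HaploNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 epsilon = "integer"))

setValidity("HaploNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (!all(c("label", "sequence", "median", "n") %in% names(nd)))
    return("nodes need label/sequence/median/n")
  if (nrow(ed) && !all(c("from", "to", "steps") %in% names(ed)))
    return("edges need from/to/steps")
  if (nrow(ed)) {
    if (!all(ed$from %in% nd$label) || !all(ed$to %in% nd$label))
      return("edge endpoints must be node labels")
    d <- mapply(function(a, b) .hamming(nd$sequence[nd$label == a],
                                        nd$sequence[nd$label == b]),
                ed$from, ed$to)
    if (!all(d == ed$steps)) return("edge steps must equal Hamming distance of endpoints")
  }
  if (nrow(nd) > 1L) {
    # connectivity by union-find
    comp <- seq_len(nrow(nd)); names(comp) <- nd$label
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (k in seq_len(nrow(ed))) {
      a <- find(match(ed$from[k], nd$label)); b <- find(match(ed$to[k], nd$label))
      comp[a] <- b
    }
    roots <- vapply(seq_len(nrow(nd)), find, integer(1))
    if (length(unique(roots)) != 1L) return("network must be connected")
  }
  TRUE
})

#' Site classification of a gap-free alignment
#'
#' Column indices (in the coordinates of the *original* alignment) that are
#' complete (no gap/ambiguity), polymorphic, parsimony-informative, or
#' singleton-variable.
#'
#' @slot complete integer vector of complete columns.
#' @slot polymorphic integer vector, subset of `complete`.
#' @slot informative integer vector, subset of `polymorphic`.
#' @slot singleton `polymorphic` minus `informative`.
#' @export
setClass("SiteClasses",
  representation(complete = "integer", polymorphic = "integer",
                 informative = "integer", singleton = "integer"))

setValidity("SiteClasses", function(object) {
  if (!all(object@polymorphic %in% object@complete)) return("polymorphic not within complete")
  if (!all(object@informative %in% object@polymorphic)) return("informative not within polymorphic")
  if (!setequal(object@singleton, setdiff(object@polymorphic, object@informative)))
    return("singleton must be polymorphic minus informative")
  TRUE
})

setMethod("show", "HaploAlignment", function(object) {
  cat("HaploAlignment:", length(object@seqs), "sequences x",
      Biostrings::width(object@seqs)[1], "bp\n")
  if (nrow(object@partitions))
    cat("  partitions:", paste0(object@partitions$region, " [",
        object@partitions$start, "-", object@partitions$end, "]",
        collapse = ", "), "\n")
  if (nrow(object@sampleData))
    cat("  metadata:", nrow(object@sampleData), "samples,",
        length(unique(object@sampleData$population)), "populations,",
        length(unique(object@sampleData$lineage)), "lineages\n")
})

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", length(object@sequences), "haplotypes,",
      sum(object@counts), "individuals,", ncol(object@counts), "populations\n")
})

setMethod("show", "HaploNetwork", function(object) {
  cat("HaploNetwork:", sum(!object@nodes$median), "haplotypes +",
      sum(object@nodes$median), "median vectors,", nrow(object@edges),
      "edges (epsilon =", object@epsilon, ")\n")
})

setMethod("show", "SiteClasses", function(object) {
  cat("SiteClasses:", length(object@complete), "complete columns;",
      length(object@polymorphic), "polymorphic,",
      length(object@informative), "parsimony-informative,",
      length(object@singleton), "singleton\n")
})
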