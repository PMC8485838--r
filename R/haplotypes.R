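#' @include alignment-io.R
NULL

#' Collapse aligned sequences into haplotypes
#'
#' Two samples share a haplotype iff their (gap-free, complete-column
#' filtered) sequences are identical. Haplotypes are labelled `H01`, `H02`,
#' ... in order of first occurrence in the alignment, and counted per
#' population.
#'
#' @param a A gap-free [HaploAlignment] (run [filterCompleteColumns] first).
#' @param meta Optional metadata `data.frame` (columns `sample_id`,
#'   `population`, `lineage`); defaults to `sampleData(a)`.
#' @return A [HaplotypeTable].
#' @export
collapseHaplotypes <- function(a, meta = NULL) {
  if (is.null(meta)) meta <- sampleData(a)
  if (nrow(meta) == 0L) stop("no sample metadata attached or supplied")
  seqs <- as.character(a@seqs)
  if (any(grepl("[^ACGT]", seqs)))
    stop("alignment still contains gaps/ambiguities; filter complete columns first")
  idx <- match(names(seqs), meta$sample_id)
  if (anyNA(idx))
    stop("sample(s) without metadata: ",
         paste(names(seqs)[is.na(idx)], collapse = ", "))
  pop <- meta$population[idx]
  uniq <- unique(unname(seqs))
  k <- length(uniq)
  labels <- sprintf("H%0*d", max(2L, nchar(k)), seq_len(k))
  hap_of <- match(unname(seqs), uniq)
  pops <- unique(pop)
  cts <- matrix(0L, nrow = k, ncol = length(pops),
                dimnames = list(labels, pops))
  for (i in seq_along(seqs))
    cts[hap_of[i], pop[i]] <- cts[hap_of[i], pop[i]] + 1L
  names(uniq) <- labels
  lin <- character(0)
  if ("lineage" %in% names(meta)) {
    map <- unique(meta[, c("population", "lineage")])
    lin <- stats::setNames(map$lineage, map$population)
  }
  new("HaplotypeTable", sequences = uniq, counts = cts, lineages = lin)
}

#' Pairwise Hamming distances between haplotypes
#'
#' @param x A [HaplotypeTable] or a character vector of equal-length
#'   sequences.
#' @return A symmetric integer matrix of differing-site counts.
#' @export
hammingMatrix <- function(x) {
  seqs <- if (is(x, "HaplotypeTable")) hapSequences(x) else x
  if (is.null(names(seqs))) names(seqs) <- paste0("S", seq_along(seqs))
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  k <- nrow(m)
  d <- matrix(0L, k, k, dimnames = list(names(seqs), names(seqs)))
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

# Minimum-spanning network: keep pair (u,v) iff d(u,v) <= single-linkage
# cophenetic distance + epsilon (equivalent to batch Kruskal with ties kept).
.msn_edges <- function(d, epsilon = 0L) {
  k <- nrow(d)
  if (k == 2L) return(data.frame(i = 1L, j = 2L, steps = d[1, 2]))
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  coph <- as.matrix(stats::cophenetic(hc))
  coph <- coph[rownames(d), rownames(d)]
  out <- which(upper.tri(d) & d <= coph + epsilon, arr.ind = TRUE)
  data.frame(i = out[, 1], j = out[, 2], steps = d[out])
}

.median_of_three <- function(rows) {
  # rows: 3 x L character matrix, ordered so rows[1,] belongs to the
  # lexicographically smallest label (which owns three-way ties)
  x1 <- rows[1, ]; x2 <- rows[2, ]; x3 <- rows[3, ]
  ifelse(x2 == x3 & x1 != x2, x2, x1)
}

#' Median-joining haplotype network
#'
#' Implements the Bandelt-Forster-Roehl median-joining heuristic: iteratively
#' (i) build the minimum-spanning network at tolerance `epsilon` over the
#' current node set, (ii) propose the majority-consensus (median) vector of
#' every connected triple and add the candidates with minimal connection
#' cost, (iii) drop median vectors of degree <= 2. Ties (equal-cost medians,
#' three-way base conflicts) are broken by lexicographic node label, so the
#' result is deterministic.
#'
#' @param h A [HaplotypeTable] with at least two haplotypes.
#' @param epsilon Non-negative integer relaxation parameter (default 0, the
#'   POPART default).
#' @param max_iter Safety cap on median-addition rounds.
#' @return A [HaploNetwork].
#' @export
medianJoiningNetwork <- function(h, epsilon = 0L, max_iter = 25L) {
  obs <- hapSequences(h)
  if (length(obs) < 2L) stop("need at least 2 haplotypes")
  nodes <- obs
  is_median <- stats::setNames(rep(FALSE, length(obs)), names(obs))
  n_mv <- 0L

  for (iter in seq_len(max_iter)) {
    ord <- order(names(nodes))
    nodes <- nodes[ord]
    is_median <- is_median[ord]
    d <- hammingMatrix(nodes)
    ed <- .msn_edges(d, epsilon)

    # prune obsolete medians (degree <= 2), innermost loop
    repeat {
      deg <- tabulate(c(ed$i, ed$j), nbins = length(nodes))
      drop <- which(is_median & deg <= 2L)
      if (length(drop) == 0L) break
      nodes <- nodes[-drop]
      is_median <- is_median[-drop]
      if (length(nodes) < 2L) break
      d <- hammingMatrix(nodes)
      ed <- .msn_edges(d, epsilon)
    }

    # candidate medians from triples u-(v,w) with v,w neighbours of u
    adj <- vector("list", length(nodes))
    for (r in seq_len(nrow(ed))) {
      adj[[ed$i[r]]] <- c(adj[[ed$i[r]]], ed$j[r])
      adj[[ed$j[r]]] <- c(adj[[ed$j[r]]], ed$i[r])
    }
    cand <- list()
    cost <- numeric(0)
    mat <- do.call(rbind, strsplit(unname(nodes), "", fixed = TRUE))
    for (u in seq_along(nodes)) {
      nb <- sort(unique(adj[[u]]))
      if (length(nb) < 2L) next
      prs <- utils::combn(nb, 2L)
      for (q in seq_len(ncol(prs))) {
        trip <- sort(c(u, prs[1, q], prs[2, q]))  # label-ordered (nodes sorted)
        medchars <- .median_of_three(mat[trip, , drop = FALSE])
        med <- paste0(medchars, collapse = "")
        if (med %in% nodes || med %in% unlist(cand)) next
        cc <- sum(mat[trip[1], ] != medchars) + sum(mat[trip[2], ] != medchars) +
          sum(mat[trip[3], ] != medchars)
        cand[[length(cand) + 1L]] <- med
        cost <- c(cost, cc)
      }
    }
    if (length(cand) == 0L) break
    lambda <- min(cost)
    keep <- which(cost <= lambda + epsilon)
    new_seqs <- unique(unlist(cand[keep]))
    new_labels <- paste0("mv", seq(n_mv + 1L, n_mv + length(new_seqs)))
    n_mv <- n_mv + length(new_seqs)
    nodes <- c(nodes, stats::setNames(new_seqs, new_labels))
    is_median <- c(is_median,
                   stats::setNames(rep(TRUE, length(new_seqs)), new_labels))
  }

  # final cleanup + edges
  ord <- order(names(nodes))
  nodes <- nodes[ord]
  is_median <- is_median[ord]
  repeat {
    d <- hammingMatrix(nodes)
    ed <- .msn_edges(d, epsilon)
    deg <- tabulate(c(ed$i, ed$j), nbins = length(nodes))
    drop <- which(is_median & deg <= 2L)
    if (length(drop) == 0L) break
    nodes <- nodes[-drop]
    is_median <- is_median[-drop]
  }
  nn <- rowSums(hapCounts(h))
  ndf <- data.frame(label = names(nodes), sequence = unname(nodes),
                    median = unname(is_median),
                    n = ifelse(is_median, 0L, nn[names(nodes)]))
  edf <- data.frame(from = names(nodes)[ed$i], to = names(nodes)[ed$j],
                    steps = as.integer(ed$steps))
  new("HaploNetwork", nodes = ndf, edges = edf, epsilon = as.integer(epsilon))
}

#' Convert a HaploNetwork to an igraph object
#'
#' @param net A [HaploNetwork].
#' @return An `igraph` graph with vertex attributes `sequence`, `median`,
#'   `n` and edge attribute `steps`.
#' @export
asIgraph <- function(net) {
  igraph::graph_from_data_frame(networkEdges(net), directed = FALSE,
                                vertices = networkNodes(net))
}

#' Write a haplotype network as GraphML
#'
#' @param net A [HaploNetwork].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' Write a POPART-compatible NEXUS file
#'
#' Writes the haplotype sequences as a DATA block and the per-population
#' counts as a TRAITS block, the input format POPART uses to draw
#' median-joining networks.
#'
#' @param h A [HaplotypeTable].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNexusHaplotypes <- function(h, path) {
  seqs <- hapSequences(h)
  cts <- hapCounts(h)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "BEGIN DATA;",
               sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(seqs), nchar(seqs[1])),
               "FORMAT DATATYPE=DNA MISSING=N GAP=-;", "MATRIX"), con)
  writeLines(paste(names(seqs), unname(seqs)), con)
  writeLines(c(";", "END;", "", "BEGIN TRAITS;",
               sprintf("Dimensions NTRAITS=%d;", ncol(cts)),
               "Format labels=yes missing=? separator=Comma;",
               sprintf("TraitLabels %s;", paste(colnames(cts), collapse = " ")),
               "Matrix"), con)
  writeLines(paste(rownames(cts), apply(cts, 1, paste, collapse = ",")), con)
  writeLines(c(";", "END;"), con)
  invisible(path)
}

#' Write a haplotype table as TSV
#'
#' One row per population with its sample size and a `H03(4), H12(1)`-style
#' haplotype listing, followed by the raw counts matrix.
#'
#' @param h A [HaplotypeTable].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHaplotypeTable <- function(h, path) {
  cts <- hapCounts(h)
  listing <- apply(cts, 2L, function(col) {
    nz <- which(col > 0)
    paste0(rownames(cts)[nz], "(", col[nz], ")", collapse = ", ")
  })
  df <- data.frame(population = colnames(cts), n = colSums(cts),
                   haplotypes = listing)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
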