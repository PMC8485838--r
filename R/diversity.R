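#' @include haplotypes.R
NULL

#' Haplotype (gene) diversity with Nei's sampling SD
#'
#' \eqn{Hd = \frac{n}{n-1}(1 - \sum p_i^2)} from per-haplotype counts, with
#' the sampling variance of Nei (1987, eq. 8.12).
#'
#' @param counts Positive integer vector of per-haplotype counts (n >= 2).
#' @return A list with `Hd`, `Hd_sd`, `n`, `n_haplotypes`.
#' @export
haplotypeDiversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 individuals")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  Hd <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = Hd, Hd_sd = sqrt(max(V, 0)), n = n,
       n_haplotypes = length(counts))
}

#' Nucleotide diversity (pi)
#'
#' Average pairwise p-distance per site over all n(n-1)/2 sequence pairs, with
#' no multiple-hit correction.
#'
#' @param x A gap-free [HaploAlignment] or character vector of equal-length
#'   sequences.
#' @return A list with `pi`, `k_bar` (mean pairwise differences, count scale),
#'   `n`, `L`.
#' @export
nucleotideDiversity <- function(x) {
  seqs <- if (is(x, "HaploAlignment")) as.character(x@seqs) else x
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  L <- nchar(seqs[1])
  if (L == 0) stop("zero-length alignment")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  # sum of pairwise differences via per-column base counts:
  # sum_sites [C(n,2) - sum_b C(c_b,2)]
  npairs <- n * (n - 1) / 2
  same <- 0
  for (b in unique(as.vector(m))) {
    cb <- colSums(m == b)
    same <- same + sum(choose(cb, 2))
  }
  k_bar <- (npairs * ncol(m) - same) / npairs
  list(pi = k_bar / L, k_bar = k_bar, n = n, L = L)
}

#' Per-group diversity summary
#'
#' Computes N, number of haplotypes, nucleotide diversity and haplotype
#' diversity for each level of a grouping column, the per-lineage (or
#' per-population) diversity report.
#'
#' @param a A gap-free [HaploAlignment] with metadata attached.
#' @param by Metadata column to group by (`"lineage"` or `"population"`).
#' @return A `data.frame` with columns `group`, `N`, `N_H`, `pi`, `Hd`,
#'   `Hd_sd`.
#' @export
diversityByGroup <- function(a, by = c("lineage", "population")) {
  by <- match.arg(by)
  meta <- sampleData(a)
  if (nrow(meta) == 0L) stop("no metadata attached")
  seqs <- as.character(a@seqs)
  grp <- meta[[by]][match(names(seqs), meta$sample_id)]
  out <- lapply(unique(grp), function(g) {
    s <- seqs[grp == g]
    if (length(s) < 2)
      return(data.frame(group = g, N = length(s), N_H = length(unique(s)),
                        pi = NA_real_, Hd = NA_real_, Hd_sd = NA_real_))
    nd <- nucleotideDiversity(s)
    hd <- haplotypeDiversity(as.integer(table(match(s, unique(s)))))
    data.frame(group = g, N = nd$n, N_H = hd$n_haplotypes, pi = nd$pi,
               Hd = hd$Hd, Hd_sd = hd$Hd_sd)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
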