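#' @include amova.R
NULL

.pons_petit <- function(p, n_k, pimat) {
  # p: haplotype x population frequency matrix; pimat: inter-haplotype
  # distances (pi_ii = 0). Pons & Petit (1995, 1996) unbiased estimators.
  K <- ncol(p)
  v_k <- vapply(seq_len(K), function(k) {
    n_k[k] / (n_k[k] - 1) * as.numeric(t(p[, k]) %*% pimat %*% p[, k])
  }, numeric(1))
  v_S <- mean(v_k)
  pbar <- rowMeans(p)
  ntilde <- K / sum(1 / n_k)
  v_T <- as.numeric(t(pbar) %*% pimat %*% pbar) + v_S / (K * ntilde)
  list(v_S = v_S, v_T = v_T,
       coef = if (v_T > 0) (v_T - v_S) / v_T else NA_real_)
}

#' GST and NST differentiation coefficients with permutation test
#'
#' Pons & Petit (1996) unbiased estimators of population differentiation
#' computed on haplotype frequencies alone (\eqn{G_{ST}}) and weighted by
#' inter-haplotype distances (\eqn{N_{ST}}). \eqn{N_{ST} > G_{ST}} indicates
#' phylogeographic structure (closely related haplotypes co-occur within
#' populations). The permutation test permutes haplotype identities on the
#' distance matrix and recomputes \eqn{N_{ST}}; the one-tailed p-value is the
#' proportion of permuted \eqn{N_{ST}} at least as large as observed,
#' \eqn{(b+1)/(B+1)}.
#'
#' @param h A [HaplotypeTable]. Populations with fewer than 2 individuals are
#'   excluded (with a message).
#' @param dist Inter-haplotype distance matrix (default: Hamming distances
#'   between the haplotype sequences).
#' @param nperm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @return A list with `G_ST`, `N_ST`, `h_S`, `h_T`, `v_S`, `v_T`, `p_NST`
#'   and the number of populations used.
#' @export
gstNst <- function(h, dist = NULL, nperm = 10000, seed = 1L) {
  cts <- hapCounts(h)
  keep <- colSums(cts) >= 2
  if (any(!keep))
    message("excluding ", sum(!keep), " population(s) with n < 2: ",
            paste(colnames(cts)[!keep], collapse = ", "))
  cts <- cts[, keep, drop = FALSE]
  if (ncol(cts) < 2) stop("need at least 2 populations with n >= 2")
  n_k <- colSums(cts)
  p <- sweep(cts, 2L, n_k, "/")
  if (is.null(dist)) dist <- hammingMatrix(h)
  dist <- as.matrix(dist)[rownames(cts), rownames(cts), drop = FALSE]
  k <- nrow(dist)
  eq <- matrix(1, k, k) - diag(k)
  g <- .pons_petit(p, n_k, eq)
  if (!is.finite(g$coef) || g$v_T <= 0) stop("monomorphic data: h_T = 0")
  v <- .pons_petit(p, n_k, dist)
  set.seed(seed)
  ref <- replicate(nperm, {
    i <- sample(k)
    .pons_petit(p, n_k, dist[i, i])$coef
  })
  list(G_ST = g$coef, N_ST = v$coef, h_S = g$v_S, h_T = g$v_T,
       v_S = v$v_S, v_T = v$v_T,
       p_NST = (sum(ref >= v$coef) + 1) / (nperm + 1),
       n_populations = ncol(cts))
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the lower triangles of a genetic and a
#' geographic distance matrix over the same populations, with significance by
#' permutation of population labels (one-tailed, r >= observed).
#'
#' @param genetic,geographic Symmetric distance matrices with identical
#'   population sets.
#' @param nperm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return A list with `r` and `p`.
#' @export
mantelIBD <- function(genetic, geographic, nperm = 1000, seed = 1L) {
  genetic <- as.matrix(genetic)
  geographic <- as.matrix(geographic)
  if (nrow(genetic) < 3) stop("need at least 3 populations")
  if (!is.null(rownames(genetic)) && !is.null(rownames(geographic))) {
    if (!setequal(rownames(genetic), rownames(geographic)))
      stop("population sets differ between matrices")
    geographic <- geographic[rownames(genetic), rownames(genetic)]
  }
  set.seed(seed)
  res <- vegan::mantel(stats::as.dist(genetic), stats::as.dist(geographic),
                       permutations = nperm)
  list(r = unname(res$statistic), p = res$signif)
}
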