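#' @include gstnst.R
NULL

# per-sequence summaries from a character matrix (rows = sequences)
.seq_summaries <- function(m) {
  n <- nrow(m)
  S <- 0L
  k_sum <- 0
  U <- numeric(n)
  npairs <- n * (n - 1) / 2
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) < 2L) next
    S <- S + 1L
    k_sum <- k_sum + (npairs - sum(choose(tab, 2))) / npairs
    # minor-base carriers at singleton sites
    if (min(tab) == 1L) {
      if (length(tab) == 2L && all(tab == 1L)) {
        # 1/1 tie (n = 2): count the carrier of the lexicographically
        # smaller base only
        b <- sort(names(tab))[1]
        U[m[, j] == b] <- U[m[, j] == b] + 1
      } else {
        for (b in names(tab)[tab == 1L]) U[m[, j] == b] <- U[m[, j] == b] + 1
      }
    }
  }
  list(n = n, S = S, k_bar = k_sum, U = U,
       n_hap = length(unique(apply(m, 1L, paste0, collapse = ""))))
}

.as_char_matrix <- function(x) {
  seqs <- if (is(x, "HaploAlignment")) as.character(x@seqs) else x
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

# summaries of a 0/1 simulated matrix (columns = biallelic sites)
.sim_summaries <- function(mat) {
  n <- nrow(mat)
  cc <- colSums(mat)
  seg <- cc > 0 & cc < n
  cc <- cc[seg]
  S <- length(cc)
  npairs <- n * (n - 1) / 2
  k_bar <- sum(cc * (n - cc)) / npairs
  U <- numeric(n)
  if (S) {
    m <- mat[, seg, drop = FALSE]
    if (n == 2L) {
      # every segregating site is a 1/1 tie: assign to the "0" carrier
      U <- U + rowSums(1 - m)
    } else {
      der1 <- which(cc == 1L)
      anc1 <- which(cc == n - 1L)
      if (length(der1)) U <- U + rowSums(m[, der1, drop = FALSE])
      if (length(anc1)) U <- U + rowSums(1 - m[, anc1, drop = FALSE])
    }
  }
  list(n = n, S = S, k_bar = k_bar, U = U,
       n_hap = if (S) nrow(unique(mat[, seg, drop = FALSE])) else 1L)
}

#' Tajima's D from summary quantities
#'
#' @param n Sample size (>= 4).
#' @param S Number of segregating sites (>= 1).
#' @param k_bar Mean pairwise differences.
#' @return Tajima's D.
#' @export
tajimaDStat <- function(n, S, k_bar) {
  if (S < 1) stop("Tajima's D undefined when S = 0")
  if (n < 4) stop("need n >= 4")
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu's Fs from haplotype count and theta
#'
#' \eqn{F_s = \ln(S'/(1-S'))} where \eqn{S' = P(K \ge k_{obs})} under the
#' Ewens sampling formula with \eqn{\theta} estimated by the mean pairwise
#' differences; unsigned Stirling numbers of the first kind are computed in
#' log space.
#'
#' @param n Sample size (>= 2).
#' @param k_obs Observed number of haplotypes.
#' @param theta Positive theta estimate (mean pairwise differences).
#' @return Fu's Fs.
#' @export
fusFs <- function(n, k_obs, theta) {
  if (n < 2) stop("need n >= 2")
  if (theta <= 0) stop("theta must be positive")
  if (k_obs < 1 || k_obs > n) stop("k_obs must be in 1..n")
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  # log |s1(n, k)| by recurrence
  ls <- c(0)                       # n = 1: |s(1,1)| = 1
  for (m in seq_len(n - 1)) {      # build up to n
    new <- numeric(m + 1)
    for (k in seq_len(m + 1)) {
      terms <- c(if (k > 1) ls[k - 1] else -Inf,
                 if (k <= m) log(m) + ls[k] else -Inf)
      new[k] <- lse(terms)
    }
    ls <- new
  }
  ldenom <- sum(log(theta + 0:(n - 1)))
  lp <- ls + seq_len(n) * log(theta) - ldenom
  if (k_obs == 1) stop("S' = 1 when k_obs = 1: Fs is -infinite")
  lS <- lse(lp[k_obs:n])
  lnotS <- lse(lp[1:(k_obs - 1)])
  if (!is.finite(lnotS)) stop("S' = 0: Fs is +infinite")
  lS - lnotS
}

#' Ramos-Onsins & Rozas R2 from summary quantities
#'
#' @param U Per-sequence counts of minor-base singletons.
#' @param k_bar Mean pairwise differences.
#' @param S Number of segregating sites (>= 1).
#' @return R2.
#' @export
r2Stat <- function(U, k_bar, S) {
  if (S < 1) stop("R2 undefined when S = 0")
  sqrt(mean((U - k_bar / 2)^2)) / S
}

#' Neutrality tests with coalescent p-values
#'
#' Computes Tajima's D, Fu's Fs and R2 for one set of sequences (one lineage)
#' and derives p-values from neutral constant-size coalescent simulations
#' conditioned on the observed n and S (infinite-sites mutations placed on
#' branches proportional to length). Tails follow the usual conventions:
#' two-tailed for D, lower tail for Fs and for R2 (small values indicate
#' expansion). All p-values use \eqn{(b+1)/(B+1)}.
#'
#' @param x Gap-free [HaploAlignment] or character vector of equal-length
#'   sequences.
#' @param nsim Number of coalescent replicates (default 1000).
#' @param seed RNG seed.
#' @return A list with `n`, `S`, `k_bar`, `n_haplotypes`, `D`, `Fs`, `R2` and
#'   `p_D`, `p_Fs`, `p_R2`.
#' @export
neutralityTests <- function(x, nsim = 1000, seed = 1L) {
  sm <- .seq_summaries(.as_char_matrix(x))
  if (sm$S < 1) stop("no segregating sites: neutrality statistics undefined")
  D <- tajimaDStat(sm$n, sm$S, sm$k_bar)
  Fs <- fusFs(sm$n, sm$n_hap, sm$k_bar)
  R2 <- r2Stat(sm$U, sm$k_bar, sm$S)
  set.seed(seed)
  simD <- simFs <- simR2 <- numeric(nsim)
  for (b in seq_len(nsim)) {
    mat <- sim_fixed_s_cpp(sm$n, sm$S)
    ss <- .sim_summaries(mat)
    simD[b] <- tajimaDStat(ss$n, max(ss$S, 1L), ss$k_bar)
    simFs[b] <- if (ss$n_hap > 1 && ss$k_bar > 0)
      fusFs(ss$n, ss$n_hap, ss$k_bar) else NA_real_
    simR2[b] <- r2Stat(ss$U, ss$k_bar, max(ss$S, 1L))
  }
  okF <- is.finite(simFs)
  list(n = sm$n, S = sm$S, k_bar = sm$k_bar, n_haplotypes = sm$n_hap,
       D = D, Fs = Fs, R2 = R2,
       p_D = (sum(abs(simD) >= abs(D)) + 1) / (nsim + 1),
       p_Fs = (sum(simFs[okF] <= Fs) + 1) / (sum(okF) + 1),
       p_R2 = (sum(simR2 <= R2) + 1) / (nsim + 1))
}

#' Per-lineage demographic report
#'
#' Runs the neutrality tests for each level of a metadata column (skipping
#' groups below `min_n`), the shape of a per-lineage demography table.
#'
#' @param a Gap-free [HaploAlignment] with metadata.
#' @param by Grouping column (default `"lineage"`).
#' @param nsim Coalescent replicates per group.
#' @param min_n Minimum group size (default 4, the smallest n for which
#'   Tajima's D is defined).
#' @param seed RNG seed.
#' @return `data.frame` with one row per group.
#' @export
neutralityByGroup <- function(a, by = "lineage", nsim = 1000, min_n = 4,
                              seed = 1L) {
  meta <- sampleData(a)
  seqs <- as.character(a@seqs)
  grp <- meta[[by]][match(names(seqs), meta$sample_id)]
  rows <- lapply(unique(grp), function(g) {
    s <- seqs[grp == g]
    if (length(s) < min_n) return(NULL)
    r <- neutralityTests(s, nsim = nsim, seed = seed)
    data.frame(group = g, N = r$n, N_H = r$n_haplotypes,
               pi = r$k_bar / nchar(s[1]), D = r$D, p_D = r$p_D,
               Fs = r$Fs, p_Fs = r$p_Fs, R2 = r$R2, p_R2 = r$p_R2)
  })
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  rows
}
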