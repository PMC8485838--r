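#' @include distances.R
NULL

# Sum of squares of a set of samples from squared distances (Excoffier,
# Smouse & Quattro 1992): SS(I) = sum_{i<j in I} d2_ij / |I|.
.ss <- function(d2, idx) sum(d2[idx, idx]) / (2 * length(idx))

.amova_components <- function(d2, pop, grp = NULL) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  np <- vapply(pops, function(p) sum(pop == p), numeric(1))
  SS_T <- .ss(d2, seq_len(N))
  SS_WP <- sum(vapply(pops, function(p) .ss(d2, which(pop == p)), numeric(1)))
  if (is.null(grp) && P == 1L) {
    # degenerate single-population design: all variance is within
    s2_w <- SS_T / (N - 1)
    return(list(
      table = data.frame(stratum = c("Within populations", "Total"),
                         df = c(N - 1, N - 1), SS = c(SS_T, SS_T),
                         variance = c(s2_w, s2_w), percent = c(100, 100)),
      indices = c(FST = 0)))
  }
  if (is.null(grp)) {
    df_AP <- P - 1
    df_WP <- N - P
    if (df_AP < 1 || df_WP < 1) stop("degrees of freedom <= 0")
    SS_AP <- SS_T - SS_WP
    s2_w <- SS_WP / df_WP
    nprime <- (N - sum(np^2) / N) / df_AP
    s2_a <- (SS_AP / df_AP - s2_w) / nprime
    tot <- s2_a + s2_w
    return(list(
      table = data.frame(
        stratum = c("Among populations", "Within populations", "Total"),
        df = c(df_AP, df_WP, N - 1),
        SS = c(SS_AP, SS_WP, SS_T),
        variance = c(s2_a, s2_w, tot),
        percent = 100 * c(s2_a, s2_w, tot) / tot),
      indices = c(FST = s2_a / tot)))
  }
  groups <- unique(grp)
  G <- length(groups)
  gof <- grp[match(pops, pop)]           # group of each population
  ng <- vapply(groups, function(g) sum(grp == g), numeric(1))
  df_AG <- G - 1
  df_APWG <- P - G
  df_WP <- N - P
  if (df_AG < 1 || df_APWG < 1 || df_WP < 1) stop("degrees of freedom <= 0")
  SS_G <- vapply(groups, function(g) .ss(d2, which(grp == g)), numeric(1))
  SS_AG <- SS_T - sum(SS_G)
  SS_APWG <- sum(SS_G) - SS_WP
  s2_c <- SS_WP / df_WP
  sum_np2_over_ng <- sum(vapply(groups, function(g)
    sum(np[gof == g]^2) / ng[which(groups == g)], numeric(1)))
  n1 <- (N - sum_np2_over_ng) / df_APWG
  n2 <- (sum_np2_over_ng - sum(np^2) / N) / df_AG
  n3 <- (N - sum(ng^2) / N) / df_AG
  s2_b <- (SS_APWG / df_APWG - s2_c) / n1
  s2_a <- (SS_AG / df_AG - s2_c - n2 * s2_b) / n3
  tot <- s2_a + s2_b + s2_c
  list(
    table = data.frame(
      stratum = c("Among groups", "Among populations within groups",
                  "Within populations", "Total"),
      df = c(df_AG, df_APWG, df_WP, N - 1),
      SS = c(SS_AG, SS_APWG, SS_WP, SS_T),
      variance = c(s2_a, s2_b, s2_c, tot),
      percent = 100 * c(s2_a, s2_b, s2_c, tot) / tot),
    indices = c(FCT = s2_a / tot, FSC = s2_b / (s2_b + s2_c),
                FST = (s2_a + s2_b) / tot))
}

#' Analysis of molecular variance (AMOVA)
#'
#' Excoffier-Smouse-Quattro variance decomposition from squared molecular
#' distances, with one level (populations) or two levels (groups of
#' populations). Negative variance components are reported as-is and percent
#' variance is computed on the signed components. Permutation p-values use
#' the stratum-appropriate scheme: samples among populations for
#' \eqn{F_{ST}}, whole populations among groups for \eqn{F_{CT}}, samples
#' among populations within groups for \eqn{F_{SC}}; all use the
#' \eqn{(b+1)/(B+1)} convention.
#'
#' @param d Pairwise distance matrix among samples (distances are squared
#'   internally).
#' @param populations Population code per sample (same order as `d`).
#' @param groups Optional group (lineage) per sample; when given, a two-level
#'   design is fitted. Every sample must be assigned.
#' @param nperm Number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return A list with `table` (df/SS/variance/percent by stratum),
#'   `indices` (fixation indices) and `pvalues`.
#' @export
amova <- function(d, populations, groups = NULL, nperm = 1000, seed = 1L) {
  d <- as.matrix(d)
  N <- nrow(d)
  stopifnot(length(populations) == N)
  if (!is.null(groups)) {
    stopifnot(length(groups) == N)
    if (anyNA(groups)) stop("sample(s) assigned to no group")
  }
  if (anyNA(populations)) stop("sample(s) assigned to no population")
  d2 <- d^2
  obs <- .amova_components(d2, populations, groups)
  set.seed(seed)
  pv <- c()
  if (is.null(groups)) {
    stat <- function(p) .amova_components(d2, p)$indices["FST"]
    ref <- replicate(nperm, stat(sample(populations)))
    pv <- c(FST = (sum(ref >= obs$indices["FST"]) + 1) / (nperm + 1))
  } else {
    # FST: samples among populations, ignoring groups
    refST <- replicate(nperm, {
      i <- sample(N)
      .amova_components(d2, populations[i], groups[i])$indices["FST"]
    })
    # FCT: permute whole populations among groups
    pops <- unique(populations)
    gof <- groups[match(pops, populations)]
    refCT <- replicate(nperm, {
      g2 <- sample(gof)
      .amova_components(d2, populations,
                        g2[match(populations, pops)])$indices["FCT"]
    })
    # FSC: samples among populations within their group
    refSC <- replicate(nperm, {
      p2 <- populations
      for (g in unique(groups)) {
        w <- which(groups == g)
        p2[w] <- p2[sample(w)]
      }
      .amova_components(d2, p2, groups)$indices["FSC"]
    })
    pv <- c(FCT = (sum(refCT >= obs$indices["FCT"]) + 1) / (nperm + 1),
            FSC = (sum(refSC >= obs$indices["FSC"]) + 1) / (nperm + 1),
            FST = (sum(refST >= obs$indices["FST"]) + 1) / (nperm + 1))
  }
  c(obs, list(pvalues = pv))
}

#' Pairwise FST between populations or lineages
#'
#' Two-stratum AMOVA \eqn{F_{ST}} for every pair of levels, with permutation
#' p-values.
#'
#' @param d Pairwise distance matrix among samples.
#' @param strata Population or lineage label per sample.
#' @param nperm Permutations per pair (default 1000).
#' @param seed RNG seed.
#' @return A list with matrices `fst` and `p`.
#' @export
pairwiseFst <- function(d, strata, nperm = 1000, seed = 1L) {
  d <- as.matrix(d)
  lev <- unique(strata)
  k <- length(lev)
  fst <- p <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  diag(fst) <- 0
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    w <- which(strata %in% c(lev[i], lev[j]))
    res <- amova(d[w, w, drop = FALSE], strata[w], nperm = nperm,
                 seed = seed + i * 1000L + j)
    fst[i, j] <- fst[j, i] <- unname(res$indices["FST"])
    p[i, j] <- p[j, i] <- unname(res$pvalues["FST"])
  }
  list(fst = fst, p = p)
}
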