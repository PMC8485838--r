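#' @include mismatch.R
NULL

.ABC_PARAM_NAMES <- c("Na", "N1", "N2", "N3", "t1", "t2", "r")
.ABC_STAT_NAMES <- c("S_1", "S_2", "S_3", "k_1", "k_2", "k_3",
                     "rare_1", "rare_2", "rare_3",
                     "S_12", "S_13", "S_23",
                     "Fst_12", "Fst_13", "Fst_23")

#' Prior specification for the demographic scenarios
#'
#' Uniform priors over haploid effective sizes and event times, the fixed
#' per-site mutation rate, and the HKY nuisance parameters. cpDNA is haploid
#' and maternally inherited, so `N*` values are haploid copy numbers and a
#' pair of lineages coalesces at rate 1/N per generation. The per-generation
#' rate is `mu_year * gen_time`.
#'
#' @param N_bounds Uniform bounds for Na, N1, N2, N3 (default `c(10, 1e5)`).
#' @param t_bounds Uniform bounds, generations, for t1 and t2 (default
#'   `c(100, 1e5)`); draws are rejected until `t2 >= t1`.
#' @param r_bounds Uniform bounds for the admixture rate of scenario 5
#'   (default `c(0.1, 0.9)`; the source did not state this prior).
#' @param gen_time Generation time in years (default 10).
#' @param mu_year Per-site per-year mutation rate (default 1.59e-9).
#' @param kappa HKY transition/transversion ratio (default 2).
#' @param base_freq HKY base frequencies A/C/G/T (default cpDNA-like
#'   AT-rich frequencies; set from your observed matrix for real data).
#' @return A list of class `prior_spec`.
#' @export
priorSpec <- function(N_bounds = c(10, 1e5), t_bounds = c(100, 1e5),
                      r_bounds = c(0.1, 0.9), gen_time = 10,
                      mu_year = 1.59e-9, kappa = 2,
                      base_freq = c(A = 0.33, C = 0.17, G = 0.17, T = 0.33)) {
  stopifnot(all(N_bounds > 0), all(t_bounds > 0), diff(N_bounds) >= 0,
            diff(t_bounds) >= 0, abs(sum(base_freq) - 1) < 1e-8)
  structure(list(N_bounds = N_bounds, t_bounds = t_bounds,
                 r_bounds = r_bounds, gen_time = gen_time, mu_year = mu_year,
                 mu_gen = mu_year * gen_time, kappa = kappa,
                 base_freq = base_freq),
            class = "prior_spec")
}

#' Draw scenario parameters from the priors
#'
#' Independent uniforms within bounds, with rejection until `t2 >= t1`; the
#' admixture rate `r` is drawn only for scenario 5 (NA otherwise).
#'
#' @param scenario Scenario id, 1-5.
#' @param spec A [priorSpec].
#' @return Named numeric vector `Na, N1, N2, N3, t1, t2, r`.
#' @export
drawPriors <- function(scenario, spec = priorSpec()) {
  N <- stats::runif(4, spec$N_bounds[1], spec$N_bounds[2])
  repeat {
    t1 <- stats::runif(1, spec$t_bounds[1], spec$t_bounds[2])
    t2 <- stats::runif(1, spec$t_bounds[1], spec$t_bounds[2])
    if (t2 >= t1) break
  }
  r <- if (scenario == 5) stats::runif(1, spec$r_bounds[1], spec$r_bounds[2])
       else NA_real_
  stats::setNames(c(N, t1, t2, r), .ABC_PARAM_NAMES)
}

#' Event list of a demographic scenario
#'
#' The five competing three-lineage histories (groups: 1 = north, 2 =
#' central, 3 = south), written backward in time for the structured
#' coalescent:
#' * scenario 1: all three lineages split from the ancestor at `t2` (stable);
#' * scenarios 2-4: one pair diverges at `t1`, the remaining lineage at `t2`
#'   (pair 1+2, 2+3, 1+3 respectively);
#' * scenario 5: 2 and 3 split at `t2`; lineage 1 is an admixture of 2 (rate
#'   `r`) and 3 at `t1` (secondary contact).
#'
#' @param scenario Scenario id, 1-5.
#' @param params Named vector as from [drawPriors].
#' @return Numeric matrix with columns `time, type, a, b, c, x` (0-based
#'   population indices) understood by the C++ simulator.
#' @export
scenarioEvents <- function(scenario, params) {
  p <- as.list(params)
  if (p$t2 < p$t1) stop("scenario invariant violated: t2 < t1")
  ev <- function(time, type, a, b = 0, c = 0, x = 0) c(time, type, a, b, c, x)
  rows <- switch(as.character(scenario),
    "1" = list(ev(p$t2, 1, 0, 1), ev(p$t2, 1, 2, 1), ev(p$t2, 2, 1, x = p$Na)),
    "2" = list(ev(p$t1, 1, 0, 1), ev(p$t2, 1, 2, 1), ev(p$t2, 2, 1, x = p$Na)),
    "3" = list(ev(p$t1, 1, 2, 1), ev(p$t2, 1, 0, 1), ev(p$t2, 2, 1, x = p$Na)),
    "4" = list(ev(p$t1, 1, 2, 0), ev(p$t2, 1, 0, 1), ev(p$t2, 2, 1, x = p$Na)),
    "5" = {
      if (is.na(p$r)) stop("scenario 5 needs an admixture rate r")
      list(ev(p$t1, 3, 0, 1, 2, p$r), ev(p$t2, 1, 2, 1), ev(p$t2, 2, 1, x = p$Na))
    },
    stop("unknown scenario id: ", scenario))
  m <- do.call(rbind, rows)
  colnames(m) <- c("time", "type", "a", "b", "c", "x")
  m[order(m[, "time"]), , drop = FALSE]
}

#' Simulate one dataset under a demographic scenario
#'
#' Hudson structured coalescent on the scenario's population tree (haploid,
#' one non-recombining cpDNA locus) with an HKY finite-sites mutation overlay
#' at per-generation rate `mu_gen` per site.
#'
#' @param scenario Scenario id, 1-5.
#' @param params Named parameter vector (see [drawPriors]).
#' @param sample_sizes Samples per group (default `c(17, 74, 5)`).
#' @param L Locus length in bp (default 2858).
#' @param spec A [priorSpec] (mutation model settings are taken from it).
#' @param full If `TRUE`, return a gap-free [HaploAlignment] with group
#'   labels; otherwise a light list with the variable-site matrix (`mat`,
#'   integer bases 0-3), positions and group factor.
#' @return See `full`.
#' @export
simulateDataset <- function(scenario, params, sample_sizes = c(17, 74, 5),
                            L = 2858, spec = priorSpec(), full = FALSE) {
  ev <- scenarioEvents(scenario, params)
  sim <- sim_scenario_cpp(as.integer(sample_sizes),
                          as.numeric(params[c("N1", "N2", "N3")]),
                          ev, as.integer(L), spec$mu_gen, spec$kappa,
                          as.numeric(spec$base_freq))
  groups <- factor(rep(c("north", "central", "south"), sample_sizes),
                   levels = c("north", "central", "south"))
  if (!full)
    return(list(mat = sim$mat, pos = sim$pos, groups = groups,
                L = L, tmrca = sim$tmrca))
  bases <- c("A", "C", "G", "T")
  n <- sum(sample_sizes)
  root <- sample(bases, L, replace = TRUE, prob = spec$base_freq)
  m <- matrix(rep(root, each = n), nrow = n)
  if (length(sim$pos))
    m[, sim$pos] <- bases[sim$mat + 1L]
  ids <- sprintf("%s_%03d", groups, seq_len(n))
  seqs <- stats::setNames(apply(m, 1L, paste0, collapse = ""), ids)
  a <- .new_alignment(seqs)
  sampleData(a) <- data.frame(sample_id = ids,
                              population = as.character(groups),
                              lineage = as.character(groups))
  a
}

# ABC summary statistics from an integer (0..3) or character base matrix
.abc_stats <- function(mat, groups) {
  lev <- levels(groups)
  stopifnot(length(lev) == 3)
  n <- nrow(mat)
  S <- ncol(mat)
  vals <- sort(unique(as.vector(mat)))
  cnt <- function(rows) {
    # base x site count matrix for a subset of rows
    out <- matrix(0L, length(vals), S)
    if (S)
      for (b in seq_along(vals))
        out[b, ] <- colSums(mat[rows, , drop = FALSE] == vals[b])
    out
  }
  per <- lapply(lev, function(g) cnt(which(groups == g)))
  ng <- vapply(lev, function(g) sum(groups == g), numeric(1))
  res <- stats::setNames(numeric(length(.ABC_STAT_NAMES)), .ABC_STAT_NAMES)
  within_k <- numeric(3)
  for (g in 1:3) {
    cg <- per[[g]]
    nn <- ng[g]
    if (nn < 2) { within_k[g] <- NA; next }
    seg <- colSums(cg > 0) >= 2
    res[paste0("S_", g)] <- sum(seg)
    npairs <- nn * (nn - 1) / 2
    kk <- if (S) sum((npairs - colSums(choose(cg, 2))) / npairs) else 0
    res[paste0("k_", g)] <- kk
    within_k[g] <- kk
    if (any(seg)) {
      cseg <- cg[, seg, drop = FALSE]
      rare <- apply(cseg, 2L, function(col) min(col[col > 0]) / nn)
      res[paste0("rare_", g)] <- mean(rare)
    }
  }
  prs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (q in seq_along(prs)) {
    i <- prs[[q]][1]; j <- prs[[q]][2]
    tag <- paste0(i, j)
    cij <- per[[i]] + per[[j]]
    res[paste0("S_", tag)] <- sum(colSums(cij > 0) >= 2)
    between <- if (S)
      sum((ng[i] * ng[j] - colSums(per[[i]] * per[[j]])) / (ng[i] * ng[j]))
      else 0
    hw <- mean(within_k[c(i, j)], na.rm = TRUE)
    fst <- if (is.finite(between) && between > 0) 1 - hw / between else 0
    res[paste0("Fst_", tag)] <- max(-1, min(1, fst))
  }
  res
}

#' ABC summary statistics of a grouped alignment
#'
#' Per group: number of segregating sites, mean pairwise differences, and
#' the mean (over that group's segregating sites) relative frequency of the
#' rarest base. Per group pair: segregating sites of the pooled pair and a
#' Hudson-type \eqn{F_{ST}} (`1 - mean within / mean between` pairwise
#' differences, clamped to [-1, 1]; monomorphic pairs report 0).
#'
#' @param x A [HaploAlignment] with `lineage` metadata over exactly 3 groups,
#'   or a light simulation result from [simulateDataset].
#' @return Named numeric vector of 15 statistics.
#' @export
summarizeStats <- function(x) {
  if (is(x, "HaploAlignment")) {
    meta <- sampleData(x)
    if (nrow(meta) == 0L) stop("no metadata attached")
    groups <- factor(meta$lineage[match(sampleIDs(x), meta$sample_id)])
    if (nlevels(groups) != 3) stop("need exactly 3 groups")
    m <- seqMatrix(x)
    keep <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
    m <- m[, keep, drop = FALSE]
    poly <- apply(m, 2L, function(col) length(unique(col)) > 1)
    .abc_stats(m[, poly, drop = FALSE], groups)
  } else {
    .abc_stats(x$mat, x$groups)
  }
}
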