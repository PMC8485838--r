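#' @include scenarios.R
NULL

.sub_seed <- function(seed, scenario, i) {
  # counter-derived substream seed: reproducible independently of execution
  # order, kept below 2^31
  as.integer(((as.numeric(seed) + scenario * 1e7 + i) * 48271) %% 2147483647)
}

#' Build an ABC reference table
#'
#' Simulates `n_sims` datasets per scenario with parameters drawn from the
#' priors and records parameters and summary statistics. Each simulation
#' seeds the RNG from a counter derived from `seed`, the scenario id and the
#' simulation index, so the table is reproducible row-by-row regardless of
#' execution order.
#'
#' @param scenarios Integer vector of scenario ids (default 1:5).
#' @param n_sims Simulations per scenario.
#' @param spec A [priorSpec].
#' @param sample_sizes Samples per group (default `c(17, 74, 5)`).
#' @param L Locus length (default 2858).
#' @param seed Master seed.
#' @param file Optional TSV path; the table is streamed there in
#'   per-scenario chunks so an interrupted run can be inspected.
#' @return `data.frame` with columns `scenario`, the parameters and the 15
#'   summary statistics.
#' @export
buildReferenceTable <- function(scenarios = 1:5, n_sims = 1000,
                                spec = priorSpec(),
                                sample_sizes = c(17, 74, 5), L = 2858,
                                seed = 1L, file = NULL) {
  out <- vector("list", length(scenarios))
  for (si in seq_along(scenarios)) {
    sc <- scenarios[si]
    block <- matrix(NA_real_, n_sims,
                    length(.ABC_PARAM_NAMES) + length(.ABC_STAT_NAMES))
    colnames(block) <- c(.ABC_PARAM_NAMES, .ABC_STAT_NAMES)
    for (i in seq_len(n_sims)) {
      set.seed(.sub_seed(seed, sc, i))
      pars <- drawPriors(sc, spec)
      sim <- simulateDataset(sc, pars, sample_sizes, L, spec)
      block[i, ] <- c(pars, summarizeStats(sim))
    }
    df <- data.frame(scenario = sc, block, check.names = FALSE)
    out[[si]] <- df
    if (!is.null(file))
      utils::write.table(df, file, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = si == 1L,
                         append = si > 1L)
  }
  do.call(rbind, out)
}

.abc_scale <- function(table) {
  s <- vapply(.ABC_STAT_NAMES, function(cn) {
    v <- stats::mad(table[[cn]])
    if (v == 0) v <- stats::sd(table[[cn]])
    v
  }, numeric(1))
  s[!is.finite(s)] <- 0
  s
}

.abc_dist <- function(observed, table, scale) {
  use <- scale > 0
  sm <- as.matrix(table[, .ABC_STAT_NAMES, drop = FALSE])[, use, drop = FALSE]
  ctr <- sweep(sm, 2L, observed[.ABC_STAT_NAMES][use], "-")
  ctr <- sweep(ctr, 2L, scale[use], "/")
  sqrt(rowSums(ctr^2))
}

#' ABC scenario choice
#'
#' Rejection plus weighted logistic regression, DIYABC-style: statistics are
#' standardised by their table-wide MAD, the `tolerance` fraction of
#' simulations nearest (Euclidean) to the observed statistics is retained,
#' and each scenario's posterior probability is read from a one-vs-rest
#' logistic regression (Epanechnikov distance weights, covariates centred at
#' the observed point) evaluated at the observed point, then normalised to
#' sum to one. CIs come from the intercept's sampling variance on the logit
#' scale. The simple rejection frequencies are reported alongside.
#'
#' @param observed Named statistic vector from [summarizeStats].
#' @param table Reference table from [buildReferenceTable].
#' @param tolerance Fraction of simulations retained (default 0.01).
#' @return A list with `pp` (posterior probabilities), `ci` (2 x k matrix),
#'   `chosen`, `rejection` (accepted-set frequencies) and `n_accepted`.
#' @export
modelChoice <- function(observed, table, tolerance = 0.01) {
  scen <- sort(unique(table$scenario))
  scale <- .abc_scale(table)
  d <- .abc_dist(observed, table, scale)
  nacc <- max(ceiling(tolerance * nrow(table)), length(scen) * 5L)
  keep <- order(d)[seq_len(nacc)]
  acc <- table[keep, , drop = FALSE]
  dk <- d[keep]
  rej <- vapply(scen, function(s) mean(acc$scenario == s), numeric(1))
  names(rej) <- scen
  if (any(rej == 0))
    warning("scenario(s) absent from the accepted set: ",
            paste(scen[rej == 0], collapse = ", "), "; PP floored at 0")
  dmax <- max(dk) * 1.000001
  w <- if (dmax > 0) 1 - (dk / dmax)^2 else rep(1, length(dk))
  use <- scale > 0
  X <- as.matrix(acc[, .ABC_STAT_NAMES, drop = FALSE])[, use, drop = FALSE]
  X <- sweep(X, 2L, observed[.ABC_STAT_NAMES][use], "-")
  X <- sweep(X, 2L, scale[use], "/")
  # drop collinear columns to keep the regression stable
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    keepc <- qx$pivot[seq_len(qx$rank)] - 1L
    X <- X[, keepc[keepc > 0], drop = FALSE]
  }
  p <- se <- stats::setNames(numeric(length(scen)), scen)
  ok <- TRUE
  for (s in scen) {
    y <- as.numeric(acc$scenario == s)
    fit <- tryCatch(
      suppressWarnings(stats::glm(y ~ X, weights = w,
                                  family = stats::quasibinomial())),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(stats::coef(fit)[1])) { ok <- FALSE; break }
    p[as.character(s)] <- stats::plogis(stats::coef(fit)[1])
    v <- tryCatch(stats::vcov(fit)[1, 1], error = function(e) NA_real_)
    se[as.character(s)] <- if (is.finite(v)) sqrt(v) else NA_real_
  }
  if (!ok) {
    warning("logistic regression failed; falling back to rejection estimate")
    pp <- rej
    ci <- rbind(lo = pmax(0, pp - 1.96 * sqrt(pp * (1 - pp) / nacc)),
                hi = pmin(1, pp + 1.96 * sqrt(pp * (1 - pp) / nacc)))
    return(list(pp = pp, ci = ci, chosen = as.integer(names(which.max(pp))),
                rejection = rej, n_accepted = nacc, method = "rejection"))
  }
  tot <- sum(p)
  pp <- p / tot
  lg <- stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  lo <- stats::plogis(lg - 1.96 * se) / tot
  hi <- stats::plogis(lg + 1.96 * se) / tot
  ci <- rbind(lo = pmin(lo, pp), hi = pmax(hi, pp))
  list(pp = pp, ci = ci, chosen = as.integer(names(which.max(pp))),
       rejection = rej, n_accepted = nacc, method = "logistic")
}

#' Scenario-choice error rates from pseudo-observed datasets
#'
#' Simulates `n_pods` pseudo-observed datasets (PODs) per scenario with
#' parameters drawn from the priors, classifies each with [modelChoice]
#' against `table`, and reports per-scenario type I error (PODs from the
#' scenario not assigned to it) and type II error (PODs from other scenarios
#' assigned to it).
#'
#' @param table Reference table.
#' @param n_pods PODs per scenario (default 500).
#' @param spec,sample_sizes,L As in [buildReferenceTable].
#' @param tolerance Passed to [modelChoice].
#' @param seed Master seed.
#' @return A list with `type1`, `type2` (named per scenario) and the full
#'   `confusion` matrix (rows = generating scenario, cols = chosen).
#' @export
podErrorRates <- function(table, n_pods = 500, spec = priorSpec(),
                          sample_sizes = c(17, 74, 5), L = 2858,
                          tolerance = 0.01, seed = 1L) {
  scen <- sort(unique(table$scenario))
  k <- length(scen)
  conf <- matrix(0L, k, k, dimnames = list(scen, scen))
  for (si in seq_along(scen)) {
    sc <- scen[si]
    for (i in seq_len(n_pods)) {
      set.seed(.sub_seed(seed + 777L, sc, i))
      pars <- drawPriors(sc, spec)
      obs <- summarizeStats(simulateDataset(sc, pars, sample_sizes, L, spec))
      ch <- suppressWarnings(modelChoice(obs, table, tolerance))$chosen
      conf[si, as.character(ch)] <- conf[si, as.character(ch)] + 1L
    }
  }
  prop <- conf / n_pods
  type1 <- 1 - diag(prop)
  type2 <- vapply(seq_len(k), function(j) sum(prop[-j, j]) / (k - 1), numeric(1))
  names(type1) <- names(type2) <- scen
  list(type1 = type1, type2 = type2, confusion = conf)
}

.wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Local-linear ABC parameter estimation
#'
#' Beaumont-style regression adjustment for the chosen scenario: within the
#' accepted set, each parameter (log10 for sizes and times, raw for the
#' admixture rate) is regressed on the standardised statistics with
#' Epanechnikov weights; the adjusted draws give the posterior mean, median
#' and 95% CI. Times are also reported in years via the generation time.
#'
#' @param observed Named statistic vector.
#' @param table Reference table (will be restricted to `scenario`).
#' @param scenario Chosen scenario id.
#' @param tolerance Fraction retained within the scenario (default 0.01,
#'   measured against the full table size as in DIYABC).
#' @param spec A [priorSpec] (for the generation time).
#' @return `data.frame` with one row per parameter: mean, median, q2.5,
#'   q97.5 (natural scale), plus `mean_years` etc. for times.
#' @export
estimateParameters <- function(observed, table, scenario, tolerance = 0.01,
                               spec = priorSpec()) {
  sub <- table[table$scenario == scenario, , drop = FALSE]
  scale <- .abc_scale(table)
  d <- .abc_dist(observed, sub, scale)
  nacc <- max(ceiling(tolerance * nrow(table)), 50L)
  nacc <- min(nacc, nrow(sub))
  keep <- order(d)[seq_len(nacc)]
  acc <- sub[keep, , drop = FALSE]
  dk <- d[keep]
  dmax <- max(dk) * 1.000001
  w <- if (dmax > 0) 1 - (dk / dmax)^2 else rep(1, length(dk))
  use <- scale > 0
  X <- as.matrix(acc[, .ABC_STAT_NAMES, drop = FALSE])[, use, drop = FALSE]
  X <- sweep(X, 2L, observed[.ABC_STAT_NAMES][use], "-")
  X <- sweep(X, 2L, scale[use], "/")
  pars <- intersect(.ABC_PARAM_NAMES, colnames(acc))
  pars <- pars[!vapply(pars, function(p) anyNA(acc[[p]]), logical(1))]
  rows <- lapply(pars, function(pn) {
    y <- acc[[pn]]
    logscale <- pn != "r"
    if (logscale) y <- log10(y)
    fit <- tryCatch(stats::lm(y ~ X, weights = w), error = function(e) NULL)
    if (is.null(fit)) {
      adj <- y
      warning("singular regression for ", pn, "; unadjusted posterior used")
    } else {
      beta <- stats::coef(fit)[-1]
      beta[!is.finite(beta)] <- 0
      adj <- y - as.numeric(X %*% beta)
    }
    if (logscale) adj <- 10^adj
    qs <- .wquantile(adj, w, c(0.025, 0.5, 0.975))
    data.frame(parameter = pn, mean = sum(w * adj) / sum(w),
               median = qs[2], q2.5 = qs[1], q97.5 = qs[3])
  })
  out <- do.call(rbind, rows)
  gt <- spec$gen_time
  tr <- out$parameter %in% c("t1", "t2")
  out$mean_years <- ifelse(tr, out$mean * gt, NA)
  out$median_years <- ifelse(tr, out$median * gt, NA)
  out$q2.5_years <- ifelse(tr, out$q2.5 * gt, NA)
  out$q97.5_years <- ifelse(tr, out$q97.5 * gt, NA)
  out
}

#' PCA model check of simulated versus observed statistics
#'
#' PCA on the standardised statistics of a table subsample, with the
#' observed point projected into the same space, for goodness-of-fit plots.
#'
#' @param observed Named statistic vector.
#' @param table Reference table.
#' @param n_sample Subsample size (default 2000).
#' @param seed RNG seed for the subsample.
#' @return A list with `scores` (subsample coordinates + scenario),
#'   `observed` (coordinates) and `var_explained`.
#' @export
modelCheckPca <- function(observed, table, n_sample = 2000, seed = 1L) {
  set.seed(seed)
  idx <- sample(nrow(table), min(n_sample, nrow(table)))
  scale <- .abc_scale(table)
  use <- scale > 0
  if (sum(use) < 3) stop("fewer than 3 statistics with nonzero variance")
  sm <- as.matrix(table[idx, .ABC_STAT_NAMES])[, use, drop = FALSE]
  ctr <- colMeans(sm)
  sm <- sweep(sweep(sm, 2L, ctr, "-"), 2L, scale[use], "/")
  pc <- stats::prcomp(sm, center = FALSE, scale. = FALSE)
  ob <- (observed[.ABC_STAT_NAMES][use] - ctr) / scale[use]
  obs_scores <- as.numeric(ob %*% pc$rotation[, 1:2])
  list(scores = data.frame(scenario = table$scenario[idx],
                           PC1 = pc$x[, 1], PC2 = pc$x[, 2]),
       observed = stats::setNames(obs_scores, c("PC1", "PC2")),
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[1:2])
}
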