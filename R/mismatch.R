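#' @include neutrality.R
NULL

#' Observed mismatch distribution
#'
#' Histogram of pairwise difference counts over all n(n-1)/2 sequence pairs,
#' normalised to relative frequencies over classes `0..max`.
#'
#' @param x Gap-free [HaploAlignment] or character vector of equal-length
#'   sequences.
#' @return Numeric vector of relative frequencies named `0`, `1`, ...
#' @export
mismatchObserved <- function(x) {
  m <- .as_char_matrix(x)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  diffs <- integer(0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    diffs <- c(diffs, sum(m[i, ] != m[j, ]))
  tab <- tabulate(diffs + 1L, nbins = max(diffs) + 1L)
  stats::setNames(tab / sum(tab), 0:max(diffs))
}

#' Expected mismatch distribution under sudden expansion
#'
#' Rogers-Harpending (1992) transient distribution for a population that
#' changed from mutation-scaled size `theta0` to `theta1` at scaled time
#' `tau` before present:
#' \deqn{F_j(\tau) = \hat F_j(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
#'   \sum_{i=0}^{j} \frac{\tau^{j-i}}{(j-i)!}
#'   \left[\hat F_i(\theta_0) - \hat F_i(\theta_1)\right]}
#' with the equilibrium geometric \eqn{\hat F_j(\theta) =
#' \theta^j/(1+\theta)^{j+1}}. As \eqn{\tau \to 0} this reduces to the
#' equilibrium at `theta0`.
#'
#' @param tau Scaled expansion time (>= 0).
#' @param theta0,theta1 Pre-/post-expansion mutation-scaled sizes.
#' @param dmax Largest difference class to evaluate.
#' @return Numeric vector of raw class probabilities for `0..dmax` (not
#'   renormalised over the truncated support).
#' @export
expectedMismatch <- function(tau, theta0, theta1, dmax) {
  eq <- function(theta, j) theta^j / (1 + theta)^(j + 1)
  j <- 0:dmax
  F1 <- eq(theta1, j)
  F0 <- eq(theta0, j)
  damp <- exp(-tau * (theta1 + 1) / theta1)
  out <- numeric(dmax + 1)
  diff0 <- F0 - F1
  lfac <- lgamma(seq_len(dmax + 1))       # log((j-i)!) lookup
  for (jj in j) {
    i <- 0:jj
    terms <- exp((jj - i) * log(max(tau, .Machine$double.xmin)) -
                   lfac[jj - i + 1]) * diff0[i + 1]
    if (tau == 0) terms <- c(rep(0, jj), diff0[jj + 1])
    out[jj + 1] <- F1[jj + 1] + damp * sum(terms)
  }
  stats::setNames(pmax(out, 0), j)
}

#' Harpending's raggedness index
#'
#' \eqn{Hri = \sum_i (x_i - x_{i-1})^2} over consecutive class frequencies,
#' with the boundary convention that classes \eqn{-1} and \eqn{d_{max}+1}
#' have frequency 0 (so the first and last classes contribute their squared
#' frequencies).
#'
#' @param obs Relative frequency vector over classes `0..dmax`.
#' @return The raggedness index.
#' @export
harpendingRaggedness <- function(obs) {
  x <- c(0, obs, 0)
  sum(diff(x)^2)
}

# infinite-sites coalescent mismatch under sudden expansion, simulated in
# mutational units (u = 1/2 per locus: sizes are theta, expansion time tau)
.sim_expansion_mismatch <- function(n, tau, theta0, theta1) {
  nnode <- 2 * n - 1
  ntime <- numeric(nnode)
  parent <- integer(nnode)
  parent[] <- NA_integer_
  active <- seq_len(n)
  t <- 0
  nextn <- n + 1
  for (k in n:2) {
    rate_pairs <- k * (k - 1) / 2
    repeat {
      Ncur <- if (t < tau) theta1 else theta0
      dt <- stats::rexp(1, rate_pairs / Ncur)
      if (t < tau && t + dt > tau) { t <- tau; next }
      t <- t + dt
      break
    }
    pick <- sample(length(active), 2)
    ntime[nextn] <- t
    parent[active[pick]] <- nextn
    active <- c(active[-pick], nextn)
    nextn <- nextn + 1
  }
  diffs <- matrix(0, n, n)
  tips_below <- vector("list", nnode)
  for (v in seq_len(n)) tips_below[[v]] <- v
  ord <- order(ntime[(n + 1):nnode]) + n
  child <- lapply(seq_len(nnode), function(v) which(parent == v))
  for (v in ord) tips_below[[v]] <- unlist(tips_below[child[[v]]])
  for (v in seq_len(nnode - 1)) {
    len <- ntime[parent[v]] - ntime[v]
    mmut <- stats::rpois(1, len / 2)
    if (mmut > 0) {
      b <- tips_below[[v]]
      diffs[b, -b] <- diffs[b, -b] + mmut
    }
  }
  d <- diffs[upper.tri(diffs)] + t(diffs)[upper.tri(diffs)]
  tab <- tabulate(d + 1L, nbins = max(d) + 1L)
  tab / sum(tab)
}

.fit_ssd <- function(obs, starts) {
  dmax <- length(obs) - 1
  ssd_of <- function(par) {
    e <- expectedMismatch(exp(par[1]), exp(par[2]), exp(par[3]), dmax)
    s <- sum(e)
    if (s <= 0) return(1e6)
    sum((obs - e / s)^2)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(log(s), ssd_of, method = "L-BFGS-B",
                   lower = log(c(1e-4, 1e-6, 1e-2)),
                   upper = log(c(4 * (dmax + 1), 1e4, 1e4))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("sudden-expansion optimiser failed for all starts")
  list(tau = exp(best$par[1]), theta0 = exp(best$par[2]),
       theta1 = exp(best$par[3]), SSD = best$value)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Estimates (tau, theta0, theta1) by bounded multistart minimisation of the
#' sum of squared deviations between the observed class frequencies and the
#' (renormalised) Rogers-Harpending expectation, and tests goodness of fit by
#' parametric bootstrap: `n_boot` coalescent samples are simulated under the
#' fitted expansion, each is refitted, and p-values are the proportions of
#' bootstrap SSD (resp. raggedness) at least as large as observed.
#'
#' @param observed Relative frequency vector over classes `0..dmax` (e.g.
#'   from [mismatchObserved]); at least 2 classes with mass.
#' @param n Sample size behind the observed distribution (used by the
#'   bootstrap); groups below `min_n` are refused.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param min_n Minimum sample size (default 8).
#' @return A list with `observed`, `expected` (renormalised over the observed
#'   support), `tau`, `theta0`, `theta1`, `SSD`, `Hri`, `p_SSD`, `p_Hri` and
#'   `boot_tau` (the bootstrap re-estimates of tau).
#' @export
fitSuddenExpansion <- function(observed, n, n_boot = 1000, seed = 1L,
                               min_n = 8) {
  if (n < min_n)
    stop("sample too small for mismatch fitting (n = ", n, " < ", min_n, ")")
  if (sum(observed > 0) < 2) stop("need at least 2 difference classes with mass")
  dmax <- length(observed) - 1
  kbar <- sum((0:dmax) * observed)
  starts <- list(c(max(kbar, 0.5), 0.1, 100),
                 c(max(kbar / 2, 0.25), 1, 1000),
                 c(max(2 * kbar, 1), 0.01, 10),
                 c(1, 0.5, 1e4))
  fit <- .fit_ssd(observed, starts)
  Hri <- harpendingRaggedness(observed)
  set.seed(seed)
  bSSD <- bHri <- bTau <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    sim <- .sim_expansion_mismatch(n, fit$tau, fit$theta0, fit$theta1)
    bfit <- tryCatch(
      .fit_ssd(sim, list(c(fit$tau, fit$theta0, fit$theta1),
                         c(max(sum((seq_along(sim) - 1) * sim), 0.5), 0.1, 100))),
      error = function(e) NULL)
    bSSD[b] <- if (is.null(bfit)) NA_real_ else bfit$SSD
    bTau[b] <- if (is.null(bfit)) NA_real_ else bfit$tau
    bHri[b] <- harpendingRaggedness(sim)
  }
  e <- expectedMismatch(fit$tau, fit$theta0, fit$theta1, dmax)
  ok <- is.finite(bSSD)
  list(observed = observed, expected = e / sum(e),
       tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
       SSD = fit$SSD, Hri = Hri,
       p_SSD = (sum(bSSD[ok] >= fit$SSD) + 1) / (sum(ok) + 1),
       p_Hri = (sum(bHri >= Hri) + 1) / (n_boot + 1),
       boot_tau = bTau, n_boot = n_boot)
}
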