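test_that("prior draws respect bounds and the t2 >= t1 constraint", {
  spec <- priorSpec()
  set.seed(1)
  draws <- t(replicate(2000, drawPriors(2, spec)))
  expect_true(all(draws[, c("Na", "N1", "N2", "N3")] >= 10 &
                  draws[, c("Na", "N1", "N2", "N3")] <= 1e5))
  expect_true(all(draws[, "t2"] >= draws[, "t1"]))
  expect_true(all(is.na(draws[, "r"])))
  # conditional mean of t1 given t2 >= t1 is a + (b - a)/3
  a <- spec$t_bounds[1]; b <- spec$t_bounds[2]
  se <- (b - a) / sqrt(18) / sqrt(2000)
  expect_lt(abs(mean(draws[, "t1"]) - (a + (b - a) / 3)), 4 * se)
  set.seed(2)
  d5 <- drawPriors(5, spec)
  expect_true(d5["r"] >= 0.1 && d5["r"] <= 0.9)
})

test_that("scenario event lists enforce their invariants", {
  p <- stats::setNames(c(1e4, 1e4, 1e4, 1e4, 5e3, 2e3, NA),
                       cpPhylogeo:::.ABC_PARAM_NAMES)
  expect_error(scenarioEvents(1, p), "t2 < t1")
  p["t2"] <- 8e3
  ev <- scenarioEvents(2, p)
  expect_true(all(diff(ev[, "time"]) >= 0))
  p5 <- p; p5["r"] <- NA
  expect_error(scenarioEvents(5, p5), "admixture rate")
  expect_error(scenarioEvents(9, p), "unknown scenario")
})

test_that("the coalescent simulator matches neutral expectations", {
  # E[TMRCA] = N for n = 2 under the haploid convention
  set.seed(31)
  tm <- replicate(2000, cpPhylogeo:::sim_scenario_cpp(
    2L, 1000, matrix(numeric(0), 0, 6), 10L, 0, 2, rep(0.25, 4))$tmrca)
  expect_lt(abs(mean(tm) - 1000), 3 * sd(tm) / sqrt(2000))
})

test_that("simulated datasets have the requested shape and group labels", {
  p <- stats::setNames(c(2e4, 6e4, 6e4, 6e4, 3500, 2e4, NA),
                       cpPhylogeo:::.ABC_PARAM_NAMES)
  set.seed(9)
  a <- simulateDataset(1, p, c(17, 74, 5), 500, full = TRUE)
  expect_s4_class(a, "HaploAlignment")
  expect_equal(length(sampleIDs(a)), 96L)
  expect_equal(alnLength(a), 500L)
  expect_equal(as.integer(table(sampleData(a)$lineage)[c("north", "central", "south")]),
               c(17L, 74L, 5L))
})

test_that("deep divergence drives pairwise FST toward 1", {
  p <- stats::setNames(c(1000, 1000, 1000, 1000, 9e5, 1e6, NA),
                       cpPhylogeo:::.ABC_PARAM_NAMES)
  set.seed(12)
  st <- summarizeStats(simulateDataset(1, p, c(10, 10, 4), 2000))
  expect_true(all(st[c("Fst_12", "Fst_13", "Fst_23")] > 0.8))
})

test_that("summary statistics honour their definitional cases", {
  groups <- factor(rep(c("north", "central", "south"), c(10, 10, 2)),
                   levels = c("north", "central", "south"))
  # monomorphic alignment: everything 0
  mono <- matrix(0L, 22, 0)
  st <- cpPhylogeo:::.abc_stats(mono, groups)
  expect_true(all(st == 0))
  # two groups fixed for different bases at every variable site
  mat <- rbind(matrix(0L, 10, 3), matrix(2L, 10, 3), matrix(2L, 2, 3))
  st2 <- cpPhylogeo:::.abc_stats(mat, groups)
  expect_equal(unname(st2["Fst_12"]), 1)
  expect_equal(unname(st2["S_1"]), 0)
  expect_equal(unname(st2["S_12"]), 3)
  # rarest-base frequency: A:9, T:1 in a group of 10 contributes 0.1
  mat3 <- cbind(c(rep(0L, 9), 3L, rep(0L, 12)))
  st3 <- cpPhylogeo:::.abc_stats(mat3, groups)
  expect_equal(unname(st3["rare_1"]), 0.1)
})

test_that("reference tables are reproducible and order-independent", {
  t1 <- buildReferenceTable(scenarios = c(1, 2), n_sims = 15, seed = 77)
  t2 <- buildReferenceTable(scenarios = c(1, 2), n_sims = 15, seed = 77)
  expect_identical(t1, t2)
  # per-simulation substreams: building scenario 2 alone gives the same rows
  t3 <- buildReferenceTable(scenarios = 2, n_sims = 15, seed = 77)
  expect_equal(t1[t1$scenario == 2, ], t3, ignore_attr = TRUE)
  expect_equal(as.integer(table(t1$scenario)), c(15L, 15L))
  # streaming writer produces a readable file
  f <- tempfile(fileext = ".tsv")
  t4 <- buildReferenceTable(scenarios = 1, n_sims = 5, seed = 3, file = f)
  expect_equal(nrow(read.delim(f, check.names = FALSE)), 5L)
})

test_that("model choice returns normalised probabilities and sane rankings", {
  # well-separated synthetic table: scenario signatures differ strongly
  set.seed(20)
  n <- 400
  mk <- function(sc, shift) {
    stats <- matrix(rnorm(n * 15, shift, 1), n, 15,
                    dimnames = list(NULL, cpPhylogeo:::.ABC_STAT_NAMES))
    pars <- matrix(1000, n, 7,
                   dimnames = list(NULL, cpPhylogeo:::.ABC_PARAM_NAMES))
    data.frame(scenario = sc, pars, stats, check.names = FALSE)
  }
  tab <- rbind(mk(1, 0), mk(2, 6), mk(3, 12))
  obs <- stats::setNames(rep(6, 15), cpPhylogeo:::.ABC_STAT_NAMES)
  mc <- suppressWarnings(modelChoice(obs, tab, tolerance = 0.05))
  expect_equal(sum(mc$pp), 1)
  expect_equal(mc$chosen, 2L)
  expect_true(all(mc$ci["lo", ] <= mc$pp + 1e-9) &&
              all(mc$ci["hi", ] >= mc$pp - 1e-9))
})

test_that("model choice is invariant to affine rescaling of a statistic", {
  set.seed(23)
  tab <- buildReferenceTable(scenarios = c(1, 3), n_sims = 150, seed = 5)
  obs <- summarizeStats(simulateDataset(
    1, stats::setNames(c(2e4, 6e4, 6e4, 6e4, 3500, 2e4, NA),
                       cpPhylogeo:::.ABC_PARAM_NAMES)))
  mc1 <- suppressWarnings(modelChoice(obs, tab))
  tab2 <- tab
  tab2$k_2 <- 7 * tab2$k_2 - 3
  obs2 <- obs
  obs2["k_2"] <- 7 * obs2["k_2"] - 3
  mc2 <- suppressWarnings(modelChoice(obs2, tab2))
  expect_equal(mc1$pp, mc2$pp, tolerance = 1e-8)
})

test_that("duplicated scenarios share the posterior mass", {
  set.seed(30)
  tab <- buildReferenceTable(scenarios = c(1, 2), n_sims = 200, seed = 9)
  dup <- tab[tab$scenario == 2, ]
  dup$scenario <- 9
  tab2 <- rbind(tab, dup)   # scenario 9 is an exact copy of scenario 2
  obs <- summarizeStats(simulateDataset(
    2, stats::setNames(c(2e4, 6e4, 6e4, 6e4, 3500, 2e4, NA),
                       cpPhylogeo:::.ABC_PARAM_NAMES)))
  mc <- suppressWarnings(modelChoice(obs, tab2, tolerance = 0.05))
  expect_lt(abs(mc$pp["2"] - mc$pp["9"]), 0.12)
})

test_that("parameter estimation adjusts draws and reports years", {
  set.seed(33)
  tab <- buildReferenceTable(scenarios = 2, n_sims = 300, seed = 13)
  obs <- summarizeStats(simulateDataset(
    2, stats::setNames(c(2e4, 6e4, 6e4, 6e4, 3500, 2e4, NA),
                       cpPhylogeo:::.ABC_PARAM_NAMES)))
  est <- suppressWarnings(estimateParameters(obs, tab, 2, tolerance = 0.2))
  expect_true(all(c("t1", "t2", "Na") %in% est$parameter))
  t2row <- est[est$parameter == "t2", ]
  expect_equal(t2row$mean_years, t2row$mean * 10)
  expect_true(all(est$q2.5 <= est$median & est$median <= est$q97.5))
  # constant statistics: the regression cannot adjust, posterior = rejection
  tabc <- tab
  tabc[cpPhylogeo:::.ABC_STAT_NAMES] <- 1
  obsc <- stats::setNames(rep(1, 15), cpPhylogeo:::.ABC_STAT_NAMES)
  estc <- suppressWarnings(estimateParameters(obsc, tabc, 2, tolerance = 0.2))
  accn <- max(ceiling(0.2 * nrow(tabc)), 50)
  expect_equal(estc[estc$parameter == "t1", "median"],
               unname(stats::quantile(tabc$t1[seq_len(accn)], 0.5, type = 1)),
               tolerance = 0.15)
})

test_that("PCA model check embeds the observed point reproducibly", {
  set.seed(40)
  tab <- buildReferenceTable(scenarios = c(1, 2), n_sims = 120, seed = 21)
  obs <- summarizeStats(simulateDataset(
    1, stats::setNames(c(2e4, 6e4, 6e4, 6e4, 3500, 2e4, NA),
                       cpPhylogeo:::.ABC_PARAM_NAMES)))
  p1 <- modelCheckPca(obs, tab, n_sample = 100, seed = 2)
  p2 <- modelCheckPca(obs, tab, n_sample = 100, seed = 2)
  expect_identical(p1$observed, p2$observed)
  expect_true(sum(p1$var_explained) <= 1 + 1e-9)
  # observed generated from a table scenario lies inside the cloud
  expect_true(p1$observed["PC1"] >= min(p1$scores$PC1) - 1 &&
              p1$observed["PC1"] <= max(p1$scores$PC1) + 1)
})
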