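#' @include synthetic.R
NULL

#' Default pipeline configuration
#'
#' Returns the default config list: input paths (or a synthetic-data block),
#' stage toggles, permutation/simulation counts and seeds. The config
#' round-trips losslessly through JSON ([jsonlite::write_json] /
#' [jsonlite::read_json]).
#'
#' @param out_dir Run directory.
#' @return A named list.
#' @export
pipelineConfig <- function(out_dir = tempfile("cpphylogeo_run_")) {
  list(
    input = list(fasta = NULL, metadata = NULL),
    synth = list(enabled = TRUE, scenario = 2, seed = 1L),
    stages = list(ingest = TRUE, haplotypes = TRUE, network = TRUE,
                  diversity = TRUE, structure = TRUE, demography = TRUE,
                  abc = FALSE),
    perms = list(amova = 200, fst = 200, gstnst = 1000, mantel = 200),
    sims = list(neutrality = 200, mismatch_boot = 100,
                abc_per_scenario = 500, pods_per_scenario = 20),
    seed = 1L,
    out_dir = out_dir)
}

.write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full phylogeography pipeline
#'
#' Executes ingest -> haplotypes -> network -> diversity -> structure ->
#' demography -> abc according to the stage toggles, writing TSV/JSON/GraphML
#' reports and a run manifest (package version, seeds, input checksums) into
#' the run directory. Stochastic stages are seeded from `config$seed`, so a
#' rerun with the same config reproduces every report byte-for-byte.
#'
#' @param config A list as from [pipelineConfig].
#' @return The run directory, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  st <- config$stages

  # ingest
  a <- .stage("ingest", {
    if (isTRUE(config$synth$enabled)) {
      g <- generateStudyLike(scenario = config$synth$scenario,
                             seed = config$synth$seed)
      g$alignment
    } else {
      al <- readAlignment(config$input$fasta)
      sampleData(al) <- readSampleMetadata(config$input$metadata)
      al
    }
  })
  flt <- .stage("ingest", filterCompleteColumns(a))
  message("complete-deletion removed ", alnLength(a) - alnLength(flt$alignment),
          " of ", alnLength(a), " columns")
  writeAlignment(flt$alignment, file.path(out, "filtered.fasta"))
  writeSiteClasses(flt$siteClasses, file.path(out, "site_classes.tsv"))
  fa <- flt$alignment

  ht <- NULL
  if (isTRUE(st$haplotypes) || isTRUE(st$network) || isTRUE(st$structure)) {
    ht <- .stage("haplotypes", collapseHaplotypes(fa))
    writeHaplotypeTable(ht, file.path(out, "haplotype_table.tsv"))
    writeNexusHaplotypes(ht, file.path(out, "haplotypes.nex"))
  }
  if (isTRUE(st$network)) {
    net <- .stage("network", medianJoiningNetwork(ht))
    writeGraphML(net, file.path(out, "network.graphml"))
  }
  if (isTRUE(st$diversity)) {
    .stage("diversity", {
      .write_tsv(diversityByGroup(fa, "population"),
                 file.path(out, "diversity_populations.tsv"))
      .write_tsv(diversityByGroup(fa, "lineage"),
                 file.path(out, "diversity_lineages.tsv"))
    })
  }
  if (isTRUE(st$structure)) {
    .stage("structure", {
      meta <- sampleData(fa)
      dtn <- tamuraNeiDistance(fa)
      pop <- meta$population[match(sampleIDs(fa), meta$sample_id)]
      lin <- meta$lineage[match(sampleIDs(fa), meta$sample_id)]
      res <- list(
        no_groups = amova(dtn, pop, nperm = config$perms$amova, seed = seed),
        two_groups = amova(dtn, pop,
                           groups = ifelse(lin == "south", "south", "north+central"),
                           nperm = config$perms$amova, seed = seed),
        three_groups = amova(dtn, pop, groups = lin,
                             nperm = config$perms$amova, seed = seed))
      for (nm in names(res))
        .write_tsv(cbind(res[[nm]]$table,
                         index = c(names(res[[nm]]$indices),
                                   rep("", nrow(res[[nm]]$table) -
                                         length(res[[nm]]$indices))),
                         value = c(res[[nm]]$indices,
                                   rep(NA, nrow(res[[nm]]$table) -
                                         length(res[[nm]]$indices)))),
                   file.path(out, paste0("amova_", nm, ".tsv")))
      pf <- pairwiseFst(dtn, lin, nperm = config$perms$fst, seed = seed)
      .write_tsv(data.frame(pair = outer(rownames(pf$fst), colnames(pf$fst),
                                         paste)[upper.tri(pf$fst)],
                            fst = pf$fst[upper.tri(pf$fst)],
                            p = pf$p[upper.tri(pf$p)]),
                 file.path(out, "pairwise_fst_lineages.tsv"))
      gn <- gstNst(ht, nperm = config$perms$gstnst, seed = seed)
      jsonlite::write_json(gn, file.path(out, "gst_nst.json"),
                           auto_unbox = TRUE, digits = NA)
      if (all(c("lat", "lon") %in% names(meta))) {
        # population-pair genetic distance for IBD; single-sample
        # populations carry no within-population information and are dropped
        big <- names(which(table(pop) >= 2))
        keep_s <- pop %in% big
        pf2 <- pairwiseFst(dtn[keep_s, keep_s], pop[keep_s], nperm = 1,
                           seed = seed)
        geo <- geographicDistance(meta)
        keep <- intersect(rownames(pf2$fst), rownames(geo))
        mt <- mantelIBD(pf2$fst[keep, keep], geo[keep, keep],
                        nperm = config$perms$mantel, seed = seed)
        jsonlite::write_json(mt, file.path(out, "mantel_ibd.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    })
  }
  if (isTRUE(st$demography)) {
    .stage("demography", {
      .write_tsv(neutralityByGroup(fa, nsim = config$sims$neutrality,
                                   seed = seed),
                 file.path(out, "neutrality_lineages.tsv"))
      meta <- sampleData(fa)
      lin <- meta$lineage[match(sampleIDs(fa), meta$sample_id)]
      seqs <- as.character(fa@seqs)
      mm <- list()
      for (g in unique(lin)) {
        s <- seqs[lin == g]
        if (length(s) < 8) next
        obs <- mismatchObserved(s)
        fit <- fitSuddenExpansion(obs, n = length(s),
                                  n_boot = config$sims$mismatch_boot,
                                  seed = seed)
        mm[[g]] <- fit[c("tau", "theta0", "theta1", "SSD", "Hri",
                         "p_SSD", "p_Hri")]
        .write_tsv(data.frame(differences = as.integer(names(obs)),
                              observed = unname(obs),
                              expected = unname(fit$expected)),
                   file.path(out, paste0("mismatch_", g, ".tsv")))
      }
      jsonlite::write_json(mm, file.path(out, "mismatch_fits.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }
  if (isTRUE(st$abc)) {
    .stage("abc", {
      obs <- summarizeStats(fa)
      tab <- buildReferenceTable(n_sims = config$sims$abc_per_scenario,
                                 seed = seed)
      mc <- suppressWarnings(modelChoice(obs, tab))
      pods <- podErrorRates(tab, n_pods = config$sims$pods_per_scenario,
                            seed = seed)
      est <- estimateParameters(obs, tab, mc$chosen)
      jsonlite::write_json(
        list(pp = as.list(mc$pp), chosen = mc$chosen,
             rejection = as.list(mc$rejection),
             type1 = as.list(pods$type1), type2 = as.list(pods$type2),
             parameters = est),
        file.path(out, "abc_results.json"), auto_unbox = TRUE, digits = NA)
    })
  }

  manifest <- list(
    package = "cpPhylogeo",
    version = as.character(utils::packageVersion("cpPhylogeo")),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    inputs = if (!isTRUE(config$synth$enabled))
      as.list(tools::md5sum(unlist(config$input))) else list(synthetic = TRUE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
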