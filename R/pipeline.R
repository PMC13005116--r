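#' Pipeline configuration
#'
#' Bundles the seeds, resampling counts and estimator settings for the
#' phase-level pipelines. All randomness in a run is derived from `seed`,
#' so a config (recorded in the output manifest) reproduces a bundle
#' exactly.
#'
#' @param outDir Output directory for the report bundle.
#' @param seed Master integer seed.
#' @param nBoot Edge-bootstrap replicates.
#' @param nPerm Network-comparison permutations.
#' @param csB Case-dropping subsamples per drop proportion.
#' @param csGrid Drop proportions for the CS-coefficient.
#' @param folds CV folds for LASSO steps.
#' @param gamma,nLambda EBIC glasso settings.
#' @return A `pipelineConfig` list.
#' @export
pipelineConfig <- function(outDir = tempfile("panelnet-run"), seed = 1L,
                           nBoot = 1000, nPerm = 1000, csB = 1000,
                           csGrid = seq(0.1, 0.75, by = 0.05), folds = 10,
                           gamma = 0.5, nLambda = 100) {
  stopifnot(nBoot >= 1, nPerm >= 1, csB >= 1)
  structure(list(outDir = outDir, seed = as.integer(seed), nBoot = nBoot,
                 nPerm = nPerm, csB = csB, csGrid = csGrid, folds = folds,
                 gamma = gamma, nLambda = nLambda),
            class = "pipelineConfig")
}

runStage <- function(bundle, name, expr) {
  res <- tryCatch(expr, error = function(e) e)
  if (inherits(res, "error")) {
    writeBundle(bundle$config, bundle$stages, bundle$file)
    stopf("pipeline stage '%s' failed: %s (partial bundle written to %s)",
          name, conditionMessage(res), bundle$config$outDir)
  }
  bundle$stages[[name]] <- res
  bundle
}

writeBundle <- function(config, stages, file) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "panelnet",
                   version = as.character(utils::packageVersion("panelnet")),
                   seed = config$seed,
                   settings = config[c("nBoot", "nPerm", "csB", "folds",
                                       "gamma", "nLambda")],
                   schema = "panelnet-bundle-1")
  jsonlite::write_json(list(manifest = manifest, stages = stages),
                       file.path(config$outDir, file),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(file.path(config$outDir, file))
}

netJson <- function(net) {
  list(nodes = colnames(net$weights), edges = asEdgeList(net),
       lambda = net$lambda %||% NULL,
       globalStrength = globalStrength(net),
       nEdges = sum(net$weights[upper.tri(net$weights)] != 0))
}

#' Run the phase-I analysis pipeline
#'
#' Reproduces the full cross-sectional + temporal comparison workflow on a
#' two-group panel: remission labelling at the final wave, baseline
#' network per group with centralities, edge-bootstrap and CS stability,
#' network comparison test (full and severity-matched samples),
#' cross-lagged panel networks per group with the temporal-constraint
#' test and prediction indices, and between-group similarity (Jaccard
#' index, edge-weight correlation) per interval. Writes a JSON bundle and
#' CSV tables to `config$outDir`.
#'
#' @param data A two-group [panelData()] with >= 3 waves; when `NULL`, a
#'   synthetic panel is generated from `synth`.
#' @param config A [pipelineConfig()].
#' @param synth A [synthConfig()] used when `data` is `NULL`.
#' @return The report bundle (list of stage results), invisibly; side
#'   effect: `phase1.json` and CSV tables in `config$outDir`.
#' @export
runPhase1 <- function(data = NULL, config = pipelineConfig(),
                      synth = phase1Config(config$seed)) {
  if (is.null(data)) data <- simulatePanel(synth)$data
  stopifnot(inherits(data, "panelData"))
  if (is.null(data$group)) stopf("phase-I pipeline needs group labels")
  groups <- sort(unique(data$group))
  if (length(groups) != 2) stopf("phase-I pipeline needs exactly 2 groups")
  waves <- data$waves[1:3]
  baseWave <- waves[1]
  finalWave <- waves[3]
  byGroup <- lapply(groups, function(g)
    subsetSubjects(data, which(data$group == g)))
  names(byGroup) <- groups
  est <- ggmEstimator(gamma = config$gamma, nLambda = config$nLambda)

  bundle <- new.env()
  bundle$config <- config
  bundle$stages <- list()
  bundle$file <- "phase1.json"

  bundle <- runStage(bundle, "remission", {
    lab <- classifyRemission(data, finalWave, missing = "na")
    list(wave = finalWave, nRemitter = sum(lab, na.rm = TRUE),
         nNonRemitter = sum(!lab, na.rm = TRUE), nMissing = sum(is.na(lab)),
         byGeneratingGroup = lapply(split(lab, data$group), function(v)
           list(remitter = sum(v, na.rm = TRUE),
                nonremitter = sum(!v, na.rm = TRUE))))
  })
  baselineNets <- NULL
  bundle <- runStage(bundle, "baseline_networks", {
    baselineNets <- lapply(byGroup, function(d)
      ebicGlasso(spearmanMatrix(d, baseWave), gamma = config$gamma,
                 nLambda = config$nLambda))
    lapply(baselineNets, netJson)
  })
  bundle <- runStage(bundle, "centrality", {
    lapply(baselineNets, centralityTable)
  })
  bundle <- runStage(bundle, "edge_stability", {
    lapply(groups, function(g) {
      bt <- bootstrapEdges(byGroup[[g]], est, B = config$nBoot,
                           seed = childSeed(config$seed, paste0("boot", g)),
                           wave = baseWave)
      list(group = g, B = bt$B, nFailed = bt$nFailed,
           meanCiWidth = mean(bt$edges$upper - bt$edges$lower),
           edges = bt$edges)
    })
  })
  bundle <- runStage(bundle, "centrality_stability", {
    res <- lapply(groups, function(g) {
      cs <- caseDropCS(byGroup[[g]], ggmCentrality(est),
                       dropGrid = config$csGrid, B = config$csB,
                       seed = childSeed(config$seed, paste0("cs", g)),
                       wave = baseWave)
      list(group = g, cs = as.list(cs$cs),
           stable = as.list(cs$cs >= 0.25), table = cs$table)
    })
    names(res) <- groups
    res
  })
  bundle <- runStage(bundle, "nct", {
    r <- nctTest(byGroup[[1]], byGroup[[2]], estimator = est,
                 nPerm = config$nPerm,
                 seed = childSeed(config$seed, "nct"), wave = baseWave)
    nctJson(r, groups)
  })
  bundle <- runStage(bundle, "nct_matched", {
    sev <- totalScore(data, baseWave)
    mres <- matchGroups(data, sev)
    md <- matchedSubset(data, mres)
    mg <- lapply(groups, function(g)
      subsetSubjects(md, which(md$group == g)))
    r <- nctTest(mg[[1]], mg[[2]], estimator = est, nPerm = config$nPerm,
                 seed = childSeed(config$seed, "nctmatch"), wave = baseWave)
    c(list(nPairs = nrow(mres$pairs)), nctJson(r, groups))
  })
  clpns <- list()
  bundle <- runStage(bundle, "clpn", {
    clpns <- lapply(groups, function(g)
      fitCLPN(byGroup[[g]], folds = config$folds,
              seed = childSeed(config$seed, paste0("clpn", g)),
              waves = waves))
    names(clpns) <- groups
    lapply(clpns, function(cl) list(
      intervals = lapply(cl$networks, function(nw) list(
        interval = nw$interval,
        nCrossLagged = sum(nw$B[row(nw$B) != col(nw$B)] != 0),
        meanAutoregressive = mean(abs(diag(nw$B))),
        edges = directedEdgeList(nw))),
      unconstrained = cl$unconstrained$fit,
      constrained = cl$constrained$fit,
      constraintTest = cl$constraintTest))
  })
  bundle <- runStage(bundle, "prediction_indices", {
    lapply(clpns, function(cl) {
      names(cl$prediction) <- c("interval1", "interval2")
      cl$prediction
    })
  })
  bundle <- runStage(bundle, "similarity", {
    lapply(1:2, function(k) {
      s <- compareDirected(clpns[[1]]$networks[[k]], clpns[[2]]$networks[[k]])
      list(interval = clpns[[1]]$networks[[k]]$interval,
           jaccard = s$jaccard, r = s$r, p = s$p,
           nIntersection = s$nIntersection, nUnion = s$nUnion)
    })
  })
  path <- writeBundle(config, bundle$stages, bundle$file)
  writePhase1Csv(config$outDir, groups, baselineNets, clpns, bundle$stages)
  invisible(list(stages = bundle$stages, file = path))
}

nctJson <- function(r, groups) {
  list(groups = groups, M = r$M, pM = r$pM, S = r$S, pS = r$pS,
       centrality = r$centrality, postHocEdges = r$postHocEdges,
       postHocCentrality = r$postHocCentrality, nPerm = r$nPerm)
}

writePhase1Csv <- function(outDir, groups, nets, clpns, stages) {
  for (g in groups) {
    write.csv(asEdgeList(nets[[g]]),
              file.path(outDir, sprintf("baseline_edges_%s.csv", g)),
              row.names = FALSE)
    write.csv(centralityTable(nets[[g]]),
              file.path(outDir, sprintf("centrality_%s.csv", g)),
              row.names = FALSE)
    for (k in 1:2) {
      write.csv(directedEdgeList(clpns[[g]]$networks[[k]]),
                file.path(outDir, sprintf("clpn_edges_%s_interval%d.csv", g, k)),
                row.names = FALSE)
      write.csv(clpns[[g]]$prediction[[k]],
                file.path(outDir, sprintf("prediction_%s_interval%d.csv", g, k)),
                row.names = FALSE)
    }
  }
  invisible(NULL)
}

#' Run the phase-II (treatment) analysis pipeline
#'
#' Network intervention analysis per wave of a two-arm panel: mixed
#' graphical model with the binary treatment node, per-node
#' predictability, bootstrap edge stability, and a summary table of
#' treatment-symptom edges (differential treatment effects). Writes
#' `phase2.json` and CSV tables to `config$outDir`.
#'
#' @param data A two-arm [panelData()]; when `NULL`, simulated from
#'   `synth` via [simulateTwoArm()].
#' @param config A [pipelineConfig()].
#' @param synth A [synthConfig()] used when `data` is `NULL`.
#' @return The report bundle, invisibly.
#' @export
runPhase2 <- function(data = NULL, config = pipelineConfig(),
                      synth = phase2Config(config$seed)) {
  if (is.null(data)) data <- simulateTwoArm(synth)$data
  stopifnot(inherits(data, "panelData"))
  if (is.null(data$arm)) stopf("phase-II pipeline needs treatment arm codes")
  bundle <- new.env()
  bundle$config <- config
  bundle$stages <- list()
  bundle$file <- "phase2.json"
  nets <- list()
  bundle <- runStage(bundle, "mgm", {
    nets <- lapply(data$waves, function(w)
      fitMGM(data, wave = w, folds = config$folds,
             seed = childSeed(config$seed, paste0("mgm", w))))
    names(nets) <- data$waves
    lapply(nets, function(nt) list(
      nodes = colnames(nt$weights),
      edges = asEdgeList(nt), n = nt$n,
      treatmentEdges = treatmentEdgeTable(nt)))
  })
  bundle <- runStage(bundle, "predictability", {
    lapply(nets, predictability)
  })
  boots <- list()
  bundle <- runStage(bundle, "bootstrap", {
    # bootstrap stability is assessed where a differential treatment
    # effect was detected
    effectWaves <- data$waves[vapply(nets, function(nt)
      nrow(treatmentEdgeTable(nt)) > 0, TRUE)]
    boots <- lapply(effectWaves, function(w)
      bootstrapMGM(data, wave = w, B = config$nBoot,
                   seed = childSeed(config$seed, paste0("mgmboot", w)),
                   folds = config$folds))
    names(boots) <- effectWaves
    lapply(boots, function(bt)
      list(B = bt$B, nFailed = bt$nFailed, edges = bt$edges))
  })
  bundle <- runStage(bundle, "treatment_edge_summary", {
    out <- list()
    for (w in names(boots)) {
      te <- treatmentEdgeTable(nets[[w]])
      if (!nrow(te)) next
      be <- boots[[w]]$edges
      key <- paste(te$item, "TX", sep = "--")
      m <- match(key, be$edge, nomatch = match(paste("TX", te$item, sep = "--"),
                                               be$edge))
      te$inclusion <- be$inclusion[m]
      te$lower <- be$lower[m]
      te$upper <- be$upper[m]
      te$wave <- w
      out[[w]] <- te
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(item = character(), weight = numeric())
  })
  path <- writeBundle(config, bundle$stages, bundle$file)
  for (w in data$waves)
    write.csv(asEdgeList(nets[[w]]),
              file.path(config$outDir, sprintf("mgm_edges_%s.csv", w)),
              row.names = FALSE)
  invisible(list(stages = bundle$stages, file = path))
}

treatmentEdgeTable <- function(net) {
  W <- net$weights
  tx <- W["TX", ]
  items <- setdiff(colnames(W), "TX")
  sel <- items[tx[items] != 0]
  data.frame(item = sel, weight = unname(tx[sel]),
             stringsAsFactors = FALSE)
}
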