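#' Default pipeline configuration
#'
#' Assembles the configuration for a full synthetic-data analysis run. The
#' defaults encode the study conditions every stage is validated against:
#' six motor regions of 20 axis vertices each, inter-effector regions and
#' the CON sharing a latent signal, injected infra-slow delays of 0.4 s
#' (inter-effector) and 0.8 s (CON) relative to the effector regions, six
#' movement conditions whose true spatial peaks sit at the region centres,
#' broad weak inter-effector responses to every movement, a planning
#' response confined to inter-effector and CON territory, and lower
#' inter-effector cortical thickness. Analysis thresholds default to the
#' standard choices (alpha = 0.05, edge threshold Z(r) > 0.2, percentile
#' sweep 80-97, top 1 percent display, smoothing sigma 2.55 axis units).
#'
#' @param seed integer root seed for the whole run.
#' @param nSubjects number of simulated subjects.
#' @param conCoupled logical; FALSE decouples the CON from the
#'   inter-effector latent signal (negative control).
#' @param noiseSd vertex-level white-noise sd.
#' @return named list understood by `runPipeline()`.
#' @export
defaultPipelineConfig <- function(seed = 1L, nSubjects = 20L,
                                  conCoupled = TRUE, noiseSd = 1) {
  list(
    seed = as.integer(seed),
    nSubjects = as.integer(nSubjects),
    layout = list(verticesPerRegion = 20L,
                  offAxis = c(CON = 40L, S1_adjacent = 40L,
                              background = 40L)),
    truth = list(
      conCoupled = conCoupled,
      globalWeight = 0.6,
      noiseSd = noiseSd,
      delays = c(foot = 0, hand = 0, mouth = 0,
                 inter_superior = 0.4, inter_middle = 0.4,
                 inter_inferior = 0.4, CON = 0.8,
                 S1_adjacent = 0, background = 0),
      peakParams = list(
        toes = c(a1 = 0.6, b1 = 10, c1 = 4),
        abdominal = c(a1 = 0.35, b1 = 30, c1 = 6, a2 = 0.25, b2 = 70,
                      c2 = 6),
        hand = c(a1 = 0.6, b1 = 50, c1 = 4),
        eyelid = c(a1 = 0.25, b1 = 30, c1 = 6, a2 = 0.35, b2 = 70,
                   c2 = 6),
        tongue = c(a1 = 0.6, b1 = 90, c1 = 4),
        swallowing = c(a1 = 0.35, b1 = 110, c1 = 6)),
      interBroadAmplitude = 0.1,
      planningAmplitude = 0.6,
      executionAmplitude = 0.6),
    rest = list(nFrames = 480L, tr = 1.1, runsPerSubject = 2L),
    task = list(tr = 2.2, runsPerSubject = 4L, blocksPerCondition = 2L),
    planningTask = list(runsPerSubject = 4L, nTrials = 12L),
    analysis = list(alpha = 0.05, maxLag = 8L, minPeak = 0.3,
                    smoothSigma = 2.55, percentiles = c(80, 97),
                    topPercent = 1, edgeThreshold = 0.2,
                    minWidth = 4,
                    fitMasks = list(
                      toes = c(ventral = 1 / 3, dorsal = 0),
                      abdominal = c(ventral = 0, dorsal = 0),
                      hand = c(ventral = 0, dorsal = 0),
                      eyelid = c(ventral = 0, dorsal = 0),
                      tongue = c(ventral = 0, dorsal = 1 / 3),
                      swallowing = c(ventral = 0, dorsal = 1 / 3))))
}

.validateConfig <- function(config) {
  need <- c("seed", "nSubjects", "layout", "truth", "rest", "task",
            "planningTask", "analysis")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("invalid pipeline config; missing field(s): ",
         paste(miss, collapse = ", "))
  if (config$nSubjects < 2L) stop("pipeline needs at least 2 subjects")
  if (config$analysis$alpha <= 0 || config$analysis$alpha >= 1)
    stop("alpha must lie in (0, 1)")
  invisible(config)
}

## Ground truth object for one pipeline config.
.configTruth <- function(config, strip) {
  tc <- config$truth
  assign <- c(foot = "foot", hand = "hand", mouth = "mouth",
              inter_superior = "scan", inter_middle = "scan",
              inter_inferior = "scan",
              CON = if (isTRUE(tc$conCoupled)) "scan" else "con",
              S1_adjacent = "s1", background = "bg")
  conds <- names(tc$peakParams)
  regs <- levels(regionLabels(strip))
  rta <- matrix(0, length(regs), length(conds) + 2L,
                dimnames = list(regs, c(conds, "planning", "execution")))
  rta[intersect(.interRegions, regs), conds] <- tc$interBroadAmplitude
  rta[intersect(.interRegions, regs), "planning"] <- tc$planningAmplitude
  if ("CON" %in% regs) rta["CON", "planning"] <- tc$planningAmplitude
  rta[intersect(.effectorRegions, regs), "execution"] <- tc$executionAmplitude
  syntheticTruth(strip,
                 networkAssignments = assign[regs],
                 globalWeight = tc$globalWeight,
                 delays = tc$delays[regs],
                 peakParams = tc$peakParams,
                 regionTaskAmplitudes = rta,
                 noiseSd = tc$noiseSd,
                 seed = config$seed)
}

#' Run the full synthetic analysis pipeline
#'
#' simulate -> connectivity -> lags -> task GLM -> somatotopy -> report.
#' For each simulated subject the pipeline generates resting, block-task,
#' event-task and structural data, then computes region-mean connectivity
#' to each network, the region time-delay matrix and its lag projection,
#' second-level activation maps, the winner-take-all map, movement
#' selectivity, the planning-versus-execution contrast, and structural
#' region comparisons; group-level tables aggregate across subjects.
#' Deterministic given the config seed.
#'
#' @param config list from `defaultPipelineConfig()`.
#' @return A \linkS4class{RunReport}.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  .validateConfig(config)
  an <- config$analysis
  stages <- character()
  strip <- generateStrip(config$layout$verticesPerRegion,
                         offAxis = config$layout$offAxis)
  truth <- .configTruth(config, strip)
  lab <- as.character(regionLabels(strip))
  onStrip <- lab %in% .motorRegions
  networks <- intersect(c("CON", "S1_adjacent", "background"), lab)
  conds <- names(truth@peakParams)
  nSub <- config$nSubjects

  fcRows <- list(); tdms <- list(); lagProj <- list()
  subjZ <- list(); subjSelect <- list(); planZ <- list()
  thickness <- list(); seedMaps <- list(); regionFC <- list()
  fcRegions <- c(list(inter = .interRegions),
                 setNames(as.list(.effectorRegions), .effectorRegions))
  fcNodes <- intersect(c(.motorRegions, .offAxisRegions), lab)

  for (s in seq_len(nSub)) {
    sSeed <- deriveSeed(config$seed, 1000L * s)
    ## resting state
    rest <- lapply(seq_len(config$rest$runsPerSubject), function(r)
      generateRestRun(strip, truth, nFrames = config$rest$nFrames,
                      tr = config$rest$tr,
                      seed = deriveSeed(sSeed, r)))
    for (net in networks) {
      fcRows[[length(fcRows) + 1L]] <- data.frame(
        subject = s,
        region = c("inter", .effectorRegions),
        network = net,
        z = c(regionMeanConnectivity(rest, lab, .interRegions, net),
              vapply(.effectorRegions, function(rr)
                regionMeanConnectivity(rest, lab, rr, net), numeric(1))))
    }
    seedMaps[[s]] <- vapply(fcRegions, function(rr)
      regionSeedMap(rest, lab, rr), numeric(length(strip)))
    regionFC[[s]] <- {
      mm <- t(vapply(fcNodes, function(rr) {
        unlist(lapply(rest, function(run)
          as.numeric(scale(colMeans(
            boldMatrix(run)[lab == rr, , drop = FALSE])))))
      }, numeric(config$rest$nFrames * config$rest$runsPerSubject)))
      fisherZ(cor(t(mm)))
    }
    tdLab <- ifelse(lab %in% c(.motorRegions, "CON"), lab, NA)
    tdm <- averageTDMatrices(lapply(rest, function(run)
      tdMatrix(run, labeling = tdLab,
               maxLag = an$maxLag, minPeak = an$minPeak,
               tr = config$rest$tr)))
    tdms[[s]] <- tdm
    lagProj[[s]] <- meanLagProjection(tdm)

    ## movement task battery
    design <- blockBattery(conds,
                           blocksPerCondition = config$task$blocksPerCondition)
    runMaps <- lapply(seq_len(config$task$runsPerSubject), function(r) {
      run <- generateTaskRun(strip, truth, design, tr = config$task$tr,
                             seed = deriveSeed(sSeed, 100L + r))
      X <- buildDesignMatrix(design, config$task$tr, ncol(run))
      fitGLM(run, X)
    })
    subj <- secondLevel(runMaps)
    z <- activationZ(subj)[, conds, drop = FALSE]
    z[onStrip, ] <- apply(z[onStrip, , drop = FALSE], 2L, smoothMap,
                          sigma = an$smoothSigma)
    subjZ[[s]] <- z
    sel <- movementSelectivity(z[onStrip, , drop = FALSE])
    labStrip <- lab[onStrip]
    subjSelect[[s]] <- c(
      inter = mean(sel[labStrip %in% .interRegions]),
      effector = mean(sel[labStrip %in% .effectorRegions]))

    ## planning / execution event task
    pdesign <- planningExecutionDesign(nTrials = config$planningTask$nTrials)
    pMaps <- lapply(seq_len(config$planningTask$runsPerSubject), function(r) {
      run <- generateTaskRun(strip, truth, pdesign, tr = config$task$tr,
                             seed = deriveSeed(sSeed, 200L + r))
      X <- buildDesignMatrix(pdesign, config$task$tr, ncol(run))
      fitGLM(run, X)
    })
    pe <- planningVsExecution(pMaps)
    planZ[[s]] <- activationZ(pe)[, 1L]

    ## structure
    thickness[[s]] <- generateStructuralMaps(strip,
                                             seed = deriveSeed(sSeed, 9L))$thickness
  }
  stages <- c(stages, simulate = "ok", connectivity = "ok", lags = "ok",
              glm = "ok")

  ## group tables
  fcTable <- do.call(rbind, fcRows)
  minDiff <- networkMinDifference(fcTable)
  per <- attr(minDiff, "perSubject")
  others <- setdiff(colnames(per), "CON")
  minDiffTests <- if ("CON" %in% colnames(per) && length(others)) {
    cmp <- lapply(setNames(others, paste0("CON_vs_", others)),
                  function(o) list(x = per[, "CON"], y = per[, o]))
    pairedTTestFDR(cmp, nTests = length(cmp), alpha = an$alpha)
  } else NULL

  lagMat <- do.call(rbind, lagProj)
  lagGroups <- colnames(lagMat)
  lagTests <- {
    cmps <- list()
    for (g in intersect(c("inter", "CON"), lagGroups))
      for (e in intersect(.effectorRegions, lagGroups))
        cmps[[paste0(g, "_vs_", e)]] <-
          list(x = lagMat[, g], y = lagMat[, e])
    pairedTTestFDR(cmps, nTests = length(cmps), alpha = an$alpha)
  }

  groupZ <- Reduce(`+`, subjZ) / length(subjZ)
  wta <- winnerTakeAll(groupZ[onStrip, , drop = FALSE],
                       topPercent = an$topPercent)
  pos <- axisPositions(strip)[onStrip]
  centroids <- vapply(conds, function(m)
    mean(pos[wtaWinner(wta) == m]), numeric(1))

  fitTable <- do.call(rbind, lapply(conds, function(m) {
    msk <- an$fitMasks[[m]]
    if (is.null(msk)) msk <- c(ventral = 0, dorsal = 0)
    prof <- axisProfile(groupZ[onStrip, m], pos,
                        excludeVentralFrac = msk[["ventral"]],
                        excludeDorsalFrac = msk[["dorsal"]])
    fits <- fitPeakModels(prof, minWidth = an$minWidth)
    cmpF <- compareModelsF(fits$onePeak, fits$twoPeaks, alpha = an$alpha)
    data.frame(movement = m,
               a1 = fits$twoPeaks@params[["a1"]],
               b1 = fits$twoPeaks@params[["b1"]],
               c1 = fits$twoPeaks@params[["c1"]],
               a2 = fits$twoPeaks@params[["a2"]],
               b2 = fits$twoPeaks@params[["b2"]],
               c2 = fits$twoPeaks@params[["c2"]],
               sse1 = fits$onePeak@sse, sse2 = fits$twoPeaks@sse,
               F = cmpF@fStat, p = cmpF@pValue,
               preferred = cmpF@preferred, flag = cmpF@flag)
  }))

  selMat <- do.call(rbind, subjSelect)
  selTest <- pairedTTestFDR(
    list(inter_vs_effector = list(x = selMat[, "inter"],
                                  y = selMat[, "effector"])),
    alpha = an$alpha)

  planMat <- do.call(rbind, planZ)   # subjects x vertices
  planRegion <- vapply(c(list(inter = .interRegions),
                         setNames(as.list(.effectorRegions),
                                  .effectorRegions)),
                       function(rr) rowMeans(planMat[, lab %in% rr,
                                                     drop = FALSE]),
                       numeric(nSub))

  thickCmp <- regionScalarCompare(thickness, lab, alpha = an$alpha)

  coact <- coactivationProfiles(groupZ, lab, exclude = NULL)

  ## group seed maps (z averaged across subjects), conservative contrast,
  ## percentile thresholding, and the region-level edge list
  groupSeed <- Reduce(`+`, seedMaps) / length(seedMaps)
  contrast <- conservativeContrast(
    groupSeed[, "inter"],
    groupSeed[, .effectorRegions, drop = FALSE])
  offStrip <- !onStrip                     # central strip masked, as the
  contrastOff <- ifelse(offStrip, contrast, NA)   # seed regions sit in it
  thresholded <- lapply(setNames(an$percentiles,
                                 paste0("p", an$percentiles)),
                        function(q) percentileThreshold(contrastOff, q))
  groupRegionFC <- Reduce(`+`, regionFC) / length(regionFC)
  diag(groupRegionFC) <- 0
  edges <- exportEdgeList(groupRegionFC, threshold = an$edgeThreshold)
  stages <- c(stages, somatotopy = "ok", report = "ok")

  recovery <- list(
    lagOrderOK = all(mean(lagMat[, "inter"]) >
                       colMeans(lagMat[, .effectorRegions])) &&
      mean(lagMat[, "CON"]) >= mean(lagMat[, "inter"]),
    wtaCentroidOrderOK = !is.unsorted(centroids[order(vapply(conds,
      function(m) {
        p <- truth@peakParams[[m]]
        if (length(p) == 6L && p[[4L]] > p[[1L]]) p[[5L]] else p[[2L]]
      }, numeric(1)))]),
    selectivityLowerFrac = mean(selMat[, "inter"] < selMat[, "effector"]),
    planningConfined =
      mean(planRegion[, "inter"]) > 1 &&
      max(colMeans(planRegion[, .effectorRegions, drop = FALSE])) < 1)

  new("RunReport", config = config,
      tables = list(networkFC = fcTable, networkMinDiff = minDiff,
                    networkMinDiffTests = minDiffTests,
                    lagProjection = lagMat, lagTests = lagTests,
                    fits = fitTable, selectivity = selMat,
                    selectivityTest = selTest,
                    planningRegionZ = planRegion,
                    thickness = thickCmp$table,
                    coactivation = coact$correlation,
                    edges = edges),
      maps = list(wta = wta, groupZ = groupZ, centroids = centroids,
                  seedMaps = groupSeed, conservativeContrast = contrast,
                  thresholdedContrast = thresholded,
                  regionFC = groupRegionFC),
      recovery = recovery,
      stages = data.frame(stage = names(stages), status = unname(stages)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "RunReport", function(object) {
  cat("RunReport:", object@config$nSubjects, "subjects\n")
  print(object@stages)
  cat("recovery:\n"); utils::str(object@recovery)
})

#' Export a thresholded edge list
#'
#' Writes the edges of a region-level Fisher-z connectivity matrix whose
#' strength exceeds a threshold (default Z(r) > 0.2), as used for
#' spring-embedded network visualization in external tools.
#'
#' @param zMatrix square symmetric region x region Fisher-z matrix.
#' @param threshold minimum z for an edge.
#' @param file optional path; if given, a TSV with columns nodeA, nodeB, z
#'   is written.
#' @return data.frame of edges (invisibly when written to file).
#' @export
exportEdgeList <- function(zMatrix, threshold = 0.2, file = NULL) {
  if (nrow(zMatrix) != ncol(zMatrix)) stop("edge export needs a square matrix")
  nm <- rownames(zMatrix) %||% paste0("n", seq_len(nrow(zMatrix)))
  idx <- which(upper.tri(zMatrix) & zMatrix > threshold, arr.ind = TRUE)
  edges <- data.frame(nodeA = nm[idx[, 1L]], nodeB = nm[idx[, 2L]],
                      z = zMatrix[idx])
  edges <- edges[order(edges$nodeA, edges$nodeB), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(file)) {
    utils::write.table(edges, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(edges))
  }
  edges
}
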