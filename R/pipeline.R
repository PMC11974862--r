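#' Default desk-scale run configuration
#'
#' A complete configuration for [runPipeline()]: phantom cohort spec,
#' model family/modality matrix, seeds, stage toggles and output root.
#' The desk preset uses a 32 x 40 x 32 grid and the fast PCA+GP family so
#' an end-to-end run finishes in about a minute on one CPU; all fields can
#' be overridden (or loaded from YAML with [readRunConfig()]).
#'
#' @param outputRoot Output directory.
#' @param seeds Integer seeds for the evaluation protocol.
#' @param families,modalities Model matrix for the evaluation stage.
#' @param stages Named logical vector toggling the eight stages.
#' @param gridShape Phantom grid.
#' @param nHealthy,nMci,nAd Cohort sizes.
#' @param seed Generator seed.
#' @return List with class `"RunConfig"`.
#' @export
runConfig <- function(outputRoot = tempfile("elastoage_run_"),
                      seeds = 1:2, families = "pca_gp", modalities = "mre",
                      stages = c(generate = TRUE, preprocess = TRUE,
                                 train = TRUE, evaluate = TRUE,
                                 saliency = TRUE, bag = TRUE,
                                 regional = TRUE, atrisk = TRUE),
                      gridShape = c(32L, 40L, 32L), nHealthy = 40L,
                      nMci = 8L, nAd = 8L, seed = 1L) {
  stopifnot(length(seeds) >= 1)
  structure(list(outputRoot = outputRoot, seeds = as.integer(seeds),
                 families = families, modalities = modalities,
                 stages = as.list(stages), gridShape = as.integer(gridShape),
                 nHealthy = as.integer(nHealthy), nMci = as.integer(nMci),
                 nAd = as.integer(nAd), seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [runConfig()].
#' @return List with class `"RunConfig"`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(runConfig)))]
  do.call(runConfig, args)
}

.fileHash <- function(paths) {
  paths <- paths[file.exists(paths)]
  unname(vapply(paths, function(p) as.character(tools::md5sum(p)),
                character(1)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — generate phantoms,
#' preprocess (properties + normalization summary), train/evaluate the
#' model matrix over seeds, occlusion saliency, whole-brain brain-age
#' gaps, regional profiles, at-risk screening — and writes a JSON manifest
#' with per-stage status, outputs and a content hash over the result
#' files. A stage failure marks downstream dependents skipped; the
#' manifest is written even on partial failure. Identical configurations
#' and seeds give identical result-file checksums.
#'
#' @param config A [runConfig()] or path to a YAML file.
#' @return The manifest (invisibly also written to
#'   `<outputRoot>/manifest.json`).
#' @export
runPipeline <- function(config = runConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  out <- config$outputRoot
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stageNames <- c("generate", "preprocess", "train", "evaluate",
                  "saliency", "bag", "regional", "atrisk")
  manifest <- list(
    package = "elastoage",
    version = as.character(utils::packageVersion("elastoage")),
    # identity of the analysis, not of where it is written
    configHash = rlang::hash(unclass(config)[setdiff(names(config),
                                                     "outputRoot")]),
    timestamp = format(Sys.time(), tz = "UTC"),
    stages = setNames(vector("list", length(stageNames)), stageNames))
  env <- new.env()
  failed <- FALSE

  runStage <- function(name, deps, fun) {
    st <- list(status = "skipped", outputs = character())
    if (!isTRUE(config$stages[[name]])) {
      st$status <- "disabled"
    } else if (failed) {
      st$status <- "skipped (upstream failure)"
    } else {
      res <- tryCatch(fun(), error = function(e) e)
      if (inherits(res, "error")) {
        st$status <- paste("failed:", conditionMessage(res))
        failed <<- TRUE
      } else {
        st$status <- "ok"
        st$outputs <- res
      }
    }
    manifest$stages[[name]] <<- st
  }

  runStage("generate", NULL, function() {
    env$atlas <- buildAtlas(config$gridShape, seed = config$seed)
    spec <- cohortSpec(nHealthy = config$nHealthy, nMci = config$nMci,
                       nAd = config$nAd, seed = config$seed)
    env$cohort <- generateCohort(spec, env$atlas)
    f <- file.path(out, "participants.tsv")
    write.table(env$cohort$participants, f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    f
  })

  runStage("preprocess", "generate", function() {
    prep <- prepareModelData(env$cohort, "mre")
    env$mreVolumes <- prep$volumes
    env$normState <- prep$state
    f <- file.path(out, "normalization_state.json")
    writeNormalizationState(prep$state, f)
    f
  })

  runStage("train", "preprocess", function() {
    # representative single fit kept for saliency; the evaluate stage
    # refits per seed
    part <- env$cohort$participants
    sp <- splitDataset(part, seed = config$seeds[1])
    trIdx <- match(sp$train, part$participant_id)
    teIdx <- match(sp$test, part$participant_id)
    tr <- prepareModelData(env$cohort, "mre", trIdx)
    te <- prepareModelData(env$cohort, "mre", teIdx, state = tr$state)
    env$model <- .fitFamily(config$families[1], tr$volumes,
                            part$age[trIdx], config$seeds[1], "mre")
    env$testVolumes <- te$volumes
    env$testAges <- part$age[teIdx]
    character()
  })

  runStage("evaluate", "train", function() {
    f <- file.path(out, "protocol_results.csv")
    tab <- runProtocol(env$cohort, config$families, config$modalities,
                       nSeeds = length(config$seeds), outFile = f)
    jsonlite::write_json(attr(tab, "summary"),
                         file.path(out, "protocol_summary.json"),
                         dataframe = "rows", digits = NA)
    c(f, file.path(out, "protocol_summary.json"))
  })

  runStage("saliency", "train", function() {
    cfg <- saliencyConfig(block = 5L, excludedSuperiorSlices = 3L,
                          positionsPerAxis = 5L,
                          nAgeBins = min(3L, length(env$testAges)))
    sal <- saliencyByAgeBin(env$model, env$testVolumes, env$testAges, cfg)
    files <- character()
    for (i in seq_along(sal$maps)) {
      f <- file.path(out, sprintf("saliency_bin%d.nii.gz", i))
      writeVolume(sal$maps[[i]], f, env$atlas@voxelSizeMm)
      files <- c(files, f)
    }
    write.table(data.frame(bin = seq_along(sal$grids),
                           t(vapply(sal$grids, range, numeric(2)))),
                file.path(out, "saliency_grid_range.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    c(files, file.path(out, "saliency_grid_range.csv"))
  })

  runStage("bag", "train", function() {
    files <- character()
    for (dis in c("MCI", "AD")) {
      if (sum(env$cohort$participants$cohort == dis) == 0) next
      bag <- cohortBag(env$cohort, dis, config$families[1], "mre",
                       seed = config$seeds[1])
      f <- file.path(out, sprintf("bag_%s.csv", dis))
      write.table(bag, f, sep = ",", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    files
  })

  runStage("regional", "bag", function() {
    files <- character()
    env$profiles <- list()
    for (dis in c("MCI", "AD")) {
      if (sum(env$cohort$participants$cohort == dis) == 0) next
      prof <- regionalProfiles(env$cohort, env$atlas, dis,
                               config$families[1], "mre",
                               seed = config$seeds[1])
      env$profiles[[dis]] <- prof
      f <- file.path(out, sprintf("regional_profiles_%s.csv", dis))
      write.table(prof, f, sep = ",", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    files
  })

  runStage("atrisk", "regional", function() {
    files <- character()
    for (dis in names(env$profiles)) {
      prof <- env$profiles[[dis]]
      ref <- cohortProfile(prof, dis)
      ctrl <- prof[prof$cohort == "control", , drop = FALSE]
      fl <- flagAtRisk(ctrl, ref)
      f <- file.path(out, sprintf("at_risk_%s.csv", dis))
      write.table(fl, f, sep = ",", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    files
  })

  allOut <- unlist(lapply(manifest$stages, `[[`, "outputs"))
  # content hash over the text results; volume containers carry
  # compression metadata (timestamps) and are excluded
  textOut <- allOut[grepl("\\.(csv|tsv|json)$", allOut)]
  manifest$resultsHash <- rlang::hash(.fileHash(textOut))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
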