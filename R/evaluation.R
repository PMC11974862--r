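#' Deterministic 80:20 split of the healthy cohort
#'
#' Only healthy subjects are eligible; disease cohorts are never used for
#' model fitting or testing of the normative models.
#'
#' @param participants Data frame with columns `participant_id` and
#'   `cohort`.
#' @param trainFraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return List with `train` and `test` participant-id vectors.
#' @export
splitDataset <- function(participants, trainFraction = 0.8, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  ids <- participants$participant_id[participants$cohort == "healthy"]
  n <- length(ids)
  if (n < 5) stop("need at least 5 healthy subjects to split")
  set.seed(seed)
  nTrain <- round(trainFraction * n)
  tr <- sample(ids, nTrain)
  list(train = sort(tr), test = sort(setdiff(ids, tr)))
}

#' Mean and median absolute prediction error
#'
#' Both expansions of "MAE" are always computed: the mean absolute error
#' and the median absolute error of predicted vs chronological age.
#'
#' @param predictions,ages Equal-length numeric vectors.
#' @return Named vector c(mean_abs, median_abs), years.
#' @export
absoluteErrorSummary <- function(predictions, ages) {
  if (length(predictions) == 0 || length(predictions) != length(ages))
    stop("predictions and ages must be non-empty and of equal length")
  ae <- abs(predictions - ages)
  c(mean_abs = mean(ae), median_abs = median(ae))
}

# fit one (family, modality) model on prepared volumes; desk-scale
# configurations throughout.
.fitFamily <- function(family, trainVol, agesTrain, seed, modality,
                       epochs = 30L) {
  if (family == "pca_gp") {
    k <- min(10L, nSubjects(trainVol) - 1L)
    fitPcaGp(trainVol, agesTrain, k = k,
             tc = trainConfig(epochs = 50L, learningRate = 0.1,
                              noiseSd = 0.02, seed = seed),
             modality = modality)
  } else if (family == "supervised_cnn") {
    fitSupervisedCnn(trainVol, agesTrain,
                     ec = deskEncoderConfig(length(trainVol@channels)),
                     tc = deskTrainConfig(epochs = epochs, seed = seed),
                     modality = modality)
  } else if (family == "ssl_contrastive") {
    pre <- modalityPreset("ssl_contrastive",
                          if (modality %in% c("mre", "stiffness", "damping",
                                              "anatomical")) modality
                          else "mre")
    fitSsl(trainVol, agesTrain,
           ec = deskEncoderConfig(length(trainVol@channels)),
           tc = deskTrainConfig(epochs = epochs, seed = seed),
           schedule = neighbourhoodSchedule(step = pre$step,
                                            endCount = min(pre$endCount, 8L),
                                            metric = pre$metric),
           modality = modality)
  } else if (family == "null") {
    agesTrain                      # handled specially in predict step
  } else stop(sprintf("unknown family '%s'", family))
}

#' Multi-seed evaluation protocol over model families and modalities
#'
#' For each (family, modality, seed): a fresh 80:20 split of the healthy
#' cohort, normalization state fitted on the training split only, a fresh
#' fit, and test-set mean/median absolute errors. The family `"null"` is
#' the baseline that predicts the training mean age. Single fit failures
#' are recorded and the protocol continues.
#'
#' @param cohort Result of [generateCohort()].
#' @param families Character vector of model families ("pca_gp",
#'   "supervised_cnn", "ssl_contrastive", "null").
#' @param modalities Character vector of modalities.
#' @param nSeeds Number of random seeds (default 10).
#' @param normMode "dataset" or "image" normalization for the mechanical
#'   channels (the image-level variant is a config switch, not separate
#'   code).
#' @param epochs Desk-scale CNN/SSL epochs.
#' @param outFile Optional CSV path for the per-seed results table.
#' @return Data frame with one row per (family, modality, seed) plus
#'   attribute `"summary"` (across-seed mean and sd per cell).
#' @export
runProtocol <- function(cohort, families = c("pca_gp"),
                        modalities = c("mre"), nSeeds = 10L,
                        normMode = "dataset", epochs = 30L,
                        outFile = NULL) {
  part <- cohort$participants
  rows <- list()
  for (family in families) for (modality in modalities) {
    for (seed in seq_len(nSeeds)) {
      row <- data.frame(family = family, modality = modality, seed = seed,
                        mae_mean = NA_real_, mae_median = NA_real_,
                        status = "ok", stringsAsFactors = FALSE)
      res <- tryCatch({
        sp <- splitDataset(part, seed = seed)
        trIdx <- match(sp$train, part$participant_id)
        teIdx <- match(sp$test, part$participant_id)
        tr <- prepareModelData(cohort, modality, trIdx, normMode)
        te <- prepareModelData(cohort, modality, teIdx, normMode,
                               state = tr$state)
        agesTr <- part$age[trIdx]
        agesTe <- part$age[teIdx]
        if (family == "null") {
          pred <- rep(mean(agesTr), length(teIdx))
        } else {
          mdl <- .fitFamily(family, tr$volumes, agesTr, seed, modality,
                            epochs)
          pred <- predictAge(mdl, te$volumes)
        }
        absoluteErrorSummary(pred, agesTe)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$status <- conditionMessage(res)
      } else {
        row$mae_mean <- res[["mean_abs"]]
        row$mae_median <- res[["median_abs"]]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab[c("family", "modality")],
                                      drop = TRUE), function(d) {
    data.frame(family = d$family[1], modality = d$modality[1],
               n_seeds = sum(d$status == "ok"),
               mae_mean = mean(d$mae_mean, na.rm = TRUE),
               mae_mean_sd = sd(d$mae_mean, na.rm = TRUE),
               mae_median = mean(d$mae_median, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  attr(tab, "summary") <- summ
  if (!is.null(outFile))
    write.table(tab, outFile, sep = ",", quote = FALSE, row.names = FALSE)
  tab
}
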