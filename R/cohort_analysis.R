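#' Theil-Sen bias model of predicted vs chronological age
#'
#' Brain-age predictions regress toward the training mean; the standard
#' correction fits predicted age against chronological age on a held-out
#' control cohort and removes that line. The fit is the Theil-Sen
#' estimator: slope = median of all pairwise slopes over distinct-age
#' pairs, intercept = median(y - slope * x) — robust to outlying
#' predictions.
#'
#' @param controlPredictions Predicted ages of the control cohort.
#' @param controlAges Their chronological ages (>= 3 subjects, >= 2
#'   distinct ages).
#' @return A [BiasModel-class].
#' @export
fitBias <- function(controlPredictions, controlAges) {
  n <- length(controlAges)
  stopifnot(length(controlPredictions) == n)
  if (n < 3) stop("need at least 3 control subjects")
  if (length(unique(controlAges)) < 2) stop("all control ages are equal")
  pr <- combn(n, 2)
  dx <- controlAges[pr[2, ]] - controlAges[pr[1, ]]
  dy <- controlPredictions[pr[2, ]] - controlPredictions[pr[1, ]]
  keep <- dx != 0
  slope <- median(dy[keep] / dx[keep])
  intercept <- median(controlPredictions - slope * controlAges)
  new("BiasModel", slope = slope, intercept = intercept,
      nControl = as.integer(n))
}

#' Bias-corrected brain-age gaps
#'
#' BAG_i = prediction_i - (intercept + slope * age_i); the corrected
#' predicted age is age_i + BAG_i, so BAG equals corrected predicted age
#' minus chronological age. For controls drawn from the bias-fitting
#' cohort, BAGs centre on zero.
#'
#' @param predictions Raw model predictions (years).
#' @param ages Chronological ages.
#' @param bias A fitted [BiasModel-class].
#' @param ids Optional subject ids.
#' @param cohort Optional cohort labels.
#' @return Data frame with columns id, age, prediction, corrected, bag,
#'   cohort.
#' @export
computeBag <- function(predictions, ages, bias, ids = NULL, cohort = NULL) {
  stopifnot(is(bias, "BiasModel"), length(predictions) == length(ages))
  expected <- bias@intercept + bias@slope * ages
  bag <- predictions - expected
  data.frame(
    id = if (is.null(ids)) sprintf("s%03d", seq_along(ages)) else ids,
    age = ages, prediction = predictions, corrected = ages + bag,
    bag = bag,
    cohort = if (is.null(cohort)) NA_character_ else cohort,
    stringsAsFactors = FALSE)
}

# resolve the leave-cohort-out index sets from a participants table
.cohortIndices <- function(participants, diseaseLabel) {
  healthy <- participants$cohort == "healthy"
  ctrl <- healthy & participants$control_for == diseaseLabel
  if (!any(ctrl))
    stop(sprintf("no matched controls flagged for cohort '%s'", diseaseLabel))
  disease <- participants$cohort == diseaseLabel
  if (!any(disease))
    stop(sprintf("no subjects in cohort '%s'", diseaseLabel))
  list(train = which(healthy & !ctrl), control = which(ctrl),
       disease = which(disease))
}

#' Leave-cohort-out refit for brain-age-gap analysis
#'
#' Retrains a model using only healthy subjects while excluding the
#' matched-control subset of the given disease cohort; the excluded
#' controls become the bias-fitting cohort and the disease cohort is never
#' seen in training.
#'
#' @param cohort Result of [generateCohort()] (participants must carry the
#'   `control_for` column).
#' @param diseaseLabel "MCI" or "AD".
#' @param family Model family (see [runProtocol()] families).
#' @param modality Input modality.
#' @param seed Training seed.
#' @param normMode Normalization mode for mechanical channels.
#' @param epochs Desk-scale epochs for the CNN/SSL families.
#' @param regionMask Optional logical 3D array restricting the analysis to
#'   one region (all other voxels zeroed).
#' @return List with the fitted `model`, `state`, index sets and the
#'   control/disease predictions.
#' @export
leaveCohortOutRefit <- function(cohort, diseaseLabel, family = "pca_gp",
                                modality = "mre", seed = 1L,
                                normMode = "dataset", epochs = 30L,
                                regionMask = NULL) {
  part <- cohort$participants
  idx <- .cohortIndices(part, diseaseLabel)
  maskVol <- function(prep) {
    if (is.null(regionMask)) return(prep)
    v <- prep$volumes
    keep <- array(rep(as.numeric(regionMask), each = length(v@channels)),
                  c(length(v@channels), dim(regionMask)))
    v@data <- lapply(v@data, function(x) x * keep)
    prep$volumes <- v
    prep
  }
  tr <- maskVol(prepareModelData(cohort, modality, idx$train, normMode))
  ct <- maskVol(prepareModelData(cohort, modality, idx$control, normMode,
                                 state = tr$state))
  ds <- maskVol(prepareModelData(cohort, modality, idx$disease, normMode,
                                 state = tr$state))
  model <- .fitFamily(family, tr$volumes, part$age[idx$train], seed,
                      modality, epochs)
  predC <- if (family == "null") rep(mean(part$age[idx$train]),
                                     length(idx$control))
           else predictAge(model, ct$volumes)
  predD <- if (family == "null") rep(mean(part$age[idx$train]),
                                     length(idx$disease))
           else predictAge(model, ds$volumes)
  list(model = model, state = tr$state, indices = idx,
       controlPredictions = predC, diseasePredictions = predD)
}

#' Whole-brain brain-age gaps for a disease cohort and its controls
#'
#' Convenience pipeline: leave-cohort-out refit, Theil-Sen bias fit on the
#' controls, BAGs for controls and patients.
#'
#' @inheritParams leaveCohortOutRefit
#' @return Data frame of BAG records for control and disease subjects.
#' @export
cohortBag <- function(cohort, diseaseLabel, family = "pca_gp",
                      modality = "mre", seed = 1L, normMode = "dataset",
                      epochs = 30L) {
  part <- cohort$participants
  fit <- leaveCohortOutRefit(cohort, diseaseLabel, family, modality, seed,
                             normMode, epochs)
  idx <- fit$indices
  bias <- fitBias(fit$controlPredictions, part$age[idx$control])
  rbind(
    computeBag(fit$controlPredictions, part$age[idx$control], bias,
               part$participant_id[idx$control], rep("control",
                                                     length(idx$control))),
    computeBag(fit$diseasePredictions, part$age[idx$disease], bias,
               part$participant_id[idx$disease],
               part$cohort[idx$disease]))
}

#' Regional refit and per-subject brain-age-gap profiles
#'
#' For each of the 12 atlas regions, volumes are masked to that region
#' (all other voxels set to 0), a region-specific model is fitted with the
#' same leave-cohort-out protocol, the Theil-Sen correction is fitted on
#' the matched controls, and BAGs are computed for the control and disease
#' subjects. The result is one profile vector per subject over the fixed
#' region order of [regionNames()]. Regions with no in-mask voxels are
#' skipped (profile entries NA) and recorded in the `skipped` attribute.
#'
#' @inheritParams leaveCohortOutRefit
#' @param atlas The [PhantomAtlas-class] the cohort was generated from.
#' @return Data frame: id, cohort, then one BAG column per region (fixed
#'   order).
#' @export
regionalProfiles <- function(cohort, atlas, diseaseLabel,
                             family = "pca_gp", modality = "mre",
                             seed = 1L, normMode = "dataset",
                             epochs = 30L) {
  part <- cohort$participants
  idx <- .cohortIndices(part, diseaseLabel)
  subjects <- c(idx$control, idx$disease)
  prof <- matrix(NA_real_, length(subjects), length(regionNames()),
                 dimnames = list(part$participant_id[subjects],
                                 regionNames()))
  skipped <- character()
  cover <- atlas@labels > 0
  for (nm in regionNames()) {
    rmask <- atlas@labels == atlas@regionTable[nm] & cover
    if (!any(rmask)) {
      skipped <- c(skipped, nm)
      next
    }
    fit <- leaveCohortOutRefit(cohort, diseaseLabel, family, modality,
                               seed, normMode, epochs, regionMask = rmask)
    bias <- fitBias(fit$controlPredictions, part$age[idx$control])
    bagC <- computeBag(fit$controlPredictions, part$age[idx$control], bias)
    bagD <- computeBag(fit$diseasePredictions, part$age[idx$disease], bias)
    prof[, nm] <- c(bagC$bag, bagD$bag)
  }
  out <- data.frame(id = part$participant_id[subjects],
                    cohort = ifelse(seq_along(subjects) <=
                                      length(idx$control),
                                    "control", diseaseLabel),
                    prof, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Mean regional profile of a cohort
#'
#' @param profiles Data frame from [regionalProfiles()].
#' @param cohort Cohort label to average over.
#' @return Named numeric vector over the fixed region order.
#' @export
cohortProfile <- function(profiles, cohort) {
  sel <- profiles$cohort == cohort
  if (!any(sel)) stop(sprintf("no profiles in cohort '%s'", cohort))
  colMeans(as.matrix(profiles[sel, regionNames(), drop = FALSE]),
           na.rm = TRUE)
}

#' Flag healthy subjects whose profiles resemble a disease cohort
#'
#' Similarity is the Pearson correlation between an individual's regional
#' BAG profile and the cohort's mean profile; subjects at or above the
#' threshold are flagged, sorted by descending similarity. Profiles with
#' zero variance have undefined correlation and are excluded with a
#' warning.
#'
#' @param healthyProfiles Data frame of individual profiles (columns as in
#'   [regionalProfiles()]).
#' @param referenceProfile Cohort mean profile ([cohortProfile()]).
#' @param threshold Similarity threshold (default 0.7).
#' @return Data frame id, similarity, flagged, sorted descending.
#' @export
flagAtRisk <- function(healthyProfiles, referenceProfile, threshold = 0.7) {
  regs <- names(referenceProfile)
  m <- as.matrix(healthyProfiles[, regs, drop = FALSE])
  sims <- apply(m, 1, function(x) {
    if (sd(x, na.rm = TRUE) == 0) return(NA_real_)
    cor(x, referenceProfile, use = "complete.obs")
  })
  if (any(is.na(sims)))
    warning("excluded subjects with zero-variance profiles")
  out <- data.frame(id = healthyProfiles$id, similarity = sims,
                    flagged = !is.na(sims) & sims >= threshold,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$similarity), ]
  out[order(out$similarity, decreasing = TRUE), ]
}

#' Normality-gated two-group comparison
#'
#' Both groups are tested for normality with the Shapiro-Wilk test. If
#' both pass (p > 0.05) a parametric t-test is used (paired or
#' independent); otherwise the matching non-parametric alternative
#' (Wilcoxon signed-rank for paired data, Mann-Whitney U otherwise).
#'
#' @param valuesA,valuesB Numeric vectors, >= 3 values each; equal lengths
#'   when paired.
#' @param paired Paired comparison?
#' @return A [StatReport-class].
#' @export
compareGroups <- function(valuesA, valuesB, paired = FALSE) {
  stopifnot(length(valuesA) >= 3, length(valuesB) >= 3)
  if (paired && length(valuesA) != length(valuesB))
    stop("paired comparison requires equal lengths")
  pa <- stats::shapiro.test(valuesA)$p.value
  pb <- stats::shapiro.test(valuesB)$p.value
  normal <- pa > 0.05 && pb > 0.05
  if (normal) {
    tt <- stats::t.test(valuesA, valuesB, paired = paired)
    test <- if (paired) "paired t-test" else "independent t-test"
  } else {
    tt <- stats::wilcox.test(valuesA, valuesB, paired = paired,
                             exact = FALSE)
    test <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U"
  }
  new("StatReport", normalityP = c(a = pa, b = pb), test = test,
      statistic = unname(tt$statistic), p = tt$p.value, paired = paired)
}
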