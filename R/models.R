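#' Assemble model-ready volumes for one modality from a phantom cohort
#'
#' Computes stiffness/damping maps from each subject's modulus pair,
#' stacks the requested channels — `"mre"` (stiffness + damping),
#' `"stiffness"`, `"damping"` or `"anatomical"` — and masks the anatomical
#' channel to the mechanical coverage. No normalization is applied here;
#' see [normalizeVolumes()].
#'
#' @param cohort Result of [generateCohort()].
#' @param modality One of "mre", "stiffness", "damping", "anatomical".
#' @param subset Optional integer/logical index of subjects to include.
#' @return A [BrainVolumes-class].
#' @export
cohortVolumes <- function(cohort,
                          modality = c("mre", "stiffness", "damping",
                                       "anatomical"),
                          subset = NULL) {
  modality <- match.arg(modality)
  subj <- cohort$subjects
  if (!is.null(subset)) subj <- subj[subset]
  mask <- subj[[1]]$modulus@mask
  chans <- switch(modality,
                  mre = c("mu", "xi"), stiffness = "mu", damping = "xi",
                  anatomical = "anat")
  dat <- lapply(subj, function(s) {
    if (modality == "anatomical") {
      a <- applyCoverageMask(s$anatomical, mask)
      array(a, c(1L, dim(mask)))
    } else {
      pr <- computeProperties(s$modulus)
      v <- array(0, c(length(chans), dim(mask)))
      i <- 1L
      if ("mu" %in% chans) { v[i, , , ] <- pr@mu; i <- i + 1L }
      if ("xi" %in% chans) v[i, , , ] <- pr@xi
      v
    }
  })
  new("BrainVolumes", data = dat, mask = mask, channels = chans)
}

#' Prepare normalized model inputs for a cohort subset
#'
#' Convenience wrapper: builds the modality channels with
#' [cohortVolumes()] and normalizes them. Mechanical channels use the
#' requested mode (dataset-level by default, so global aging trends
#' survive); the anatomical channel is always normalized per image, after
#' coverage masking. When `state` is supplied (dataset mode) it is applied
#' without refitting, which is how held-out and disease subjects must be
#' prepared.
#'
#' @inheritParams cohortVolumes
#' @param normMode "dataset" or "image" for the mechanical channels.
#' @param state Optional [NormalizationState-class] fitted on the training
#'   subjects.
#' @return List with `volumes` and `state`.
#' @export
prepareModelData <- function(cohort, modality = "mre", subset = NULL,
                             normMode = c("dataset", "image"),
                             state = NULL) {
  normMode <- match.arg(normMode)
  v <- cohortVolumes(cohort, modality, subset)
  if (modality == "anatomical") {
    normalizeVolumes(v, "image")
  } else if (normMode == "image") {
    normalizeVolumes(v, "image")
  } else {
    normalizeVolumes(v, "dataset", state = state)
  }
}

#' Flatten a BrainVolumes batch to a subjects x voxels matrix
#'
#' In-mask voxels of every channel are concatenated per subject (channels
#' side by side), the input format of the PCA + Gaussian-process family.
#'
#' @param volumes A [BrainVolumes-class].
#' @return Numeric matrix, one row per subject.
#' @export
volumesToMatrix <- function(volumes) {
  idx <- which(volumes@mask)
  C <- length(volumes@channels)
  t(vapply(volumes@data, function(v) {
    unlist(lapply(seq_len(C), function(ch) v[ch, , , ][idx]),
           use.names = FALSE)
  }, numeric(C * length(idx))))
}

# log marginal likelihood and gradients for a linear-kernel GP
# K = sf2 * S S^T + sn2 * I on centered targets.
.gpObjective <- function(scores, yc, logSf2, logSn2) {
  n <- length(yc)
  K0 <- tcrossprod(scores)
  K <- exp(logSf2) * K0 + exp(logSn2) * diag(n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  Kinv <- chol2inv(ch)
  ll <- -0.5 * sum(yc * alpha) - sum(log(diag(ch))) - 0.5 * n * log(2 * pi)
  A <- tcrossprod(alpha) - Kinv
  # d ll / d log sf2 and d log sn2 (chain rule through exp)
  gSf2 <- 0.5 * sum(A * K0) * exp(logSf2)
  gSn2 <- 0.5 * sum(diag(A)) * exp(logSn2)
  list(ll = ll, grad = c(gSf2, gSn2))
}

#' Fit the PCA + Gaussian-process brain-age model
#'
#' Flattened masked voxels (channels concatenated) are reduced to `k`
#' principal components; an exact GP regression with a linear kernel
#' \eqn{K = \sigma_f^2 S S^\top + \sigma_n^2 I} is fitted on the scores.
#' The kernel variance and noise variance are optimized by `epochs` Adam
#' steps on the log marginal likelihood, with fresh Gaussian augmentation
#' noise applied to the inputs at every step (projected through the
#' orthonormal PCA basis, which is distributionally identical to adding it
#' to the voxels).
#'
#' @param trainVolumes Normalized training [BrainVolumes-class].
#' @param ages Training ages (years).
#' @param k Number of principal components, <= min(n, p).
#' @param tc A [trainConfig()]; `epochs`, `learningRate`, `noiseSd` and
#'   `seed` are used.
#' @param modality Tag stored on the model.
#' @return A [PcaGpModel-class].
#' @export
fitPcaGp <- function(trainVolumes, ages, k = 10L,
                     tc = trainConfig(learningRate = 0.1, noiseSd = 0.02),
                     modality = "mre") {
  X <- volumesToMatrix(trainVolumes)
  n <- nrow(X); p <- ncol(X)
  if (k > min(n, p))
    stop(sprintf("k too large; admissible maximum is %d", min(n, p)))
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = 0, nv = k)
  rotation <- sv$v[, seq_len(k), drop = FALSE]
  scores <- Xc %*% rotation
  yMean <- mean(ages)
  yc <- ages - yMean

  set.seed(tc$seed)
  vy <- max(var(yc), 1e-8)
  theta <- c(log(vy / max(mean(rowSums(scores^2)), 1e-12)), log(0.1 * vy))
  m <- c(0, 0); v <- c(0, 0)
  for (step in seq_len(tc$epochs)) {
    sAug <- scores + matrix(rnorm(length(scores), 0, tc$noiseSd),
                            nrow = n)
    ob <- .gpObjective(sAug, yc, theta[1], theta[2])
    if (is.null(ob)) break
    g <- -ob$grad                 # minimize negative log likelihood
    m <- 0.9 * m + 0.1 * g
    v <- 0.999 * v + 0.001 * g^2
    theta <- theta - tc$learningRate *
      (m / (1 - 0.9^step)) / (sqrt(v / (1 - 0.999^step)) + 1e-8)
  }
  K <- exp(theta[1]) * tcrossprod(scores) + exp(theta[2]) * diag(n)
  alpha <- solve(K, yc)
  new("PcaGpModel", family = "pca_gp", modality = modality,
      channels = trainVolumes@channels, normState = NULL,
      seed = tc$seed, center = center, rotation = rotation,
      trainScores = scores, yMean = yMean, yCentered = yc,
      logSf2 = theta[1], logSn2 = theta[2], alphaVec = as.numeric(alpha))
}

#' Fit the supervised 3D CNN brain-age model
#'
#' A residual convolutional encoder (see [encoderConfig()]) with a linear
#' latent head and a two-layer regression MLP (embedding -> 64 -> 1, ReLU
#' throughout) trained end-to-end with the L1 loss and Adam, stepwise
#' learning-rate decay, in-mask Gaussian input augmentation, dropout on
#' the pooled features and weight decay. Targets are centered on the
#' training mean age; the final head layer starts at zero so the model
#' begins at the mean-age prediction and learns deviations.
#'
#' @param trainVolumes Normalized training [BrainVolumes-class].
#' @param ages Training ages.
#' @param ec An [encoderConfig()]; `inputChannels` must match the volumes.
#' @param tc A [trainConfig()].
#' @param modality Tag stored on the model.
#' @return A [CnnModel-class].
#' @export
fitSupervisedCnn <- function(trainVolumes, ages, ec, tc, modality = "mre") {
  .checkShape(dim(trainVolumes@mask))
  if (length(trainVolumes@channels) != ec$inputChannels)
    stop("encoder inputChannels does not match the volume channels")
  n <- nSubjects(trainVolumes)
  maskIdx <- which(trainVolumes@mask)
  yMean <- mean(ages)
  yc <- ages - yMean

  set.seed(tc$seed)
  w <- .nnInit(ec, head = TRUE)
  st <- .adamInit(w)
  keep <- 1 - ec$dropout
  for (epoch in seq_len(tc$epochs) - 1L) {
    lr <- .lrAt(tc, epoch)
    perm <- sample.int(n)
    starts <- seq(1, n, by = tc$batchSize)
    for (b0 in starts) {
      bIdx <- perm[b0:min(b0 + tc$batchSize - 1L, n)]
      nb <- length(bIdx)
      g <- .zeroLike(w)
      for (i in bIdx) {
        x <- .augmentNoise(trainVolumes@data[[i]], maskIdx, tc$noiseSd)
        fw <- .trunkForward(x, w)
        feat <- fw$feat
        dmask <- if (ec$dropout > 0)
          (runif(length(feat)) > ec$dropout) / keep else rep(1, length(feat))
        fd <- feat * dmask
        z <- drop(w$latent$W %*% fd) + w$latent$b
        h <- pmax(z, 0)
        mm <- drop(w$head$W1 %*% h) + w$head$b1
        mr <- pmax(mm, 0)
        pred <- drop(w$head$W2 %*% mr) + w$head$b2
        dpred <- sign(pred - yc[i]) / nb
        # head backward
        g$head$W2 <- g$head$W2 + dpred * matrix(mr, 1)
        g$head$b2 <- g$head$b2 + dpred
        dm <- drop(t(w$head$W2)) * dpred * (mm > 0)
        g$head$W1 <- g$head$W1 + outer(dm, h)
        g$head$b1 <- g$head$b1 + dm
        dh <- drop(crossprod(w$head$W1, dm)) * (z > 0)
        g$latent$W <- g$latent$W + outer(dh, fd)
        g$latent$b <- g$latent$b + dh
        dfeat <- drop(crossprod(w$latent$W, dh)) * dmask
        gt <- .trunkBackward(dfeat, fw$cache, w)
        g$stem <- .treeAdd(g$stem, gt$stem)
        g$stages <- .treeAdd(g$stages, gt$stages)
      }
      up <- .adamStep(w, g, st, lr, tc$weightDecay)
      w <- up$w; st <- up$state
    }
  }
  new("CnnModel", family = "supervised_cnn", modality = modality,
      channels = trainVolumes@channels, normState = NULL, seed = tc$seed,
      weights = w, encoderConfig = unclass(ec), trainConfig = unclass(tc),
      yMean = yMean)
}

# Eval-mode embedding of one volume: unit-norm latent vector.
.sslEmbedOne <- function(x, w) {
  fw <- .trunkForward(x, w)
  z <- drop(w$latent$W %*% fw$feat) + w$latent$b
  nz <- sqrt(sum(z^2)) + 1e-12
  list(e = z / nz, z = z, nz = nz, cache = fw$cache, feat = fw$feat)
}

#' Fit the self-supervised contrastive brain-age model
#'
#' The same residual encoder is trained with the adaptive-neighbourhood
#' contrastive regression loss ([lossAdaptive()]): embeddings are
#' L2-normalized, per-batch neighbour sets are selected from the current
#' embeddings under the schedule's metric, and the learning rate decays
#' stepwise. After training the encoder is frozen and a ridge regression
#' readout (intercept plus L2-penalized coefficients, strength
#' `ridgeAlpha`) is fitted on the training embeddings to predict age.
#'
#' @inheritParams fitSupervisedCnn
#' @param schedule A [neighbourhoodSchedule()]; `endCount` must be smaller
#'   than the batch size.
#' @param sigma Gaussian age-kernel bandwidth in years (default 2).
#' @param ridgeAlpha Ridge regularization strength (default 1).
#' @return An [SslModel-class].
#' @export
fitSsl <- function(trainVolumes, ages, ec, tc,
                   schedule = neighbourhoodSchedule(), sigma = 2,
                   ridgeAlpha = 1, modality = "mre") {
  .checkShape(dim(trainVolumes@mask))
  if (length(trainVolumes@channels) != ec$inputChannels)
    stop("encoder inputChannels does not match the volume channels")
  if (schedule$endCount >= tc$batchSize)
    stop("schedule endCount must be smaller than the batch size")
  n <- nSubjects(trainVolumes)
  maskIdx <- which(trainVolumes@mask)

  set.seed(tc$seed)
  w <- .nnInit(ec, head = FALSE)
  st <- .adamInit(w)
  keep <- 1 - ec$dropout
  for (epoch in seq_len(tc$epochs) - 1L) {
    lr <- .lrAt(tc, epoch)
    perm <- sample.int(n)
    starts <- seq(1, n, by = tc$batchSize)
    # fold a tail batch of < 3 samples into the previous one
    if (length(starts) > 1 && n - starts[length(starts)] + 1L < 3L)
      starts <- starts[-length(starts)]
    for (si in seq_along(starts)) {
      b0 <- starts[si]
      b1 <- if (si < length(starts)) starts[si + 1] - 1L else n
      bIdx <- perm[b0:b1]
      nb <- length(bIdx)
      fwd <- vector("list", nb)
      E <- matrix(0, nb, ec$embeddingDim)
      drops <- vector("list", nb)
      for (j in seq_len(nb)) {
        x <- .augmentNoise(trainVolumes@data[[bIdx[j]]], maskIdx, tc$noiseSd)
        fw <- .trunkForward(x, w)
        drop_j <- if (ec$dropout > 0)
          (runif(length(fw$feat)) > ec$dropout) / keep
          else rep(1, length(fw$feat))
        fd <- fw$feat * drop_j
        z <- drop(w$latent$W %*% fd) + w$latent$b
        nz <- sqrt(sum(z^2)) + 1e-12
        E[j, ] <- z / nz
        fwd[[j]] <- list(cache = fw$cache, fd = fd, z = z, nz = nz)
        drops[[j]] <- drop_j
      }
      nn <- selectNeighbours(E, epoch, schedule)
      batch <- new("EmbeddingBatch", features = E, ages = ages[bIdx])
      lg <- lossAdaptive(batch, sigma, nn, grad = TRUE)
      gE <- lg$grad / nb
      g <- .zeroLike(w)
      for (j in seq_len(nb)) {
        e <- E[j, ]
        gz <- (gE[j, ] - sum(gE[j, ] * e) * e) / fwd[[j]]$nz
        g$latent$W <- g$latent$W + outer(gz, fwd[[j]]$fd)
        g$latent$b <- g$latent$b + gz
        dfeat <- drop(crossprod(w$latent$W, gz)) * drops[[j]]
        gt <- .trunkBackward(dfeat, fwd[[j]]$cache, w)
        g$stem <- .treeAdd(g$stem, gt$stem)
        g$stages <- .treeAdd(g$stages, gt$stages)
      }
      up <- .adamStep(w, g, st, lr, tc$weightDecay)
      w <- up$w; st <- up$state
    }
  }
  # frozen-encoder embeddings and closed-form ridge readout
  Z <- t(vapply(trainVolumes@data,
                function(x) .sslEmbedOne(x, w)$e,
                numeric(ec$embeddingDim)))
  zMean <- colMeans(Z)
  Zc <- sweep(Z, 2, zMean)
  yMean <- mean(ages)
  beta <- solve(crossprod(Zc) + ridgeAlpha * diag(ncol(Zc)),
                crossprod(Zc, ages - yMean))
  intercept <- yMean - sum(zMean * beta)
  new("SslModel", family = "ssl_contrastive", modality = modality,
      channels = trainVolumes@channels, normState = NULL, seed = tc$seed,
      weights = w, encoderConfig = unclass(ec), trainConfig = unclass(tc),
      schedule = unclass(schedule), sigma = sigma,
      ridgeCoef = c(intercept, as.numeric(beta)), ridgeAlpha = ridgeAlpha)
}

#' Embed volumes with a fitted self-supervised model
#'
#' @param model An [SslModel-class].
#' @param volumes A [BrainVolumes-class] prepared like the training data.
#' @return Matrix of unit-norm embeddings, one row per subject.
#' @export
getEmbeddings <- function(model, volumes) {
  stopifnot(is(model, "SslModel"))
  t(vapply(volumes@data, function(x) .sslEmbedOne(x, model@weights)$e,
           numeric(model@encoderConfig$embeddingDim)))
}

#' Predict ages from a fitted brain-age model
#'
#' Deterministic inference (augmentation and dropout off). Volumes must be
#' prepared with the same channels and normalization as the training data.
#' A plain function can also be used as a model (it receives the
#' [BrainVolumes-class] and returns ages), which is convenient for
#' testing model-dependent procedures such as occlusion saliency.
#'
#' @param model A fitted model or a function.
#' @param volumes A [BrainVolumes-class].
#' @return Numeric vector of predicted ages.
#' @export
setGeneric("predictAge", function(model, volumes) {
  standardGeneric("predictAge")
})

.checkChannels <- function(model, volumes) {
  if (!identical(model@channels, volumes@channels))
    stop(sprintf("channel mismatch: model fitted on [%s], volumes have [%s]",
                 paste(model@channels, collapse = ","),
                 paste(volumes@channels, collapse = ",")))
}

#' @rdname predictAge
setMethod("predictAge", signature(model = "PcaGpModel"),
  function(model, volumes) {
    .checkChannels(model, volumes)
    X <- volumesToMatrix(volumes)
    S <- sweep(X, 2, model@center) %*% model@rotation
    Ks <- exp(model@logSf2) * tcrossprod(S, model@trainScores)
    as.numeric(model@yMean + Ks %*% model@alphaVec)
  })

#' @rdname predictAge
setMethod("predictAge", signature(model = "CnnModel"),
  function(model, volumes) {
    .checkChannels(model, volumes)
    w <- model@weights
    vapply(volumes@data, function(x) {
      feat <- .trunkForward(x, w)$feat
      z <- drop(w$latent$W %*% feat) + w$latent$b
      h <- pmax(z, 0)
      mr <- pmax(drop(w$head$W1 %*% h) + w$head$b1, 0)
      model@yMean + drop(w$head$W2 %*% mr) + w$head$b2
    }, numeric(1))
  })

#' @rdname predictAge
setMethod("predictAge", signature(model = "SslModel"),
  function(model, volumes) {
    .checkChannels(model, volumes)
    Z <- getEmbeddings(model, volumes)
    as.numeric(model@ridgeCoef[1] + Z %*% model@ridgeCoef[-1])
  })

#' @rdname predictAge
setMethod("predictAge", signature(model = "function"),
  function(model, volumes) model(volumes))

setMethod("show", "BrainAgeModel", function(object) {
  cat(sprintf("<%s> family %s, modality %s, channels [%s], seed %d\n",
              class(object), object@family, object@modality,
              paste(object@channels, collapse = ", "), object@seed))
})

#' Best published hyperparameter presets per model family and modality
#'
#' Named configurations for each family/modality pair (learning rates, PCA
#' components, augmentation noise, weight decay, dropout, neighbourhood
#' metric/schedule) as selected in the whole-brain analyses these tools
#' re-implement. Hyperparameter search itself is out of scope; presets are
#' accepted as given.
#'
#' @param family "pca_gp", "supervised_cnn" or "ssl_contrastive".
#' @param modality "stiffness", "damping", "mre" or "anatomical".
#' @return Named list of hyperparameters.
#' @export
modalityPreset <- function(family = c("pca_gp", "supervised_cnn",
                                      "ssl_contrastive"),
                           modality = c("mre", "stiffness", "damping",
                                        "anatomical")) {
  family <- match.arg(family)
  modality <- match.arg(modality)
  presets <- list(
    pca_gp = list(
      stiffness  = list(learningRate = 0.001, k = 100L, noiseSd = 0.02),
      damping    = list(learningRate = 0.001, k = 100L, noiseSd = 0.1),
      mre        = list(learningRate = 0.1, k = 100L, noiseSd = 0.15),
      anatomical = list(learningRate = 0.1, k = 100L, noiseSd = 0.2)),
    supervised_cnn = list(
      stiffness  = list(learningRate = 5e-5, dropout = 0.1,
                        weightDecay = 1e-4, noiseSd = 0.2),
      damping    = list(learningRate = 5e-5, dropout = 0.1,
                        weightDecay = 1e-4, noiseSd = 0.1),
      mre        = list(learningRate = 5e-5, dropout = 0.1,
                        weightDecay = 5e-5, noiseSd = 0.15),
      anatomical = list(learningRate = 5e-5, dropout = 0.1,
                        weightDecay = 5e-5, noiseSd = 0.15)),
    ssl_contrastive = list(
      stiffness  = list(learningRate = 1e-4, metric = "euclidean",
                        weightDecay = 5e-5, noiseSd = 0.15, step = 2L,
                        endCount = 8L),
      damping    = list(learningRate = 1e-4, metric = "euclidean",
                        weightDecay = 1e-4, noiseSd = 0.2, step = 1L,
                        endCount = 14L),
      mre        = list(learningRate = 1e-4, metric = "manhattan",
                        weightDecay = 5e-5, noiseSd = 0.1, step = 5L,
                        endCount = 9L),
      anatomical = list(learningRate = 1e-4, metric = "euclidean",
                        weightDecay = 5e-5, noiseSd = 0.15, step = 1L,
                        endCount = 12L)))
  presets[[family]][[modality]]
}
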