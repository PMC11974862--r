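# Compact CPU implementation of a 3D residual encoder in the ResNet-18
# style: stride-2 stem convolution, four stages of residual blocks
# (3x3x3 convolutions, identity or 1x1x1 projection shortcuts, stages 2-4
# downsample by 2), ReLU throughout, global average pooling, and a linear
# latent head. Forward, backpropagation and Adam live here; the
# convolutions themselves are Rcpp/Armadillo (see src/conv3d.cpp).
#
# Weight layout: a convolution with Cin inputs, Cout outputs and kernel K
# is a (Cout x Cin*K^3) matrix; see conv3d.cpp for the column ordering.

#' Encoder architecture configuration
#'
#' @param inputChannels 1 (single property or anatomical) or 2 (stiffness
#'   + damping).
#' @param stageChannels Channels of the four stages (default
#'   c(16, 32, 64, 128)).
#' @param embeddingDim Latent dimension (default 256).
#' @param dropout Dropout fraction on pooled features during training.
#' @param blocksPerStage Residual blocks per stage (2 matches ResNet-18; 1
#'   is the compact desk setting).
#' @return List with class `"EncoderConfig"`.
#' @export
encoderConfig <- function(inputChannels, stageChannels = c(16, 32, 64, 128),
                          embeddingDim = 256L, dropout = 0.1,
                          blocksPerStage = 2L) {
  stopifnot(inputChannels >= 1, all(stageChannels >= 1), embeddingDim >= 2,
            length(stageChannels) == 4L, dropout >= 0, dropout < 1)
  structure(list(inputChannels = as.integer(inputChannels),
                 stageChannels = as.integer(stageChannels),
                 embeddingDim = as.integer(embeddingDim),
                 dropout = dropout,
                 blocksPerStage = as.integer(blocksPerStage)),
            class = "EncoderConfig")
}

#' Compact desk-scale encoder configuration
#'
#' Shrinks channels to c(4, 8, 16, 32), the embedding to 32 and uses one
#' block per stage, so full training runs on one CPU in seconds to minutes
#' at grids of 16-32 voxels per side.
#'
#' @inheritParams encoderConfig
#' @return List with class `"EncoderConfig"`.
#' @export
deskEncoderConfig <- function(inputChannels, embeddingDim = 32L,
                              dropout = 0.1) {
  encoderConfig(inputChannels, stageChannels = c(4, 8, 16, 32),
                embeddingDim = embeddingDim, dropout = dropout,
                blocksPerStage = 1L)
}

#' Training configuration
#'
#' @param epochs Training epochs (>= 1).
#' @param batchSize Batch size (>= 3; contrastive denominators need n >= 3).
#' @param learningRate Initial Adam learning rate.
#' @param weightDecay L2 penalty added to gradients.
#' @param noiseSd Gaussian input-augmentation noise (applied in-mask, in
#'   normalized units, each time a volume is visited).
#' @param lrDecayFactor,lrDecayEvery Stepwise learning-rate decay: multiply
#'   by `lrDecayFactor` every `lrDecayEvery` epochs.
#' @param seed Integer seed controlling initialization, shuffling, noise
#'   and dropout.
#' @return List with class `"TrainConfig"`.
#' @export
trainConfig <- function(epochs = 50L, batchSize = 32L, learningRate = 1e-4,
                        weightDecay = 5e-5, noiseSd = 0.1,
                        lrDecayFactor = 0.9, lrDecayEvery = 10L, seed = 1L) {
  stopifnot(epochs >= 1, batchSize >= 3, learningRate > 0)
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, weightDecay = weightDecay,
                 noiseSd = noiseSd, lrDecayFactor = lrDecayFactor,
                 lrDecayEvery = as.integer(lrDecayEvery),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Desk-scale training configuration
#'
#' Fewer epochs, a smaller batch and a larger learning rate than the
#' full-scale defaults, chosen so the compact encoder converges within the
#' short desk-scale schedule.
#'
#' @inheritParams trainConfig
#' @return List with class `"TrainConfig"`.
#' @export
deskTrainConfig <- function(epochs = 30L, batchSize = 16L,
                            learningRate = 1e-3, weightDecay = 1e-5,
                            noiseSd = 0.05, seed = 1L) {
  trainConfig(epochs = epochs, batchSize = batchSize,
              learningRate = learningRate, weightDecay = weightDecay,
              noiseSd = noiseSd, seed = seed)
}

.blockStride <- function(stage, block) {
  if (stage > 1 && block == 1) 2L else 1L
}

.heInit <- function(cout, cin, k) {
  fanIn <- cin * k^3
  list(W = matrix(rnorm(cout * fanIn, 0, sqrt(2 / fanIn)), cout, fanIn),
       b = numeric(cout))
}

# Initialize encoder (+ optional supervised head) weights. Uses the
# current RNG state; callers seed beforehand.
.nnInit <- function(cfg, head = FALSE) {
  ch <- cfg$stageChannels
  w <- list(stem = .heInit(ch[1], cfg$inputChannels, 3))
  w$stages <- vector("list", 4L)
  inCh <- ch[1]
  for (s in 1:4) {
    blocks <- vector("list", cfg$blocksPerStage)
    for (b in seq_len(cfg$blocksPerStage)) {
      stride <- .blockStride(s, b)
      blk <- list(conv1 = .heInit(ch[s], inCh, 3),
                  conv2 = .heInit(ch[s], ch[s], 3))
      if (stride != 1L || inCh != ch[s])
        blk$proj <- .heInit(ch[s], inCh, 1)
      blocks[[b]] <- blk
      inCh <- ch[s]
    }
    w$stages[[s]] <- blocks
  }
  w$latent <- list(W = matrix(rnorm(cfg$embeddingDim * inCh, 0,
                                    sqrt(2 / inCh)),
                              cfg$embeddingDim, inCh),
                   b = numeric(cfg$embeddingDim))
  if (head) {
    w$head <- list(W1 = matrix(rnorm(64 * cfg$embeddingDim, 0,
                                     sqrt(2 / cfg$embeddingDim)),
                               64, cfg$embeddingDim),
                   b1 = numeric(64),
                   W2 = matrix(0, 1, 64),  # zero-init: start at the mean age
                   b2 = numeric(1))
  }
  w
}

.checkShape <- function(gridShape) {
  if (min(gridShape) < 16)
    stop("spatial shape too small for the 4-stage encoder (need >= 16 per axis)")
}

# Forward through the convolutional trunk; returns pooled features and the
# per-layer cache needed for backprop.
.trunkForward <- function(x, w) {
  cache <- list(x = x)
  a <- .conv3dForward(x, w$stem$W, w$stem$b, 2L, 3L)
  a[a < 0] <- 0
  cache$stemOut <- a
  for (s in 1:4) {
    for (b in seq_along(w$stages[[s]])) {
      blk <- w$stages[[s]][[b]]
      stride <- .blockStride(s, b)
      inp <- a
      h1 <- .conv3dForward(inp, blk$conv1$W, blk$conv1$b, stride, 3L)
      h1[h1 < 0] <- 0
      h2 <- .conv3dForward(h1, blk$conv2$W, blk$conv2$b, 1L, 3L)
      sc <- if (is.null(blk$proj)) inp else
        .conv3dForward(inp, blk$proj$W, blk$proj$b, stride, 1L)
      out <- h2 + sc
      out[out < 0] <- 0
      cache[[sprintf("s%db%d", s, b)]] <- list(inp = inp, h1 = h1, out = out)
      a <- out
    }
  }
  d <- dim(a)
  feat <- rowMeans(matrix(a, nrow = d[1]))
  cache$lastDim <- d
  list(feat = feat, cache = cache)
}

# Backprop through the trunk. gradFeat: gradient at the pooled features.
# Returns gradients mirroring the stem/stages weight trees.
.trunkBackward <- function(gradFeat, cache, w) {
  d <- cache$lastDim
  nvox <- prod(d[-1])
  ga <- array(rep(gradFeat / nvox, nvox), d)
  gw <- list(stem = NULL, stages = vector("list", 4L))
  for (s in 4:1) {
    nb <- length(w$stages[[s]])
    gw$stages[[s]] <- vector("list", nb)
    for (b in nb:1) {
      blk <- w$stages[[s]][[b]]
      stride <- .blockStride(s, b)
      cc <- cache[[sprintf("s%db%d", s, b)]]
      gout <- ga * (cc$out > 0)
      # shortcut branch
      if (is.null(blk$proj)) {
        gsc <- gout
        gproj <- NULL
      } else {
        bp <- .conv3dBackward(cc$inp, blk$proj$W, gout, stride, 1L)
        gsc <- bp$gradInput
        gproj <- list(W = bp$gradWeight, b = bp$gradBias)
      }
      # main branch
      b2 <- .conv3dBackward(cc$h1, blk$conv2$W, gout, 1L, 3L)
      gh1 <- b2$gradInput * (cc$h1 > 0)
      b1 <- .conv3dBackward(cc$inp, blk$conv1$W, gh1, stride, 3L)
      ga <- b1$gradInput + gsc
      g <- list(conv1 = list(W = b1$gradWeight, b = b1$gradBias),
                conv2 = list(W = b2$gradWeight, b = b2$gradBias))
      if (!is.null(gproj)) g$proj <- gproj
      gw$stages[[s]][[b]] <- g
    }
  }
  gstem <- ga * (cache$stemOut > 0)
  bs <- .conv3dBackward(cache$x, w$stem$W, gstem, 2L, 3L)
  gw$stem <- list(W = bs$gradWeight, b = bs$gradBias)
  gw
}

# ---- weight-tree utilities ------------------------------------------------

.zeroLike <- function(w) {
  if (is.list(w)) lapply(w, .zeroLike) else w * 0
}

.treeAdd <- function(a, b) {
  if (is.list(a)) {
    for (j in seq_along(a)) a[[j]] <- .treeAdd(a[[j]], b[[j]])
    a
  } else a + b
}

.treeScale <- function(a, s) {
  if (is.list(a)) lapply(a, .treeScale, s = s) else a * s
}

.adamInit <- function(w) list(m = .zeroLike(w), v = .zeroLike(w), t = 0L)

.adamRec <- function(w, g, m, v, lr, wd, bc1, bc2) {
  if (is.list(w)) {
    for (j in seq_along(w)) {
      r <- .adamRec(w[[j]], g[[j]], m[[j]], v[[j]], lr, wd, bc1, bc2)
      w[[j]] <- r$w; m[[j]] <- r$m; v[[j]] <- r$v
    }
    return(list(w = w, m = m, v = v))
  }
  g <- g + wd * w
  m <- 0.9 * m + 0.1 * g
  v <- 0.999 * v + 0.001 * g^2
  w <- w - lr * (m / bc1) / (sqrt(v / bc2) + 1e-8)
  list(w = w, m = m, v = v)
}

.adamStep <- function(w, g, state, lr, wd) {
  state$t <- state$t + 1L
  bc1 <- 1 - 0.9^state$t
  bc2 <- 1 - 0.999^state$t
  r <- .adamRec(w, g, state$m, state$v, lr, wd, bc1, bc2)
  state$m <- r$m; state$v <- r$v
  list(w = r$w, state = state)
}

# In-mask Gaussian augmentation noise on a (C, X, Y, Z) volume.
.augmentNoise <- function(x, maskIdx, sd) {
  if (sd <= 0) return(x)
  C <- dim(x)[1]
  for (ch in seq_len(C)) {
    v <- x[ch, , , ]
    v[maskIdx] <- v[maskIdx] + rnorm(length(maskIdx), 0, sd)
    x[ch, , , ] <- v
  }
  x
}

.lrAt <- function(tc, epoch) {
  tc$learningRate * tc$lrDecayFactor^(epoch %/% tc$lrDecayEvery)
}
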