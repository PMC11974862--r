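#' Occlusion-saliency configuration
#'
#' @param block Occlusion block edge length in voxels (default 7).
#' @param excludedSuperiorSlices Slices dropped from the top of the
#'   superior-inferior (third) axis, typically non-brain (default 9).
#' @param positionsPerAxis Number of block origins per axis (default 13;
#'   with the default block on a 91-voxel axis this reproduces exact
#'   stride-7 tiling, 13^3 = 2197 origins in total).
#' @param clipPercentiles Lower/upper percentile clip of the delta-MAE
#'   grid (default c(5, 95)).
#' @param nAgeBins Number of quantile age bins (default 5).
#' @param fillValue Occlusion fill value (0, which coincides with
#'   background in normalized space).
#' @return List with class `"SaliencyConfig"`.
#' @export
saliencyConfig <- function(block = 7L, excludedSuperiorSlices = 9L,
                           positionsPerAxis = 13L,
                           clipPercentiles = c(5, 95), nAgeBins = 5L,
                           fillValue = 0) {
  stopifnot(block >= 1, positionsPerAxis >= 1,
            clipPercentiles[1] >= 0, clipPercentiles[2] <= 100,
            clipPercentiles[1] < clipPercentiles[2])
  structure(list(block = as.integer(block),
                 excludedSuperiorSlices = as.integer(excludedSuperiorSlices),
                 positionsPerAxis = as.integer(positionsPerAxis),
                 clipPercentiles = clipPercentiles,
                 nAgeBins = as.integer(nAgeBins), fillValue = fillValue),
            class = "SaliencyConfig")
}

#' Quantile age bins for saliency analysis
#'
#' Test subjects are divided into `nBins` groups at chronological-age
#' quantiles. Ties that would empty a bin are merged into their neighbour
#' with a warning.
#'
#' @param testAges Numeric ages, length >= nBins.
#' @param nBins Number of bins (default 5).
#' @return List with `labels` (bin index per subject, 1 = youngest) and
#'   `edges` (bin boundaries).
#' @export
assignAgeBins <- function(testAges, nBins = 5L) {
  stopifnot(length(testAges) >= nBins, nBins >= 1)
  edges <- unique(quantile(testAges, probs = seq(0, 1, length.out = nBins + 1)))
  if (length(edges) < nBins + 1)
    warning("age ties collapsed one or more bins; merged with neighbours")
  labels <- cut(testAges, breaks = edges, include.lowest = TRUE,
                labels = FALSE)
  list(labels = labels, edges = unname(edges))
}

#' Ordered occlusion-block origins
#'
#' `positionsPerAxis` origins per axis, evenly spaced (rounded linear
#' spacing) over the admissible extent so every block lies fully inside
#' the volume; on the superior-inferior (third) axis the topmost
#' `excludedSuperiorSlices` slices are excluded. On a clean 91-voxel axis
#' with the default block this reduces to the exact non-overlapping
#' stride of 7.
#'
#' @param volumeShape Integer (X, Y, Z) spatial shape.
#' @param config A [saliencyConfig()].
#' @return Integer matrix (nOrigins x 3) of 1-based block origins, ordered
#'   with the first axis fastest; attribute `"perAxis"` holds the per-axis
#'   origin vectors.
#' @export
occlusionOrigins <- function(volumeShape, config = saliencyConfig()) {
  b <- config$block
  p <- config$positionsPerAxis
  maxOrigin <- c(volumeShape[1] - b,
                 volumeShape[2] - b,
                 volumeShape[3] - config$excludedSuperiorSlices - b)
  if (any(maxOrigin < 0))
    stop("volume too small for the occlusion block (after slab exclusion)")
  axes <- lapply(maxOrigin, function(m) {
    if (p == 1) 1L else as.integer(round(seq(0, m, length.out = p))) + 1L
  })
  grid <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
  storage.mode(grid) <- "integer"
  attr(grid, "perAxis") <- axes
  grid
}

#' Delta-MAE occlusion grid for one age bin
#'
#' For every block origin, the block is replaced by the fill value in
#' every subject of the bin (all channels), ages are re-predicted, and the
#' effect is the change in mean absolute error relative to the unoccluded
#' predictions: delta MAE = MAE(occluded) - MAE(original).
#'
#' @param model A fitted brain-age model (or a function; see
#'   [predictAge()]).
#' @param volumes [BrainVolumes-class] of the bin's subjects.
#' @param ages Their chronological ages.
#' @param config A [saliencyConfig()].
#' @param origins Optional precomputed [occlusionOrigins()].
#' @return 3D array of delta-MAE values, dim positionsPerAxis^3 (or the
#'   per-axis origin counts), ordered to match the origins.
#' @export
deltaMaeGrid <- function(model, volumes, ages, config = saliencyConfig(),
                         origins = NULL) {
  stopifnot(nSubjects(volumes) >= 1)
  if (is.null(origins))
    origins <- occlusionOrigins(dim(volumes@mask), config)
  axes <- attr(origins, "perAxis")
  base <- absoluteErrorSummary(predictAge(model, volumes), ages)[["mean_abs"]]
  b <- config$block
  vals <- numeric(nrow(origins))
  for (o in seq_len(nrow(origins))) {
    occ <- volumes
    for (i in seq_len(nSubjects(volumes))) {
      v <- occ@data[[i]]
      v[, origins[o, 1]:(origins[o, 1] + b - 1L),
        origins[o, 2]:(origins[o, 2] + b - 1L),
        origins[o, 3]:(origins[o, 3] + b - 1L)] <- config$fillValue
      occ@data[[i]] <- v
    }
    pred <- tryCatch(predictAge(model, occ), error = function(e)
      stop(sprintf("prediction failed at origin (%d,%d,%d): %s",
                   origins[o, 1], origins[o, 2], origins[o, 3],
                   conditionMessage(e))))
    vals[o] <- absoluteErrorSummary(pred, ages)[["mean_abs"]] - base
  }
  array(vals, vapply(axes, length, integer(1)))
}

# Separable 1-D cubic-convolution (Keys, a = -0.5) resampling of a 3D
# array to a new shape, with edge clamping.
.cubicResize <- function(arr, newShape) {
  keys <- function(t) {
    at <- abs(t)
    ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
           ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
  }
  resize1 <- function(a, axis, nOut) {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    d <- dim(ap)
    nIn <- d[1]
    m <- matrix(ap, nrow = nIn)
    # map output voxel centers into input coordinates
    src <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5 + 1  # 1-based
    out <- matrix(0, nOut, ncol(m))
    for (i in seq_len(nOut)) {
      i0 <- floor(src[i])
      idx <- (i0 - 1):(i0 + 2)
      wts <- keys(src[i] - idx)
      idx <- pmin(pmax(idx, 1), nIn)
      out[i, ] <- wts %*% m[idx, , drop = FALSE]
    }
    aperm(array(out, c(nOut, d[2], d[3])), order(perm))
  }
  for (ax in 1:3) arr <- resize1(arr, ax, newShape[ax])
  arr
}

#' Post-process a delta-MAE grid into a saliency map
#'
#' Clips the grid between the configured percentiles, upsamples it to the
#' target volume shape (minus the excluded superior slab) with cubic
#' interpolation, zero-pads the slab back, and min-max scales to \[0, 1\].
#' A constant grid has no contrast and returns an all-zero map with a
#' warning.
#'
#' @param grid Output of [deltaMaeGrid()].
#' @param config A [saliencyConfig()].
#' @param targetShape Integer (X, Y, Z) of the original volumes.
#' @return 3D array in \[0, 1\] with the excluded slab exactly 0.
#' @export
postprocessSaliency <- function(grid, config, targetShape) {
  lo <- quantile(grid, config$clipPercentiles[1] / 100)
  hi <- quantile(grid, config$clipPercentiles[2] / 100)
  g <- pmin(pmax(grid, lo), hi)
  zKeep <- targetShape[3] - config$excludedSuperiorSlices
  if (max(g) - min(g) <= 0) {
    warning("constant delta-MAE grid: returning an all-zero saliency map")
    return(array(0, targetShape))
  }
  up <- .cubicResize(g, c(targetShape[1], targetShape[2], zKeep))
  up <- (up - min(up)) / (max(up) - min(up))
  out <- array(0, targetShape)
  out[, , seq_len(zKeep)] <- up
  out
}

#' Occlusion saliency maps per age bin
#'
#' Runs the full recipe: quantile age-binning of the test subjects,
#' per-bin delta-MAE occlusion grids, and post-processing into \[0, 1\]
#' saliency volumes.
#'
#' @param model Fitted brain-age model.
#' @param volumes Test-set [BrainVolumes-class].
#' @param ages Test-set ages.
#' @param config A [saliencyConfig()].
#' @return List with `maps` (one 3D array per bin), `bins` (the
#'   [assignAgeBins()] result) and `grids` (raw delta-MAE grids).
#' @export
saliencyByAgeBin <- function(model, volumes, ages,
                             config = saliencyConfig()) {
  bins <- assignAgeBins(ages, config$nAgeBins)
  origins <- occlusionOrigins(dim(volumes@mask), config)
  shape <- dim(volumes@mask)
  maps <- list(); grids <- list()
  for (bin in sort(unique(bins$labels))) {
    sel <- which(bins$labels == bin)
    sub <- volumes
    sub@data <- volumes@data[sel]
    g <- deltaMaeGrid(model, sub, ages[sel], config, origins)
    grids[[bin]] <- g
    maps[[bin]] <- postprocessSaliency(g, config, shape)
  }
  list(maps = maps, bins = bins, grids = grids)
}
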