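#' Gaussian age-kernel weight matrix
#'
#' Pairwise attraction/repulsion strengths for contrastive regression:
#' \deqn{w_{ik} = \exp(-(y_i - y_k)^2 / (2\sigma^2))}
#' The diagonal is set to 0 because self-pairs take part in no loss.
#'
#' @param ages Numeric vector of ages (years).
#' @param sigma Kernel bandwidth in years, > 0.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
ageKernelWeights <- function(ages, sigma) {
  stopifnot(sigma > 0)
  d <- outer(ages, ages, "-")
  w <- exp(-d^2 / (2 * sigma^2))
  diag(w) <- 0
  w
}

#' Cosine similarity matrix of unit-norm embeddings
#'
#' @param features n x d matrix; rows are renormalized (with a warning) if
#'   not already unit-norm.
#' @return n x n matrix in \[-1, 1\] with unit diagonal.
#' @export
similarityMatrix <- function(features) {
  features <- as.matrix(features)
  nrm <- sqrt(rowSums(features^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    warning("features were not unit-norm; renormalizing")
    features <- features / nrm
  }
  s <- tcrossprod(features)
  s[s > 1] <- 1; s[s < -1] <- -1
  diag(s) <- 1
  s
}

#' Neighbourhood shrink schedule for adaptive contrastive regression
#'
#' The per-anchor neighbourhood starts at `startCount` (all other samples
#' when NULL) and shrinks by `step` each epoch down to `endCount`:
#' size(epoch) = clamp(start - step * epoch, end, start).
#'
#' @param step Non-negative per-epoch decrement.
#' @param endCount Final neighbourhood size, >= 1.
#' @param metric Distance in embedding space: "manhattan", "euclidean", or
#'   "similarity" (descending cosine similarity).
#' @param startCount Initial size; NULL means n - 1 at use time.
#' @return List with class `"NeighbourhoodSchedule"`.
#' @export
neighbourhoodSchedule <- function(step = 5L, endCount = 9L,
                                  metric = c("manhattan", "euclidean",
                                             "similarity"),
                                  startCount = NULL) {
  metric <- match.arg(metric)
  stopifnot(step >= 0, endCount >= 1)
  structure(list(startCount = startCount, step = as.integer(step),
                 endCount = as.integer(endCount), metric = metric),
            class = "NeighbourhoodSchedule")
}

#' Neighbourhood size at a given epoch
#' @param schedule A [neighbourhoodSchedule()].
#' @param epoch Zero-based epoch index.
#' @param n Batch size.
#' @return Integer neighbourhood size.
#' @export
neighbourhoodSize <- function(schedule, epoch, n) {
  start <- if (is.null(schedule$startCount)) n - 1L else schedule$startCount
  min(max(start - schedule$step * epoch, schedule$endCount), start)
}

#' Per-sample nearest-neighbour sets in embedding space
#'
#' For each sample, its `neighbourhoodSize(schedule, epoch, n)` nearest
#' other samples under the configured metric ("similarity" ranks by
#' descending cosine similarity). Self is always excluded; ties are broken
#' by index order.
#'
#' @param features n x d embedding matrix (unit-norm rows).
#' @param epoch Zero-based epoch index.
#' @param schedule A [neighbourhoodSchedule()].
#' @return List of n integer vectors of neighbour indices.
#' @export
selectNeighbours <- function(features, epoch, schedule) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(epoch >= 0)
  start <- if (is.null(schedule$startCount)) n - 1L else schedule$startCount
  if (schedule$endCount >= n)
    stop("endCount must be smaller than the batch size")
  size <- neighbourhoodSize(schedule, epoch, n)
  d <- switch(schedule$metric,
    manhattan = as.matrix(dist(features, method = "manhattan")),
    euclidean = as.matrix(dist(features, method = "euclidean")),
    similarity = -similarityMatrix(features))
  lapply(seq_len(n), function(i) {
    di <- d[i, ]
    di[i] <- Inf
    head(order(di), size)
  })
  }

# shared pieces of the three losses
.lossPrep <- function(batch, sigma) {
  stopifnot(is(batch, "EmbeddingBatch"))
  f <- batch@features
  list(f = f, n = nrow(f), w = ageKernelWeights(batch@ages, sigma),
       s = similarityMatrix(f))
}

#' Y-aware contrastive regression loss
#'
#' \deqn{L = -\sum_i \sum_{k \neq i} w_{ik}
#'   \log\frac{\exp(s_{ik})}{\sum_{t \notin \{i,k\}} \exp(s_{it})}}
#' where \eqn{w} is the Gaussian age kernel and \eqn{s} the cosine
#' similarity of embeddings. Age-similar samples are attracted, distant
#' ones repelled; self-similarity terms are excluded from the softmax
#' denominator.
#'
#' @param batch An [EmbeddingBatch-class] with n >= 3.
#' @param sigma Age-kernel bandwidth in years.
#' @param grad If TRUE also return the analytic gradient with respect to
#'   the feature matrix.
#' @return The scalar loss, or `list(value, grad)` when `grad = TRUE`.
#' @export
lossYaware <- function(batch, sigma, grad = FALSE) {
  p <- .lossPrep(batch, sigma)
  if (p$n < 3) stop("need n >= 3 for a non-empty denominator")
  e <- exp(p$s); diag(e) <- 0
  r <- rowSums(e)
  d <- r - e                       # d[i,k] = sum_{t != i,k} exp(s_it)
  off <- !diag(p$n)
  val <- -sum(p$w[off] * (p$s[off] - log(d[off])))
  if (!grad) return(val)
  q <- rowSums(p$w / d)            # Q_i = sum_{k != i} w_ik / d_ik
  g <- -p$w + e * (q - p$w / d)
  diag(g) <- 0
  list(value = val, grad = (g + t(g)) %*% p$f)
}

#' Exponentially scaled contrastive regression loss
#'
#' As [lossYaware()] but with denominator terms
#' \eqn{\exp(s_{it} (1 - w_{it}))}, which increases repulsion strength for
#' age-dissimilar samples (their weight is near 0, leaving the full
#' exponent) while age-similar samples contribute almost nothing.
#'
#' @inheritParams lossYaware
#' @return The scalar loss, or `list(value, grad)` when `grad = TRUE`.
#' @export
lossExponential <- function(batch, sigma, grad = FALSE) {
  p <- .lossPrep(batch, sigma)
  if (p$n < 3) stop("need n >= 3 for a non-empty denominator")
  e <- exp(p$s * (1 - p$w)); diag(e) <- 0
  r <- rowSums(e)
  d <- r - e
  off <- !diag(p$n)
  val <- -sum(p$w[off] * (p$s[off] - log(d[off])))
  if (!grad) return(val)
  q <- rowSums(p$w / d)
  g <- -p$w + (1 - p$w) * e * (q - p$w / d)
  diag(g) <- 0
  list(value = val, grad = (g + t(g)) %*% p$f)
}

#' Adaptive-neighbourhood contrastive regression loss
#'
#' \deqn{L = -\sum_i \sum_{k \neq i} \frac{w_{ik}}{\sum_t w_{it}}
#'   \log\frac{\exp(s_{ik})}
#'            {\sum_{t \in NN(x_i) \setminus \{k\}} \exp(s_{it}(1-w_{it}))}}
#' The anchor-normalized age weights make the loss invariant to a common
#' rescaling of the kernel, and the per-anchor neighbour sets restrict the
#' softmax to the currently most relevant comparisons. With full
#' neighbourhoods (all samples but the anchor) this reduces to the
#' anchor-normalized [lossExponential()].
#'
#' Pairs whose effective denominator set is empty (the anchor's
#' neighbourhood reduced to \{k\}) are skipped with a warning.
#'
#' @inheritParams lossYaware
#' @param neighbourSets List of per-anchor neighbour index vectors, e.g.
#'   from [selectNeighbours()]; the anchor itself must not be a member.
#' @return The scalar loss, or `list(value, grad)` when `grad = TRUE`.
#' @export
lossAdaptive <- function(batch, sigma, neighbourSets, grad = FALSE) {
  p <- .lossPrep(batch, sigma)
  n <- p$n
  stopifnot(length(neighbourSets) == n)
  e <- exp(p$s * (1 - p$w)); diag(e) <- 0
  wsum <- rowSums(p$w)
  a <- p$w / wsum                     # anchor-normalized weights
  val <- 0
  g <- matrix(0, n, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    nn <- setdiff(as.integer(neighbourSets[[i]]), i)
    ei <- e[i, ]
    totalNN <- sum(ei[nn])
    for (k in seq_len(n)[-i]) {
      dik <- totalNN - if (k %in% nn) ei[k] else 0
      if (dik <= 0 || length(setdiff(nn, k)) == 0L) {
        skipped <- skipped + 1L
        next
      }
      val <- val - a[i, k] * (p$s[i, k] - log(dik))
      if (grad) {
        g[i, k] <- g[i, k] - a[i, k]
        tset <- setdiff(nn, k)
        g[i, tset] <- g[i, tset] +
          a[i, k] * (1 - p$w[i, tset]) * ei[tset] / dik
      }
    }
  }
  if (skipped > 0)
    warning(sprintf("%d anchor/positive pairs skipped (empty denominator)",
                    skipped))
  if (!grad) return(val)
  list(value = val, grad = (g + t(g)) %*% p$f)
}
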