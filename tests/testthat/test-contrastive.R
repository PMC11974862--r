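test_that("age kernel weights follow the Gaussian closed form", {
  w <- ageKernelWeights(c(30, 30, 32), sigma = 2)
  expect_equal(w[1, 2], 1)                     # age twins
  expect_equal(w[1, 3], exp(-1 / 2))           # delta = sigma
  expect_identical(diag(w), rep(0, 3))
  set.seed(1)
  ages <- runif(10, 18, 90)
  w <- ageKernelWeights(ages, 5)
  expect_equal(w, t(w))
  expect_error(ageKernelWeights(ages, 0))
})

test_that("cosine similarity handles identical/orthogonal/antipodal pairs", {
  f <- rbind(c(1, 0), c(1, 0), c(0, 1), c(-1, 0))
  s <- similarityMatrix(f)
  expect_equal(s[1, 2], 1)
  expect_equal(s[1, 3], 0)
  expect_equal(s[1, 4], -1)
  expect_warning(similarityMatrix(rbind(c(2, 0), c(0, 1))), "unit-norm")
})

test_that("neighbourhood size clamps along the schedule", {
  sch <- neighbourhoodSchedule(step = 5, endCount = 9)
  expect_equal(neighbourhoodSize(sch, 0, 32), 31)
  expect_equal(neighbourhoodSize(sch, 2, 32), 21)
  expect_equal(neighbourhoodSize(sch, 100, 32), 9)
  sch2 <- neighbourhoodSchedule(step = 0, endCount = 1)
  expect_equal(neighbourhoodSize(sch2, 50, 10), 9)
})

test_that("nearest-neighbour sets match brute force for all metrics", {
  # 4 points on a line in 2D (then renormalized is wrong for geometry, so
  # use raw coordinates with unit padding in a 3rd dimension)
  f <- cbind(c(0, 1, 3, 7), 0, 1)
  f <- f / sqrt(rowSums(f^2))
  for (metric in c("manhattan", "euclidean", "similarity")) {
    sch <- neighbourhoodSchedule(step = 1, endCount = 1, metric = metric)
    nn <- selectNeighbours(f, epoch = 10, sch)  # size clamped to 1
    d <- switch(metric,
      manhattan = as.matrix(dist(f, "manhattan")),
      euclidean = as.matrix(dist(f)),
      similarity = -tcrossprod(f))
    for (i in 1:4) {
      di <- d[i, ]; di[i] <- Inf
      expect_equal(nn[[i]], unname(which.min(di)), info = metric)
    }
  }
  # epoch 0 with default start: everything but self
  sch <- neighbourhoodSchedule(step = 5, endCount = 2)
  nn <- selectNeighbours(f, 0, sch)
  expect_true(all(vapply(nn, length, 1L) == 3))
  expect_false(any(vapply(seq_len(4), function(i) i %in% nn[[i]], TRUE)))
  expect_error(selectNeighbours(f, 0, neighbourhoodSchedule(endCount = 4)),
               "smaller than the batch")
})

test_that("losses equal scalar brute-force enumeration", {
  set.seed(7)
  sigma <- 2
  for (n in 3:5) {
    f <- randomUnitRows(n, 4)
    ages <- sort(runif(n, 28, 36))  # close ages so weights discriminate
    b <- embeddingBatch(f, ages, normalize = FALSE)
    expect_equal(lossYaware(b, sigma), bfYaware(f, ages, sigma),
                 tolerance = 1e-10)
    expect_equal(lossExponential(b, sigma), bfExponential(f, ages, sigma),
                 tolerance = 1e-10)
    nnAll <- lapply(1:n, function(i) setdiff(1:n, i))
    expect_equal(lossAdaptive(b, sigma, nnAll),
                 bfAdaptive(f, ages, sigma, nnAll), tolerance = 1e-10)
    # neighbourhoods of size 1
    sch <- neighbourhoodSchedule(step = 1, endCount = 1,
                                 metric = "euclidean")
    nn1 <- selectNeighbours(f, 10, sch)
    expect_equal(suppressWarnings(lossAdaptive(b, sigma, nn1)),
                 suppressWarnings(bfAdaptive(f, ages, sigma, nn1)),
                 tolerance = 1e-10)
  }
})

test_that("sigma -> Inf reduces the y-aware loss to the unweighted form", {
  set.seed(8)
  n <- 5
  f <- randomUnitRows(n, 3)
  ages <- runif(n, 20, 80)
  b <- embeddingBatch(f, ages, normalize = FALSE)
  unweighted <- bfYaware(f, rep(50, n), 1)  # all weights exactly 1
  expect_equal(lossYaware(b, sigma = 1e9), unweighted, tolerance = 1e-6)
})

test_that("identical ages collapse exponential denominators to n - 2", {
  set.seed(9)
  n <- 4
  f <- randomUnitRows(n, 3)
  ages <- rep(40, n)  # all weights 1, all denominator terms exp(0) = 1
  b <- embeddingBatch(f, ages, normalize = FALSE)
  s <- tcrossprod(f)
  expected <- 0
  for (i in 1:n) for (k in 1:n) if (k != i)
    expected <- expected - (s[i, k] - log(n - 2))
  expect_equal(lossExponential(b, sigma = 2), expected, tolerance = 1e-10)
})

test_that("adaptive loss with full neighbourhoods is anchor-normalized
          exponential and is invariant to weight rescaling", {
  set.seed(10)
  n <- 5
  f <- randomUnitRows(n, 4)
  ages <- runif(n, 30, 40)
  b <- embeddingBatch(f, ages, normalize = FALSE)
  nnAll <- lapply(1:n, function(i) setdiff(1:n, i))
  v <- lossAdaptive(b, 2, nnAll)
  # equals the brute-force exponential loss with per-anchor weight
  # normalization, for any overall weight scale
  expect_equal(v, bfAdaptive(f, ages, 2, nnAll, weightScale = 1),
               tolerance = 1e-12)
  expect_equal(v, bfAdaptive(f, ages, 2, nnAll, weightScale = 7.3),
               tolerance = 1e-12)
})

test_that("losses are invariant under a common rotation of embeddings", {
  set.seed(11)
  n <- 4; d <- 4
  f <- randomUnitRows(n, d)
  ages <- runif(n, 30, 50)
  q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  b1 <- embeddingBatch(f, ages, normalize = FALSE)
  b2 <- embeddingBatch(f %*% q, ages, normalize = FALSE)
  nnAll <- lapply(1:n, function(i) setdiff(1:n, i))
  expect_equal(lossYaware(b1, 2), lossYaware(b2, 2), tolerance = 1e-10)
  expect_equal(lossExponential(b1, 2), lossExponential(b2, 2),
               tolerance = 1e-10)
  expect_equal(lossAdaptive(b1, 2, nnAll), lossAdaptive(b2, 2, nnAll),
               tolerance = 1e-10)
})

test_that("analytic gradients match finite differences through the
          unit-norm constraint", {
  set.seed(12)
  sigma <- 2
  for (rep in 1:3) {
    n <- sample(4:6, 1); d <- sample(3:8, 1)
    f <- randomUnitRows(n, d)
    ages <- runif(n, 25, 45)
    nnAll <- lapply(1:n, function(i) setdiff(1:n, i))
    fns <- list(
      an = list(function(b) lossYaware(b, sigma, grad = TRUE),
                function(ff) bfYaware(ff, ages, sigma)),
      ex = list(function(b) lossExponential(b, sigma, grad = TRUE),
                function(ff) bfExponential(ff, ages, sigma)),
      ad = list(function(b) lossAdaptive(b, sigma, nnAll, grad = TRUE),
                function(ff) bfAdaptive(ff, ages, sigma, nnAll)))
    b <- embeddingBatch(f, ages, normalize = FALSE)
    for (fn in fns) {
      g <- fn[[1]](b)$grad
      gp <- g - f * rowSums(g * f)   # tangent projection of the renorm map
      eps <- 1e-6
      for (idx in sample(n * d, 5)) {
        fp <- f; fp[idx] <- fp[idx] + eps
        fm <- f; fm[idx] <- fm[idx] - eps
        fd <- (fn[[2]](fp) - fn[[2]](fm)) / (2 * eps)
        expect_equal(gp[idx], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("raising the similarity of an age-close pair lowers every loss", {
  ages <- c(30, 31, 70)
  mk <- function(theta) {
    f <- rbind(c(cos(theta), sin(theta), 0),
               c(cos(theta), -sin(theta), 0),
               c(0, 0, 1))
    embeddingBatch(f, ages, normalize = FALSE)
  }
  nnAll <- lapply(1:3, function(i) setdiff(1:3, i))
  bFar <- mk(0.8); bNear <- mk(0.3)  # s_12 increases as theta shrinks
  expect_lt(lossYaware(bNear, 2), lossYaware(bFar, 2))
  expect_lt(lossExponential(bNear, 2), lossExponential(bFar, 2))
  expect_lt(lossAdaptive(bNear, 2, nnAll), lossAdaptive(bFar, 2, nnAll))
})

test_that("degenerate inputs are rejected or skipped with a warning", {
  f <- randomUnitRows(2, 3)
  b <- embeddingBatch(f, c(30, 40), normalize = FALSE)
  expect_error(lossYaware(b, 2), "n >= 3")
  expect_error(lossExponential(b, 2), "n >= 3")
  f3 <- randomUnitRows(3, 3)
  b3 <- embeddingBatch(f3, c(30, 35, 40), normalize = FALSE)
  # anchor 1's neighbourhood is only {2}: the (1,2) pair has an empty
  # denominator and is skipped
  nnDeg <- list(2L, c(1L, 3L), c(1L, 2L))
  expect_warning(lossAdaptive(b3, 2, nnDeg), "skipped")
})
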