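test_that("quantile age bins partition subjects as expected", {
  b <- assignAgeBins(1:10, 5)
  expect_equal(as.vector(table(b$labels)), rep(2, 5))
  expect_equal(b$labels, rep(1:5, each = 2))

  set.seed(1)
  ages <- runif(23, 20, 80)
  b <- assignAgeBins(ages, 5)
  expect_true(max(table(b$labels)) - min(table(b$labels)) <= 1)
  # bins ordered by age
  expect_true(all(diff(tapply(ages, b$labels, mean)) > 0))

  b1 <- assignAgeBins(ages, 1)
  expect_true(all(b1$labels == 1))

  expect_warning(assignAgeBins(c(5, 5, 5, 5, 9, 10), 5), "merged")
})

test_that("occlusion origins reproduce the printed 13x13x13 geometry", {
  cfg <- saliencyConfig()
  o <- occlusionOrigins(c(91, 109, 91), cfg)
  expect_equal(nrow(o), 2197)
  ax <- attr(o, "perAxis")
  expect_true(all(vapply(ax, length, 1L) == 13))
  # clean 91-voxel axis: exact non-overlapping stride 7
  expect_equal(diff(ax[[1]]), rep(7, 12))
  # every block inside the volume and below the excluded slab
  expect_true(all(o[, 1] + cfg$block - 1 <= 91))
  expect_true(all(o[, 2] + cfg$block - 1 <= 109))
  expect_true(all(o[, 3] + cfg$block - 1 <= 91 - cfg$excludedSuperiorSlices))
})

test_that("degenerate occlusion geometries behave as specified", {
  cfg <- saliencyConfig(block = 7, excludedSuperiorSlices = 0,
                        positionsPerAxis = 1)
  o <- occlusionOrigins(c(7, 7, 7), cfg)
  expect_equal(nrow(o), 1)
  expect_equal(unname(o[1, ]), c(1L, 1L, 1L))
  expect_error(occlusionOrigins(c(7, 7, 7), saliencyConfig(block = 7)),
               "too small")
})

test_that("a model that ignores its input yields an all-zero grid", {
  cohort <- tinyCohort()
  prep <- prepareModelData(cohort, "mre")
  cfg <- saliencyConfig(block = 4, excludedSuperiorSlices = 2,
                        positionsPerAxis = 3)
  g <- deltaMaeGrid(function(v) rep(50, nSubjects(v)), prep$volumes,
                    cohort$participants$age, cfg)
  expect_identical(dim(g), c(3L, 3L, 3L))
  expect_true(all(g == 0))
})

test_that("occluding an all-background block changes nothing", {
  cohort <- tinyCohort()
  prep <- prepareModelData(cohort, "mre")
  mask <- prep$volumes@mask
  # corner block is outside the brain ellipsoid
  expect_true(all(!mask[1:4, 1:4, 1:4]))
  meanModel <- function(v)
    vapply(v@data, function(x) 40 + 20 * mean(x), numeric(1))
  base <- predictAge(meanModel, prep$volumes)
  occ <- prep$volumes
  occ@data <- lapply(occ@data, function(x) { x[, 1:4, 1:4, 1:4] <- 0; x })
  expect_identical(predictAge(meanModel, occ), base)
})

test_that("occlusion localizes a single age-informative region", {
  atlas <- deskAtlas()
  mods <- setNames(rep(0, 12), regionNames())
  mods["thalamus"] <- 1
  spec <- cohortSpec(nHealthy = 24, regionalRateModifiers = mods,
                     noiseSd = 0.02, seed = 31)
  cohort <- generateCohort(spec, atlas)
  prep <- prepareModelData(cohort, "mre")
  mdl <- fitPcaGp(prep$volumes, cohort$participants$age, k = 5,
                  tc = trainConfig(epochs = 30, learningRate = 0.1,
                                   noiseSd = 0.02, seed = 1))
  cfg <- saliencyConfig(block = 5, excludedSuperiorSlices = 2,
                        positionsPerAxis = 5)
  g <- deltaMaeGrid(mdl, prep$volumes, cohort$participants$age, cfg)
  o <- occlusionOrigins(dim(prep$volumes@mask), cfg)
  peak <- o[which.max(g), ]
  thal <- atlas@labels == atlas@regionTable["thalamus"]
  block <- thal[peak[1]:(peak[1] + 4), peak[2]:(peak[2] + 4),
                peak[3]:(peak[3] + 4)]
  expect_gt(sum(block), 0)

  # mean saliency inside the informative region exceeds outside
  sal <- postprocessSaliency(g, cfg, dim(prep$volumes@mask))
  brain <- atlas@labels > 0
  expect_gt(mean(sal[thal]), mean(sal[brain & !thal]))
})

test_that("post-processing clips, rescales to {0,1} and zero-pads the slab", {
  cfg <- saliencyConfig(block = 5, excludedSuperiorSlices = 6,
                        positionsPerAxis = 5)
  expect_warning(m <- postprocessSaliency(array(3, c(5, 5, 5)), cfg,
                                          c(24, 24, 24)),
                 "constant")
  expect_true(all(m == 0))

  set.seed(2)
  g <- array(rnorm(125), c(5, 5, 5))
  m <- postprocessSaliency(g, cfg, c(24, 24, 24))
  expect_equal(min(m), 0)
  expect_equal(max(m), 1)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(m[, , 19:24] == 0))
})

test_that("clipping and min-max scaling keep the peak location stable", {
  # smooth bump: the top-5% plateau after clipping clusters at the peak
  cfg <- saliencyConfig(block = 5, excludedSuperiorSlices = 0,
                        positionsPerAxis = 7)
  ax <- seq_len(7)
  g <- outer(outer(exp(-(ax - 5)^2 / 4), exp(-(ax - 3)^2 / 4)),
             exp(-(ax - 4)^2 / 4))
  target <- c(35, 35, 35)
  m <- postprocessSaliency(g, cfg, target)
  rawPeak <- (c(5, 3, 4) - 0.5) / 7 * 35   # grid peak in volume coords
  upPeak <- which(m == max(m), arr.ind = TRUE)[1, ]
  expect_true(all(abs(upPeak - rawPeak) <= 5))  # within one block spacing
})

test_that("per-bin saliency maps are produced for every age bin", {
  cohort <- tinyCohort()
  prep <- prepareModelData(cohort, "mre")
  cfg <- saliencyConfig(block = 6, excludedSuperiorSlices = 2,
                        positionsPerAxis = 2, nAgeBins = 2)
  meanModel <- function(v)
    vapply(v@data, function(x) 40 + 20 * mean(x), numeric(1))
  sal <- saliencyByAgeBin(meanModel, prep$volumes,
                          cohort$participants$age, cfg)
  expect_length(sal$maps, 2)
  expect_true(all(vapply(sal$maps, function(m)
    identical(dim(m), dim(prep$volumes@mask)), TRUE)))
})
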