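cubeMap <- function(gp, gl, maskVal = TRUE) {
  d <- c(3, 3, 3)
  new("ComplexModulusMap", gStorage = array(gp, d), gLoss = array(gl, d),
      mask = array(maskVal, d))
}

test_that("stiffness and damping match hand-evaluated formulas", {
  # elastic limit: G'' = 0 gives mu = G', xi = 0
  p <- computeProperties(cubeMap(1, 0))
  expect_equal(p@mu[1], 1)
  expect_equal(p@xi[1], 0)

  p <- computeProperties(cubeMap(2, 1))
  expect_equal(p@xi[1], 0.25)

  # |G*| = sqrt(2): mu = 2*2/(1+sqrt(2))
  p <- computeProperties(cubeMap(1, 1))
  expect_equal(p@mu[1], 4 / (1 + sqrt(2)), tolerance = 1e-12)
  expect_equal(p@xi[1], 0.5)

  # outside-mask voxels are zero
  m <- cubeMap(1, 1)
  m@mask[1, 1, 1] <- FALSE
  p <- computeProperties(m)
  expect_identical(p@mu[1, 1, 1], 0)
})

test_that("zero storage modulus inside the mask is rejected", {
  m <- new("ComplexModulusMap", gStorage = array(1, c(2, 2, 2)),
           gLoss = array(0, c(2, 2, 2)), mask = array(TRUE, c(2, 2, 2)))
  m@gStorage[1] <- 0  # direct slot edit bypasses construction validity
  expect_error(computeProperties(m), "zero")
})

test_that("invertProperties is the exact algebraic inverse", {
  iv <- invertProperties(1, 0)
  expect_equal(iv$gStorage, 1)
  expect_equal(iv$gLoss, 0)

  iv <- invertProperties(4 / (1 + sqrt(2)), 0.5)
  expect_equal(iv$gStorage, 1, tolerance = 1e-12)
  expect_equal(iv$gLoss, 1, tolerance = 1e-12)

  set.seed(1)
  mu <- runif(1000, 0.1, 10)
  xi <- runif(1000, 0, 0.9)
  iv <- invertProperties(mu, xi)
  gabs <- sqrt(iv$gStorage^2 + iv$gLoss^2)
  mu2 <- 2 * gabs^2 / (iv$gStorage + gabs)
  xi2 <- iv$gLoss / (2 * iv$gStorage)
  expect_lt(max(abs(mu2 - mu)), 1e-10)
  expect_lt(max(abs(xi2 - xi)), 1e-10)
})

test_that("mu is homogeneous of degree 1 and xi scale-invariant", {
  set.seed(2)
  gp <- runif(50, 0.5, 5); gl <- runif(50, 0, 3)
  for (c0 in c(0.3, 2, 17)) {
    d <- c(50, 1, 1)
    p1 <- computeProperties(new("ComplexModulusMap",
      gStorage = array(gp, d), gLoss = array(gl, d),
      mask = array(TRUE, d)))
    p2 <- computeProperties(new("ComplexModulusMap",
      gStorage = array(c0 * gp, d), gLoss = array(c0 * gl, d),
      mask = array(TRUE, d)))
    expect_equal(as.vector(p2@mu), c0 * as.vector(p1@mu), tolerance = 1e-12)
    expect_equal(as.vector(p2@xi), as.vector(p1@xi), tolerance = 1e-12)
  }
})

test_that("mu increases monotonically in G' at fixed xi", {
  for (xi in c(0, 0.2, 0.5, 0.9)) {
    gp <- seq(0.2, 8, length.out = 60)
    gl <- 2 * xi * gp
    gabs <- sqrt(gp^2 + gl^2)
    mu <- 2 * gabs^2 / (gp + gabs)
    expect_true(all(diff(mu) > 0))
  }
})

test_that("dataset normalization pools channels to mean 0, sd 1", {
  set.seed(3)
  d <- c(6, 6, 6)
  mask <- array(TRUE, d)
  vols <- new("BrainVolumes",
    data = lapply(1:4, function(i)
      array(rnorm(2 * prod(d), mean = i), c(2, d))),
    mask = mask, channels = c("mu", "xi"))
  nr <- normalizeVolumes(vols, "dataset")
  idx <- which(mask)
  for (ch in 1:2) {
    pooled <- unlist(lapply(nr$volumes@data, function(v) v[ch, , , ][idx]))
    expect_lt(abs(mean(pooled)), 1e-12)
    expect_lt(abs(sqrt(mean((pooled - mean(pooled))^2)) - 1), 1e-12)
  }

  # applying the stored state is the affine map (x - loc) / scale
  newVol <- new("BrainVolumes", data = vols@data[1], mask = mask,
                channels = c("mu", "xi"))
  applied <- normalizeVolumes(newVol, "dataset", state = nr$state)
  raw <- vols@data[[1]][1, , , ][idx]
  expect_equal(applied$volumes@data[[1]][1, , , ][idx],
               (raw - nr$state@location["mu"]) / nr$state@scale["mu"],
               ignore_attr = TRUE, tolerance = 1e-12)

  # de-normalization recovers the input
  back <- applied$volumes@data[[1]][1, , , ][idx] * nr$state@scale["mu"] +
    nr$state@location["mu"]
  expect_lt(max(abs(back - raw)), 1e-12)
})

test_that("image normalization zero-centres every single volume", {
  set.seed(4)
  d <- c(5, 5, 5)
  mask <- array(runif(prod(d)) > 0.3, d)
  vols <- new("BrainVolumes",
    data = lapply(1:3, function(i) array(rnorm(prod(d), i, i), c(1, d))),
    mask = mask, channels = "mu")
  nr <- normalizeVolumes(vols, "image")
  for (v in nr$volumes@data) {
    x <- v[1, , , ][which(mask)]
    expect_lt(abs(mean(x)), 1e-12)
    expect_equal(sd(x), 1, tolerance = 1e-6)
  }
})

test_that("zero-variance channels are reported by name", {
  d <- c(4, 4, 4)
  vols <- new("BrainVolumes", data = list(array(1, c(1, d))),
              mask = array(TRUE, d), channels = "xi")
  expect_error(normalizeVolumes(vols, "dataset"), "xi")
})

test_that("coverage masking zeroes exactly the out-of-mask voxels", {
  set.seed(5)
  d <- c(6, 6, 6)
  anat <- array(runif(prod(d), 1, 2), d)
  full <- array(TRUE, d)
  expect_identical(applyCoverageMask(anat, full), anat)
  empty <- array(FALSE, d)
  expect_true(all(applyCoverageMask(anat, empty) == 0))
  m <- array(runif(prod(d)) > 0.5, d)
  out <- applyCoverageMask(anat, m)
  expect_equal(sum(out != 0), sum(m))
  expect_error(applyCoverageMask(anat, array(TRUE, c(2, 2, 2))), "shape")
})

test_that("normalization state survives a JSON round trip", {
  st <- new("NormalizationState", mode = "dataset",
            location = c(mu = 2.5, xi = 0.25), scale = c(mu = 0.3, xi = 0.05))
  f <- tempfile(fileext = ".json")
  writeNormalizationState(st, f)
  st2 <- readNormalizationState(f)
  expect_equal(st2@location, st@location)
  expect_equal(st2@scale, st@scale)
  expect_identical(st2@mode, "dataset")
})

test_that("volumes survive a NIfTI round trip with voxel size recorded", {
  set.seed(6)
  v <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(v, f, voxelSizeMm = 2)
  v2 <- readVolume(f)
  expect_equal(v2, v, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(RNifti::pixdim(RNifti::readNifti(f))[1]), 2)
})
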