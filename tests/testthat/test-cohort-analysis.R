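test_that("Theil-Sen bias fit recovers exact linear relations", {
  ages <- c(60, 62, 65, 70, 71, 75, 80)
  b <- fitBias(ages, ages)
  expect_equal(b@slope, 1, tolerance = 1e-12)
  expect_equal(b@intercept, 0, tolerance = 1e-12)

  b <- fitBias(0.5 * ages + 10, ages)
  expect_equal(b@slope, 0.5, tolerance = 1e-12)
  expect_equal(b@intercept, 10, tolerance = 1e-12)

  expect_error(fitBias(c(1, 2), c(60, 61)), "3 control")
  expect_error(fitBias(c(1, 2, 3), c(60, 60, 60)), "equal")
})

test_that("Theil-Sen slope is immune to one wild outlier among nine", {
  ages <- seq(50, 82, by = 4)               # 9 exact-linear points
  pred <- 0.7 * ages + 5
  pred[4] <- pred[4] + 200                   # wild outlier
  b <- fitBias(pred, ages)
  expect_equal(b@slope, 0.7, tolerance = 1e-12)

  # brute-force median of all pairwise slopes as the independent oracle
  slopes <- c()
  for (i in 1:8) for (j in (i + 1):9)
    slopes <- c(slopes, (pred[j] - pred[i]) / (ages[j] - ages[i]))
  expect_equal(b@slope, median(slopes), tolerance = 1e-12)
})

test_that("affine prediction rules give exactly zero corrected BAGs", {
  set.seed(1)
  ages <- runif(20, 55, 85)
  pred <- 0.6 * ages + 13
  b <- fitBias(pred, ages)
  bag <- computeBag(pred, ages, b)
  expect_lt(max(abs(bag$bag)), 1e-10)
  expect_equal(bag$corrected, ages + bag$bag)

  # identity bias, prediction = age + 5 -> BAG = 5
  bId <- fitBias(ages, ages)
  bag5 <- computeBag(ages + 5, ages, bId)
  expect_equal(bag5$bag, rep(5, 20), tolerance = 1e-10)
})

test_that("control BAGs centre near zero under symmetric noise", {
  set.seed(2)
  ages <- runif(60, 50, 85)
  pred <- 0.8 * ages + 8 + rnorm(60, 0, 1.5)
  b <- fitBias(pred, ages)
  bag <- computeBag(pred, ages, b)
  expect_lt(abs(median(bag$bag)), 0.75)
})

test_that("leave-cohort-out training excludes controls and patients", {
  atlas <- tinyAtlas()
  spec <- cohortSpec(nHealthy = 20, nMci = 5, nAd = 0, nControlMci = 5,
                     nControlAd = 0, seed = 13)
  cohort <- generateCohort(spec, atlas)
  fit <- leaveCohortOutRefit(cohort, "MCI", family = "pca_gp")
  idx <- fit$indices
  expect_length(idx$train, 15)
  expect_length(idx$control, 5)
  expect_length(idx$disease, 5)
  expect_length(intersect(idx$train, c(idx$control, idx$disease)), 0)
  part <- cohort$participants
  expect_true(all(part$cohort[idx$train] == "healthy"))
  expect_true(all(part$cohort[idx$disease] == "MCI"))

  # deterministic per seed
  fit2 <- leaveCohortOutRefit(cohort, "MCI", family = "pca_gp")
  expect_identical(fit$controlPredictions, fit2$controlPredictions)

  expect_error(leaveCohortOutRefit(cohort, "AD"), "no subjects|no matched")
})

test_that("regional profiles share one fixed region order", {
  atlas <- tinyAtlas()
  spec <- cohortSpec(nHealthy = 14, nMci = 0, nAd = 4, nControlMci = 0,
                     nControlAd = 5, seed = 17)
  cohort <- generateCohort(spec, atlas)
  prof <- regionalProfiles(cohort, atlas, "AD", family = "pca_gp",
                           modality = "stiffness")
  expect_identical(colnames(prof)[-(1:2)], regionNames())
  expect_equal(nrow(prof), 9)
  expect_length(attr(prof, "skipped"), 0)
})

test_that("cohort profiles average entrywise and ignore subject order", {
  prof <- data.frame(id = c("a", "b"), cohort = c("AD", "AD"),
                     matrix(c(1:12, 13:24), 2, byrow = TRUE,
                            dimnames = list(NULL, regionNames())),
                     check.names = FALSE, stringsAsFactors = FALSE)
  cp <- cohortProfile(prof, "AD")
  expect_equal(unname(cp), (c(1:12) + c(13:24)) / 2)
  expect_equal(cohortProfile(prof[2:1, ], "AD"), cp)
  single <- cohortProfile(prof[1, ], "AD")
  expect_equal(unname(single), as.numeric(1:12))
  expect_error(cohortProfile(prof, "MCI"), "no profiles")
})

test_that("profile similarity flags resemblance and rejects degeneracy", {
  ref <- setNames(as.numeric(1:12), regionNames())
  hp <- data.frame(id = c("same", "anti", "flat"),
                   rbind(1:12, -(1:12), rep(1, 12)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(hp)[-1] <- regionNames()
  expect_warning(fl <- flagAtRisk(hp, ref, threshold = 0.7),
                 "zero-variance")
  expect_identical(fl$id[1], "same")
  expect_equal(fl$similarity[fl$id == "same"], 1)
  expect_true(fl$flagged[fl$id == "same"])
  expect_equal(fl$similarity[fl$id == "anti"], -1)
  expect_false(fl$flagged[fl$id == "anti"])
  expect_false("flat" %in% fl$id)
})

test_that("normality gate dispatches to the matching test", {
  # identical groups: no significance whatever the branch
  x <- c(1.2, 1.9, 2.4, 3.1, 3.3, 4.0)
  r <- compareGroups(x, x, paired = FALSE)
  expect_gt(r@p, 0.05)

  set.seed(3)
  a <- rnorm(50); b <- rnorm(50, 2)
  r <- compareGroups(a, b)
  expect_identical(r@test, "independent t-test")
  expect_lt(r@p, 0.05)

  set.seed(4)
  h1 <- rcauchy(50); h2 <- rcauchy(50)
  r <- compareGroups(h1, h2)
  expect_identical(r@test, "Mann-Whitney U")

  r <- compareGroups(a, b + rnorm(50), paired = TRUE)
  expect_identical(r@test, "paired t-test")
  h3 <- rcauchy(50)
  r <- compareGroups(h1, h3, paired = TRUE)
  expect_identical(r@test, "Wilcoxon signed-rank")

  expect_error(compareGroups(a, b[1:10], paired = TRUE), "equal lengths")
  expect_error(compareGroups(a[1:2], b))
})
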