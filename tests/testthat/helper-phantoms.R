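# Shared phantom fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- build()
  .fixtureCache[[key]]
}

deskAtlas <- function() {
  fixture("atlas24", function() buildAtlas(c(24, 24, 24), seed = 0))
}

# healthy desk cohort used by the model-family and ordering tests
deskCohort <- function() {
  fixture("cohort60", function() {
    generateCohort(cohortSpec(nHealthy = 60, seed = 11), deskAtlas())
  })
}

# noiseless cohort: masked means exactly affine in age
noiselessCohort <- function() {
  fixture("cohortNoiseless", function() {
    generateCohort(cohortSpec(nHealthy = 12, noiseSd = 0, seed = 4),
                   deskAtlas())
  })
}

tinyAtlas <- function() {
  fixture("atlas16", function() buildAtlas(c(16, 16, 16), seed = 0))
}

tinyCohort <- function() {
  fixture("cohortTiny", function() {
    generateCohort(cohortSpec(nHealthy = 8, seed = 2), tinyAtlas())
  })
}

# train/test preparation used in several files
prepSplit <- function(cohort, modality, seed = 1) {
  part <- cohort$participants
  sp <- splitDataset(part, seed = seed)
  trIdx <- match(sp$train, part$participant_id)
  teIdx <- match(sp$test, part$participant_id)
  tr <- prepareModelData(cohort, modality, trIdx)
  te <- prepareModelData(cohort, modality, teIdx, state = tr$state)
  list(train = tr$volumes, test = te$volumes,
       agesTrain = part$age[trIdx], agesTest = part$age[teIdx])
}

randomUnitRows <- function(n, d) {
  f <- matrix(rnorm(n * d), n)
  f / sqrt(rowSums(f^2))
}
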