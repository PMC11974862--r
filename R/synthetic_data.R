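#' Separable Gaussian smoothing of a 3D field
#'
#' Used to give generated noise fields the spatial autocorrelation of
#' reconstructed elastography maps. Zero padding at the edges; intended for
#' zero-mean noise, where edge attenuation is immaterial.
#'
#' @param arr 3D numeric array.
#' @param sigma Kernel width in voxels; 0 returns the input unchanged.
#' @return Smoothed array of the same shape.
#' @keywords internal
gaussianSmooth3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  smooth1 <- function(a, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, nrow = d[1])
    out <- matrix(0, d[1], ncol(m))
    for (j in -r:r) {
      src <- (1 + max(0, j)):(d[1] + min(0, j))
      dst <- src - j
      out[dst, ] <- out[dst, ] + w[j + r + 1] * m[src, ]
    }
    aperm(array(out, d), order(perm))
  }
  for (ax in 1:3) arr <- smooth1(arr, ax)
  arr
}

# Ellipsoid geometry of each phantom region in normalized coordinates
# (each axis mapped to [-1, 1] at the voxel centers). Paired structures are
# mirrored about the mid-sagittal plane. Radii are chosen so region volumes
# as fractions of the brain track the relative subcortical volumes of
# common-space segmentations (cerebellum ~11% of brain, thalamus ~1.7%,
# pallidum ~0.4%, nucleus accumbens ~0.13%, i.e. cerebellum largest and
# accumbens smallest). Regions are carved in this order (large to small)
# so small structures survive overlaps intact.
.regionGeometry <- function() {
  list(
    cerebellum  = list(center = c(0.00, -0.45, -0.55), radii = c(0.57, 0.42, 0.35), paired = FALSE),
    `brain-stem` = list(center = c(0.00, -0.05, -0.50), radii = c(0.18, 0.18, 0.45), paired = FALSE),
    thalamus    = list(center = c(0.20, -0.08,  0.00), radii = c(0.16, 0.22, 0.19), paired = TRUE),
    putamen     = list(center = c(0.32,  0.08,  0.02), radii = c(0.11, 0.20, 0.14), paired = TRUE),
    hippocampus = list(center = c(0.30, -0.20, -0.15), radii = c(0.10, 0.20, 0.13), paired = TRUE),
    `ventral-diencephalon` = list(center = c(0.12, -0.12, -0.25), radii = c(0.11, 0.14, 0.16), paired = TRUE),
    caudate     = list(center = c(0.16,  0.15,  0.12), radii = c(0.09, 0.18, 0.13), paired = TRUE),
    pallidum    = list(center = c(0.24,  0.10,  0.00), radii = c(0.10, 0.13, 0.12), paired = TRUE),
    amygdala    = list(center = c(0.28, -0.02, -0.18), radii = c(0.10, 0.10, 0.10), paired = TRUE),
    `nucleus-accumbens` = list(center = c(0.14, 0.24, -0.12), radii = c(0.07, 0.09, 0.08), paired = TRUE)
  )
}

#' Build a deterministic phantom atlas
#'
#' Lays out 12 labelled regions (ten subcortical structures plus grey and
#' white matter) as ellipsoidal components inside a brain-shaped ellipsoid.
#' Paired structures are mirrored about the mid-sagittal plane so their
#' voxel counts are exactly equal. Among the ten subcortical structures the
#' cerebellum is the largest and the nucleus accumbens the smallest. The
#' seed jitters region centers slightly (identically for both members of a
#' pair) so different seeds give different but reproducible atlases.
#'
#' @param gridShape Integer vector (X, Y, Z); each dimension >= 16.
#' @param voxelSizeMm Voxel edge length in mm (default 2, the common-space
#'   resolution of 91 x 109 x 91 volumes).
#' @param seed Integer seed.
#' @return A [PhantomAtlas-class].
#' @export
buildAtlas <- function(gridShape, voxelSizeMm = 2, seed = 0L) {
  gridShape <- as.integer(gridShape)
  stopifnot(length(gridShape) == 3L)
  if (any(gridShape < 16L))
    stop("each grid dimension must be >= 16")
  X <- gridShape[1]; Y <- gridShape[2]; Z <- gridShape[3]

  # voxel-center coordinates normalized to [-1, 1] per axis
  ux <- (seq_len(X) - (X + 1) / 2) / (X / 2)
  uy <- (seq_len(Y) - (Y + 1) / 2) / (Y / 2)
  uz <- (seq_len(Z) - (Z + 1) / 2) / (Z / 2)

  labels <- array(0L, gridShape)
  regions <- setNames(seq_along(regionNames()), regionNames())

  inEllipsoid <- function(center, radii) {
    dx <- (ux - center[1]) / radii[1]
    dy <- (uy - center[2]) / radii[2]
    dz <- (uz - center[3]) / radii[3]
    outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= 1
  }
  nearestVoxel <- function(center) {
    i <- pmin(pmax(round(center[1] * X / 2 + (X + 1) / 2), 1), X)
    j <- pmin(pmax(round(center[2] * Y / 2 + (Y + 1) / 2), 1), Y)
    k <- pmin(pmax(round(center[3] * Z / 2 + (Z + 1) / 2), 1), Z)
    c(i, j, k)
  }

  brain <- inEllipsoid(c(0, 0, 0), c(0.92, 0.92, 0.92))
  labels[brain] <- regions["grey-matter"]
  labels[brain & inEllipsoid(c(0, 0, 0.02), c(0.62, 0.62, 0.60))] <-
    regions["white-matter"]

  set.seed(seed)
  geom <- .regionGeometry()
  # carve large -> small so small structures survive overlaps
  for (nm in names(geom)) {
    g <- geom[[nm]]
    jit <- c(abs(rnorm(1, 0, 0.015)), rnorm(2, 0, 0.015))
    ctr <- g$center + jit * c(sign(g$center[1] + 1e-9), 1, 1)
    sides <- if (g$paired) list(ctr, ctr * c(-1, 1, 1)) else {
      list(c(0, ctr[2], ctr[3]))
    }
    placed <- FALSE
    for (s in sides) {
      sel <- inEllipsoid(s, g$radii)
      if (!any(sel)) {
        nv <- nearestVoxel(s)
        sel[nv[1], nv[2], nv[3]] <- TRUE
      }
      if (any(sel)) placed <- TRUE
      labels[sel] <- regions[nm]
    }
    if (!placed)
      stop(sprintf("grid too small: region '%s' does not fit", nm))
  }
  for (nm in regionNames()) {
    if (!any(labels == regions[nm]))
      stop(sprintf("grid too small: region '%s' does not fit", nm))
  }
  new("PhantomAtlas", labels = labels, regionTable = regions,
      voxelSizeMm = voxelSizeMm, seed = as.integer(seed))
}

#' Default cohort specification for phantom generation
#'
#' Bundles every knob of the generator. Defaults encode the study
#' conditions the analysis assumes: a young-skewed two-component uniform
#' age mixture (0.5 U\[18,35\] + 0.5 U\[35,90\]), whole-brain aging trends of
#' -0.33 %/yr in stiffness and +0.34 %/yr in damping ratio, regionally
#' heterogeneous baseline mechanics, and disease signatures (damping
#' elevation in hippocampus/brain stem for MCI; stiffness reduction in
#' thalamus/pallidum for AD).
#'
#' @param nHealthy,nMci,nAd Cohort sizes.
#' @param ageRange Admissible age range in years.
#' @param ageMixture List with `weights` (summing to 1) and `bounds`
#'   (matrix, one \[min, max\] row per component).
#' @param betaMu,betaXi Fractional change per year of stiffness / damping.
#' @param ageRef Reference age at which regions take their baseline values.
#' @param baselineMu,baselineXi Named per-region baselines (kPa /
#'   dimensionless). Literature-plausible values; freely configurable.
#' @param regionalRateModifiers Named per-region multiplier on the aging
#'   rates (default 1 everywhere).
#' @param diseaseEffects Per-cohort list of effects, each
#'   `list(region =, property = "mu"|"xi", offset =)` with `offset` an
#'   additive fractional change.
#' @param diseaseAgeRange Age range disease-cohort subjects are drawn from
#'   (neurodegenerative cohorts are elderly).
#' @param noiseSd Voxel noise scale, as a fraction of the regional baseline.
#' @param smoothSigma Gaussian width (voxels) applied to the noise field.
#' @param anatBeta Fractional per-year age slope of the anatomical channel
#'   (weaker than the mechanical trends by design).
#' @param sexRatio Named vector of F:M weights (default 183:128).
#' @param nControlMci,nControlAd Number of healthy subjects labelled as
#'   matched controls for each disease cohort (the oldest healthy subjects
#'   are used, mirroring elderly disease cohorts).
#' @param seed Integer seed.
#' @return A list with class `"CohortSpec"`.
#' @export
cohortSpec <- function(nHealthy = 60L, nMci = 0L, nAd = 0L,
                       ageRange = c(18, 90),
                       ageMixture = list(weights = c(0.5, 0.5),
                                         bounds = rbind(c(18, 35), c(35, 90))),
                       betaMu = -0.0033, betaXi = 0.0034, ageRef = 45,
                       baselineMu = NULL, baselineXi = NULL,
                       regionalRateModifiers = NULL,
                       diseaseEffects = list(
                         MCI = list(
                           list(region = "hippocampus", property = "xi", offset = 0.10),
                           list(region = "brain-stem", property = "xi", offset = 0.08)),
                         AD = list(
                           list(region = "thalamus", property = "mu", offset = -0.15),
                           list(region = "pallidum", property = "mu", offset = -0.08))),
                       diseaseAgeRange = c(60, 85),
                       noiseSd = 0.05, smoothSigma = 1,
                       anatBeta = -0.00033,
                       sexRatio = c(F = 183, M = 128),
                       nControlMci = 12L, nControlAd = 12L,
                       seed = 1L) {
  rn <- regionNames()
  if (is.null(baselineMu))
    baselineMu <- setNames(c(2.7, 2.9, 2.8, 3.0, 2.5, 2.6, 2.7, 2.9,
                             3.2, 2.3, 2.6, 3.0), rn)
  if (is.null(baselineXi))
    baselineXi <- setNames(c(0.26, 0.25, 0.27, 0.24, 0.28, 0.27, 0.26,
                             0.25, 0.22, 0.24, 0.27, 0.23), rn)
  if (is.null(regionalRateModifiers))
    regionalRateModifiers <- setNames(rep(1, 12), rn)
  stopifnot(all(baselineMu > 0), all(baselineXi > 0 & baselineXi < 1),
            identical(sort(names(baselineMu)), sort(rn)),
            identical(sort(names(baselineXi)), sort(rn)))
  if (abs(sum(ageMixture$weights) - 1) > 1e-8)
    stop("age mixture weights must sum to 1")
  structure(list(
    nHealthy = as.integer(nHealthy), nMci = as.integer(nMci),
    nAd = as.integer(nAd), ageRange = ageRange, ageMixture = ageMixture,
    betaMu = betaMu, betaXi = betaXi, ageRef = ageRef,
    baselineMu = baselineMu[rn], baselineXi = baselineXi[rn],
    regionalRateModifiers = regionalRateModifiers[rn],
    diseaseEffects = diseaseEffects, diseaseAgeRange = diseaseAgeRange,
    noiseSd = noiseSd, smoothSigma = smoothSigma, anatBeta = anatBeta,
    sexRatio = sexRatio, nControlMci = as.integer(nControlMci),
    nControlAd = as.integer(nControlAd), seed = as.integer(seed)),
    class = "CohortSpec")
}

#' Sample ages from the two-component uniform mixture
#'
#' @param n Number of ages (>= 0).
#' @param ageMixture List with `weights` and `bounds` as in [cohortSpec()].
#' @param seed Integer seed.
#' @return Numeric vector of n ages.
#' @export
sampleAges <- function(n, ageMixture = cohortSpec()$ageMixture, seed = 1L) {
  stopifnot(n >= 0)
  if (abs(sum(ageMixture$weights) - 1) > 1e-8)
    stop("age mixture weights must sum to 1")
  if (n == 0) return(numeric(0))
  set.seed(seed)
  comp <- sample.int(length(ageMixture$weights), n, replace = TRUE,
                     prob = ageMixture$weights)
  lo <- ageMixture$bounds[comp, 1]
  hi <- ageMixture$bounds[comp, 2]
  runif(n, lo, hi)
}

# Per-region target (mu, xi) for one subject: baseline, linear aging trend,
# optional disease offsets.
.regionTargets <- function(spec, age, cohort) {
  rn <- regionNames()
  dAge <- age - spec$ageRef
  mod <- spec$regionalRateModifiers
  mu <- spec$baselineMu * (1 + mod * spec$betaMu * dAge)
  xi <- spec$baselineXi * (1 + mod * spec$betaXi * dAge)
  if (cohort != "healthy" && !is.null(spec$diseaseEffects[[cohort]])) {
    for (eff in spec$diseaseEffects[[cohort]]) {
      if (eff$property == "mu") {
        mu[eff$region] <- mu[eff$region] * (1 + eff$offset)
      } else {
        xi[eff$region] <- xi[eff$region] * (1 + eff$offset)
      }
    }
  }
  list(mu = mu[rn], xi = xi[rn])
}

#' Generate a subject's complex modulus map
#'
#' Builds the target stiffness/damping fields from the atlas and cohort
#' spec — per region r, mu_r(age) = baselineMu\[r\] (1 + modifier_r betaMu
#' (age - ageRef)), analogously for xi, plus any disease offsets for the
#' subject's cohort — adds smoothed voxel noise, clips to the physical
#' ranges (mu > 0, 0 < xi < 1), and emits the result as storage/loss
#' modulus components via [invertProperties()], so downstream property
#' computation is exercised on every phantom.
#'
#' @param atlas A [PhantomAtlas-class].
#' @param age Subject age in years (within the spec's range).
#' @param cohort One of "healthy", "MCI", "AD".
#' @param spec A [cohortSpec()].
#' @param seed Integer seed for the noise field.
#' @return A [ComplexModulusMap-class]; the mask is the atlas support.
#' @export
generateSubjectMaps <- function(atlas, age, cohort = "healthy",
                                spec = cohortSpec(), seed = 1L) {
  stopifnot(is(atlas, "PhantomAtlas"),
            cohort %in% c("healthy", "MCI", "AD"))
  if (age < spec$ageRange[1] || age > spec$ageRange[2])
    stop("age outside the configured range")
  lab <- atlas@labels
  mask <- lab > 0
  tg <- .regionTargets(spec, age, cohort)
  mu <- array(0, dim(lab)); xi <- array(0, dim(lab))
  baseMuVox <- array(0, dim(lab)); baseXiVox <- array(0, dim(lab))
  for (nm in regionNames()) {
    sel <- lab == atlas@regionTable[nm]
    mu[sel] <- tg$mu[nm]
    xi[sel] <- tg$xi[nm]
    baseMuVox[sel] <- spec$baselineMu[nm]
    baseXiVox[sel] <- spec$baselineXi[nm]
  }
  if (spec$noiseSd > 0) {
    set.seed(seed)
    e1 <- gaussianSmooth3d(array(rnorm(length(lab)), dim(lab)),
                           spec$smoothSigma)
    e2 <- gaussianSmooth3d(array(rnorm(length(lab)), dim(lab)),
                           spec$smoothSigma)
    mu <- mu + spec$noiseSd * baseMuVox * e1
    xi <- xi + spec$noiseSd * baseXiVox * e2
  }
  eps <- 1e-6
  if (any(mu[mask] <= 0) || any(xi[mask] <= 0) || any(xi[mask] >= 1))
    warning("generated properties outside physical range; clipping")
  mu[mask] <- pmax(mu[mask], eps)
  xi[mask] <- pmin(pmax(xi[mask], eps), 1 - eps)
  mu[!mask] <- 0; xi[!mask] <- 0

  g <- invertProperties(ifelse(mask, mu, 1), ifelse(mask, xi, 0))
  gp <- array(0, dim(lab)); gl <- array(0, dim(lab))
  gp[mask] <- g$gStorage[mask]
  gl[mask] <- g$gLoss[mask]
  new("ComplexModulusMap", gStorage = gp, gLoss = gl, mask = mask)
}

#' Generate a subject's anatomical channel
#'
#' A monotone transform of the region labels (so structures are visible)
#' with a weak, age-dependent grey/white-matter contrast change
#' (`anatBeta` per year, opposite sign in GM and WM, emulating
#' atrophy-like intensity shifts) plus smoothed noise; masked to the
#' mechanical coverage. Because the age effect is a within-image contrast,
#' it survives the per-image normalization applied to anatomical data,
#' giving anatomical-vs-mechanical model comparisons a meaningful but
#' clearly weaker-signal reference channel.
#'
#' @inheritParams generateSubjectMaps
#' @return 3D numeric array.
#' @export
generateAnatomical <- function(atlas, age, spec = cohortSpec(), seed = 1L) {
  lab <- atlas@labels
  mask <- lab > 0
  base <- array(0, dim(lab))
  base[mask] <- 0.5 + 0.05 * lab[mask]
  contrast <- array(0, dim(lab))
  contrast[lab == atlas@regionTable["grey-matter"]] <- 1
  contrast[lab == atlas@regionTable["white-matter"]] <- -1
  anat <- base * (1 + spec$anatBeta * (age - spec$ageRef) * contrast)
  if (spec$noiseSd > 0) {
    set.seed(seed)
    e <- gaussianSmooth3d(array(rnorm(length(lab)), dim(lab)),
                          spec$smoothSigma)
    anat <- anat + spec$noiseSd * base * e
  }
  applyCoverageMask(anat, mask)
}

#' Generate a full phantom cohort
#'
#' Draws ages, sexes and cohort labels, generates every subject's modulus
#' pair and anatomical volume, labels matched-control subsets for the MCI
#' and AD cohorts (the oldest healthy subjects, mirroring elderly disease
#' cohorts), and optionally writes everything to disk: per subject
#' `<id>_gstorage.nii.gz`, `<id>_gloss.nii.gz`, `<id>_T1w.nii.gz`, plus
#' `atlas.nii.gz` and a tab-separated `participants.tsv` with columns
#' participant_id, age, sex, cohort, control_for. Fully reproducible from
#' (spec, atlas).
#'
#' @param spec A [cohortSpec()].
#' @param atlas A [PhantomAtlas-class].
#' @param outputDir Optional directory to write volumes and the table to.
#' @return List with `participants` (data.frame) and `subjects` (list of
#'   `list(modulus =, anatomical =)`), plus the atlas.
#' @export
generateCohort <- function(spec, atlas, outputDir = NULL) {
  nH <- spec$nHealthy; nM <- spec$nMci; nA <- spec$nAd
  n <- nH + nM + nA
  agesH <- sampleAges(nH, spec$ageMixture, seed = spec$seed)
  set.seed(spec$seed + 1L)
  agesD <- runif(nM + nA, spec$diseaseAgeRange[1], spec$diseaseAgeRange[2])
  ages <- c(agesH, agesD)
  cohort <- c(rep("healthy", nH), rep("MCI", nM), rep("AD", nA))
  set.seed(spec$seed + 2L)
  sex <- sample(names(spec$sexRatio), n, replace = TRUE,
                prob = spec$sexRatio / sum(spec$sexRatio))
  id <- sprintf("sub-%03d", seq_len(n))

  controlFor <- rep("none", n)
  ordH <- order(agesH, decreasing = TRUE)
  nCm <- min(spec$nControlMci, nH)
  nCa <- min(spec$nControlAd, max(0, nH - nCm))
  if (nCm > 0) controlFor[ordH[seq_len(nCm)]] <- "MCI"
  if (nCa > 0) controlFor[ordH[nCm + seq_len(nCa)]] <- "AD"

  participants <- data.frame(participant_id = id, age = ages, sex = sex,
                             cohort = cohort, control_for = controlFor,
                             stringsAsFactors = FALSE)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    subjects[[i]] <- list(
      modulus = generateSubjectMaps(atlas, ages[i], cohort[i], spec,
                                    seed = sseed),
      anatomical = generateAnatomical(atlas, ages[i], spec,
                                      seed = sseed + 1L))
  }
  res <- list(participants = participants, subjects = subjects,
              atlas = atlas)

  if (!is.null(outputDir)) {
    if (!dir.exists(outputDir) &&
        !dir.create(outputDir, recursive = TRUE, showWarnings = FALSE))
      stop(sprintf("cannot create output directory '%s'", outputDir))
    vs <- atlas@voxelSizeMm
    writeVolume(atlas@labels, file.path(outputDir, "atlas.nii.gz"), vs)
    for (i in seq_len(n)) {
      writeVolume(subjects[[i]]$modulus@gStorage,
                  file.path(outputDir, paste0(id[i], "_gstorage.nii.gz")), vs)
      writeVolume(subjects[[i]]$modulus@gLoss,
                  file.path(outputDir, paste0(id[i], "_gloss.nii.gz")), vs)
      writeVolume(subjects[[i]]$anatomical,
                  file.path(outputDir, paste0(id[i], "_T1w.nii.gz")), vs)
    }
    write.table(participants, file.path(outputDir, "participants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
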