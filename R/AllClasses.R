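#' @import methods
#' @importFrom stats median quantile rnorm runif sd setNames cor coef
#' @importFrom stats dist var lm
#' @importFrom utils head write.table read.delim combn
NULL

#' Canonical region names used throughout the package
#'
#' Ten deep grey-matter / subcortical structures plus whole grey matter and
#' white matter, in the fixed order every regional profile uses.
#'
#' @return Character vector of length 12.
#' @export
regionNames <- function() {
  c("caudate", "thalamus", "putamen", "pallidum", "hippocampus",
    "amygdala", "nucleus-accumbens", "ventral-diencephalon",
    "brain-stem", "cerebellum", "grey-matter", "white-matter")
}

#' PhantomAtlas: integer region-label volume for synthetic brains
#'
#' @slot labels 3D integer array, 0 = background, values 1..12 index
#'   [regionNames()].
#' @slot regionTable Named integer vector mapping region name -> label id.
#' @slot voxelSizeMm Positive scalar voxel edge length in mm.
#' @slot seed Integer seed the atlas was built from.
#' @export
setClass("PhantomAtlas",
  representation(labels = "array", regionTable = "integer",
                 voxelSizeMm = "numeric", seed = "integer"))

setValidity("PhantomAtlas", function(object) {
  msgs <- character()
  if (length(dim(object@labels)) != 3L)
    msgs <- c(msgs, "labels must be a 3D array")
  if (!identical(sort(names(object@regionTable)), sort(regionNames())))
    msgs <- c(msgs, "regionTable must contain exactly the 12 canonical regions")
  lab <- unique(as.vector(object@labels))
  if (!all(lab %in% c(0L, unname(object@regionTable))))
    msgs <- c(msgs, "labels contains ids not present in regionTable")
  if (length(object@voxelSizeMm) != 1L || object@voxelSizeMm <= 0)
    msgs <- c(msgs, "voxelSizeMm must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' ComplexModulusMap: storage/loss modulus volumes with a coverage mask
#'
#' Raw mechanical input: the real (storage, G') and imaginary (loss, G'')
#' parts of the complex shear modulus G* = G' + iG'', in kPa, on a voxel
#' grid, together with the boolean coverage mask of reliable voxels.
#'
#' @slot gStorage 3D numeric array, kPa; > 0 inside the mask.
#' @slot gLoss 3D numeric array, kPa; >= 0 inside the mask.
#' @slot mask 3D logical array, same shape.
#' @export
setClass("ComplexModulusMap",
  representation(gStorage = "array", gLoss = "array", mask = "array"))

setValidity("ComplexModulusMap", function(object) {
  msgs <- character()
  d <- dim(object@gStorage)
  if (length(d) != 3L) msgs <- c(msgs, "gStorage must be 3D")
  if (!identical(d, dim(object@gLoss)) || !identical(d, dim(object@mask)))
    msgs <- c(msgs, "gStorage, gLoss and mask must share one shape")
  if (!is.logical(object@mask)) msgs <- c(msgs, "mask must be logical")
  if (!length(msgs)) {
    m <- object@mask
    if (any(object@gStorage[m] <= 0))
      msgs <- c(msgs, "storage modulus must be > 0 inside the mask")
    if (any(object@gLoss[m] < 0))
      msgs <- c(msgs, "loss modulus must be >= 0 inside the mask")
  }
  if (length(msgs)) msgs else TRUE
})

#' PropertyMaps: stiffness and damping-ratio volumes
#'
#' Derived model inputs: stiffness mu (kPa) and dimensionless damping ratio
#' xi, with the shared coverage mask. Voxels outside the mask are 0.
#'
#' @slot mu 3D numeric array, kPa.
#' @slot xi 3D numeric array, dimensionless.
#' @slot mask 3D logical array.
#' @export
setClass("PropertyMaps",
  representation(mu = "array", xi = "array", mask = "array"))

setValidity("PropertyMaps", function(object) {
  msgs <- character()
  d <- dim(object@mu)
  if (!identical(d, dim(object@xi)) || !identical(d, dim(object@mask)))
    msgs <- c(msgs, "mu, xi and mask must share one shape")
  if (!length(msgs)) {
    m <- object@mask
    if (any(object@mu[m] <= 0)) msgs <- c(msgs, "mu must be > 0 inside mask")
    if (any(object@xi[m] < 0)) msgs <- c(msgs, "xi must be >= 0 inside mask")
  }
  if (length(msgs)) msgs else TRUE
})

#' NormalizationState: per-channel location/scale for z-scoring volumes
#'
#' @slot mode Either "dataset" (one location/scale pair per channel pooled
#'   over the fitting set) or "image" (each volume z-scored independently;
#'   no reusable state).
#' @slot location Named numeric, per channel.
#' @slot scale Named numeric, per channel, > 0.
#' @export
setClass("NormalizationState",
  representation(mode = "character", location = "numeric", scale = "numeric"))

setValidity("NormalizationState", function(object) {
  msgs <- character()
  if (!object@mode %in% c("dataset", "image"))
    msgs <- c(msgs, "mode must be 'dataset' or 'image'")
  if (object@mode == "dataset" && any(object@scale <= 0))
    msgs <- c(msgs, "scale must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' BrainVolumes: a batch of channel-first volumes sharing one mask
#'
#' The container every model consumes: one array of dim (C, X, Y, Z) per
#' subject, a shared coverage mask and channel names (e.g. c("mu", "xi")).
#'
#' @slot data List of numeric arrays, each dim (C, X, Y, Z).
#' @slot mask 3D logical array of dim (X, Y, Z).
#' @slot channels Character vector of channel names, length C.
#' @export
setClass("BrainVolumes",
  representation(data = "list", mask = "array", channels = "character"))

setValidity("BrainVolumes", function(object) {
  msgs <- character()
  C <- length(object@channels)
  for (i in seq_along(object@data)) {
    d <- dim(object@data[[i]])
    if (length(d) != 4L || d[1] != C ||
        !identical(d[-1], dim(object@mask))) {
      msgs <- c(msgs, sprintf("volume %d has wrong shape", i))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' EmbeddingBatch: unit-norm feature vectors with ages
#'
#' Substrate of the contrastive losses: n embeddings f(x_i) on the unit
#' sphere plus their chronological ages in years.
#'
#' @slot features n x d numeric matrix, rows unit-norm (tolerance 1e-6).
#' @slot ages Numeric vector of length n, years.
#' @export
setClass("EmbeddingBatch",
  representation(features = "matrix", ages = "numeric"))

setValidity("EmbeddingBatch", function(object) {
  msgs <- character()
  n <- nrow(object@features)
  if (n < 2L) msgs <- c(msgs, "need at least 2 samples")
  if (length(object@ages) != n)
    msgs <- c(msgs, "ages length must match feature rows")
  nrm <- sqrt(rowSums(object@features^2))
  if (any(abs(nrm - 1) > 1e-6))
    msgs <- c(msgs, "feature rows must be unit-norm (within 1e-6)")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EmbeddingBatch, normalizing rows if needed
#'
#' @param features n x d matrix of embeddings.
#' @param ages Ages in years, length n.
#' @param normalize Renormalize rows to unit length (with a warning if they
#'   were not already unit-norm).
#' @return An [EmbeddingBatch-class] object.
#' @export
embeddingBatch <- function(features, ages, normalize = TRUE) {
  features <- as.matrix(features)
  nrm <- sqrt(rowSums(features^2))
  if (normalize && any(abs(nrm - 1) > 1e-6)) {
    warning("features were not unit-norm; renormalizing rows")
    features <- features / nrm
  }
  new("EmbeddingBatch", features = features, ages = as.numeric(ages))
}

#' Virtual parent of all fitted brain-age models
#'
#' @slot family One of "pca_gp", "supervised_cnn", "ssl_contrastive".
#' @slot modality Free-text tag of the input channels (e.g. "mre").
#' @slot channels Channel names the model was fitted on.
#' @slot normState The [NormalizationState-class] the training volumes were
#'   prepared with (or NULL); predictions require identically prepared input.
#' @slot seed Integer training seed.
#' @export
setClass("BrainAgeModel",
  representation(family = "character", modality = "character",
                 channels = "character", normState = "ANY",
                 seed = "integer", "VIRTUAL"))

#' PCA + Gaussian-process brain-age model
#'
#' @slot center Column means of the flattened masked training matrix.
#' @slot rotation p x k PCA loading matrix.
#' @slot trainScores n x k training score matrix.
#' @slot yMean Training mean age.
#' @slot yCentered Centered training ages.
#' @slot logSf2,logSn2 Optimized log kernel variance and log noise variance.
#' @slot alphaVec Precomputed (K + sn2 I)^-1 y_centered.
#' @export
setClass("PcaGpModel", contains = "BrainAgeModel",
  representation(center = "numeric", rotation = "matrix",
                 trainScores = "matrix", yMean = "numeric",
                 yCentered = "numeric", logSf2 = "numeric",
                 logSn2 = "numeric", alphaVec = "numeric"))

#' Supervised 3D CNN brain-age model
#'
#' @slot weights Nested list of layer weights of the residual encoder and
#'   regression head.
#' @slot encoderConfig,trainConfig The configurations used for fitting.
#' @slot yMean Training mean age (targets are centered during training).
#' @export
setClass("CnnModel", contains = "BrainAgeModel",
  representation(weights = "list", encoderConfig = "list",
                 trainConfig = "list", yMean = "numeric"))

#' Self-supervised contrastive brain-age model with ridge readout
#'
#' @slot weights Encoder weights (trained with the adaptive-neighbourhood
#'   contrastive regression loss).
#' @slot encoderConfig,trainConfig,schedule Configurations used.
#' @slot sigma Gaussian age-kernel bandwidth (years).
#' @slot ridgeCoef Ridge readout coefficients (intercept first).
#' @slot ridgeAlpha Ridge regularization strength.
#' @export
setClass("SslModel", contains = "BrainAgeModel",
  representation(weights = "list", encoderConfig = "list",
                 trainConfig = "list", schedule = "list", sigma = "numeric",
                 ridgeCoef = "numeric", ridgeAlpha = "numeric"))

#' BiasModel: Theil-Sen fit of predicted vs chronological age on controls
#'
#' @slot slope,intercept Robust line parameters (median of pairwise slopes;
#'   median residual intercept).
#' @slot nControl Number of control subjects used.
#' @export
setClass("BiasModel",
  representation(slope = "numeric", intercept = "numeric",
                 nControl = "integer"))

setValidity("BiasModel", function(object) {
  if (!is.finite(object@slope)) return("slope must be finite")
  if (object@nControl < 3L) return("bias model needs >= 3 control subjects")
  TRUE
})

#' StatReport: outcome of the normality-gated two-group comparison
#'
#' @slot normalityP Named numeric, Shapiro-Wilk p per group.
#' @slot test Chosen test name.
#' @slot statistic,p Test statistic and p-value.
#' @slot paired Whether a paired comparison was requested.
#' @export
setClass("StatReport",
  representation(normalityP = "numeric", test = "character",
                 statistic = "numeric", p = "numeric", paired = "logical"))

setMethod("show", "PhantomAtlas", function(object) {
  d <- dim(object@labels)
  cat(sprintf("PhantomAtlas: %dx%dx%d @ %g mm, %d regions, %d labelled voxels\n",
              d[1], d[2], d[3], object@voxelSizeMm,
              length(object@regionTable), sum(object@labels > 0)))
})

setMethod("show", "ComplexModulusMap", function(object) {
  d <- dim(object@gStorage)
  m <- object@mask
  cat(sprintf("ComplexModulusMap: %dx%dx%d, %d masked voxels, G' in [%.3g, %.3g] kPa\n",
              d[1], d[2], d[3], sum(m),
              min(object@gStorage[m]), max(object@gStorage[m])))
})

setMethod("show", "PropertyMaps", function(object) {
  d <- dim(object@mu)
  m <- object@mask
  cat(sprintf("PropertyMaps: %dx%dx%d, mean mu %.3g kPa, mean xi %.3g\n",
              d[1], d[2], d[3], mean(object@mu[m]), mean(object@xi[m])))
})

setMethod("show", "BrainVolumes", function(object) {
  cat(sprintf("BrainVolumes: %d subjects, channels [%s], grid %s, %d masked voxels\n",
              length(object@data), paste(object@channels, collapse = ", "),
              paste(dim(object@mask), collapse = "x"), sum(object@mask)))
})

setMethod("show", "BiasModel", function(object) {
  cat(sprintf("BiasModel (Theil-Sen): slope %.4f, intercept %.4f (n = %d controls)\n",
              object@slope, object@intercept, object@nControl))
})

setMethod("show", "StatReport", function(object) {
  cat(sprintf("StatReport: %s (paired = %s), statistic %.4g, p = %.4g\n",
              object@test, object@paired, object@statistic, object@p))
})

#' @describeIn regionNames Accessor for the atlas label array.
#' @param atlas A [PhantomAtlas-class].
#' @export
atlasLabels <- function(atlas) atlas@labels

#' Region name -> label id table of an atlas
#' @param atlas A [PhantomAtlas-class].
#' @return Named integer vector.
#' @export
atlasRegions <- function(atlas) atlas@regionTable

#' Coverage mask accessor
#' @param x A ComplexModulusMap, PropertyMaps or BrainVolumes object.
#' @return Logical 3D array.
#' @export
coverageMask <- function(x) x@mask

#' Number of subjects in a BrainVolumes batch
#' @param volumes A [BrainVolumes-class].
#' @return Integer count.
#' @export
nSubjects <- function(volumes) length(volumes@data)
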