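#' Compute stiffness and damping ratio from a complex modulus map
#'
#' Converts the storage/loss modulus pair into the two scalar viscoelastic
#' properties used as model inputs: voxelwise stiffness
#' \deqn{\mu = 2|G^*|^2 / (G' + |G^*|)}{mu = 2|G*|^2 / (G' + |G*|)}
#' with \eqn{|G^*| = \sqrt{G'^2 + G''^2}}, and damping ratio
#' \deqn{\xi = G'' / (2 G')}{xi = G'' / (2 G')}.
#' Voxels outside the coverage mask are set to 0.
#'
#' In the purely elastic limit (\eqn{G'' = 0}) the stiffness reduces to
#' \eqn{\mu = G'} and the damping ratio to 0.
#'
#' @param modulus A [ComplexModulusMap-class].
#' @return A [PropertyMaps-class] with the same mask.
#' @export
computeProperties <- function(modulus) {
  stopifnot(is(modulus, "ComplexModulusMap"))
  gp <- modulus@gStorage
  gl <- modulus@gLoss
  m <- modulus@mask
  if (any(gp[m] == 0))
    stop("storage modulus is zero inside the mask: damping ratio undefined")
  gabs <- sqrt(gp^2 + gl^2)
  mu <- array(0, dim(gp))
  xi <- array(0, dim(gp))
  mu[m] <- 2 * gabs[m]^2 / (gp[m] + gabs[m])
  xi[m] <- gl[m] / (2 * gp[m])
  new("PropertyMaps", mu = mu, xi = xi, mask = m)
}

#' Invert stiffness/damping back to complex modulus components
#'
#' Algebraic inverse of [computeProperties()]:
#' \deqn{G' = \mu (1 + \sqrt{1 + 4\xi^2}) / (2 (1 + 4\xi^2)), \quad
#'       G'' = 2 \xi G'.}
#' Substituting \eqn{G'' = 2\xi G'} gives \eqn{|G^*| = G'\sqrt{1+4\xi^2}}
#' and the stiffness formula collapses to
#' \eqn{\mu = 2 G' (1+4\xi^2)/(1+\sqrt{1+4\xi^2})}, which this solves for
#' G'. The round trip is exact to floating-point precision.
#'
#' @param mu Stiffness array/vector, kPa, > 0.
#' @param xi Damping ratio array/vector, >= 0, same shape.
#' @return List with components `gStorage` and `gLoss`.
#' @export
invertProperties <- function(mu, xi) {
  stopifnot(all(mu > 0), all(xi >= 0))
  q <- 1 + 4 * xi^2
  gp <- mu * (1 + sqrt(q)) / (2 * q)
  gl <- 2 * xi * gp
  list(gStorage = gp, gLoss = gl)
}

#' Z-score a set of volumes at dataset or image level
#'
#' In `"dataset"` mode the in-mask voxels of all volumes are pooled per
#' channel and a single (location, scale) pair per channel is fitted, so
#' global trends (e.g. whole-brain softening with age) survive
#' normalization; the returned [NormalizationState-class] can be re-applied
#' to held-out or disease subjects without refitting. In `"image"` mode
#' every volume is independently z-scored in-mask, removing global
#' per-subject levels and leaving only spatial contrast.
#'
#' Out-of-mask voxels are set to 0 after normalization (not to the
#' normalized value of 0), so a zero fill coincides with background.
#'
#' @param volumes A [BrainVolumes-class].
#' @param mode "dataset" or "image".
#' @param state Optional fitted [NormalizationState-class] (dataset mode):
#'   apply it without refitting.
#' @return List with `volumes` (normalized [BrainVolumes-class]) and
#'   `state` (a [NormalizationState-class]).
#' @export
normalizeVolumes <- function(volumes, mode = c("dataset", "image"),
                             state = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(volumes, "BrainVolumes"), nSubjects(volumes) >= 1L)
  m <- volumes@mask
  idx <- which(m)
  C <- length(volumes@channels)
  dat <- volumes@data

  if (mode == "image") {
    for (i in seq_along(dat)) {
      v <- dat[[i]]
      for (ch in seq_len(C)) {
        x <- v[ch, , , ][idx]
        s <- sd(x)
        if (!is.finite(s) || s == 0)
          stop(sprintf("zero variance in channel '%s' of volume %d",
                       volumes@channels[ch], i))
        vn <- array(0, dim(m))
        vn[idx] <- (x - mean(x)) / s
        v[ch, , , ] <- vn
      }
      dat[[i]] <- v
    }
    st <- new("NormalizationState", mode = "image",
              location = setNames(numeric(C), volumes@channels),
              scale = setNames(rep(1, C), volumes@channels))
  } else {
    if (is.null(state)) {
      loc <- numeric(C); sc <- numeric(C)
      for (ch in seq_len(C)) {
        pooled <- unlist(lapply(dat, function(v) v[ch, , , ][idx]),
                         use.names = FALSE)
        loc[ch] <- mean(pooled)
        sc[ch] <- sqrt(mean((pooled - loc[ch])^2))
        if (!is.finite(sc[ch]) || sc[ch] == 0)
          stop(sprintf("zero variance in channel '%s'", volumes@channels[ch]))
      }
      st <- new("NormalizationState", mode = "dataset",
                location = setNames(loc, volumes@channels),
                scale = setNames(sc, volumes@channels))
    } else {
      stopifnot(is(state, "NormalizationState"), state@mode == "dataset")
      st <- state
    }
    for (i in seq_along(dat)) {
      v <- dat[[i]]
      for (ch in seq_len(C)) {
        vn <- array(0, dim(m))
        vn[idx] <- (v[ch, , , ][idx] - st@location[ch]) / st@scale[ch]
        v[ch, , , ] <- vn
      }
      dat[[i]] <- v
    }
  }
  out <- volumes
  out@data <- dat
  list(volumes = out, state = st)
}

#' Mask an anatomical volume to the mechanical coverage
#'
#' MRE property maps can have partial brain coverage; the anatomical
#' channel is masked to the same support so all modalities see identical
#' voxels. Masking precedes image-level normalization of the anatomical
#' channel.
#'
#' @param anatomical 3D numeric array.
#' @param propertyMask 3D logical array of the same shape.
#' @return The masked array (voxels outside the mask set to 0).
#' @export
applyCoverageMask <- function(anatomical, propertyMask) {
  if (!identical(dim(anatomical), dim(propertyMask)))
    stop("anatomical and mask shapes differ")
  anatomical[!propertyMask] <- 0
  anatomical
}

#' Serialize / restore a NormalizationState as JSON
#'
#' @param state A [NormalizationState-class].
#' @param path File path.
#' @return `writeNormalizationState` returns `path` invisibly;
#'   `readNormalizationState` returns the restored state.
#' @export
writeNormalizationState <- function(state, path) {
  jsonlite::write_json(list(mode = state@mode,
                            location = as.list(state@location),
                            scale = as.list(state@scale)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNormalizationState
#' @export
readNormalizationState <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("NormalizationState", mode = x$mode,
      location = unlist(x$location), scale = unlist(x$scale))
}

#' Read / write a 3D volume as NIfTI-1
#'
#' Thin wrappers over RNifti with the voxel size recorded in the affine.
#'
#' @param vol 3D numeric array.
#' @param path Output path (`.nii.gz`).
#' @param voxelSizeMm Isotropic voxel edge length in mm.
#' @return `writeVolume` returns `path` invisibly; `readVolume` the array.
#' @export
writeVolume <- function(vol, path, voxelSizeMm = 2) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(voxelSizeMm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}
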