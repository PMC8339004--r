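#' Thorax phantom specification
#'
#' Describes a synthetic thorax CT volume: an elliptical body cylinder,
#' two lung ellipsoids, a mediastinal slab between the lungs, an optional
#' patient-table slab behind the body, and optional embedded blobs
#' (vessel/lesion stand-ins). Region HU values default to air -1000,
#' body +20, mediastinum +40, lung -800 — values chosen so the default
#' segmentation thresholds are exercised rather than trivially satisfied.
#'
#' A small seeded jitter on the lung geometry makes phantoms from different
#' seeds anatomically distinct, which is how a pool of nodule-free "scans"
#' for study generation is obtained.
#'
#' @param shape grid dimensions `(IS, AP, RL)`.
#' @param spacing_mm isotropic voxel size, mm.
#' @param with_table include the table slab.
#' @param blobs list of blobs, each `list(center = fractional (IS, AP, RL)
#'   position, radius_mm =, hu =)`; blobs are painted last.
#' @param hu named HU values for `air`, `body`, `mediastinum`, `lung`,
#'   `table`.
#' @param seed integer controlling the geometry jitter.
#' @param jitter relative geometry jitter amplitude (0 disables).
#' @return object of class `phantom_spec`.
#' @export
thorax_phantom_spec <- function(shape = c(128, 128, 128), spacing_mm = 2.5,
                                with_table = TRUE, blobs = list(),
                                hu = c(air = -1000, body = 20,
                                       mediastinum = 40, lung = -800,
                                       table = 0),
                                seed = 0, jitter = 0.03) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop_validation("phantom grid must be 3D with at least 16 voxels per axis")
  if (spacing_mm <= 0) stop_validation("spacing must be positive")
  need <- c("air", "body", "mediastinum", "lung", "table")
  if (!all(need %in% names(hu)))
    stop_validation(paste("hu must name", paste(need, collapse = ", ")))
  if (any(hu < -1024) || any(hu > 3071))
    stop_validation("HU values must lie in [-1024, 3071]")
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 with_table = with_table, blobs = blobs, hu = hu,
                 seed = seed, jitter = jitter),
            class = "phantom_spec")
}

# fractional-coordinate grids for a phantom's voxel centres, in [0, 1)
.phantom_grids <- function(shape) {
  list(z = (seq_len(shape[1]) - 0.5) / shape[1],
       y = (seq_len(shape[2]) - 0.5) / shape[2],
       x = (seq_len(shape[3]) - 0.5) / shape[3])
}

#' Generate a thorax phantom
#'
#' Composes the phantom back-to-front (air, body, mediastinum, lungs,
#' blobs, table) and returns the HU volume together with exact truth masks.
#' The lung truth mask excludes blob voxels, so it is precisely the set of
#' voxels carrying the lung HU value. Deterministic for a fixed spec.
#'
#' @param spec a [thorax_phantom_spec()].
#' @return list with `volume` (a [ct_volume()]) and `masks` (logical arrays
#'   `body`, `lungs`, `table`).
#' @export
generate_thorax_phantom <- function(spec = thorax_phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  g <- .phantom_grids(d)
  jit <- if (spec$jitter > 0)
    with_seed(spec$seed, runif(8, -spec$jitter, spec$jitter))
  else rep(0, 8)

  # body: elliptical cylinder along IS
  cy <- 0.5; cx <- 0.5
  ay <- 0.34 * (1 + jit[1]); ax <- 0.42 * (1 + jit[2])
  zlo <- 0.04; zhi <- 0.96
  Y <- ((g$y - cy) / ay)^2
  X <- ((g$x - cx) / ax)^2
  body2d <- outer(Y, X, `+`) <= 1                       # (AP, RL)
  zin <- g$z >= zlo & g$z <= zhi
  body <- array(FALSE, d)
  body[zin, , ] <- rep(body2d, each = sum(zin))

  # lungs: two ellipsoids
  lungs <- array(FALSE, d)
  lz <- 0.5 + jit[3] * 0.5
  az <- 0.33 * (1 + jit[4]); aly <- 0.21 * (1 + jit[5]); alx <- 0.13 * (1 + jit[6])
  ly <- 0.48 + jit[7] * 0.3
  for (sgn in c(-1, 1)) {
    lx <- 0.5 + sgn * (0.20 + jit[8] * 0.2)
    e <- outer(outer(((g$z - lz) / az)^2, ((g$y - ly) / aly)^2, `+`),
               ((g$x - lx) / alx)^2, `+`) <= 1
    lungs <- lungs | e
  }
  if (!all(body[lungs]))
    stop_validation("phantom lungs are not contained in the body")

  # mediastinum: central slab, only where the body is, between the lungs
  med <- array(FALSE, d)
  medx <- abs(g$x - 0.5) <= 0.07
  med[, , medx] <- body[, , medx]
  medz <- g$z >= lz - az & g$z <= lz + az
  med[!medz, , ] <- FALSE

  # table: slab behind (posterior to) the body
  tab <- array(FALSE, d)
  if (spec$with_table) {
    ty <- g$y >= cy + ay + 0.03 & g$y <= cy + ay + 0.08
    tx <- abs(g$x - 0.5) <= 0.30
    if (!any(ty))
      stop_validation("no room for the table slab behind the body")
    tab[zin, ty, tx] <- TRUE
    if (any(tab & body))
      stop_validation("table overlaps the body")
  }

  vox <- array(spec$hu[["air"]], d)
  vox[body] <- spec$hu[["body"]]
  vox[med] <- spec$hu[["mediastinum"]]
  vox[lungs] <- spec$hu[["lung"]]
  lung_truth <- lungs
  for (b in spec$blobs) {
    ctr <- b$center
    rad <- b$radius_mm / (spec$spacing_mm * d)   # fractional radii per axis
    e <- outer(outer(((g$z - ctr[1]) / rad[1])^2,
                     ((g$y - ctr[2]) / rad[2])^2, `+`),
               ((g$x - ctr[3]) / rad[3])^2, `+`) <= 1
    vox[e] <- b$hu
    lung_truth <- lung_truth & !e
  }
  vox[tab] <- spec$hu[["table"]]

  list(volume = ct_volume(vox, rep(spec$spacing_mm, 3)),
       masks = list(body = body, lungs = lung_truth, table = tab))
}

#' Add HU noise to a volume
#'
#' Additive Gaussian noise, clipped to the valid HU range
#' \[-1024, 3071\]. `noise_sd_hu = 0` is the identity.
#'
#' @param volume a [ct_volume()].
#' @param noise_sd_hu noise standard deviation, HU.
#' @param seed integer seed.
#' @export
perturb_phantom <- function(volume, noise_sd_hu, seed = 1) {
  stopifnot(inherits(volume, "ct_volume"))
  if (noise_sd_hu < 0) stop_validation("noise_sd_hu must be >= 0")
  if (noise_sd_hu == 0) return(volume)
  vox <- with_seed(seed, volume$voxels + rnorm(length(volume$voxels),
                                               sd = noise_sd_hu))
  vox <- pmin(pmax(vox, -1024), 3071)
  ct_volume(array(vox, dim(volume$voxels)), volume$spacing,
            scale_factor_S = volume$scale_factor_S)
}
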