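# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# tight bounding box of voxels with value >= level; NULL when empty
support_bbox <- function(arr, level = 0.5) {
  idx <- which(arr >= level, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  rbind(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

measure_extent_mm <- function(shape, spacing, level = 0.5) {
  bb <- support_bbox(shape, level)
  if (is.null(bb)) return(c(0, 0, 0))
  unname((bb["hi", ] - bb["lo", ] + 1) * spacing)
}

#' Nodule container
#'
#' A nodule is a 3D occupancy grid with values in \[0, 1\] (soft occupancy;
#' 1 = fully inside the lesion) on an isotropic grid, plus its physical
#' extent. Occupancy is normalised so the maximum is exactly 1. The extent
#' is the tight bounding box of the half-occupancy support (voxels with
#' value >= 0.5), in mm.
#'
#' @param shape 3D numeric array, values in \[0, 1\], canonical
#'   `(IS, AP, RL)` axis order.
#' @param grid_spacing isotropic voxel size, mm.
#' @param id label for provenance.
#' @return object of class `nodule` with fields `shape`, `grid_spacing`,
#'   `extent_mm`, `id`.
#' @export
nodule <- function(shape, grid_spacing, id = "nodule") {
  if (!is.array(shape) || length(dim(shape)) != 3L)
    stop_validation("`shape` must be a 3D array")
  if (length(grid_spacing) != 1L || grid_spacing <= 0)
    stop_validation("`grid_spacing` must be a single positive mm value")
  mx <- max(shape)
  if (mx <= 0) stop_validation("nodule occupancy is empty (all zero)")
  if (min(shape) < 0) stop_validation("occupancy values must be >= 0")
  shape <- shape / mx
  structure(list(shape = shape, grid_spacing = grid_spacing,
                 extent_mm = measure_extent_mm(shape, grid_spacing),
                 id = id),
            class = "nodule")
}

#' @export
print.nodule <- function(x, ...) {
  cat(sprintf("<nodule> '%s' %s voxels @ %.2g mm, extent %s mm\n", x$id,
              paste(dim(x$shape), collapse = "x"), x$grid_spacing,
              paste(format(x$extent_mm, digits = 3), collapse = " x ")))
  invisible(x)
}

#' Generate a synthetic nodule shape
#'
#' Builds a connected, lumpy quasi-sphere: a sphere of diameter
#' `base_diameter_mm` whose radius is modulated along each direction by a
#' smooth random angular field with relative amplitude at most
#' `irregularity`. The field is a fixed small sum of random-direction
#' cosine waves evaluated on the unit sphere, so the support stays
#' star-shaped (hence connected). At `irregularity = 0` the result is an
#' exact discretised sphere: a voxel is occupied iff its centre lies within
#' the base radius. Deterministic for a fixed seed.
#'
#' These stand-ins play the role of a library of segmented patient nodules;
#' study realism comes from drawing repeatedly from a fixed pool and
#' augmenting each draw, not from any one shape.
#'
#' @param seed integer seed.
#' @param base_diameter_mm sphere diameter before modulation, mm.
#' @param irregularity relative radius-modulation amplitude in \[0, 1\].
#' @param grid_spacing isotropic voxel size, mm; must resolve the diameter
#'   with at least 3 voxels.
#' @return a [nodule()].
#' @export
generate_shape <- function(seed, base_diameter_mm, irregularity = 0.3,
                           grid_spacing = 0.5) {
  if (base_diameter_mm <= 0) stop_validation("base_diameter_mm must be > 0")
  if (irregularity < 0 || irregularity > 1)
    stop_validation("irregularity must lie in [0, 1]")
  if (base_diameter_mm / grid_spacing < 3)
    stop_validation("grid too coarse: fewer than 3 voxels across the diameter")
  R0 <- base_diameter_mm / 2
  n <- 2L * ceiling(R0 * (1 + irregularity) / grid_spacing) + 3L
  ctr <- (n - 1) / 2
  waves <- with_seed(seed, {
    m <- 6L
    k <- matrix(rnorm(3 * m), m, 3) * 2      # wave vectors on the unit sphere
    list(k = k, phase = runif(m, 0, 2 * pi), amp = runif(m, 0.3, 1))
  })
  amp_norm <- sum(waves$amp)                  # bounds |f| by 1
  ax <- (seq_len(n) - 1 - ctr) * grid_spacing
  g <- expand.grid(z = ax, y = ax, x = ax)    # varies fastest in z = dim 1
  r <- sqrt(g$z^2 + g$y^2 + g$x^2)
  occ <- numeric(nrow(g))
  nz <- r > 0
  if (irregularity > 0) {
    u <- cbind(g$z, g$y, g$x)[nz, , drop = FALSE] / r[nz]
    f <- rep(0, sum(nz))
    for (j in seq_len(nrow(waves$k)))
      f <- f + waves$amp[j] *
        cos(u %*% waves$k[j, ] + waves$phase[j])[, 1]
    Rdir <- R0 * (1 + irregularity * f / amp_norm)
  } else {
    Rdir <- rep(R0, sum(nz))
  }
  occ[nz] <- as.numeric(r[nz] <= Rdir)
  occ[!nz] <- 1
  nodule(array(occ, dim = c(n, n, n)), grid_spacing,
         id = sprintf("synthetic-%d", as.integer(seed)))
}

#' Load a nodule shape from a mask volume
#'
#' Reads a binary or scalar 3D mask (MetaImage or NIfTI), renormalises it to
#' \[0, 1\] with maximum 1, and resamples anisotropic grids to the smallest
#' header spacing so the nodule grid is isotropic.
#'
#' @param path mask volume path.
#' @return a [nodule()].
#' @export
load_shape <- function(path) {
  vol <- read_volume(path)
  shape <- vol$voxels
  if (max(shape) <= 0) stop_validation("nodule mask is empty")
  sp <- vol$spacing
  if (diff(range(sp)) > 1e-9) {
    iso <- min(sp)
    d_in <- dim(shape)
    d_out <- pmax(ceiling(d_in * sp / iso), 1L)
    coords <- as.matrix(expand.grid(i = seq_len(d_out[1]) - 1,
                                    j = seq_len(d_out[2]) - 1,
                                    k = seq_len(d_out[3]) - 1))
    shape <- array(trilinear_sample(shape,
                                    coords[, 1] * iso / sp[1],
                                    coords[, 2] * iso / sp[2],
                                    coords[, 3] * iso / sp[3]),
                   dim = d_out)
    sp <- c(iso, iso, iso)
  }
  nodule(shape, sp[1], id = basename(path))
}

# resample a nodule grid through an inverse affine map (rotation about the
# AP axis and/or per-axis scaling), with optional subvoxel supersampling
affine_resample <- function(shape, d_out, map, supersample = 1L) {
  offs <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  coords <- as.matrix(expand.grid(i = seq_len(d_out[1]) - 1,
                                  j = seq_len(d_out[2]) - 1,
                                  k = seq_len(d_out[3]) - 1))
  acc <- numeric(nrow(coords))
  for (oi in offs) for (oj in offs) for (ok in offs) {
    src <- map(coords[, 1] + oi, coords[, 2] + oj, coords[, 3] + ok)
    acc <- acc + trilinear_sample(shape, src[[1]], src[[2]], src[[3]])
  }
  array(acc / supersample^3, dim = d_out)
}

#' Augment a nodule
#'
#' Applies the study's augmentation: rotation in the coronal plane (about
#' the anterior-posterior axis) followed by per-axis rescaling so the tight
#' bounding box of the half-occupancy support matches `target_extent_mm`
#' within one voxel. Occupancy stays in \[0, 1\] with maximum renormalised
#' to 1.
#'
#' @param x a [nodule()].
#' @param rotation_deg coronal-plane rotation angle in degrees.
#' @param target_extent_mm length-3 target extents (IS, AP, RL), mm; or a
#'   single value applied isotropically.
#' @param limits admissible range for each target extent, mm; `NULL` skips
#'   the range check. Default `c(8, 20)`, the augmentation range used for
#'   training-style insertion.
#' @return a [nodule()].
#' @export
augment <- function(x, rotation_deg = 0, target_extent_mm = NULL,
                    limits = c(8, 20)) {
  stopifnot(inherits(x, "nodule"))
  h <- x$grid_spacing
  shape <- x$shape
  theta <- rotation_deg %% 360
  if (theta != 0) {
    d <- dim(shape)
    diag13 <- ceiling(sqrt(d[1]^2 + d[3]^2)) + 2L
    d_out <- c(diag13, d[2], diag13)
    c_in <- (d - 1) / 2; c_out <- (d_out - 1) / 2
    th <- theta * pi / 180
    co <- cos(th); si <- sin(th)
    map <- function(i, j, k) {
      zi <- i - c_out[1]; xk <- k - c_out[3]
      list(co * zi - si * xk + c_in[1],
           j - c_out[2] + c_in[2],
           si * zi + co * xk + c_in[3])
    }
    shape <- affine_resample(shape, d_out, map)
    mx <- max(shape)
    if (mx <= 0) stop_validation("rotation destroyed the nodule support")
    shape <- shape / mx
  }
  if (!is.null(target_extent_mm)) {
    target <- rep(as.numeric(target_extent_mm), length.out = 3)
    if (any(target < 2 * h))
      stop_validation("target extent below 2 voxels of the nodule grid")
    if (!is.null(limits) && (any(target < limits[1]) || any(target > limits[2])))
      stop_validation(sprintf("target extent outside [%g, %g] mm",
                              limits[1], limits[2]))
    cur <- measure_extent_mm(shape, h)
    if (any(cur <= 0)) stop_validation("empty support before scaling")
    d <- dim(shape)
    bb <- support_bbox(shape)
    c_in <- unname(colMeans(bb))               # centre of support, 1-based
    s <- target / cur
    src <- shape
    # interpolating a near-binary occupancy field contracts its
    # half-occupancy surface slightly, so re-measure and correct the scale
    # factors until the tight box lands within one voxel of the target
    for (pass in 1:3) {
      d_out <- pmax(ceiling(d * s) + 2L, 3L)
      d_out <- d_out + (d_out %% 2L == 0L)     # odd: sample the midplane
      c_out <- (d_out - 1) / 2
      map <- function(i, j, k) {
        list((i - c_out[1]) / s[1] + c_in[1] - 1,
             (j - c_out[2]) / s[2] + c_in[2] - 1,
             (k - c_out[3]) / s[3] + c_in[3] - 1)
      }
      shape <- affine_resample(src, d_out, map)
      mx <- max(shape)
      if (mx <= 0) stop_validation("scaling destroyed the nodule support")
      shape <- shape / mx
      got <- measure_extent_mm(shape, h)
      if (any(got <= 0)) stop_validation("scaling destroyed the nodule support")
      if (all(abs(got - target) <= h)) break
      s <- s * target / got
    }
  }
  # crop to a tight grid (support > 0, one voxel pad)
  bb <- support_bbox(shape, level = .Machine$double.eps)
  lo <- pmax(bb["lo", ] - 1L, 1L); hi <- pmin(bb["hi", ] + 1L, dim(shape))
  shape <- shape[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  nodule(shape, h, id = x$id)
}

#' Nodule intensity model
#'
#' Attenuation assigned to full nodule occupancy. The default is the
#' soft-tissue value implied by the active attenuation model at +50 HU.
#'
#' @param mu_soft linear attenuation for occupancy 1, cm^-1.
#' @param model attenuation model used for the default.
#' @export
nodule_intensity_model <- function(mu_soft = NULL,
                                   model = attenuation_model()) {
  if (is.null(mu_soft)) mu_soft <- hu_to_mu(50, model)
  if (mu_soft <= 0) stop_validation("mu_soft must be > 0")
  structure(list(mu_soft = mu_soft), class = "nodule_intensity_model")
}

#' Rasterise a nodule to an attenuation grid
#'
#' Resamples the occupancy onto the target (CT) grid spacing and multiplies
#' by the soft-tissue attenuation; the output maximum equals `mu_soft`.
#' Resampling uses supersampled linear interpolation (box-average within
#' each coarse voxel), which preserves the occupancy integral — and hence
#' the nodule's projected mass — under coarsening.
#'
#' @param x a [nodule()].
#' @param target_spacing per-axis target spacing in mm (scalar recycled).
#' @param intensity a [nodule_intensity_model()].
#' @return 3D array of attenuation values, cm^-1.
#' @export
rasterize_mu <- function(x, target_spacing,
                         intensity = nodule_intensity_model()) {
  stopifnot(inherits(x, "nodule"), inherits(intensity, "nodule_intensity_model"))
  target <- rep(as.numeric(target_spacing), length.out = 3)
  if (any(target <= 0)) stop_validation("target_spacing must be positive")
  h <- x$grid_spacing
  d_in <- dim(x$shape)
  s <- target / h                              # coarse voxels per fine voxel
  d_out <- pmax(ceiling(d_in / s), 1L)
  c_in <- (d_in - 1) / 2; c_out <- (d_out - 1) / 2
  map <- function(i, j, k) {
    list((i - c_out[1]) * s[1] + c_in[1],
         (j - c_out[2]) * s[2] + c_in[2],
         (k - c_out[3]) * s[3] + c_in[3])
  }
  ss <- max(2L, min(4L, ceiling(max(s))))
  grid <- affine_resample(x$shape, d_out, map, supersample = ss)
  mx <- max(grid)
  if (mx <= 0) stop_validation("rasterisation produced an empty grid")
  grid / mx * intensity$mu_soft
}

#' Build a pool of synthetic nodule shapes
#'
#' A fixed pool of seeded synthetic shapes that insertion draws from
#' uniformly with replacement. The default pool size of 19 mirrors a
#' realistic library of segmented lesions.
#'
#' @param n_shapes pool size.
#' @param seed integer; shape j uses seed `seed + j`.
#' @param base_diameter_mm base diameter for all pool shapes, mm.
#' @param irregularity radius-modulation amplitude.
#' @param grid_spacing shape grid spacing, mm.
#' @return object of class `nodule_pool`: list with `shapes` (list of
#'   [nodule()]) and `manifest` (tibble: id, seed, base_diameter_mm,
#'   irregularity).
#' @export
nodule_pool <- function(n_shapes = 19, seed = 1, base_diameter_mm = 10,
                        irregularity = 0.3, grid_spacing = 0.5) {
  if (n_shapes < 1) stop_validation("pool needs at least one shape")
  seeds <- seed + seq_len(n_shapes)
  shapes <- lapply(seeds, generate_shape, base_diameter_mm = base_diameter_mm,
                   irregularity = irregularity, grid_spacing = grid_spacing)
  manifest <- tibble(id = vapply(shapes, function(s) s$id, ""),
                     seed = seeds, base_diameter_mm = base_diameter_mm,
                     irregularity = irregularity)
  structure(list(shapes = shapes, manifest = manifest), class = "nodule_pool")
}

#' @export
print.nodule_pool <- function(x, ...) {
  cat(sprintf("<nodule_pool> %d shapes\n", length(x$shapes)))
  invisible(x)
}

#' Persist / load a nodule pool
#'
#' The pool is stored as one MetaImage volume per shape plus a
#' `manifest.csv` (id, seed, base_diameter_mm, irregularity, file).
#'
#' @param pool a [nodule_pool()].
#' @param dir directory (created if needed).
#' @rdname nodule_pool_io
#' @export
save_pool <- function(pool, dir) {
  stopifnot(inherits(pool, "nodule_pool"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("shape_%03d.mhd", seq_along(pool$shapes))
  for (i in seq_along(pool$shapes)) {
    s <- pool$shapes[[i]]
    write_volume(ct_volume(s$shape, rep(s$grid_spacing, 3)),
                 file.path(dir, files[i]))
  }
  man <- pool$manifest
  man$file <- files
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(NULL)
}

#' @rdname nodule_pool_io
#' @export
load_pool <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop_io(paste("no manifest.csv in", dir))
  man <- read.csv(man_path, stringsAsFactors = FALSE)
  shapes <- lapply(seq_len(nrow(man)), function(i) {
    s <- load_shape(file.path(dir, man$file[i]))
    s$id <- man$id[i]
    s
  })
  structure(list(shapes = shapes,
                 manifest = as_tibble(man[setdiff(names(man), "file")])),
            class = "nodule_pool")
}
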