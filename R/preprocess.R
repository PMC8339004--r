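#' Attenuation model
#'
#' Monochromatic conversion between CT numbers (Hounsfield units) and linear
#' attenuation coefficients. The conversion is the affine map
#' \deqn{\mu_x = \mu_{water} + (\mu_{water} - \mu_{air}) \cdot HU_x / S}
#' where `S` is the vendor HU scale (1000 or 1024). With the defaults
#' (`mu_water = 0.2059` cm^-1, `mu_air = 0`, `S = 1000`), water (0 HU) maps
#' to 0.2059 cm^-1 and air (-1000 HU) to exactly `mu_air`.
#'
#' @param mu_water linear attenuation of water, cm^-1.
#' @param mu_air linear attenuation of air, cm^-1; effectively zero at
#'   diagnostic energies and defaulted to 0.
#' @param S HU scale factor, 1000 or 1024.
#' @return an `attenuation_model` object.
#' @export
attenuation_model <- function(mu_water = 0.2059, mu_air = 0, S = 1000) {
  if (!is.numeric(mu_water) || !is.numeric(mu_air) || mu_water <= mu_air ||
      mu_air < 0)
    stop_validation("need mu_water > mu_air >= 0")
  if (!S %in% c(1000, 1024)) stop_validation("S must be 1000 or 1024")
  structure(list(mu_water = mu_water, mu_air = mu_air, S = S),
            class = "attenuation_model")
}

#' Convert HU to linear attenuation
#'
#' @param hu HU value, vector or array, or a [ct_volume()].
#' @param model an [attenuation_model()].
#' @param clamp if `TRUE` (default) negative attenuation values arising from
#'   HU below `-S` (e.g. padding at -1024 under S = 1000) are clamped to 0.
#' @return attenuation in cm^-1, same shape as the input (a plain array for
#'   a `ct_volume` input).
#' @export
hu_to_mu <- function(hu, model = attenuation_model(), clamp = TRUE) {
  stopifnot(inherits(model, "attenuation_model"))
  x <- if (inherits(hu, "ct_volume")) hu$voxels else hu
  mu <- model$mu_water + (model$mu_water - model$mu_air) * x / model$S
  if (clamp) mu <- pmax(mu, 0)
  mu
}

# connected components of a 3D logical mask; returns list(labels, sizes)
# with labels assigned in canonical scan order (see src/connected.cpp)
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  labels <- .cc_label(as.logical(mask), dim(mask), as.integer(connectivity))
  ncomp <- attr(labels, "n_components")
  sizes <- if (ncomp > 0) tabulate(labels, nbins = ncomp) else integer(0)
  list(labels = labels, sizes = sizes, n = ncomp)
}

#' Remove the patient table from a CT volume
#'
#' The table does not appear on a real radiograph, so it must be removed
#' before projection. Voxels above `threshold_hu` are grouped into 3D
#' connected components; the second-largest component (the table — the
#' largest is the body) is replaced with air (-1000 HU). Ranking is by voxel
#' count with ties broken in favour of the component whose first voxel comes
#' earlier in canonical scan order, so equal-sized components resolve
#' deterministically (the later one is removed).
#'
#' @param volume a [ct_volume()].
#' @param threshold_hu HU threshold separating tissue/table from air.
#' @param connectivity 6, 18 or 26 neighbourhood.
#' @return the volume with the table component set to -1000 HU. If fewer
#'   than two components exist the volume is returned unchanged with a
#'   warning.
#' @export
remove_table <- function(volume, threshold_hu = -300, connectivity = 26) {
  stopifnot(inherits(volume, "ct_volume"))
  cc <- label_components(volume$voxels > threshold_hu, connectivity)
  if (cc$n < 2L) {
    warn("fewer than two components above threshold; nothing removed",
         class = "cxrsim_no_table_warning")
    return(volume)
  }
  # order by size descending; ties already favour smaller label id
  # (earlier first voxel) because order() is stable
  ranking <- order(cc$sizes, decreasing = TRUE)
  table_label <- ranking[2L]
  vox <- volume$voxels
  vox[cc$labels == table_label] <- -1000
  ct_volume(vox, volume$spacing, scale_factor_S = volume$scale_factor_S)
}

# fill holes of a logical mask independently in each axial (IS) slice
fill_holes_axial <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (i in seq_len(d[1])) {
    sl <- mask[i, , ]
    if (!any(sl)) next
    out[i, , ] <- EBImage::fillHull(matrix(as.numeric(sl), d[2], d[3])) > 0
  }
  out
}

#' Segment the lung
#'
#' A tissue mask is extracted by thresholding (body voxels are above the
#' tissue threshold), holes are filled slice-wise so the lungs become part
#' of the body silhouette, and the lung is recovered as the low-density
#' voxels inside the filled body. Components smaller than `min_component_cm3`
#' are dropped to suppress airway and noise fragments. Air outside the
#' patient is excluded by construction.
#'
#' Run [remove_table()] first: a table left in place becomes part of the
#' largest-component bookkeeping.
#'
#' @param volume a [ct_volume()], table already removed.
#' @param tissue_threshold_hu HU below which a voxel counts as lung-like
#'   air/parenchyma; default -400.
#' @param min_component_cm3 minimum component volume kept, in cm^3.
#' @return a `lung_mask` object: list with `voxels` (logical array, same
#'   shape as the volume), `spacing`, and `empty` flag (`TRUE`, with a
#'   warning, when nothing was found).
#' @export
segment_lung <- function(volume, tissue_threshold_hu = -400,
                         min_component_cm3 = 1) {
  stopifnot(inherits(volume, "ct_volume"))
  body <- volume$voxels > tissue_threshold_hu
  body_filled <- fill_holes_axial(body)
  candidates <- body_filled & (volume$voxels <= tissue_threshold_hu)
  voxel_cm3 <- prod(volume$spacing) / 1000
  mask <- array(FALSE, dim(candidates))
  if (any(candidates)) {
    cc <- label_components(candidates, 26L)
    keep <- which(cc$sizes * voxel_cm3 >= min_component_cm3)
    if (length(keep)) mask <- array(cc$labels %in% keep, dim(candidates))
  }
  empty <- !any(mask)
  if (empty)
    warn("lung segmentation produced an empty mask",
         class = "cxrsim_empty_mask_warning")
  structure(list(voxels = mask, spacing = volume$spacing, empty = empty),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %s voxels set (%.1f cm^3)%s\n",
              format(sum(x$voxels), big.mark = ","),
              sum(x$voxels) * prod(x$spacing) / 1000,
              if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}
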