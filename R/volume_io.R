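#' CT volume container
#'
#' A CT volume is a 3D array of Hounsfield-unit voxels with physical spacing.
#' The array is always held in a canonical anatomical order:
#' dimension 1 runs inferior to superior (axial slices), dimension 2 anterior
#' to posterior (rows), dimension 3 right to left (columns). Readers permute
#' external files into this order so that downstream code (projection,
#' segmentation) never branches on orientation.
#'
#' @param voxels 3D numeric array of HU values in canonical `(IS, AP, RL)`
#'   order.
#' @param spacing numeric length-3, voxel size in mm along each canonical
#'   axis; all strictly positive.
#' @param axes character length-3 naming the anatomical direction of each
#'   array axis; must be a permutation of `c("IS", "AP", "RL")`. The
#'   constructor permutes `voxels` and `spacing` into canonical order when a
#'   non-canonical permutation is given.
#' @param scale_factor_S HU scale factor of the scanner, 1000 or 1024.
#'   1000 is the common DICOM value and the default.
#'
#' @return An object of class `ct_volume`: a list with elements `voxels`,
#'   `spacing`, `axes` (always canonical after construction) and
#'   `scale_factor_S`.
#' @export
ct_volume <- function(voxels, spacing, axes = c("IS", "AP", "RL"),
                      scale_factor_S = 1000) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_validation("`voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop_validation("`spacing` must be three strictly positive values (mm)")
  if (length(axes) != 3L || !setequal(axes, c("IS", "AP", "RL")))
    stop_validation("`axes` must be a permutation of c(\"IS\", \"AP\", \"RL\")")
  if (!scale_factor_S %in% c(1000, 1024))
    stop_validation("`scale_factor_S` must be 1000 or 1024")
  perm <- match(c("IS", "AP", "RL"), axes)
  if (!identical(perm, 1:3)) {
    voxels <- aperm(voxels, perm)
    spacing <- spacing[perm]
  }
  structure(
    list(voxels = voxels, spacing = spacing, axes = c("IS", "AP", "RL"),
         scale_factor_S = scale_factor_S),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels (IS x AP x RL), spacing %s mm, S = %d\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              as.integer(x$scale_factor_S)))
  cat(sprintf("  HU range [%s, %s]\n",
              format(min(x$voxels)), format(max(x$voxels))))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Relabel the array axes of a volume
#'
#' Permutes the voxel array so its axes appear in the requested anatomical
#' order. Mostly useful for interoperating with code that expects, say, an
#' `(RL, AP, IS)` layout; `ct_volume()` puts everything back in canonical
#' order, so `relabel_axes()` followed by `ct_volume()` on the result is the
#' identity.
#'
#' @param volume a `ct_volume`.
#' @param axes target axis order, a permutation of `c("IS","AP","RL")`.
#' @return list with `voxels`, `spacing`, `axes` in the requested order.
#' @export
relabel_axes <- function(volume, axes) {
  stopifnot(inherits(volume, "ct_volume"))
  if (length(axes) != 3L || !setequal(axes, c("IS", "AP", "RL")))
    stop_validation("`axes` must be a permutation of c(\"IS\", \"AP\", \"RL\")")
  perm <- match(axes, volume$axes)
  list(voxels = aperm(volume$voxels, perm), spacing = volume$spacing[perm],
       axes = axes)
}

#' Radiograph container
#'
#' @param pixels 2D numeric matrix. For `kind = "raw_line_integral"` these
#'   are dimensionless optical depths (line integrals of attenuation) and
#'   must be non-negative; for `kind = "display"` they are display values in
#'   \[0, 1\].
#' @param pixel_spacing mm per pixel along (rows, columns).
#' @param kind `"raw_line_integral"` or `"display"`.
#' @return object of class `radiograph`.
#' @export
radiograph <- function(pixels, pixel_spacing,
                       kind = c("raw_line_integral", "display")) {
  kind <- match.arg(kind)
  if (!is.matrix(pixels)) stop_validation("`pixels` must be a matrix")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop_validation("`pixel_spacing` must be one or two positive values (mm)")
  finite <- is.finite(pixels)
  if (all(finite)) {
    if (kind == "raw_line_integral" && any(pixels < 0))
      stop_validation("raw line-integral pixels must be >= 0")
    if (kind == "display" && (min(pixels) < 0 || max(pixels) > 1))
      stop_validation("display pixels must lie in [0, 1]")
  }
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing, kind = kind),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %d x %d px (%s), spacing %s mm, range [%s, %s]\n",
              nrow(x$pixels), ncol(x$pixels), x$kind,
              paste(format(x$pixel_spacing, digits = 4), collapse = " x "),
              format(min(x$pixels), digits = 4),
              format(max(x$pixels), digits = 4)))
  invisible(x)
}

#' Convert a raw line-integral radiograph to a display image
#'
#' Applies the default display transform: transmitted intensity
#' `I = exp(-optical depth)` is inverted (so dense anatomy appears bright, as
#' on a clinical radiograph) and min-max normalised to \[0, 1\] per image.
#'
#' @param image a `radiograph`. A `display` image is returned unchanged.
#' @return a `radiograph` of kind `"display"`.
#' @export
display_radiograph <- function(image) {
  stopifnot(inherits(image, "radiograph"))
  if (image$kind == "display") return(image)
  p <- 1 - exp(-image$pixels)
  rng <- range(p)
  p <- if (rng[2] > rng[1]) (p - rng[1]) / (rng[2] - rng[1]) else p * 0
  radiograph(p, image$pixel_spacing, kind = "display")
}

# ---------------------------------------------------------------------------
# MetaImage (.mhd + .raw)
#
# Minimal axis-aligned reader/writer for the uncompressed MetaImage layout
# used by public chest-CT collections: x (right-left) fastest, then y
# (anterior-posterior), then z (inferior-superior). Direction cosines beyond
# axis-aligned identity are out of scope.

.metaimage_types <- c(MET_CHAR = 1L, MET_UCHAR = 1L, MET_SHORT = 2L,
                      MET_USHORT = 2L, MET_INT = 4L, MET_UINT = 4L,
                      MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop_io(paste("cannot read", path)))
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  if (length(kv) == 0L) stop_format("not a MetaImage header")
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  ndims <- suppressWarnings(as.integer(get("NDims", "3")))
  if (is.na(ndims) || ndims != 3L)
    stop_format("only 3-dimensional MetaImage volumes are supported")
  dims <- suppressWarnings(as.integer(strsplit(get("DimSize", ""), "\\s+")[[1]]))
  if (length(dims) != 3L || anyNA(dims) || any(dims <= 0))
    stop_format("missing or malformed DimSize")
  sp <- get("ElementSpacing", get("ElementSize", NULL))
  if (is.null(sp)) stop_validation("MetaImage header lacks ElementSpacing")
  spacing <- suppressWarnings(as.numeric(strsplit(sp, "\\s+")[[1]]))
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop_validation("ElementSpacing must be three positive values")
  etype <- get("ElementType", "MET_SHORT")
  if (!etype %in% names(.metaimage_types))
    stop_format(paste("unsupported ElementType", etype))
  msb <- toupper(get("ElementByteOrderMSB", get("BinaryDataByteOrderMSB", "FALSE")))
  endian <- if (msb %in% c("TRUE", "1")) "big" else "little"
  datafile <- get("ElementDataFile", NULL)
  if (is.null(datafile)) stop_format("MetaImage header lacks ElementDataFile")
  if (identical(datafile, "LOCAL"))
    stop_format("MetaImage with LOCAL payload is not supported; use .mhd + .raw")
  raw_path <- file.path(dirname(path), datafile)
  if (!file.exists(raw_path)) stop_io(paste("missing raw payload:", raw_path))
  n <- prod(dims)
  size <- .metaimage_types[[etype]]
  what <- if (etype %in% c("MET_FLOAT", "MET_DOUBLE")) numeric() else integer()
  signed <- !etype %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vox <- readBin(con, what, n = n + 1L, size = size, signed = signed,
                 endian = endian)
  if (length(vox) != n)
    stop_validation(sprintf(
      "declared DimSize (%s = %d voxels) does not match raw payload (%d read)",
      paste(dims, collapse = "x"), n, length(vox)))
  arr <- array(as.numeric(vox), dim = dims)      # (x, y, z) = (RL, AP, IS)
  ct_volume(aperm(arr, c(3L, 2L, 1L)), spacing = rev(spacing))
}

write_metaimage <- function(volume, path) {
  arr <- aperm(volume$voxels, c(3L, 2L, 1L))     # back to (x, y, z)
  dims <- dim(arr)
  integral <- all(arr == round(arr)) && min(arr) >= -32768 && max(arr) <= 32767
  etype <- if (integral) "MET_SHORT" else "MET_DOUBLE"
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
    sprintf("ElementSpacing = %.10g %.10g %.10g",
            volume$spacing[3], volume$spacing[2], volume$spacing[1]),
    sprintf("ElementType = %s", etype),
    sprintf("ElementDataFile = %s", raw_name)
  )
  ok <- tryCatch(suppressWarnings({
    writeLines(header, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    if (integral)
      writeBin(as.integer(arr), con, size = 2L, endian = "little")
    else
      writeBin(as.numeric(arr), con, size = 8L, endian = "little")
    TRUE
  }), error = function(e) e)
  if (!isTRUE(ok)) stop_io(paste("cannot write", path, ":", conditionMessage(ok)))
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# NIfTI via RNifti; files are assumed axis-aligned with (x, y, z) =
# (RL, AP, IS), the layout our own writer produces.

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_format(conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop_format("only 3-dimensional NIfTI volumes are supported")
  spacing <- RNifti::pixdim(img)[1:3]
  if (anyNA(spacing) || any(spacing <= 0))
    stop_validation("NIfTI pixdim missing or non-positive")
  storage.mode(arr) <- "double"
  ct_volume(aperm(arr, c(3L, 2L, 1L)), spacing = rev(spacing))
}

write_nifti_volume <- function(volume, path) {
  arr <- aperm(volume$voxels, c(3L, 2L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(volume$spacing)
  ok <- tryCatch({ RNifti::writeNifti(img, path, datatype = "double"); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop_io(paste("cannot write", path, ":", conditionMessage(ok)))
  invisible(NULL)
}

#' Read a CT volume
#'
#' Reads MetaImage (`.mhd` + `.raw`) or NIfTI (`.nii`, `.nii.gz`) volumes
#' into the canonical `ct_volume` orientation. HU values are passed through
#' unmodified; spacing is taken from the header.
#'
#' @param path path to the volume file.
#' @param format `"metaimage"`, `"nifti"` or `"auto"` (by file extension).
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, format = c("auto", "metaimage", "nifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io(paste("no such file:", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, mhd = "metaimage", mha = "metaimage",
                     nii = "nifti",
                     stop_format(paste("cannot infer volume format from", path)))
  }
  switch(format, metaimage = read_metaimage(path), nifti = read_nifti_volume(path))
}

#' Write a CT volume
#'
#' @param volume a [ct_volume()].
#' @param path output path (`.mhd` for MetaImage, `.nii`/`.nii.gz` for NIfTI).
#' @param format `"metaimage"` or `"nifti"`.
#' @return invisibly `NULL`; the file round-trips through [read_volume()]
#'   with identical voxels and spacing.
#' @export
write_volume <- function(volume, path, format = c("metaimage", "nifti")) {
  format <- match.arg(format)
  stopifnot(inherits(volume, "ct_volume"))
  switch(format,
         metaimage = write_metaimage(volume, path),
         nifti = write_nifti_volume(volume, path))
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Radiograph and mask export

# 16-bit grayscale PNG writer. R's png bindings only write 8-bit images;
# the PNG container itself is simple enough to emit directly: zlib streams
# come from memCompress() and chunk CRCs from the compiled CRC-32.
write_png16 <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  h <- nrow(pixels); w <- ncol(pixels)
  v <- as.integer(round(pmin(pmax(pixels, 0), 1) * 65535))
  v <- matrix(v, h, w)
  # row-major sample stream, big-endian 16-bit, one filter-0 byte per row
  samples <- as.integer(t(v))
  bytes <- as.raw(rbind(samples %/% 256L, samples %% 256L))
  scan <- rbind(as.raw(0L), matrix(bytes, nrow = 2L * w))
  idat <- memCompress(as.raw(scan), type = "gzip")  # zlib stream
  u32 <- function(x) as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(u32(length(data)), body, u32(.crc32_raw(body)))
  }
  ihdr <- c(u32(w), u32(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           chunk("IHDR", ihdr), chunk("IDAT", idat), chunk("IEND", raw(0)))
  ok <- tryCatch({ writeBin(out, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) stop_io(paste("cannot write", path))
  invisible(NULL)
}

#' Export a radiograph
#'
#' `"png16"` writes the display image linearly quantised to 16-bit grayscale
#' (a raw line-integral image is passed through [display_radiograph()]
#' first). `"float_csv"` writes the pixel values as CSV at full double
#' precision, preserving raw optical depths exactly.
#'
#' @param image a [radiograph()].
#' @param path output path.
#' @param format `"png16"` or `"float_csv"`.
#' @export
export_radiograph <- function(image, path, format = c("png16", "float_csv")) {
  format <- match.arg(format)
  stopifnot(inherits(image, "radiograph"))
  if (!all(is.finite(image$pixels)))
    stop_validation("radiograph contains non-finite pixels")
  if (format == "png16") {
    write_png16(display_radiograph(image)$pixels, path)
  } else {
    ok <- tryCatch({
      write.table(format(image$pixels, digits = 17, scientific = TRUE,
                         trim = TRUE),
                  path, sep = ",", row.names = FALSE, col.names = FALSE,
                  quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop_io(paste("cannot write", path))
  }
  invisible(NULL)
}

#' Read a float CSV radiograph back
#'
#' @param path CSV written by [export_radiograph()] with `format="float_csv"`.
#' @param kind radiograph kind of the stored data.
#' @param pixel_spacing mm per pixel.
#' @return a [radiograph()].
#' @export
import_radiograph_csv <- function(path, kind = "raw_line_integral",
                                  pixel_spacing = 1) {
  m <- as.matrix(read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  radiograph(m, pixel_spacing, kind = kind)
}

#' Export a binary mask
#'
#' Writes a 2D mask as an 8-bit PNG (0/255) or a 3D mask as NIfTI.
#'
#' @param mask logical/0-1 matrix (PNG) or 3D array (NIfTI).
#' @param path output path.
#' @param spacing spacing metadata for NIfTI export.
#' @export
export_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  if (is.matrix(mask)) {
    png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  } else if (is.array(mask) && length(dim(mask)) == 3L) {
    write_nifti_volume(ct_volume(array(as.numeric(mask != 0), dim(mask)),
                                 spacing = spacing), path)
  } else stop_validation("mask must be a matrix or a 3D array")
  invisible(NULL)
}
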