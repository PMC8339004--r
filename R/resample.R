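# Internal resampling helpers.
#
# 2D resizes are separable, so they are expressed as sparse-ish weight
# matrices applied from the left and right: out = W_row %*% m %*% t(W_col).
# This keeps both bilinear (used for images) and exact area-overlap
# interpolation (used for masks before thresholding) in plain matrix algebra.

# weight matrix mapping n_in samples to n_out by bilinear interpolation of
# pixel centers (half-pixel aligned, the standard image-resize convention)
resize_weights_bilinear <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  x <- (seq_len(n_out) - 0.5) * scale - 0.5   # 0-based input coordinate
  x <- pmin(pmax(x, 0), n_in - 1)
  lo <- floor(x)
  frac <- x - lo
  hi <- pmin(lo + 1, n_in - 1)
  idx <- seq_len(n_out)
  W[cbind(idx, lo + 1)] <- W[cbind(idx, lo + 1)] + (1 - frac)
  W[cbind(idx, hi + 1)] <- W[cbind(idx, hi + 1)] + frac
  W
}

# exact overlap of output cells with input cells (area interpolation)
resize_weights_area <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    a <- (i - 1) * scale; b <- i * scale
    j0 <- floor(a); j1 <- ceiling(b) - 1
    for (j in j0:j1) {
      ov <- min(b, j + 1) - max(a, j)
      if (ov > 0 && j >= 0 && j < n_in) W[i, j + 1] <- ov / scale
    }
  }
  W
}

resize_matrix <- function(m, out_dim, method = c("bilinear", "area")) {
  method <- match.arg(method)
  f <- switch(method, bilinear = resize_weights_bilinear,
              area = resize_weights_area)
  W1 <- f(nrow(m), out_dim[1])
  W2 <- f(ncol(m), out_dim[2])
  W1 %*% m %*% t(W2)
}

# trilinear interpolation of arr at fractional 0-based voxel coordinates;
# coordinates outside the grid read as zero
trilinear_sample <- function(arr, ci, cj, ck) {
  d <- dim(arr)
  inside <- ci > -1 & ci < d[1] & cj > -1 & cj < d[2] & ck > -1 & ck < d[3]
  out <- numeric(length(ci))
  if (!any(inside)) return(out)
  ci <- ci[inside]; cj <- cj[inside]; ck <- ck[inside]
  i0 <- floor(ci); j0 <- floor(cj); k0 <- floor(ck)
  fi <- ci - i0; fj <- cj - j0; fk <- ck - k0
  # clamp corner indices; weights of out-of-range corners are applied to a
  # zero value via the `val` helper
  val <- function(i, j, k) {
    ok <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
    v <- numeric(length(i))
    if (any(ok))
      v[ok] <- arr[cbind(i[ok], j[ok], k[ok]) + 1]
    v
  }
  acc <- val(i0, j0, k0) * (1 - fi) * (1 - fj) * (1 - fk) +
         val(i0 + 1, j0, k0) * fi * (1 - fj) * (1 - fk) +
         val(i0, j0 + 1, k0) * (1 - fi) * fj * (1 - fk) +
         val(i0, j0, k0 + 1) * (1 - fi) * (1 - fj) * fk +
         val(i0 + 1, j0 + 1, k0) * fi * fj * (1 - fk) +
         val(i0 + 1, j0, k0 + 1) * fi * (1 - fj) * fk +
         val(i0, j0 + 1, k0 + 1) * (1 - fi) * fj * fk +
         val(i0 + 1, j0 + 1, k0 + 1) * fi * fj * fk
  out[inside] <- acc
  out
}
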