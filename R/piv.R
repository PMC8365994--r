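#' Rasterize a particle frame into an image
#'
#' Stand-in for fluorescence imaging of the simulated field.  In `binary`
#' mode a pixel is 1 when at least one particle lies in it; in `gaussian`
#' mode each particle deposits a unit-mass Gaussian kernel centred on its
#' (sub-pixel) position, which gives PIV textures with smooth sub-pixel
#' structure.  Particles outside the extent are ignored with a message.
#'
#' @param df Frame table with `x`, `y` columns.
#' @param cell_size Pixel edge length in model units.
#' @param extent `list(xlim =, ylim =)` image extent; defaults to the data
#'   range.
#' @param mode `"binary"` or `"gaussian"`.
#' @param kernel_sigma Gaussian kernel width in model units.
#' @return A [swarm_raster()] (rows = y from the bottom, columns = x).
#' @export
rasterize_frame <- function(df, cell_size = 1, extent = NULL,
                            mode = c("binary", "gaussian"),
                            kernel_sigma = cell_size) {
  mode <- match.arg(mode)
  if (cell_size <= 0) abort("`cell_size` must be > 0")
  g <- grid_geometry(df$x, df$y, cell_size, extent)
  m <- matrix(0, nrow = g$ny, ncol = g$nx)
  n_out <- sum(!g$inside)
  if (n_out > 0) {
    inform(sprintf("rasterize_frame: %d particle(s) outside the extent ignored", n_out))
  }
  if (mode == "binary") {
    idx <- cbind(g$iy[g$inside], g$ix[g$inside])
    m[idx] <- 1
  } else {
    h <- max(1L, ceiling(3 * kernel_sigma / cell_size))
    xc <- g$x0 + (seq_len(g$nx) - 0.5) * cell_size
    yc <- g$y0 + (seq_len(g$ny) - 0.5) * cell_size
    for (p in which(g$inside)) {
      jx <- max(1L, g$ix[p] - h):min(g$nx, g$ix[p] + h)
      jy <- max(1L, g$iy[p] - h):min(g$ny, g$iy[p] + h)
      wx <- exp(-(xc[jx] - df$x[p])^2 / (2 * kernel_sigma^2))
      wy <- exp(-(yc[jy] - df$y[p])^2 / (2 * kernel_sigma^2))
      ker <- outer(wy, wx)
      s <- sum(ker)
      if (s > 0) m[jy, jx] <- m[jy, jx] + ker / s
    }
  }
  swarm_raster(m, origin = c(g$x0, g$y0), cell_size = cell_size)
}

#' PIV displacement field by windowed cross-correlation
#'
#' Splits the image pair into interrogation windows and, for each window,
#' computes the zero-mean cross-correlation of the two windows normalised
#' by the overlapping energy, searches the correlation peak within half a
#' window of zero displacement, and refines it with a 3-point Gaussian
#' sub-pixel fit.  Windows whose peak correlation falls below `threshold`,
#' or that are featureless (zero variance), are masked rather than
#' zero-filled.  The published analysis settings are the defaults: window
#' 128 px, spacing 64 px, correlation threshold 0.6.
#'
#' @param a,b Numeric matrices (frame at t and t + 1), equal dimensions.
#' @param window Interrogation window size in px.
#' @param spacing Window spacing in px.
#' @param threshold Minimum acceptable peak correlation.
#' @return A tibble of class `piv_field`: `cx`, `cy` (window centres, px,
#'   column/row coordinates), `dx`, `dy` (displacement of frame `b`
#'   relative to `a`, px), `corr`, `valid`.
#' @export
piv_field <- function(a, b, window = 128, spacing = 64, threshold = 0.6) {
  if (!all(dim(a) == dim(b))) abort("images must have identical dimensions")
  if (window > min(dim(a))) abort("`window` larger than the image")
  if (spacing < 1) abort("`spacing` must be >= 1")
  a <- unclass(a); b <- unclass(b)
  w <- as.integer(window)
  r0 <- seq(1L, nrow(a) - w + 1L, by = spacing)
  c0 <- seq(1L, ncol(a) - w + 1L, by = spacing)
  half <- w %/% 2L
  res <- list()
  for (ri in r0) for (ci in c0) {
    A <- a[ri:(ri + w - 1L), ci:(ci + w - 1L)]
    B <- b[ri:(ri + w - 1L), ci:(ci + w - 1L)]
    pk <- window_ncc_peak(A, B, half)
    res[[length(res) + 1L]] <- tibble::tibble(
      cx = ci + (w - 1) / 2, cy = ri + (w - 1) / 2,
      dx = pk$dx, dy = pk$dy, corr = pk$corr,
      valid = is.finite(pk$corr) && pk$corr >= threshold)
  }
  out <- dplyr::bind_rows(res)
  out$dx[!out$valid] <- NA_real_
  out$dy[!out$valid] <- NA_real_
  class(out) <- c("piv_field", class(out))
  out
}

# Zero-mean, overlap-energy-normalised cross-correlation of two equal
# windows via FFT, peak restricted to |offset| <= half, 3-point Gaussian
# sub-pixel refinement (parabolic fallback when a log is undefined).
window_ncc_peak <- function(A, B, half) {
  w <- nrow(A)
  A <- A - mean(A); B <- B - mean(B)
  if (sum(A^2) < 1e-20 || sum(B^2) < 1e-20) {
    return(list(dx = NA_real_, dy = NA_real_, corr = NA_real_))
  }
  n2 <- 2L * w
  pad <- function(m) { p <- matrix(0, n2, n2); p[1:w, 1:w] <- m; p }
  FA <- fft(pad(A)); FB <- fft(pad(B))
  FM <- fft(pad(matrix(1, w, w)))
  FA2 <- fft(pad(A^2)); FB2 <- fft(pad(B^2))
  num <- Re(fft(Conj(FA) * FB, inverse = TRUE)) / (n2 * n2)
  sa2 <- Re(fft(Conj(FA2) * FM, inverse = TRUE)) / (n2 * n2)
  sb2 <- Re(fft(Conj(FM) * FB2, inverse = TRUE)) / (n2 * n2)
  den <- sqrt(pmax(sa2, 0) * pmax(sb2, 0))
  ncc <- ifelse(den > 1e-12, num / den, -Inf)
  offs <- c(0:half, -(half:1))            # fft index -> offset
  idx <- c(1:(half + 1L), (n2 - half + 1L):n2)
  sub <- ncc[idx, idx]
  pkij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  du <- offs[pkij[1]] ; dv <- offs[pkij[2]]
  cpk <- sub[pkij[1], pkij[2]]
  at <- function(u, v) ncc[(u %% n2) + 1L, (v %% n2) + 1L]
  refine <- function(cm, c0, cp) {
    if (cm > 0 && c0 > 0 && cp > 0 && c0 >= cm && c0 >= cp) {
      den <- log(cm) - 2 * log(c0) + log(cp)
      if (den < 0) return((log(cm) - log(cp)) / (2 * den))
    }
    den <- cm - 2 * c0 + cp
    if (den < 0) (cm - cp) / (2 * den) else 0
  }
  ddu <- refine(at(du - 1L, dv), at(du, dv), at(du + 1L, dv))
  ddv <- refine(at(du, dv - 1L), at(du, dv), at(du, dv + 1L))
  # rows are y, columns are x
  list(dx = dv + ddv, dy = du + ddu, corr = min(1, max(-1, cpk)))
}

#' Convert a PIV field to physical speeds
#'
#' `speed = ||(dx, dy)|| * px_size / frame_interval` over valid windows;
#' masked windows produce no entries.
#'
#' @param field A [piv_field()] tibble.
#' @param px_size Physical size of one pixel.
#' @param frame_interval Physical time between the two frames.
#' @return A tibble `cx`, `cy`, `speed` (valid windows only).
#' @export
field_speeds <- function(field, px_size = 1, frame_interval = 1) {
  if (px_size <= 0 || frame_interval <= 0) {
    abort("`px_size` and `frame_interval` must be > 0")
  }
  v <- field[field$valid, ]
  tibble::tibble(cx = v$cx, cy = v$cy,
                 speed = sqrt(v$dx^2 + v$dy^2) * px_size / frame_interval)
}
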