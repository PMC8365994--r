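#' Raster grid container
#'
#' A plain numeric matrix with grid geometry attached: `origin` is the
#' lower-left corner of cell `[1, 1]`, `cell_size` the cell edge length.
#' Rows index y (row 1 at the bottom), columns index x.
#'
#' @param values Numeric matrix.
#' @param origin Length-2 numeric, lower-left corner `(x0, y0)`.
#' @param cell_size Cell edge length (`> 0`).
#' @return A `swarm_raster` object.
#' @export
swarm_raster <- function(values, origin = c(0, 0), cell_size = 1) {
  if (cell_size <= 0) abort("`cell_size` must be > 0")
  stopifnot(is.matrix(values), length(origin) == 2)
  structure(values, origin = as.numeric(origin),
            cell_size = as.numeric(cell_size),
            class = c("swarm_raster", "matrix", "array"))
}

#' @export
print.swarm_raster <- function(x, ...) {
  cat(sprintf("<swarm_raster> %d x %d cells, cell size %g, origin (%g, %g)\n",
              nrow(x), ncol(x), attr(x, "cell_size"),
              attr(x, "origin")[1], attr(x, "origin")[2]))
  invisible(x)
}

# Shared grid geometry: returns origin snapped so the extent covers the data,
# and the integer cell index of each point.
grid_geometry <- function(x, y, cell_size, extent = NULL) {
  if (cell_size <= 0) abort("`cell_size` must be > 0")
  if (is.null(extent)) {
    extent <- list(xlim = range(x), ylim = range(y))
  }
  x0 <- extent$xlim[1]; y0 <- extent$ylim[1]
  nx <- max(1L, ceiling((extent$xlim[2] - x0) / cell_size + 1e-9))
  ny <- max(1L, ceiling((extent$ylim[2] - y0) / cell_size + 1e-9))
  ix <- floor((x - x0) / cell_size) + 1L
  iy <- floor((y - y0) / cell_size) + 1L
  # points exactly on the top/right edge belong to the last cell
  ix[ix == nx + 1L & abs(x - (x0 + nx * cell_size)) < 1e-9] <- nx
  iy[iy == ny + 1L & abs(y - (y0 + ny * cell_size)) < 1e-9] <- ny
  inside <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  list(x0 = x0, y0 = y0, nx = nx, ny = ny, ix = ix, iy = iy, inside = inside)
}

#' Passing-count occupancy map
#'
#' For every frame each grid cell is scored 1 if at least one particle lies
#' in it (binarised occupancy, regardless of how many particles share the
#' cell), the per-frame maps are summed over the movie, and the result is
#' reported on a `log10` scale.  Cells never visited are `NA` (masked), so
#' a single visit (`log10(1) = 0`) stays distinguishable from "never".
#' This is the standard way to visualise the trails wandering colonies
#' leave over hundreds of frames.
#'
#' @param x A `swarm_trajectory` or long frame table (`step`, `x`, `y`).
#' @param cell_size Grid cell edge length.
#' @param extent Optional `list(xlim =, ylim =)`; defaults to the data
#'   range.
#' @return A `swarm_raster` of `log10` counts with the raw visit counts in
#'   attribute `counts`.
#' @export
passing_count_map <- function(x, cell_size = 1, extent = NULL) {
  df <- swarm_frames(x)
  g <- grid_geometry(df$x, df$y, cell_size, extent)
  key <- (g$ix - 1L) * g$ny + g$iy
  keep <- g$inside & !duplicated(cbind(df$step, key))
  counts <- tabulate(key[keep], nbins = g$nx * g$ny)
  m <- matrix(counts, nrow = g$ny, ncol = g$nx)
  vals <- ifelse(m > 0, log10(m), NA_real_)
  out <- swarm_raster(vals, origin = c(g$x0, g$y0), cell_size = cell_size)
  attr(out, "counts") <- m
  out
}

#' Space-time kymograph along a line
#'
#' Samples each frame along the segment `p0 -> p1`: particles (or occupied
#' raster cells) within `half_width` of the line are projected onto it and
#' counted in `bins` equal-length bins.  Rows are time, top row first
#' frame; columns run from `p0` to `p1`.  A stationary rotating cluster
#' shows up as a vertical trace, a passing wandering cluster as a slanted
#' one.
#'
#' @param x A `swarm_trajectory`, a long frame table, or a list of rasters
#'   (`swarm_raster` or plain matrices sharing `origin`/`cell_size`
#'   attributes), one per frame.
#' @param p0,p1 Segment endpoints (length-2 numeric, distinct).
#' @param half_width Maximum perpendicular distance from the line.
#' @param bins Number of bins along the segment (`>= 2`).
#' @return A numeric matrix (frames x bins) of class `kymograph` with
#'   attributes `steps` and `positions` (bin centres as distances from
#'   `p0`).
#' @export
kymograph <- function(x, p0, p1, half_width = 0.5, bins = 100) {
  if (bins < 2) abort("`bins` must be >= 2")
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  L <- sqrt(sum((p1 - p0)^2))
  if (L < 1e-12) abort("`p0` and `p1` must be distinct")
  if (is.list(x) && !is.data.frame(x) && !inherits(x, "swarm_trajectory")) {
    df <- raster_stack_points(x)
  } else {
    df <- swarm_frames(x)
    df$w <- 1
  }
  ux <- (p1[1] - p0[1]) / L; uy <- (p1[2] - p0[2]) / L
  rx <- df$x - p0[1]; ry <- df$y - p0[2]
  along <- rx * ux + ry * uy
  perp <- abs(-rx * uy + ry * ux)
  keep <- perp <= half_width & along >= 0 & along <= L
  steps <- sort(unique(df$step))
  bin <- pmin(bins, floor(along / L * bins) + 1L)
  m <- matrix(0, nrow = length(steps), ncol = bins)
  if (any(keep)) {
    ti <- match(df$step, steps)
    agg <- rowsum(df$w[keep], (ti[keep] - 1L) * bins + bin[keep])
    idx <- as.integer(rownames(agg))
    m[cbind((idx - 1L) %/% bins + 1L, (idx - 1L) %% bins + 1L)] <- agg[, 1]
  }
  structure(m, steps = steps,
            positions = (seq_len(bins) - 0.5) * L / bins,
            class = c("kymograph", "matrix", "array"))
}

# Convert a list of rasters into a weighted point table at cell centres.
raster_stack_points <- function(stack) {
  res <- vector("list", length(stack))
  for (s in seq_along(stack)) {
    r <- stack[[s]]
    org <- attr(r, "origin"); cs <- attr(r, "cell_size")
    if (is.null(org) || is.null(cs)) {
      abort("raster stack elements need `origin` and `cell_size` attributes")
    }
    nz <- which(r > 0, arr.ind = TRUE)
    res[[s]] <- tibble::tibble(
      step = s,
      x = org[1] + (nz[, 2] - 0.5) * cs,
      y = org[2] + (nz[, 1] - 0.5) * cs,
      w = r[nz])
  }
  dplyr::bind_rows(res)
}

#' Radial speed profile about a centre
#'
#' Pairs each particle's displacement magnitude per unit time with the
#' distance of its midpoint from a given centre — the analysis used to test
#' rigid-body rotation of disk-like clusters, for which `v(R) = omega * R`.
#'
#' @param df0,df1 Frame tables (columns `id`, `x`, `y`) at times `t` and
#'   `t + delta`, matched by `id`.
#' @param center Length-2 numeric rotation centre.
#' @param delta Time separation of the two frames (`> 0`).
#' @param n_bins Optional number of equal-width radius bins; when given,
#'   returns bin-averaged speeds.
#' @return A tibble `radius`, `speed` (plus `n` per bin when binned).
#' @export
radial_speed_profile <- function(df0, df1, center = c(0, 0), delta = 1,
                                 n_bins = NULL) {
  if (delta <= 0) abort("`delta` must be > 0")
  m <- dplyr::inner_join(tibble::as_tibble(df0), tibble::as_tibble(df1),
                         by = "id", suffix = c("0", "1"))
  if (nrow(m) == 0 || nrow(m) < max(nrow(df0), nrow(df1))) {
    abort("particle sets do not match between the two frames")
  }
  speed <- sqrt((m$x1 - m$x0)^2 + (m$y1 - m$y0)^2) / delta
  mx <- (m$x0 + m$x1) / 2 - center[1]
  my <- (m$y0 + m$y1) / 2 - center[2]
  out <- tibble::tibble(radius = sqrt(mx^2 + my^2), speed = speed)
  if (is.null(n_bins)) return(dplyr::arrange(out, .data$radius))
  br <- seq(0, max(out$radius) * (1 + 1e-9), length.out = n_bins + 1)
  out$bin <- cut(out$radius, br, include.lowest = TRUE, labels = FALSE)
  dplyr::summarise(dplyr::group_by(out, .data$bin),
                   radius = mean(.data$radius), speed = mean(.data$speed),
                   n = dplyr::n(), .groups = "drop")[, c("radius", "speed", "n")]
}
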