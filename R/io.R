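#' Write and read trajectories
#'
#' Trajectories are stored as a CSV with header
#' `step,id,x,y,theta,omega` (one row per particle per recorded frame) and
#' a JSON sidecar (`<path>.json`) echoing the model parameters, seed,
#' record stride and particle count, so every output directory is
#' self-describing.  Values survive the round trip to at least 12
#' significant digits.
#'
#' @param traj A `swarm_trajectory`.
#' @param path Output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  readr::write_csv(traj$frames[, c("step", "id", "x", "y", "theta", "omega")],
                   path)
  meta <- list(params = unclass(traj$params), seed = traj$seed,
               record_stride = traj$record_stride, n = traj$n,
               radius = traj$radius,
               package = "cyanoswarm",
               version = as.character(utils::packageVersion("cyanoswarm")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("step", "id", "x", "y", "theta", "omega")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("trajectory file is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad) > 0) {
    abort(sprintf("trajectory file has missing values (first bad row: %d)",
                  bad[1]))
  }
  steps <- unique(df$step)
  if (any(diff(steps) <= 0)) {
    abort("frame steps must be strictly increasing in file order")
  }
  meta_path <- paste0(path, ".json")
  params <- swarm_params(); seed <- NA_integer_
  stride <- if (length(steps) > 1) as.integer(steps[2] - steps[1]) else 1L
  n <- length(unique(df$id)); radius <- NA_real_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    params <- do.call(swarm_params, meta$params)
    seed <- if (is.null(meta$seed)) NA_integer_ else meta$seed
    stride <- meta$record_stride
    n <- meta$n
    radius <- if (is.null(meta$radius)) NA_real_ else meta$radius
  }
  new_swarm_trajectory(frames = tibble::as_tibble(df[need]), params = params,
                       seed = seed, record_stride = stride, n = n,
                       radius = radius)
}

#' Write and read rasters as plain-matrix CSV
#'
#' The matrix is stored row by row, with a two-line `#` header carrying the
#' grid origin and cell size; `NA` cells (masked) are empty fields.
#'
#' @param r A [swarm_raster()] (or plain matrix for writing).
#' @param path File path.
#' @return `path` invisibly / the raster.
#' @export
write_raster_csv <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  org <- attr(r, "origin"); cs <- attr(r, "cell_size")
  if (is.null(org)) org <- c(0, 0)
  if (is.null(cs)) cs <- 1
  writeLines(sprintf("# origin %.15g %.15g", org[1], org[2]), con)
  writeLines(sprintf("# cell_size %.15g", cs), con)
  utils::write.table(unclass(r), con, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  org <- as.numeric(strsplit(hdr[1], " ")[[1]][3:4])
  cs <- as.numeric(strsplit(hdr[2], " ")[[1]][3])
  m <- as.matrix(utils::read.table(path, sep = ",", skip = 2,
                                   header = FALSE, na.strings = ""))
  dimnames(m) <- NULL
  swarm_raster(m, origin = org, cell_size = cs)
}

#' Write a raster as a PNG image
#'
#' Grey-scale export: values are min-max scaled to `[0, 1]`, masked (`NA`)
#' cells map to 0, and rows are flipped so the top image row is the highest
#' y.  Requires the `png` package.
#'
#' @param r A [swarm_raster()] or matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(r, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the `png` package is required for PNG export")
  }
  m <- unclass(r)
  rng <- range(m, na.rm = TRUE)
  m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  m[is.na(m)] <- 0
  png::writePNG(m[rev(seq_len(nrow(m))), , drop = FALSE], path)
  invisible(path)
}
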