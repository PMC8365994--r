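#' Detect clusters by single-linkage connected components
#'
#' Joins every pair of particles at distance `<= linkage` (inclusive) and
#' labels the connected components.  Every particle gets a label — a
#' singleton is a cluster of size one, there is no "noise" class.  Labels
#' are ordered by descending member count, ties broken by the smallest
#' member id.  The default linkage of twice the repulsion range is the
#' package's stand-in for the image-based colony segmentation used on real
#' plates.
#'
#' @param x A `swarm_trajectory`, a long frame table, or a single-state
#'   tibble with `x`, `y` columns.  When a `step` column is present,
#'   detection runs independently within each step.
#' @param linkage Linkage distance (`> 0`).
#' @return The input records as a tibble with a `cluster` column added.
#' @examples
#' pts <- tibble::tibble(id = 1:4, x = c(0, 0.15, 0.35, 5), y = c(0, 0, 0, 5))
#' detect_clusters(pts, linkage = 0.2)$cluster
#' @export
detect_clusters <- function(x, linkage = 0.4) {
  if (linkage <= 0) abort("`linkage` must be > 0")
  df <- if (inherits(x, "swarm_trajectory")) x$frames else tibble::as_tibble(x)
  if (nrow(df) == 0) {
    df$cluster <- integer(0)
    return(df)
  }
  if (!all(c("x", "y") %in% names(df))) abort("need `x` and `y` columns")
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  if ("step" %in% names(df)) {
    dplyr::group_modify(
      dplyr::group_by(df, .data$step),
      ~ label_one_frame(.x, linkage)
    ) |> dplyr::ungroup() |> dplyr::relocate("step")
  } else {
    label_one_frame(df, linkage)
  }
}

label_one_frame <- function(df, linkage) {
  lab <- linkage_components_cpp(df$x, df$y, linkage)
  # order labels: descending size, ties by smallest member id
  sizes <- tabulate(lab)
  min_id <- vapply(seq_along(sizes), function(k) min(df$id[lab == k]), 0)
  ord <- order(-sizes, min_id)
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(ord)
  df$cluster <- remap[lab]
  df
}

#' Summarise detected clusters per frame
#'
#' @param labeled A tibble from [detect_clusters()] (columns `step`
#'   optional, `id`, `x`, `y`, `cluster`).
#' @param cell_size Optional raster cell size; when given, an `area` column
#'   reports the occupied-cell area (number of grid cells containing at
#'   least one member, times the cell area).  The grid is anchored at the
#'   origin.
#' @return A tibble with one row per cluster (and step): `cluster`, `n`,
#'   `cx`, `cy` and optionally `area`.
#' @export
cluster_table <- function(labeled, cell_size = NULL) {
  if (!"cluster" %in% names(labeled)) {
    abort("`labeled` must come from detect_clusters()")
  }
  if (!is.null(cell_size) && cell_size <= 0) abort("`cell_size` must be > 0")
  grp <- intersect(c("step", "cluster"), names(labeled))
  out <- dplyr::summarise(
    dplyr::group_by(labeled, dplyr::across(dplyr::all_of(grp))),
    n = dplyr::n(),
    cx = mean(.data$x), cy = mean(.data$y),
    area = if (!is.null(cell_size)) {
      cell_size^2 *
        nrow(unique(cbind(floor(.data$x / cell_size),
                          floor(.data$y / cell_size))))
    } else NA_real_,
    .groups = "drop"
  )
  if (is.null(cell_size)) out$area <- NULL
  dplyr::arrange(out, dplyr::across(dplyr::all_of(grp)))
}

#' Cluster sizes of one frame
#'
#' Member counts (`mode = "count"`) or occupied-cell areas
#' (`mode = "area"`, requires `cell_size`) of every cluster in a labelled
#' frame, ordered by cluster label.
#'
#' @inheritParams cluster_table
#' @param mode `"count"` or `"area"`.
#' @return Numeric vector of sizes.
#' @export
cluster_sizes <- function(labeled, mode = c("count", "area"),
                          cell_size = NULL) {
  mode <- match.arg(mode)
  if (mode == "area" && is.null(cell_size)) {
    abort("area mode needs `cell_size`")
  }
  tb <- cluster_table(labeled, cell_size = cell_size)
  if (mode == "count") tb$n else tb$area
}

#' Link clusters across frames into tracks
#'
#' Greedy nearest-centroid matching between consecutive recorded frames:
#' clusters of the newer frame are processed in descending size order and
#' each claims the nearest unclaimed track from the previous frame whose
#' centroid lies within `max_jump`.  Unmatched clusters start new tracks;
#' unmatched tracks terminate.  When two former clusters merge, the merged
#' cluster continues whichever track its centroid is nearest to — in
#' practice the larger one, matching how large colonies absorb small ones.
#'
#' Each track row also carries `spin`, the mean normalised angular momentum
#' of the members about the cluster centroid, computed from member
#' displacements to the next recorded frame relative to the cluster's own
#' translation (`NA` on the last frame of a track).  `spin` is close to
#' +1/-1 for a rigidly rotating cluster and close to 0 for pure
#' translation.
#'
#' @param labeled Labelled frames from [detect_clusters()]; must contain a
#'   `step` column with at least two distinct values.
#' @param max_jump Maximum centroid displacement between consecutive
#'   recorded frames for a match.
#' @return A tibble `track`, `step`, `cluster`, `n`, `cx`, `cy`, `spin`.
#' @export
link_tracks <- function(labeled, max_jump = 1) {
  if (!"step" %in% names(labeled)) abort("`labeled` must have a `step` column")
  steps <- sort(unique(labeled$step))
  if (length(steps) < 2) abort("need at least two frames to link tracks")
  spin_tb <- cluster_spin(labeled)
  tb <- dplyr::left_join(cluster_table(labeled), spin_tb,
                         by = c("step", "cluster"))
  by_step <- split(tb, tb$step)[as.character(steps)]

  next_track <- 0L
  out <- vector("list", length(steps))
  prev <- NULL
  for (s in seq_along(steps)) {
    cur <- by_step[[s]]
    cur <- cur[order(-cur$n, cur$cluster), ]
    cur$track <- NA_integer_
    if (!is.null(prev)) {
      free <- rep(TRUE, nrow(prev))
      for (r in seq_len(nrow(cur))) {
        d <- sqrt((prev$cx - cur$cx[r])^2 + (prev$cy - cur$cy[r])^2)
        d[!free] <- Inf
        b <- which.min(d)
        if (length(b) == 1 && is.finite(d[b]) && d[b] <= max_jump) {
          cur$track[r] <- prev$track[b]
          free[b] <- FALSE
        }
      }
    }
    new <- is.na(cur$track)
    if (any(new)) {
      cur$track[new] <- next_track + seq_len(sum(new))
      next_track <- next_track + sum(new)
    }
    out[[s]] <- cur
    prev <- cur
  }
  dplyr::arrange(
    dplyr::select(dplyr::bind_rows(out), "track", "step", "cluster",
                  "n", "cx", "cy", "spin"),
    .data$track, .data$step)
}

# Mean normalised angular momentum of each cluster-frame, from member
# displacements to the next recorded frame, relative to the mean member
# displacement (removes the cluster's translation).
cluster_spin <- function(labeled) {
  steps <- sort(unique(labeled$step))
  res <- list()
  for (s in seq_along(steps)) {
    cur <- labeled[labeled$step == steps[s], ]
    if (s == length(steps)) {
      res[[s]] <- tibble::tibble(step = steps[s],
                                 cluster = sort(unique(cur$cluster)),
                                 spin = NA_real_)
      next
    }
    nxt <- labeled[labeled$step == steps[s + 1], ]
    m <- dplyr::inner_join(cur, nxt[, c("id", "x", "y")], by = "id",
                           suffix = c("", "_next"))
    m$vx <- m$x_next - m$x
    m$vy <- m$y_next - m$y
    res[[s]] <- dplyr::summarise(
      dplyr::group_by(m, .data$cluster),
      spin = {
        rx <- .data$x - mean(.data$x); ry <- .data$y - mean(.data$y)
        vx <- .data$vx - mean(.data$vx); vy <- .data$vy - mean(.data$vy)
        rn <- sqrt(rx^2 + ry^2); vn <- sqrt(vx^2 + vy^2)
        ok <- rn > 0 & vn > 0
        if (!any(ok)) 0 else mean((rx * vy - ry * vx)[ok] / (rn * vn)[ok])
      },
      .groups = "drop")
    res[[s]]$step <- steps[s]
  }
  dplyr::bind_rows(res)[, c("step", "cluster", "spin")]
}

#' Classify tracks as wandering or rotating
#'
#' Over the trailing `window` track points ending at each frame, computes
#' `straightness` (net centroid displacement divided by centroid path
#' length) and the mean member `spin`.  A track point is labelled
#' `rotating` when straightness is below `straightness_threshold` and the
#' absolute mean spin exceeds `spin_threshold` (the cluster stays put while
#' members circulate), `wandering` when straightness is at or above the
#' threshold (comet-like straight motion), and `unclassified` otherwise or
#' when fewer than `window` points are available.
#'
#' @param tracks Track tibble from [link_tracks()].
#' @param window Number of trailing track points used (`>= 2`).
#' @param straightness_threshold,spin_threshold Classifier thresholds.
#' @return `tracks` with `straightness`, `mean_spin` and `label` columns.
#' @export
classify_tracks <- function(tracks, window = 20,
                            straightness_threshold = 0.5,
                            spin_threshold = 0.3) {
  if (window < 2) abort("`window` must be >= 2")
  one <- function(df) {
    nr <- nrow(df)
    stn <- rep(NA_real_, nr); spn <- rep(NA_real_, nr)
    lab <- rep("unclassified", nr)
    if (nr >= window) {
      dx <- diff(df$cx); dy <- diff(df$cy)
      seg <- sqrt(dx^2 + dy^2)
      cumseg <- c(0, cumsum(seg))
      for (r in window:nr) {
        i0 <- r - window + 1L
        path <- cumseg[r] - cumseg[i0]
        net <- sqrt((df$cx[r] - df$cx[i0])^2 + (df$cy[r] - df$cy[i0])^2)
        stn[r] <- if (path > 0) net / path else 1
        spn[r] <- mean(df$spin[i0:r], na.rm = TRUE)
        lab[r] <- if (stn[r] >= straightness_threshold) "wandering"
        else if (!is.nan(spn[r]) && abs(spn[r]) > spin_threshold) "rotating"
        else "unclassified"
      }
    }
    df$straightness <- stn
    df$mean_spin <- ifelse(is.nan(spn), NA_real_, spn)
    df$label <- lab
    df
  }
  dplyr::ungroup(dplyr::group_modify(dplyr::group_by(tracks, .data$track),
                                     ~ one(.x))) |>
    dplyr::relocate("track")
}

#' Per-track summary
#'
#' Path length, net displacement and the label at the final classified
#' point of each track.
#'
#' @param classified Output of [classify_tracks()].
#' @return One row per track.
#' @export
track_summary <- function(classified) {
  dplyr::summarise(
    dplyr::group_by(classified, .data$track),
    n_frames = dplyr::n(),
    first_step = min(.data$step), last_step = max(.data$step),
    mean_size = mean(.data$n),
    path_length = sum(sqrt(diff(.data$cx)^2 + diff(.data$cy)^2)),
    net_displacement = sqrt((.data$cx[dplyr::n()] - .data$cx[1])^2 +
                              (.data$cy[dplyr::n()] - .data$cy[1])^2),
    label = {
      cl <- .data$label[.data$label != "unclassified"]
      if (length(cl) == 0) "unclassified" else cl[length(cl)]
    },
    ever_rotating = any(.data$label == "rotating"),
    ever_wandering = any(.data$label == "wandering"),
    .groups = "drop")
}

#' Centroid speed series of tracks
#'
#' Speed between consecutive track points:
#' `||centroid_{k+1} - centroid_k|| / (delta_step * frame_interval)`.
#'
#' @param tracks Track tibble from [link_tracks()] (or any tibble with
#'   `track`, `step`, `cx`, `cy`).
#' @param frame_interval Physical time per simulation step.
#' @return Tibble `track`, `step` (interval start), `speed`.
#' @export
centroid_speed <- function(tracks, frame_interval = 1) {
  if (frame_interval <= 0) abort("`frame_interval` must be > 0")
  one <- function(df) {
    if (nrow(df) < 2) abort("tracks need at least two points for speeds")
    tibble::tibble(
      step = df$step[-nrow(df)],
      speed = sqrt(diff(df$cx)^2 + diff(df$cy)^2) /
        (diff(df$step) * frame_interval))
  }
  dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(tibble::as_tibble(tracks), .data$track), ~ one(.x)))
}
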