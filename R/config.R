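#' Parse and serialise run configurations
#'
#' A run configuration is a flat JSON object whose keys are the model
#' constants (`v0`, `l`, `r_rep`, `omega0`, `sigma_omega`, `tau`, `k_rep`,
#' `k_att`, `align_gain`) and the run controls (`n`, `radius`, `n_steps`,
#' `record_stride`, `seed`).  Omitted keys take the documented defaults —
#' the published model constants and a 1000-particle, 2000-step run —
#' and unknown keys are rejected by name.  `parse_config(serialize_config(cfg))`
#' reproduces `cfg` exactly.
#'
#' @param text JSON text, or the path of a JSON file.
#' @return A named list of class `swarm_config` with components `params`
#'   (a [swarm_params()]) and the run controls.
#' @examples
#' cfg <- parse_config('{"n": 200, "seed": 7}')
#' cfg$params$v0    # default 0.1
#' @export
parse_config <- function(text = "{}") {
  raw <- if (length(text) == 1 && file.exists(text)) {
    jsonlite::read_json(text, simplifyVector = TRUE)
  } else {
    jsonlite::parse_json(paste(text, collapse = "\n"), simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config must be a JSON object")
  param_keys <- c("v0", "l", "r_rep", "omega0", "sigma_omega", "tau",
                  "k_rep", "k_att", "align_gain")
  run_keys <- c("n", "radius", "n_steps", "record_stride", "seed")
  unknown <- setdiff(names(raw), c(param_keys, run_keys))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  params <- do.call(swarm_params, raw[intersect(names(raw), param_keys)])
  run <- list(n = 1000L, radius = 5 * params$l, n_steps = 2000L,
              record_stride = 10L, seed = NA_integer_)
  for (k in intersect(names(raw), run_keys)) {
    if (!is.null(raw[[k]])) run[[k]] <- raw[[k]]   # JSON null = use default
  }
  if (run$n < 1) abort("`n` must be >= 1")
  if (run$radius <= 0) abort("`radius` must be > 0")
  if (run$n_steps < 0) abort("`n_steps` must be >= 0")
  if (run$record_stride < 1) abort("`record_stride` must be >= 1")
  structure(c(list(params = params), run), class = "swarm_config")
}

#' @rdname parse_config
#' @param config A `swarm_config`.
#' @param path Optional path; when given the JSON is written there.
#' @export
serialize_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "swarm_config"))
  flat <- c(unclass(config$params),
            config[c("n", "radius", "n_steps", "record_stride", "seed")])
  js <- jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  as.character(js)
}

#' @export
print.swarm_config <- function(x, ...) {
  cat("<swarm_config>\n")
  print(x$params)
  cat(sprintf("  run: n=%d radius=%g n_steps=%d record_stride=%d seed=%s\n",
              x$n, x$radius, x$n_steps, x$record_stride, format(x$seed)))
  invisible(x)
}

#' Run a simulation from a configuration
#'
#' @param config A `swarm_config` from [parse_config()].
#' @param seed Optional seed overriding the config's.
#' @return A `swarm_trajectory`.
#' @export
run_config <- function(config, seed = NULL) {
  stopifnot(inherits(config, "swarm_config"))
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed) || is.na(seed)) seed <- NULL
  run_swarm(config$params, n = config$n, radius = config$radius,
            n_steps = config$n_steps, record_stride = config$record_stride,
            seed = seed)
}
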