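#' Write / read a study configuration as YAML
#'
#' Round-trips the fields of a [study_config()] (plus feedback parameters)
#' through a YAML file. Requires the `yaml` package.
#'
#' @param config A [study_config()].
#' @param params A [feedback_params()].
#' @param path Output path.
#' @export
write_study_config <- function(config, path, params = feedback_params()) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required", call. = FALSE)
  obj <- c(unclass(config), list(feedback = unclass(params)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_study_config
#' @return For `read_study_config`, a list with elements `config` and
#'   `params`.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required", call. = FALSE)
  obj <- yaml::read_yaml(path)
  fb <- obj$feedback
  params <- feedback_params(d_max = fb$d_max, tone_hz = fb$tone_hz,
                            curve_base = fb$curve_base,
                            silence_radius = fb$silence_radius)
  config <- study_config(bias_side = obj$bias_side, n_trials = obj$n_trials,
                         zone_counts = obj$zone_counts, dwell_s = obj$dwell_s,
                         deadline_s = obj$deadline_s,
                         start_fix_s = obj$start_fix_s, fs = obj$fs,
                         target_radius = obj$target_radius,
                         seed = obj$seed)
  list(config = config, params = params)
}

#' Write a density map as a portable text grid
#'
#' Plain-text matrix preceded by a one-line JSON header describing the grid.
#' @param map A `density_map`.
#' @param path Output path.
#' @export
write_density_map <- function(map, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("the 'jsonlite' package is required", call. = FALSE)
  hdr <- jsonlite::toJSON(list(x0 = map$x[1], y0 = map$y[1],
                               dx = diff(map$x[1:2]), dy = diff(map$y[1:2]),
                               nx = length(map$x), ny = length(map$y),
                               bandwidth = map$bandwidth),
                          auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  utils::write.table(map$z, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
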