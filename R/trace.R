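#' Construct a gaze trace
#'
#' A gaze trace is a data frame with columns `t` (seconds), `x`, `y`
#' (screen-centred degrees, +x right, +y up) and `valid` (logical), carrying
#' the sampling rate and screen geometry as attributes. Timestamps must be
#' strictly increasing.
#'
#' @param t,x,y,valid Sample columns.
#' @param fs Sampling rate in Hz.
#' @param geometry A [screen_geometry()].
#' @return A data frame of class `gaze_trace`.
#' @export
gaze_trace <- function(t, x, y, valid = rep(TRUE, length(t)), fs = 600,
                       geometry = screen_geometry()) {
  stopifnot(length(t) == length(x), length(x) == length(y),
            length(valid) == length(t))
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(t < 0)) stop("timestamps must be non-negative", call. = FALSE)
  df <- data.frame(t = t, x = x, y = y, valid = as.logical(valid))
  attr(df, "fs") <- fs
  attr(df, "geometry") <- geometry
  class(df) <- c("gaze_trace", "data.frame")
  df
}

#' @export
`[.gaze_trace` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "fs") <- attr(x, "fs")
    attr(out, "geometry") <- attr(x, "geometry")
    class(out) <- class(x)
  }
  out
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> %d samples @ %g Hz, %.2f s, %.1f%% valid\n",
              nrow(x), attr(x, "fs"),
              if (nrow(x)) max(x$t) - min(x$t) else 0,
              100 * mean(x$valid)))
  invisible(x)
}

#' Sampling rate of a trace
#' @param trace A [gaze_trace()].
#' @export
trace_fs <- function(trace) {
  fs <- attr(trace, "fs")
  if (is.null(fs)) stop("trace has no sampling-rate attribute", call. = FALSE)
  fs
}

#' Mirror a trace about the vertical midline
#'
#' Negates the x coordinate of every sample; used by mirror-equivariance
#' checks and to fold left-bias-group data onto the right hemifield.
#' @param trace A [gaze_trace()].
#' @export
mirror_trace <- function(trace) {
  trace$x <- -trace$x
  trace
}

#' Write / read a gaze trace as CSV
#'
#' The on-disk format is a plain CSV with header `t,x,y,valid` (seconds,
#' degrees, degrees, 0/1); the sampling rate travels in a `# fs=` comment on
#' the first line.
#'
#' @param trace A [gaze_trace()].
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", trace_fs(trace)), con)
  utils::write.csv(data.frame(t = trace$t, x = trace$x, y = trace$y,
                              valid = as.integer(trace$valid)),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param geometry Geometry to attach on read.
#' @export
read_trace_csv <- function(path, geometry = screen_geometry()) {
  first <- readLines(path, n = 1)
  fs <- 600
  skip <- 0
  if (startsWith(first, "# fs=")) {
    fs <- as.numeric(sub("# fs=", "", first))
    skip <- 1
  }
  df <- utils::read.csv(path, skip = skip)
  gaze_trace(df$t, df$x, df$y, df$valid == 1, fs = fs, geometry = geometry)
}
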