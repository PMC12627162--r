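#' Auditory feedback parameters
#'
#' Parameters of the distance-to-loudness mapping used by the closed-loop
#' search task. Gaze-target distance is mapped exponentially onto loudness
#' (to compensate for the roughly logarithmic perception of sound intensity),
#' saturating at `d_max` and silent within `silence_radius` of the target.
#'
#' @param d_max Distance (degrees) at which loudness saturates at 1.
#' @param tone_hz Nominal carrier frequency of the feedback tone (metadata).
#' @param curve_base Base of the exponential mapping; must exceed 1. The
#'   default `exp(1)` gives the natural exponential curve.
#' @param silence_radius Distance (degrees) below which the tone is silent;
#'   defaults to the target radius so that silence means "on target".
#' @return An object of class `feedback_params`.
#' @export
feedback_params <- function(d_max = 17.8, tone_hz = 440, curve_base = exp(1),
                            silence_radius = 4.1) {
  if (curve_base <= 1) stop("curve_base must be > 1", call. = FALSE)
  if (silence_radius < 0 || d_max <= silence_radius)
    stop("need d_max > silence_radius >= 0", call. = FALSE)
  structure(list(d_max = d_max, tone_hz = tone_hz, curve_base = curve_base,
                 silence_radius = silence_radius),
            class = "feedback_params")
}

#' Study configuration for the audio-visual search task
#'
#' Defines the biased target distribution and the trial timing rules. With a
#' left bias the 180 trials are distributed 90-60-30 over the left, central
#' and right pair of grid columns (mirrored for a right bias), a 2:1 ratio of
#' targets between the two hemifields.
#'
#' @param bias_side `"left"` or `"right"`: the target-rich hemifield.
#' @param n_trials Number of search trials.
#' @param zone_counts Trial counts over the left, centre and right
#'   column-pair zones, in left-to-right order. Defaults to `c(90, 60, 30)`
#'   for a left bias and its mirror for a right bias.
#' @param dwell_s Continuous on-target dwell required for success (seconds).
#' @param deadline_s Trial deadline (seconds).
#' @param start_fix_s Central fixation required before trial start (seconds).
#' @param fs Sampling rate of the gaze stream (Hz).
#' @param target_radius Target radius in degrees.
#' @param seed Optional integer seed recorded with the configuration.
#' @return An object of class `study_config`.
#' @export
study_config <- function(bias_side = c("left", "right"), n_trials = 180L,
                         zone_counts = NULL, dwell_s = 0.5, deadline_s = 10,
                         start_fix_s = 0.5, fs = 600, target_radius = 4.1,
                         seed = NULL) {
  bias_side <- match.arg(bias_side)
  if (is.null(zone_counts)) {
    zone_counts <- if (bias_side == "left") c(90L, 60L, 30L) else c(30L, 60L, 90L)
    zone_counts <- round(zone_counts * n_trials / 180)
  }
  if (length(zone_counts) != 3L || sum(zone_counts) != n_trials)
    stop("zone_counts must be a length-3 vector summing to n_trials", call. = FALSE)
  stopifnot(dwell_s > 0, deadline_s > dwell_s, fs > 0, target_radius > 0)
  structure(list(bias_side = bias_side, n_trials = as.integer(n_trials),
                 zone_counts = as.integer(zone_counts), dwell_s = dwell_s,
                 deadline_s = deadline_s, start_fix_s = start_fix_s,
                 fs = fs, target_radius = target_radius, seed = seed),
            class = "study_config")
}

#' Build the search target grid
#'
#' Targets lie on the Cartesian product of mirrored horizontal eccentricities
#' and vertical eccentricities (mirrored about the centre where non-zero).
#' The defaults give 6 horizontal x 3 vertical = 18 unique positions.
#'
#' @param h_ecc Positive horizontal eccentricities, mirrored to both sides.
#' @param v_ecc Vertical eccentricities (0 allowed), mirrored where non-zero.
#' @param radius Target radius in degrees.
#' @return A data frame with columns `x`, `y`, `radius`, `column`, `row`.
#' @examples
#' nrow(build_target_grid())  # 18
#' @export
build_target_grid <- function(h_ecc = c(3.8, 11.4, 19.9), v_ecc = c(0, 7.5),
                              radius = 4.1) {
  if (any(h_ecc <= 0)) stop("horizontal eccentricities must be positive", call. = FALSE)
  if (any(v_ecc < 0)) stop("vertical eccentricities must be non-negative", call. = FALSE)
  xs <- sort(c(-h_ecc, h_ecc))
  ys <- sort(unique(c(-v_ecc, v_ecc)))
  if (anyDuplicated(xs) || anyDuplicated(ys))
    stop("duplicate grid coordinates", call. = FALSE)
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  grid$radius <- radius
  grid$column <- match(grid$x, xs)
  grid$row <- match(grid$y, ys)
  grid[order(grid$column, grid$row), c("x", "y", "radius", "column", "row")]
}

# Zone index per grid column: 1 = leftmost column pair, 2 = central, 3 = right.
.zone_of_column <- function(column, n_cols = 6L) {
  ceiling(column / (n_cols / 3))
}

#' Sample a biased target sequence
#'
#' Allocates the configured per-zone trial counts over the grid positions of
#' each zone (as evenly as possible, remainders assigned deterministically by
#' position index) and returns them in a seeded uniform random order. The
#' multiset of targets depends only on the configuration, never on the seed.
#'
#' @param config A [study_config()].
#' @param grid A target grid from [build_target_grid()].
#' @return A data frame of `n_trials` rows: the grid columns plus `trial`
#'   (1-based trial number), `zone` and `bias_label`
#'   (`"biased"`/`"unbiased"` hemifield of the target).
#' @export
sample_target_sequence <- function(config, grid = build_target_grid()) {
  stopifnot(inherits(config, "study_config"))
  grid$zone <- .zone_of_column(grid$column, max(grid$column))
  reps <- integer(nrow(grid))
  for (z in 1:3) {
    idx <- which(grid$zone == z)
    n_z <- config$zone_counts[z]
    base <- n_z %/% length(idx)
    rem <- n_z %% length(idx)
    reps[idx] <- base + as.integer(seq_along(idx) <= rem)
  }
  seq_rows <- rep(seq_len(nrow(grid)), times = reps)
  seq_rows <- sample(seq_rows)   # seeded by the caller's RNG state
  out <- grid[seq_rows, ]
  out$trial <- seq_len(nrow(out))
  biased_sign <- if (config$bias_side == "left") -1 else 1
  out$bias_label <- ifelse(sign(out$x) == biased_sign, "biased", "unbiased")
  rownames(out) <- NULL
  out
}

#' Map gaze-target distance to loudness
#'
#' Normalised exponential mapping: silent at or inside `silence_radius`,
#' saturating at 1 for distances at or beyond `d_max`, and
#' \eqn{(B^u - 1)/(B - 1)} in between, with
#' \eqn{u = (d - r_0)/(d_{max} - r_0)} and \eqn{B} the curve base. The curve
#' is continuous, strictly increasing and convex on the open interval.
#'
#' @param d Gaze-target distance(s) in degrees; must be non-negative.
#' @param params A [feedback_params()].
#' @return Loudness in `[0, 1]`, same length as `d`.
#' @export
volume_from_distance <- function(d, params = feedback_params()) {
  stopifnot(inherits(params, "feedback_params"))
  if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative", call. = FALSE)
  u <- (d - params$silence_radius) / (params$d_max - params$silence_radius)
  u <- pmin(pmax(u, 0), 1)
  B <- params$curve_base
  (B^u - 1) / (B - 1)
}

#' Euclidean gaze-target distance
#'
#' @param x,y Gaze coordinates in degrees (vectorised).
#' @param target A single row of a target grid (list or data frame with
#'   `x` and `y`).
#' @param valid Optional logical vector; invalid samples yield `NA`.
#' @return Distance(s) to the target centre, degrees.
#' @export
gaze_target_distance <- function(x, y, target, valid = NULL) {
  d <- sqrt((x - target$x)^2 + (y - target$y)^2)
  if (!is.null(valid)) d[!valid] <- NA_real_
  d
}

#' Create the per-trial state machine
#'
#' The trial runs from `t = 0` (after the pre-trial central fixation has been
#' held) and ends either in `SUCCESS`, when the gaze has stayed continuously
#' within the target radius for `dwell_s`, or in `TIMEOUT` at `deadline_s`.
#' The dwell accumulator resets to zero whenever the gaze leaves the radius
#' (or the sample is invalid).
#'
#' @param target Target row (`x`, `y`, `radius`).
#' @param config A [study_config()].
#' @param params A [feedback_params()].
#' @return A state list; advance it with [step_trial()].
#' @export
trial_state <- function(target, config, params = feedback_params()) {
  list(target = target, config = config, params = params,
       status = "RUNNING", dwell = 0, t = 0, n = 0L, end_time = NA_real_)
}

#' Advance the trial state machine by one gaze sample
#'
#' @param state State from [trial_state()] or a previous step.
#' @param t Sample time, seconds from trial onset.
#' @param x,y Gaze position in degrees.
#' @param valid Logical validity flag.
#' @return A list `(state, loudness)`; `state$status` is one of
#'   `"RUNNING"`, `"SUCCESS"`, `"TIMEOUT"`.
#' @export
step_trial <- function(state, t, x, y, valid = TRUE) {
  if (state$status != "RUNNING")
    stop("trial already ended (", state$status, ")", call. = FALSE)
  d <- if (valid) gaze_target_distance(x, y, state$target) else NA_real_
  loud <- if (valid) volume_from_distance(d, state$params) else NA_real_
  radius <- if (!is.null(state$target$radius)) state$target$radius else state$config$target_radius
  if (valid && !is.na(d) && d <= radius) {
    state$dwell <- state$dwell + 1 / state$config$fs
  } else {
    state$dwell <- 0
  }
  state$t <- t
  state$n <- state$n + 1L
  if (state$dwell >= state$config$dwell_s - 1e-9) {
    state$status <- "SUCCESS"
    state$end_time <- t
  } else if (t >= state$config$deadline_s) {
    state$status <- "TIMEOUT"
    state$end_time <- t
  }
  list(state = state, loudness = loud)
}

# Vectorised equivalent of running step_trial over a whole candidate trace.
# Returns the index at which the trial ends and the terminal status.
.scan_trial <- function(d, valid, config, radius) {
  n_dwell <- as.integer(round(config$dwell_s * config$fs))
  inside <- !is.na(d) & valid & d <= radius
  if (any(inside)) {
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= n_dwell)
    if (length(hit)) {
      k <- hit[1]
      end_idx <- ends[k] - r$lengths[k] + n_dwell  # dwell completes here
      return(list(status = "SUCCESS", end_idx = end_idx))
    }
  }
  list(status = "TIMEOUT", end_idx = length(d))
}

#' Run one closed-loop search trial with a synthetic agent
#'
#' Composes the trial state machine with an agent policy: the agent proposes
#' a gaze trajectory driven only by the scalar loudness feedback (see
#' [simulate_avs_search()]), the engine computes per-sample loudness and
#' terminates the trial at the success dwell or the deadline.
#'
#' @param agent An [agent_params()] object (with current `prior`).
#' @param target Target row (`x`, `y`, `radius`).
#' @param config A [study_config()].
#' @param params A [feedback_params()].
#' @param geometry A [screen_geometry()].
#' @return A list of class `trial_record`: `target`, `trace` (data frame
#'   `t,x,y,valid`), `volume_series`, `found`, `search_time_s`,
#'   `bias_label`.
#' @export
run_trial <- function(agent, target, config, params = feedback_params(),
                      geometry = screen_geometry()) {
  trace <- simulate_avs_search(agent, target, config, params, geometry)
  if (any(!is.finite(trace$x[trace$valid])) || any(!is.finite(trace$y[trace$valid])))
    stop("agent emitted non-finite coordinates", call. = FALSE)
  radius <- if (!is.null(target$radius)) target$radius else config$target_radius
  d <- gaze_target_distance(trace$x, trace$y, target, trace$valid)
  res <- .scan_trial(d, trace$valid, config, radius)
  idx <- seq_len(res$end_idx)
  trace <- trace[idx, , drop = FALSE]
  loud <- volume_from_distance(ifelse(is.na(d[idx]), params$d_max, d[idx]), params)
  loud[is.na(d[idx])] <- NA_real_
  biased_sign <- if (config$bias_side == "left") -1 else 1
  structure(list(target = target, trace = trace, volume_series = loud,
                 distance_series = d[idx],
                 found = res$status == "SUCCESS",
                 search_time_s = trace$t[res$end_idx],
                 bias_label = if (sign(target$x) == biased_sign) "biased" else "unbiased"),
            class = "trial_record")
}
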