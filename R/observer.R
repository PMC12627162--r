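#' Search-agent parameters
#'
#' Parameters of the synthetic run-and-tumble observer that performs the
#' closed-loop search. The agent alternates fixations and saccades; at the
#' end of each fixation it reads the scalar loudness, keeps (approximately)
#' its heading if loudness decreased since the previous fixation and
#' re-draws the heading ("tumbles") otherwise. The first saccade of a trial
#' is drawn toward the hemifield favoured by the agent's learned prior. The
#' policy never sees target coordinates — only the loudness sequence.
#'
#' @param saccade_amp_mean,saccade_amp_sd Saccade amplitude distribution
#'   (degrees); realised amplitudes are additionally scaled by the current
#'   loudness so that the agent takes smaller steps close to the target.
#' @param fixation_dur_mean,fixation_dur_sd Fixation duration distribution
#'   (seconds).
#' @param prior_learning_rate Exponential-moving-average rate with which the
#'   hemifield prior tracks observed target sides, in `[0, 1]`.
#' @param prior_strength How strongly the prior biases the first-saccade
#'   direction: the probability of starting toward the biased side is
#'   `0.5 + prior_strength * (prior - 0.5)`.
#' @param tumble_angle_sd Heading wobble (radians) kept between successful
#'   (loudness-decreasing) saccades; the reversal after a loudness increase
#'   uses twice this spread.
#' @param noise_sd Per-sample gaze jitter during fixations (degrees).
#' @param prior Initial probability assigned to the biased hemifield.
#' @param practice_gain,practice_tau Task-practice effect: at trial `k` the
#'   fixation-duration mean is multiplied by
#'   `1 + practice_gain * exp(-(k - 1) / practice_tau)`, so sampling is
#'   slower early in training and speeds up with practice.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(saccade_amp_mean = 8, saccade_amp_sd = 2,
                         fixation_dur_mean = 0.25, fixation_dur_sd = 0.05,
                         prior_learning_rate = 0.02, prior_strength = 0.8,
                         tumble_angle_sd = 0.3, noise_sd = 0.05,
                         prior = 0.5, practice_gain = 0.5,
                         practice_tau = 60) {
  stopifnot(saccade_amp_sd >= 0, fixation_dur_sd >= 0, tumble_angle_sd >= 0,
            noise_sd >= 0, prior >= 0, prior <= 1)
  if (prior_learning_rate < 0 || prior_learning_rate > 1)
    stop("prior_learning_rate must be in [0,1]", call. = FALSE)
  structure(as.list(environment()), class = "agent_params")
}

#' Update the hemifield prior
#'
#' Exponential moving average of the indicator that the target fell on the
#' biased side: `prior' = (1 - rate) * prior + rate * on_biased_side`.
#'
#' @param prior Current probability of the biased side, in `[0, 1]`.
#' @param on_biased_side Logical (or 0/1): was this trial's target on the
#'   biased side?
#' @param rate Learning rate in `[0, 1]`.
#' @return Updated prior, bounded in `[0, 1]`.
#' @export
update_hemifield_prior <- function(prior, on_biased_side, rate) {
  if (rate < 0 || rate > 1) stop("rate must be in [0,1]", call. = FALSE)
  stopifnot(prior >= 0, prior <= 1)
  (1 - rate) * prior + rate * as.numeric(on_biased_side)
}

#' Simulate one closed-loop search trajectory
#'
#' Generates a full-deadline candidate gaze trace for one trial under the
#' run-and-tumble policy described in [agent_params()]: keep (approximately)
#' the heading while loudness decreases, reverse it (with twice the wobble)
#' when loudness increases, and tumble to a uniform heading where loudness
#' is saturated and therefore carries no gradient. Loudness is read at each
#' fixation centroid; once the agent hears silence (gaze inside the target
#' radius) it holds fixation for the remainder of the trial. Gaze is clamped
#' to the physical screen. [run_trial()] truncates the result at the success
#' dwell or deadline.
#'
#' @param agent An [agent_params()].
#' @param target Target row (`x`, `y`).
#' @param config A [study_config()].
#' @param params A [feedback_params()].
#' @param geometry A [screen_geometry()].
#' @return A [gaze_trace()] covering the whole deadline.
#' @export
simulate_avs_search <- function(agent, target, config,
                                params = feedback_params(),
                                geometry = screen_geometry()) {
  fs <- config$fs
  n_max <- as.integer(round(config$deadline_s * fs))
  half <- screen_half_extent_deg(geometry)
  x <- numeric(n_max); y <- numeric(n_max)
  filled <- 0L
  cur <- c(0, 0)
  heading <- NA_real_
  last_loud <- volume_from_distance(
    gaze_target_distance(cur[1], cur[2], target), params)
  biased_sign <- if (config$bias_side == "left") -1 else 1
  first <- TRUE

  emit <- function(n, px, py, jitter = TRUE) {
    n <- min(n, n_max - filled)
    if (n <= 0) return(invisible(NULL))
    idx <- filled + seq_len(n)
    if (jitter && agent$noise_sd > 0) {
      x[idx] <<- px + stats::rnorm(n, 0, agent$noise_sd)
      y[idx] <<- py + stats::rnorm(n, 0, agent$noise_sd)
    } else {
      x[idx] <<- px; y[idx] <<- py
    }
    filled <<- filled + n
    invisible(NULL)
  }

  while (filled < n_max) {
    dur <- max(stats::rnorm(1, agent$fixation_dur_mean, agent$fixation_dur_sd),
               0.05)
    loud <- volume_from_distance(
      gaze_target_distance(cur[1], cur[2], target), params)
    if (loud == 0) {           # silence: on target, hold until trial end
      emit(n_max - filled, cur[1], cur[2])
      break
    }
    emit(max(1L, as.integer(round(dur * fs))), cur[1], cur[2])
    if (filled >= n_max) break
    if (first) {
      p_biased <- min(max(0.5 + agent$prior_strength * (agent$prior - 0.5), 0), 1)
      s <- if (stats::runif(1) < p_biased) biased_sign else -biased_sign
      theta <- stats::runif(1, -pi / 2, pi / 2)
      heading <- if (s > 0) theta else pi - theta
      first <- FALSE
    } else if (loud >= 1 - 1e-9 && last_loud >= 1 - 1e-9) {
      # saturated: no gradient signal; explore, recentring when far out
      # (screen knowledge only, never target coordinates)
      heading <- if (sqrt(sum(cur^2)) > 12)
        atan2(-cur[2], -cur[1]) + stats::rnorm(1, 0, agent$tumble_angle_sd)
      else stats::runif(1, 0, 2 * pi)
    } else if (loud < last_loud - 1e-9) {
      heading <- heading + stats::rnorm(1, 0, agent$tumble_angle_sd)
    } else {
      heading <- heading + pi + stats::rnorm(1, 0, 2 * agent$tumble_angle_sd)
    }
    last_loud <- loud
    amp <- max(stats::rnorm(1, agent$saccade_amp_mean, agent$saccade_amp_sd), 1) *
      max(loud, 0.15)
    nxt <- cur + amp * c(cos(heading), sin(heading))
    nxt[1] <- min(max(nxt[1], -half[1]), half[1])
    nxt[2] <- min(max(nxt[2], -half[2]), half[2])
    for (k in 1:3) {                       # 3-sample ballistic ramp
      p <- cur + (nxt - cur) * k / 3
      emit(1L, p[1], p[2], jitter = FALSE)
      if (filled >= n_max) break
    }
    cur <- nxt
  }
  gaze_trace(t = seq_len(n_max) / fs, x = x, y = y,
             valid = rep(TRUE, n_max), fs = fs, geometry = geometry)
}

#' Free-viewing style parameters
#'
#' Generative description of a free-viewing observer: lognormal fixation
#' durations, gamma saccade amplitudes, a stationary horizontal bias toward
#' which the scanpath mean-reverts, an extra early bias applied in the first
#' second (emulating the initial horizontal deviation typical of scene
#' viewing), and blink statistics. "Static" viewers are obtained with long
#' durations and large amplitudes, "dynamic" viewers with short durations
#' and small amplitudes.
#'
#' @param fix_dur_meanlog,fix_dur_sdlog Lognormal fixation-duration
#'   parameters (log-seconds). Defaults give a mean near 2.1 s.
#' @param sacc_amp_shape,sacc_amp_scale Gamma saccade-amplitude parameters
#'   (degrees). Defaults give a mean near 6.8 degrees.
#' @param horiz_bias Stationary mean horizontal fixation position (degrees).
#' @param early_bias Extra horizontal offset of fixations whose onset falls
#'   in the first second (degrees).
#' @param blink_rate Blinks per minute.
#' @param blink_dur_mean Mean blink duration (seconds).
#' @param pull Mean-reversion (recentring) strength per saccade toward
#'   `(horiz_bias, 0)`, in `(0, 1]`; keeps the stationary scanpath spread at
#'   the few-degree scale typical of screen viewing.
#' @param jitter_sd Within-fixation positional jitter (degrees).
#' @return An object of class `viewer_style`.
#' @export
viewer_style_params <- function(fix_dur_meanlog = log(2.1) - 0.125,
                                fix_dur_sdlog = 0.5,
                                sacc_amp_shape = 4, sacc_amp_scale = 1.7,
                                horiz_bias = 0, early_bias = 0,
                                blink_rate = 15, blink_dur_mean = 0.12,
                                pull = 0.7, jitter_sd = 0.05) {
  stopifnot(fix_dur_sdlog >= 0, sacc_amp_shape > 0, sacc_amp_scale > 0,
            blink_rate >= 0, blink_dur_mean > 0, pull > 0, pull <= 1,
            jitter_sd >= 0)
  structure(as.list(environment()), class = "viewer_style")
}

#' Generate a free-viewing fixation sequence
#'
#' Event-level generator underlying [simulate_free_viewing()]: produces the
#' fixation table (onset, duration, centroid) directly, without rendering a
#' sample-level trace. Each saccade target is a mean-reverting step toward
#' `(horiz_bias, 0)` plus a gamma-amplitude displacement in a uniform
#' direction, clamped to the screen, so the long-run mean fixation abscissa
#' converges to `horiz_bias`.
#'
#' @param style A [viewer_style_params()].
#' @param duration_s Record duration in seconds.
#' @param sacc_dur_s Inter-fixation (saccade) duration in seconds.
#' @param geometry A [screen_geometry()].
#' @return Data frame `onset, duration, x, y`.
#' @export
simulate_fixation_sequence <- function(style, duration_s, sacc_dur_s = 3 / 600,
                                       geometry = screen_geometry()) {
  stopifnot(inherits(style, "viewer_style"), duration_s > 0)
  half <- screen_half_extent_deg(geometry)
  onset <- dur <- fx <- fy <- numeric(0)
  cur <- c(0, 0)
  t <- 0
  while (t < duration_s) {
    d <- stats::rlnorm(1, style$fix_dur_meanlog, style$fix_dur_sdlog)
    d <- min(d, duration_s - t)
    if (d <= 0) break
    onset <- c(onset, t); dur <- c(dur, d)
    fx <- c(fx, cur[1] + if (t < 1) style$early_bias else 0)
    fy <- c(fy, cur[2])
    t <- t + d + sacc_dur_s
    amp <- stats::rgamma(1, style$sacc_amp_shape, scale = style$sacc_amp_scale)
    theta <- stats::runif(1, 0, 2 * pi)
    cur <- c(style$horiz_bias + (1 - style$pull) * (cur[1] - style$horiz_bias) +
               amp * cos(theta),
             (1 - style$pull) * cur[2] + amp * sin(theta))
    cur[1] <- min(max(cur[1], -half[1]), half[1])
    cur[2] <- min(max(cur[2], -half[2]), half[2])
  }
  data.frame(onset = onset, duration = dur, x = fx, y = fy)
}

#' Simulate a free-viewing gaze trace
#'
#' Renders a [simulate_fixation_sequence()] into a sample-level trace:
#' jittered samples around each fixation centroid, 3-sample linear ramps for
#' saccades, and blink-like runs of invalid samples inserted at a Poisson
#' rate. The true fixation table is attached as attribute
#' `"fixations_true"`.
#'
#' @inheritParams simulate_fixation_sequence
#' @param fs Sampling rate in Hz.
#' @return A [gaze_trace()].
#' @export
simulate_free_viewing <- function(style, duration_s, fs = 600,
                                  geometry = screen_geometry()) {
  fix <- simulate_fixation_sequence(style, duration_s, sacc_dur_s = 3 / fs,
                                    geometry = geometry)
  n <- as.integer(round(duration_s * fs))
  tt <- seq_len(n) / fs
  x <- numeric(n); y <- numeric(n)
  # paint fixations, then ramps between consecutive centroids
  prev_end <- 0L
  prev_xy <- c(fix$x[1], fix$y[1])
  for (i in seq_len(nrow(fix))) {
    i0 <- max(1L, as.integer(floor(fix$onset[i] * fs)) + 1L)
    i1 <- min(n, as.integer(round((fix$onset[i] + fix$duration[i]) * fs)))
    if (i1 < i0) next
    idx <- i0:i1
    x[idx] <- fix$x[i] + stats::rnorm(length(idx), 0, style$jitter_sd)
    y[idx] <- fix$y[i] + stats::rnorm(length(idx), 0, style$jitter_sd)
    if (prev_end > 0L && i0 > prev_end + 1L) {   # saccade ramp
      ramp <- (prev_end + 1L):(i0 - 1L)
      w <- seq_along(ramp) / (length(ramp) + 1)
      x[ramp] <- prev_xy[1] + w * (fix$x[i] - prev_xy[1])
      y[ramp] <- prev_xy[2] + w * (fix$y[i] - prev_xy[2])
    }
    prev_end <- i1
    prev_xy <- c(fix$x[i], fix$y[i])
  }
  if (prev_end < n && prev_end > 0L) {           # hold last fixation
    idx <- (prev_end + 1L):n
    x[idx] <- prev_xy[1] + stats::rnorm(length(idx), 0, style$jitter_sd)
    y[idx] <- prev_xy[2] + stats::rnorm(length(idx), 0, style$jitter_sd)
  }
  valid <- rep(TRUE, n)
  n_blinks <- stats::rpois(1, style$blink_rate * duration_s / 60)
  if (n_blinks > 0) {
    starts <- stats::runif(n_blinks, 0, duration_s)
    durs <- pmax(stats::rnorm(n_blinks, style$blink_dur_mean,
                              0.25 * style$blink_dur_mean), 0.05)
    for (b in seq_len(n_blinks)) {
      idx <- which(tt >= starts[b] & tt < starts[b] + durs[b])
      valid[idx] <- FALSE
    }
  }
  out <- gaze_trace(tt, x, y, valid, fs = fs, geometry = geometry)
  attr(out, "fixations_true") <- fix
  out
}

#' Landmark-task design
#'
#' Eleven equidistant bisection offsets spanning +/- `range_deg` about the
#' veridical centre (including it), each repeated `reps` times.
#'
#' @param range_deg Half-range of bisection offsets (degrees).
#' @param n_offsets Number of distinct offsets (odd, so 0 is included).
#' @param reps Repetitions per offset.
#' @param timeout_s Response deadline (metadata).
#' @return An object of class `landmark_design`.
#' @export
landmark_design <- function(range_deg = 0.68, n_offsets = 11L, reps = 8L,
                            timeout_s = 5) {
  stopifnot(n_offsets %% 2 == 1, reps >= 1, range_deg > 0)
  offsets <- seq(-range_deg, range_deg, length.out = n_offsets)
  structure(list(offsets = offsets, reps = reps, timeout_s = timeout_s,
                 n_trials = n_offsets * reps),
            class = "landmark_design")
}

#' Simulate a landmark-task session
#'
#' Bernoulli responses from a two-parameter logistic psychometric function:
#' `P(respond "right longer" | offset o) = logistic(slope * (o - pse))`.
#'
#' @param pse True point of subjective equality (degrees).
#' @param slope Psychometric slope (1/degrees), positive.
#' @param design A [landmark_design()].
#' @return Data frame `offset, response` (`response` 1 = "right longer"),
#'   trials in randomised order.
#' @export
simulate_landmark_session <- function(pse, slope, design = landmark_design()) {
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  offs <- sample(rep(design$offsets, design$reps))
  p <- stats::plogis(slope * (offs - pse))
  data.frame(offset = offs, response = stats::rbinom(length(offs), 1, p))
}

#' Population description for synthetic cohorts
#'
#' Hyper-parameters from which per-participant styles, agents and
#' psychometric parameters are drawn. Defaults emulate healthy adults:
#' blank-screen viewing with ~2 s fixations and ~7-degree saccades, image
#' viewing with ~0.3 s fixations and ~4-degree saccades, a small natural
#' leftward bias, and modest inter-individual variability.
#'
#' @param natural_bias_mean,natural_bias_sd Population distribution of the
#'   stationary horizontal bias (degrees; negative = leftward).
#' @param early_bias_mean,early_bias_sd Extra first-second bias (degrees).
#' @param transfer_gain Degrees of post-training bias shift per unit of
#'   `2 * prior - 1` (a fully learned 2:1 prior contributes 1/3 of this).
#' @param ivt_transfer_frac Fraction of the learned shift expressed during
#'   image viewing: visual content anchors gaze, so the transfer measured
#'   over images is attenuated relative to the blank screen.
#' @param lt_transfer_gain Same as `transfer_gain`, for the landmark-task
#'   PSE (default 0: no transfer to the landmark task).
#' @param pse_sd Population SD of the true pre-test PSE (degrees).
#' @param lt_slope_mean Mean psychometric slope (1/degrees).
#' @param prior_learning_rate,prior_strength Agent learning parameters.
#' @return A list of class `cohort_population`.
#' @export
cohort_population <- function(natural_bias_mean = -0.3, natural_bias_sd = 1.0,
                              early_bias_mean = -0.2, early_bias_sd = 0.4,
                              transfer_gain = 1.5, ivt_transfer_frac = 0.4,
                              lt_transfer_gain = 0,
                              pse_sd = 0.2, lt_slope_mean = 8,
                              prior_learning_rate = 0.02,
                              prior_strength = 0.8) {
  structure(as.list(environment()), class = "cohort_population")
}

#' Generate a balanced synthetic cohort
#'
#' Assigns participants to the left- and right-bias groups by shuffle
#' randomisation of a balanced ordered list and draws each participant's
#' style, agent and psychometric parameters from the population
#' distributions. For odd `n` the groups differ by one (with a warning).
#'
#' @param n Number of participants.
#' @param population A [cohort_population()].
#' @return Data frame manifest, one row per participant, with group
#'   assignment and all true generative parameters.
#' @export
generate_cohort <- function(n, population = cohort_population()) {
  if (n %% 2 == 1) warning("odd n: groups differ by 1")
  groups <- sample(rep(c("left", "right"), length.out = n))
  pop <- population
  mult <- function(sd) exp(stats::rnorm(n, 0, sd))
  data.frame(
    participant = seq_len(n),
    group = groups,
    natural_bias = stats::rnorm(n, pop$natural_bias_mean, pop$natural_bias_sd),
    early_bias = stats::rnorm(n, pop$early_bias_mean, pop$early_bias_sd),
    bsv_dur_meanlog = log(2.1) - 0.125 + stats::rnorm(n, 0, 0.2),
    bsv_amp_scale = 1.7 * mult(0.2),
    ivt_dur_meanlog = log(0.3) - 0.08 + stats::rnorm(n, 0, 0.2),
    ivt_amp_scale = 1.0 * mult(0.2),
    agent_amp_mean = 8 * mult(0.15),
    agent_fix_dur = 0.25 * mult(0.15),
    prior_learning_rate = pop$prior_learning_rate,
    prior_strength = pop$prior_strength,
    transfer_gain = pop$transfer_gain,
    ivt_transfer_frac = pop$ivt_transfer_frac,
    lt_transfer_gain = pop$lt_transfer_gain,
    pse_pre = stats::rnorm(n, 0, pop$pse_sd),
    lt_slope = pop$lt_slope_mean * mult(0.3),
    stringsAsFactors = FALSE
  )
}

#' Select a horizontally balanced image subset
#'
#' Greedy selection followed by single-swap exchange: chooses `k` candidates
#' whose centres of mass average as close as possible to the horizontal
#' midpoint; the returned subset admits no single swap that reduces the
#' absolute mean.
#'
#' @param candidate_bias_values Horizontal centre of mass of each candidate
#'   image (degrees from midline).
#' @param k Subset size.
#' @return Integer indices of the selected candidates.
#' @export
select_balanced_images <- function(candidate_bias_values, k) {
  v <- candidate_bias_values
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > length(v)) stop("k exceeds number of candidates", call. = FALSE)
  chosen <- integer(0)
  s <- 0
  for (i in seq_len(k)) {     # greedy: minimise |running mean| at each add
    rest <- setdiff(seq_along(v), chosen)
    gains <- abs((s + v[rest]) / (length(chosen) + 1))
    pick <- rest[which.min(gains)]
    chosen <- c(chosen, pick)
    s <- s + v[pick]
  }
  repeat {                    # exchange passes to a single-swap local optimum
    rest <- setdiff(seq_along(v), chosen)
    if (!length(rest)) break
    # best single swap: replace chosen i by unchosen j
    deltas <- outer(v[chosen], v[rest], function(a, b) abs((s - a + b) / k))
    if (min(deltas) >= abs(s / k) - 1e-15) break
    w <- arrayInd(which.min(deltas), dim(deltas))
    i <- chosen[w[1]]; j <- rest[w[2]]
    s <- s - v[i] + v[j]
    chosen[chosen == i] <- j
  }
  sort(chosen)
}
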