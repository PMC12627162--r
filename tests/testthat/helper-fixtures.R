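# Shared fixtures and independent oracles, built in code at test time.

# A jittered stationary trace with linear-displacement "saccades" injected at
# known sample indices. Returns the trace plus the ground-truth onsets.
make_saccade_fixture <- function(n = 600, fs = 600, jitter = 0.01,
                                 sacc_starts = c(150, 300, 450),
                                 sacc_len = 18, velocity = 20) {
  x <- cumsum(rep(0, n)) + rnorm(n, 0, jitter)
  y <- rnorm(n, 0, jitter)
  base <- numeric(n)
  for (s in sacc_starts) {
    idx <- s:(s + sacc_len - 1)
    base[idx] <- base[idx] + cumsum(rep(velocity / fs, sacc_len))
    if (s + sacc_len <= n)
      base[(s + sacc_len):n] <- base[(s + sacc_len):n] + velocity * sacc_len / fs
  }
  gaze_trace(seq_len(n) / fs, x + base, y, fs = fs)
}

# Independent brute-force event detector: direct per-sample thresholding and
# an explicit loop for run grouping. Deliberately naive; mirrors the stated
# detection rule, not the package implementation.
brute_force_events <- function(trace, lambda = 6, min_sacc_dur_s = 0.012) {
  fs <- attr(trace, "fs")
  n <- nrow(trace)
  p <- trace$x
  q <- trace$y
  vx <- vy <- numeric(n)
  for (i in 3:(n - 2)) {
    vx[i] <- (p[i + 2] + p[i + 1] - p[i - 1] - p[i - 2]) * fs / 6
    vy[i] <- (q[i + 2] + q[i + 1] - q[i - 1] - q[i - 2]) * fs / 6
  }
  vx[2] <- (p[3] - p[1]) * fs / 2; vx[n - 1] <- (p[n] - p[n - 2]) * fs / 2
  vy[2] <- (q[3] - q[1]) * fs / 2; vy[n - 1] <- (q[n] - q[n - 2]) * fs / 2
  vx[1] <- (p[2] - p[1]) * fs; vx[n] <- (p[n] - p[n - 1]) * fs
  vy[1] <- (q[2] - q[1]) * fs; vy[n] <- (q[n] - q[n - 1]) * fs
  sdr <- function(v) sqrt(max(median(v^2) - median(v)^2, .Machine$double.eps))
  ex <- lambda * sdr(vx); ey <- lambda * sdr(vy)
  lab <- (vx / ex)^2 + (vy / ey)^2 > 1
  min_len <- max(1, round(min_sacc_dur_s * fs))
  # drop short saccadic runs
  i <- 1
  while (i <= n) {
    if (lab[i]) {
      j <- i
      while (j < n && lab[j + 1]) j <- j + 1
      if (j - i + 1 < min_len) lab[i:j] <- FALSE
      i <- j + 1
    } else i <- i + 1
  }
  # collect event boundaries
  onsets <- offsets <- numeric(0); types <- character(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && lab[j + 1] == lab[i]) j <- j + 1
    onsets <- c(onsets, trace$t[i]); offsets <- c(offsets, trace$t[j])
    types <- c(types, if (lab[i]) "saccade" else "fixation")
    i <- j + 1
  }
  data.frame(onset = onsets, offset = offsets, type = types)
}

# Event-level cohort shift experiment: pre/post free-viewing records per
# participant, an optional induced shift toward the biased side, t-test on
# the sign-corrected shifts. `n_images > 1` emulates the image-viewing
# condition (per-image shifts collapsed by the median); `n_images = 1` a
# single blank-screen record. Fast path used by calibration tests.
simulate_shift_experiment <- function(n = 40, delta = 0, duration_s = 10,
                                      n_images = 1) {
  group <- rep(c("left", "right"), length.out = n)
  shift_raw <- numeric(n)
  ivt_style <- function(bias)
    if (n_images > 1)
      viewer_style_params(fix_dur_meanlog = log(0.3) - 0.08,
                          fix_dur_sdlog = 0.4, sacc_amp_shape = 4,
                          sacc_amp_scale = 1, horiz_bias = bias)
    else viewer_style_params(horiz_bias = bias)
  for (i in seq_len(n)) {
    bias <- rnorm(1, 0, 1)
    s <- if (group[i] == "left") -1 else 1
    per_img <- vapply(seq_len(n_images), function(img)
      barycenter(simulate_fixation_sequence(ivt_style(bias + s * delta),
                                            duration_s)) -
        barycenter(simulate_fixation_sequence(ivt_style(bias), duration_s)),
      0)
    shift_raw[i] <- image_shift_collapse(per_img)
  }
  signed <- ifelse(group == "left", -shift_raw, shift_raw)
  one_sample_t_one_sided(signed)
}
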