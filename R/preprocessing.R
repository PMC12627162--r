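#' Saccade-detector parameters
#'
#' Tunables for velocity-threshold event detection and fixation refinement.
#' The velocity threshold is `lambda` median-based standard deviations per
#' axis, combined elliptically; candidate saccades shorter than
#' `min_sacc_dur_s` are discarded. Fixation refinement merges fixations
#' separated by less than `merge_gap_s` in time and `merge_dist_deg` in
#' space and drops fixations shorter than `min_fix_dur_s`.
#'
#' @param lambda Velocity-threshold multiplier.
#' @param min_sacc_dur_s Minimum saccade duration (seconds).
#' @param smooth_window Samples in the velocity kernel (odd; 5 selects the
#'   classical 5-sample kernel, 3 a plain centred difference).
#' @param merge_gap_s,merge_dist_deg,min_fix_dur_s Fixation-refinement
#'   criteria.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(lambda = 6, min_sacc_dur_s = 0.012,
                            smooth_window = 5, merge_gap_s = 0.075,
                            merge_dist_deg = 0.5, min_fix_dur_s = 0.060) {
  stopifnot(lambda > 0, min_sacc_dur_s > 0, smooth_window %in% c(3, 5),
            merge_gap_s > 0, merge_dist_deg > 0, min_fix_dur_s > 0)
  structure(as.list(environment()), class = "detector_params")
}

#' Interpolate blink gaps in a gaze trace
#'
#' Replaces interior invalid samples by linear interpolation of x and y
#' against time; leading and trailing invalid runs (no flanking valid
#' sample) are left invalid. Valid samples are unchanged.
#'
#' @param trace A [gaze_trace()].
#' @return The trace with interior gaps filled and marked valid.
#' @export
interpolate_gaps <- function(trace) {
  v <- which(trace$valid)
  if (!length(v)) stop("trace has no valid samples", call. = FALSE)
  first <- v[1]; last <- v[length(v)]
  gap <- which(!trace$valid)
  gap <- gap[gap > first & gap < last]
  if (length(gap)) {
    trace$x[gap] <- stats::approx(trace$t[v], trace$x[v], xout = trace$t[gap])$y
    trace$y[gap] <- stats::approx(trace$t[v], trace$y[v], xout = trace$t[gap])$y
    trace$valid[gap] <- TRUE
  }
  trace
}

#' Trial-validity rule for missing data
#'
#' A trial is unreliable when more than `max_contig_missing_frac` of its
#' samples are missing in one continuous run (strictly greater than).
#' Scattered missing data of any total amount does not invalidate the trial;
#' the rule applies to the longest contiguous run and is evaluated before
#' interpolation.
#'
#' @param trace A [gaze_trace()].
#' @param max_contig_missing_frac Fraction threshold (default 0.4).
#' @return `TRUE` if the trial is usable.
#' @export
is_valid_trial <- function(trace, max_contig_missing_frac = 0.4) {
  n <- nrow(trace)
  if (n == 0) return(FALSE)
  if (all(trace$valid)) return(TRUE)
  r <- rle(!trace$valid)
  longest <- max(r$lengths[r$values])
  longest <= max_contig_missing_frac * n
}

#' Per-sample gaze velocity
#'
#' Smoothed velocity per axis. With `smooth_window = 5` (default) the
#' classical 5-sample kernel is used,
#' `v[i] = (x[i+2] + x[i+1] - x[i-1] - x[i-2]) * fs / 6`; with 3, a centred
#' difference. Endpoints use shortened one-sided differences.
#'
#' @param trace A uniformly sampled, gap-interpolated [gaze_trace()].
#' @param smooth_window 5 or 3.
#' @return Data frame `vx, vy` in degrees/second, one row per sample.
#' @export
compute_velocity <- function(trace, smooth_window = 5) {
  n <- nrow(trace)
  if (n < smooth_window) stop("trace shorter than velocity window", call. = FALSE)
  fs <- trace_fs(trace)
  one_axis <- function(p) {
    v <- numeric(n)
    if (smooth_window == 5) {
      i <- 3:(n - 2)
      v[i] <- (p[i + 2] + p[i + 1] - p[i - 1] - p[i - 2]) * fs / 6
      v[2] <- (p[3] - p[1]) * fs / 2
      v[n - 1] <- (p[n] - p[n - 2]) * fs / 2
      v[1] <- (p[2] - p[1]) * fs
      v[n] <- (p[n] - p[n - 1]) * fs
    } else {
      i <- 2:(n - 1)
      v[i] <- (p[i + 1] - p[i - 1]) * fs / 2
      v[1] <- (p[2] - p[1]) * fs
      v[n] <- (p[n] - p[n - 1]) * fs
    }
    v
  }
  data.frame(vx = one_axis(trace$x), vy = one_axis(trace$y))
}

# Median-based robust SD of a velocity component, floored at machine scale.
.robust_sd <- function(v) {
  s2 <- stats::median(v^2) - stats::median(v)^2
  sqrt(max(s2, .Machine$double.eps))
}

#' Velocity-threshold saccade detection
#'
#' Labels a sample saccadic when its velocity exceeds the elliptic criterion
#' `(vx/etax)^2 + (vy/etay)^2 > 1`, where `eta = lambda * sigma` per axis
#' and `sigma` is the median-based robust SD of that axis' velocity.
#' Saccades are runs of saccadic samples at least `min_sacc_dur_s` long;
#' the complementary intervals are fixations with centroid equal to the mean
#' sample position. Leading/trailing invalid samples are excluded; interior
#' gaps must have been interpolated first.
#'
#' @param trace A gap-interpolated [gaze_trace()].
#' @param params A [detector_params()].
#' @return An object of class `event_segmentation`: list with data frames
#'   `fixations` (`onset, offset, x, y, duration`) and `saccades`
#'   (`onset, offset, amplitude, peak_velocity, duration`), plus the valid
#'   span analysed.
#' @export
detect_saccades_ek <- function(trace, params = detector_params()) {
  v <- which(trace$valid)
  if (length(v) < params$smooth_window)
    stop("too few valid samples", call. = FALSE)
  span <- v[1]:v[length(v)]
  if (any(!trace$valid[span]))
    stop("interior gaps present; run interpolate_gaps() first", call. = FALSE)
  sub <- trace[span, , drop = FALSE]
  attr(sub, "fs") <- trace_fs(trace)
  vel <- compute_velocity(sub, params$smooth_window)
  etax <- params$lambda * .robust_sd(vel$vx)
  etay <- params$lambda * .robust_sd(vel$vy)
  sacc <- (vel$vx / etax)^2 + (vel$vy / etay)^2 > 1
  fs <- trace_fs(trace)
  min_len <- max(1L, as.integer(round(params$min_sacc_dur_s * fs)))
  r <- rle(sacc)
  # short saccadic runs become fixation samples
  r$values[r$values & r$lengths < min_len] <- FALSE
  lab <- inverse.rle(r)
  r2 <- rle(lab)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  speed <- sqrt(vel$vx^2 + vel$vy^2)
  fix_list <- sacc_list <- list()
  for (k in seq_along(r2$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (r2$values[k]) {
      sacc_list[[length(sacc_list) + 1L]] <- data.frame(
        onset = sub$t[i0], offset = sub$t[i1],
        amplitude = sqrt((sub$x[i1] - sub$x[i0])^2 + (sub$y[i1] - sub$y[i0])^2),
        peak_velocity = max(speed[i0:i1]),
        duration = (i1 - i0 + 1L) / fs)
    } else {
      fix_list[[length(fix_list) + 1L]] <- data.frame(
        onset = sub$t[i0], offset = sub$t[i1],
        x = mean(sub$x[i0:i1]), y = mean(sub$y[i0:i1]),
        duration = (i1 - i0 + 1L) / fs)
    }
  }
  empty_fix <- data.frame(onset = numeric(0), offset = numeric(0),
                          x = numeric(0), y = numeric(0), duration = numeric(0))
  empty_sac <- data.frame(onset = numeric(0), offset = numeric(0),
                          amplitude = numeric(0), peak_velocity = numeric(0),
                          duration = numeric(0))
  structure(list(
    fixations = if (length(fix_list)) do.call(rbind, fix_list) else empty_fix,
    saccades = if (length(sacc_list)) do.call(rbind, sacc_list) else empty_sac,
    valid_span_s = c(sub$t[1], sub$t[nrow(sub)]),
    fs = fs),
    class = "event_segmentation")
}

#' @export
print.event_segmentation <- function(x, ...) {
  cat(sprintf("<event_segmentation> %d fixations, %d saccades over %.2f s\n",
              nrow(x$fixations), nrow(x$saccades),
              diff(x$valid_span_s)))
  invisible(x)
}

#' Fixation refinement (merge-then-discard)
#'
#' Merges consecutive fixations separated by less than `merge_gap_s` in time
#' AND less than `merge_dist_deg` between centroids (the intervening saccade
#' is absorbed), then discards fixations shorter than `min_fix_dur_s`.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param seg An `event_segmentation` from [detect_saccades_ek()].
#' @param params A [detector_params()].
#' @return The refined `event_segmentation`.
#' @export
refine_fixations_hooge <- function(seg, params = detector_params()) {
  fx <- seg$fixations
  if (nrow(fx) > 1) {
    out <- fx[1, , drop = FALSE]
    for (i in 2:nrow(fx)) {
      last <- nrow(out)
      gap <- fx$onset[i] - out$offset[last]
      dist <- sqrt((fx$x[i] - out$x[last])^2 + (fx$y[i] - out$y[last])^2)
      if (gap < params$merge_gap_s && dist < params$merge_dist_deg) {
        w <- c(out$duration[last], fx$duration[i])
        out$x[last] <- stats::weighted.mean(c(out$x[last], fx$x[i]), w)
        out$y[last] <- stats::weighted.mean(c(out$y[last], fx$y[i]), w)
        out$offset[last] <- fx$offset[i]
        out$duration[last] <- out$duration[last] + gap + fx$duration[i]
      } else {
        out <- rbind(out, fx[i, , drop = FALSE])
      }
    }
    fx <- out
  }
  fx <- fx[fx$duration >= params$min_fix_dur_s, , drop = FALSE]
  rownames(fx) <- NULL
  seg$fixations <- fx
  # drop saccades swallowed by merged fixations
  if (nrow(seg$saccades) && nrow(fx)) {
    keep <- !vapply(seq_len(nrow(seg$saccades)), function(i) {
      any(seg$saccades$onset[i] >= fx$onset - 1e-9 &
            seg$saccades$offset[i] <= fx$offset + 1e-9)
    }, logical(1))
    seg$saccades <- seg$saccades[keep, , drop = FALSE]
    rownames(seg$saccades) <- NULL
  }
  seg
}

#' Full preprocessing chain for one trace
#'
#' Validity check (before interpolation), gap interpolation, velocity-based
#' saccade detection and fixation refinement.
#'
#' @param trace A [gaze_trace()].
#' @param params A [detector_params()].
#' @param max_contig_missing_frac Passed to [is_valid_trial()].
#' @return The refined `event_segmentation`, or `NULL` (with a warning) if
#'   the trial fails the validity rule.
#' @export
preprocess_trace <- function(trace, params = detector_params(),
                             max_contig_missing_frac = 0.4) {
  if (!is_valid_trial(trace, max_contig_missing_frac)) {
    warning("trial invalid: contiguous missing data exceeds threshold")
    return(NULL)
  }
  refine_fixations_hooge(detect_saccades_ek(interpolate_gaps(trace), params),
                         params)
}

#' Write an event segmentation as CSV
#'
#' Long format with columns `onset,offset,type,x,y,amplitude,duration`.
#' @param seg An `event_segmentation`.
#' @param path Output path.
#' @export
write_events_csv <- function(seg, path) {
  fx <- seg$fixations
  sc <- seg$saccades
  rows <- rbind(
    if (nrow(fx)) data.frame(onset = fx$onset, offset = fx$offset,
                             type = "fixation", x = fx$x, y = fx$y,
                             amplitude = NA_real_, duration = fx$duration),
    if (nrow(sc)) data.frame(onset = sc$onset, offset = sc$offset,
                             type = "saccade", x = NA_real_, y = NA_real_,
                             amplitude = sc$amplitude, duration = sc$duration))
  rows <- rows[order(rows$onset), ]
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
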