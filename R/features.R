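#' Gaze steps
#'
#' Euclidean distances between successive valid gaze samples. Pairs with an
#' invalid member are skipped.
#'
#' @param trace A [gaze_trace()].
#' @return Numeric vector of step lengths in degrees (empty if fewer than
#'   two valid samples).
#' @export
gaze_steps <- function(trace) {
  ok <- trace$valid
  if (sum(ok) < 2) return(numeric(0))
  pair <- ok[-length(ok)] & ok[-1]
  dx <- diff(trace$x)[pair]
  dy <- diff(trace$y)[pair]
  sqrt(dx^2 + dy^2)
}

#' Gaze-flip rate
#'
#' Rate of direction inversions of successive per-axis sample displacements
#' (movement inversions), per second of valid trace. Zero displacements are
#' transparent by default: the sign of the last non-zero displacement is
#' compared. With `zero_policy = "break"` a zero displacement instead
#' restarts the comparison.
#'
#' @param trace A [gaze_trace()].
#' @param axis `"horizontal"` or `"vertical"`.
#' @param zero_policy `"transparent"` (default) or `"break"`.
#' @return Flips per second (0 for monotone or empty displacement streams).
#' @export
gaze_flip_rate <- function(trace, axis = c("horizontal", "vertical"),
                           zero_policy = c("transparent", "break")) {
  axis <- match.arg(axis)
  zero_policy <- match.arg(zero_policy)
  ok <- trace$valid
  if (sum(ok) < 3) return(0)
  p <- if (axis == "horizontal") trace$x else trace$y
  pair <- ok[-length(ok)] & ok[-1]
  d <- diff(p)[pair]
  s <- sign(d)
  if (zero_policy == "transparent") s <- s[s != 0]
  if (length(s) < 2) return(0)
  flips <- sum(s[-1] != 0 & s[-length(s)] != 0 & s[-1] != s[-length(s)])
  dur <- sum(ok) / trace_fs(trace)
  flips / dur
}

#' Names of the 12 oculomotor features
#' @export
feature_names <- function() {
  c("n_fixations", "mean_fix_dur_s", "total_fix_dur_s",
    "mean_fix_dur_first_window_s", "mean_fix_dur_last_window_s",
    "mean_gaze_step_deg", "sd_gaze_step_deg", "max_gaze_step_deg",
    "flip_rate_horizontal_per_s", "flip_rate_vertical_per_s",
    "mean_saccade_amp_deg", "saccade_rate_per_s")
}

#' Build the 12-feature oculomotor vector
#'
#' Spatiotemporal summary of one viewing record: fixation counts and
#' durations (overall and within task-specific early/late windows), gaze
#' steps, horizontal/vertical gaze-flip rates, and saccade statistics. For
#' image viewing (`task = "IVT"`, 5-s records) the windows are the first and
#' last 1.25 s; for blank-screen viewing (`task = "BSV"`, 1-min records) the
#' first and last 15 s. Window membership is decided by fixation onset.
#'
#' @param trace A [gaze_trace()].
#' @param seg Its `event_segmentation` (refined).
#' @param task `"BSV"` or `"IVT"`.
#' @return Named numeric vector of length 12; duration features are `NA`
#'   when there are no fixations (counts are 0).
#' @export
build_feature_vector <- function(trace, seg, task = c("BSV", "IVT")) {
  task <- match.arg(task)
  win <- if (task == "IVT") 1.25 else 15
  dur_total <- max(trace$t) - min(trace$t) + 1 / trace_fs(trace)
  t0 <- min(trace$t)
  fx <- seg$fixations
  sc <- seg$saccades
  steps <- gaze_steps(trace)
  in_first <- fx$onset - t0 < win
  in_last <- fx$onset - t0 >= dur_total - win
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  out <- c(
    n_fixations = nrow(fx),
    mean_fix_dur_s = mean_or_na(fx$duration),
    total_fix_dur_s = if (nrow(fx)) sum(fx$duration) else NA_real_,
    mean_fix_dur_first_window_s = mean_or_na(fx$duration[in_first]),
    mean_fix_dur_last_window_s = mean_or_na(fx$duration[in_last]),
    mean_gaze_step_deg = mean_or_na(steps),
    sd_gaze_step_deg = if (length(steps) > 1) stats::sd(steps) else NA_real_,
    max_gaze_step_deg = if (length(steps)) max(steps) else NA_real_,
    flip_rate_horizontal_per_s = gaze_flip_rate(trace, "horizontal"),
    flip_rate_vertical_per_s = gaze_flip_rate(trace, "vertical"),
    mean_saccade_amp_deg = mean_or_na(sc$amplitude),
    saccade_rate_per_s = nrow(sc) / dur_total)
  out[feature_names()]
}

#' PCA reduction of the feature matrix
#'
#' Standardises the features (correlation-matrix PCA: features are
#' heterogeneous in units) and returns the top `k` components with a fixed
#' sign convention — each component's largest-magnitude loading is positive
#' — so results are deterministic. Constant columns are dropped with a
#' warning; rows with missing entries must be removed beforehand.
#'
#' @param mat Numeric matrix or data frame, participants x features.
#' @param k Number of components to keep.
#' @return List of class `pca_result`: `loadings` (features x k), `scores`
#'   (participants x k), `explained_variance_fraction` (all components),
#'   `dropped` (names of constant columns).
#' @export
pca_reduce <- function(mat, k = 3) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("feature matrix contains missing values; drop those rows first",
                       call. = FALSE)
  sds <- apply(mat, 2, stats::sd)
  dropped <- colnames(mat)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant feature column(s): ",
            paste(dropped, collapse = ", "))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  if (nrow(mat) < k + 1) stop("need at least k+1 rows", call. = FALSE)
  p <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  k <- min(k, ncol(p$rotation))
  load <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {        # sign convention
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = load, scores = scores,
                 explained_variance_fraction = ev, dropped = dropped),
            class = "pca_result")
}
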