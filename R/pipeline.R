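#' Simulate a full search-training session for one agent
#'
#' Runs the configured number of closed-loop trials, updating the agent's
#' hemifield prior after every trial from the target's true hemifield (which
#' the loudness feedback reveals over the course of a trial), and collects
#' per-trial outcomes and 500-ms-binned gaze-target distances.
#'
#' @param agent An [agent_params()].
#' @param config A [study_config()].
#' @param params A [feedback_params()].
#' @param geometry A [screen_geometry()].
#' @return List: `trials` (data frame `trial, bias_label, found,
#'   search_time_s, target_x, target_y`), `binned` (long data frame
#'   `trial, bias_label, bin_center_s, median_distance_deg`),
#'   `prior_final`, `prior_track`.
#' @export
simulate_avs_session <- function(agent, config,
                                 params = feedback_params(),
                                 geometry = screen_geometry()) {
  seq_tab <- sample_target_sequence(config)
  prior <- agent$prior
  prior_track <- numeric(nrow(seq_tab))
  trial_rows <- vector("list", nrow(seq_tab))
  bin_rows <- vector("list", nrow(seq_tab))
  base_fix_dur <- agent$fixation_dur_mean
  for (i in seq_len(nrow(seq_tab))) {
    tgt <- seq_tab[i, ]
    agent$prior <- prior
    agent$fixation_dur_mean <- base_fix_dur *
      (1 + agent$practice_gain * exp(-(i - 1) / agent$practice_tau))
    rec <- run_trial(agent, tgt, config, params, geometry)
    trial_rows[[i]] <- data.frame(
      trial = i, bias_label = rec$bias_label, found = rec$found,
      search_time_s = rec$search_time_s, target_x = tgt$x, target_y = tgt$y)
    b <- bin_gaze_target_distance(rec$trace$t, rec$distance_series)
    bin_rows[[i]] <- data.frame(trial = i, bias_label = rec$bias_label,
                                bin_center_s = b$bin_center_s,
                                median_distance_deg = b$median_distance_deg)
    prior <- update_hemifield_prior(prior, rec$bias_label == "biased",
                                    agent$prior_learning_rate)
    prior_track[i] <- prior
  }
  list(trials = do.call(rbind, trial_rows),
       binned = do.call(rbind, bin_rows),
       prior_final = prior, prior_track = prior_track)
}

# viewer style for one cohort row and task
.style_for <- function(row, task, horiz_bias, early_bias) {
  if (task == "BSV")
    viewer_style_params(fix_dur_meanlog = row$bsv_dur_meanlog,
                        sacc_amp_scale = row$bsv_amp_scale,
                        horiz_bias = horiz_bias, early_bias = early_bias)
  else
    viewer_style_params(fix_dur_meanlog = row$ivt_dur_meanlog, fix_dur_sdlog = 0.4,
                        sacc_amp_shape = 4, sacc_amp_scale = row$ivt_amp_scale,
                        horiz_bias = horiz_bias, early_bias = early_bias)
}

#' Simulate a complete transfer study with synthetic observers
#'
#' Generates a balanced cohort, runs for every participant the pre-test
#' blank-screen viewing (BSV) and image viewing (IVT) records and a landmark
#' session, the full closed-loop search training (during which the hemifield
#' prior is learned), and the post-test records with the free-viewing
#' horizontal bias shifted by the learned prior (`transfer_gain *
#' (2 * prior - 1)` toward the trained side).
#'
#' BSV records can be rendered as sample-level traces and passed through the
#' full event-detection chain (`bsv_mode = "trace"`), or generated at the
#' event level for speed (`"events"`). IVT records are event-level.
#'
#' @param n Cohort size.
#' @param population A [cohort_population()].
#' @param config_template A [study_config()]; its `bias_side` is replaced by
#'   each participant's group.
#' @param bsv_duration_s,ivt_n_images,ivt_duration_s Assessment parameters.
#' @param bsv_mode `"trace"` or `"events"`.
#' @param run_avs If `FALSE`, skip the search training (priors stay at
#'   their initial value; used for null-calibration studies).
#' @return A list of class `avs_study` with elements `cohort`, `avs`,
#'   `bsv`, `ivt`, `lt`.
#' @export
simulate_study <- function(n = 40, population = cohort_population(),
                           config_template = study_config(),
                           bsv_duration_s = 60, ivt_n_images = 30,
                           ivt_duration_s = 5,
                           bsv_mode = c("events", "trace"),
                           run_avs = TRUE) {
  bsv_mode <- match.arg(bsv_mode)
  cohort <- generate_cohort(n, population)
  image_bias <- stats::rnorm(ivt_n_images, 0, 1)   # per-image content bias
  image_bias <- image_bias - mean(image_bias)      # balanced image set
  avs <- bsv <- ivt <- lt <- vector("list", n)
  for (i in seq_len(n)) {
    row <- cohort[i, ]
    side_sign <- if (row$group == "left") -1 else 1
    cfg <- config_template
    cfg$bias_side <- row$group
    cfg$zone_counts <- if (row$group == "left")
      sort(cfg$zone_counts, decreasing = TRUE) else sort(cfg$zone_counts)
    agent <- agent_params(saccade_amp_mean = row$agent_amp_mean,
                          fixation_dur_mean = row$agent_fix_dur,
                          prior_learning_rate = row$prior_learning_rate,
                          prior_strength = row$prior_strength)
    bsv_record <- function(bias) {
      style <- .style_for(row, "BSV", bias, row$early_bias)
      if (bsv_mode == "trace") {
        tr <- simulate_free_viewing(style, bsv_duration_s)
        seg <- preprocess_trace(tr)
        list(fixations = if (is.null(seg)) NULL else seg$fixations,
             trace = tr, seg = seg)
      } else {
        list(fixations = simulate_fixation_sequence(style, bsv_duration_s),
             trace = NULL, seg = NULL)
      }
    }
    ivt_record <- function(bias) {
      lapply(seq_len(ivt_n_images), function(img) {
        style <- .style_for(row, "IVT", bias + image_bias[img],
                            row$early_bias)
        simulate_fixation_sequence(style, ivt_duration_s)
      })
    }
    bsv_pre <- bsv_record(row$natural_bias)
    ivt_pre <- ivt_record(row$natural_bias)
    lt_pre <- simulate_landmark_session(row$pse_pre, row$lt_slope)
    if (run_avs) {
      sess <- simulate_avs_session(agent, cfg)
    } else {
      sess <- list(trials = NULL, binned = NULL, prior_final = agent$prior,
                   prior_track = NULL)
    }
    learned <- row$transfer_gain * (2 * sess$prior_final - 1)
    post_bias <- row$natural_bias + side_sign * learned
    bsv_post <- bsv_record(post_bias)
    ivt_post <- ivt_record(row$natural_bias +
                             side_sign * learned * row$ivt_transfer_frac)
    pse_post <- row$pse_pre +
      side_sign * row$lt_transfer_gain * (2 * sess$prior_final - 1)
    lt_post <- simulate_landmark_session(pse_post, row$lt_slope)
    avs[[i]] <- sess
    bsv[[i]] <- list(pre = bsv_pre, post = bsv_post)
    ivt[[i]] <- list(pre = ivt_pre, post = ivt_post)
    lt[[i]] <- list(pre = lt_pre, post = lt_post)
  }
  structure(list(cohort = cohort, avs = avs, bsv = bsv, ivt = ivt, lt = lt),
            class = "avs_study")
}

#' Analyse a simulated transfer study
#'
#' Runs the confirmatory analysis chain on an [simulate_study()] result:
#' per-participant barycenter shifts for blank-screen and image viewing
#' (per-image shifts collapsed by the median), PSE shifts from logistic
#' psychometric fits, group-sign correction, the three one-sided t-tests,
#' the three-way bias-direction alignment test, and — when search data are
#' present — the gamma log-link learning-curve model on the 500-ms-binned
#' gaze-target distances and the search summary.
#'
#' @param study An `avs_study`.
#' @return List of class `avs_analysis`: `shifts` (per-participant data
#'   frame), `tests` (per-task t-test results), `alignment`, `learning`
#'   (coefficient table or `NULL`), `avs_summary`.
#' @export
analyze_study <- function(study) {
  stopifnot(inherits(study, "avs_study"))
  n <- nrow(study$cohort)
  group <- study$cohort$group
  bsv_pre <- vapply(study$bsv, function(b) barycenter(b$pre$fixations), 0)
  bsv_post <- vapply(study$bsv, function(b) barycenter(b$post$fixations), 0)
  ivt_raw <- vapply(seq_len(n), function(i) {
    per_img <- vapply(seq_along(study$ivt[[i]]$pre), function(img)
      barycenter(study$ivt[[i]]$post[[img]]) -
        barycenter(study$ivt[[i]]$pre[[img]]), 0)
    image_shift_collapse(per_img)
  }, 0)
  lt_pre <- vapply(study$lt, function(l)
    fit_psychometric(l$pre$offset, l$pre$response)$pse, 0)
  lt_post <- vapply(study$lt, function(l)
    fit_psychometric(l$post$offset, l$post$response)$pse, 0)
  sm_bsv <- shift_measure(bsv_pre, bsv_post, group)
  sm_ivt <- data.frame(raw_shift = ivt_raw,
                       signed_shift = ifelse(group == "left", -ivt_raw, ivt_raw))
  sm_lt <- shift_measure(lt_pre, lt_post, group)
  shifts <- data.frame(
    participant = study$cohort$participant, group = group,
    bsv_raw = sm_bsv$raw_shift, bsv_signed = sm_bsv$signed_shift,
    ivt_raw = sm_ivt$raw_shift, ivt_signed = sm_ivt$signed_shift,
    lt_raw = sm_lt$raw_shift, lt_signed = sm_lt$signed_shift)
  tests <- list(BSV = one_sample_t_one_sided(shifts$bsv_signed),
                IVT = one_sample_t_one_sided(shifts$ivt_signed),
                LT = one_sample_t_one_sided(shifts$lt_signed))
  dir_of <- function(v) ifelse(v < 0, "left", ifelse(v > 0, "right", NA))
  align <- alignment_test(group, dir_of(shifts$ivt_raw),
                          dir_of(shifts$bsv_raw))
  learning <- NULL
  avs_summary <- NULL
  if (!is.null(study$avs[[1]]$binned)) {
    long <- do.call(rbind, lapply(seq_len(n), function(i) {
      b <- study$avs[[i]]$binned
      b$participant <- i
      b
    }))
    long <- long[long$median_distance_deg > 0, ]
    long$z_trial <- standardize(long$trial)
    long$z_time <- standardize(long$bin_center_s)
    long$bias <- long$bias_label
    long$distance <- long$median_distance_deg
    learning <- fit_learning_model(long)
    trials <- do.call(rbind, lapply(study$avs, `[[`, "trials"))
    avs_summary <- list(hit_rate = mean(trials$found),
                        mean_search_time_s = mean(trials$search_time_s),
                        mean_prior_final = mean(vapply(study$avs, `[[`,
                                                       0, "prior_final")))
  }
  structure(list(shifts = shifts, tests = tests, alignment = align,
                 learning = learning, avs_summary = avs_summary),
            class = "avs_analysis")
}

#' @export
print.avs_analysis <- function(x, ...) {
  cat("Transfer-of-bias analysis\n")
  for (task in names(x$tests)) {
    tt <- x$tests[[task]]
    cat(sprintf("  %s: M = %.2f, SD = %.2f, t(%d) = %.2f, p = %.3f, d = %.2f\n",
                task, tt$mean, tt$sd, tt$df, tt$t, tt$p, tt$cohens_d))
  }
  cat(sprintf("  alignment: %.2f (k = %d / n = %d), p = %.3f\n",
              x$alignment$proportion, x$alignment$k, x$alignment$n,
              x$alignment$p_one_sided))
  if (!is.null(x$avs_summary))
    cat(sprintf("  search: hit rate %.2f, mean time %.2f s\n",
                x$avs_summary$hit_rate, x$avs_summary$mean_search_time_s))
  invisible(x)
}
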