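#' Horizontal fixation barycenter
#'
#' Mean horizontal fixation position (centre of mass of fixation centroids)
#' over a viewing record. Unweighted by default; set
#' `duration_weighted = TRUE` to weight centroids by fixation duration.
#'
#' @param fixations Data frame with columns `x` and (optionally) `duration`.
#' @param duration_weighted Logical.
#' @return Degrees, or `NA` if there are no fixations.
#' @export
barycenter <- function(fixations, duration_weighted = FALSE) {
  if (is.null(fixations) || nrow(fixations) == 0) return(NA_real_)
  if (duration_weighted)
    stats::weighted.mean(fixations$x, fixations$duration)
  else
    mean(fixations$x)
}

#' Collapse per-image shifts to one value per participant
#'
#' Sample median of the per-image pre-to-post shifts; robust against the
#' skewed shift distributions that make the mean inadequate for some
#' participants.
#'
#' @param per_image_shifts Numeric vector (one shift per image).
#' @return Degrees.
#' @export
image_shift_collapse <- function(per_image_shifts) {
  if (!length(per_image_shifts)) stop("no shifts supplied", call. = FALSE)
  stats::median(per_image_shifts)
}

#' Group-sign-corrected shift measure
#'
#' `raw_shift = post - pre`; to collapse both bias groups onto a common
#' scale, shifts of the left-bias group are reversed in sign, so a positive
#' `signed_shift` always means a shift toward the biased hemifield.
#'
#' @param pre,post Pre- and post-training values (degrees; barycenter or
#'   PSE), vectorised.
#' @param group `"left"` or `"right"` per participant.
#' @return Data frame `pre, post, raw_shift, signed_shift`.
#' @export
shift_measure <- function(pre, post, group) {
  stopifnot(length(pre) == length(post), length(group) == length(pre),
            all(group %in% c("left", "right")))
  raw <- post - pre
  data.frame(pre = pre, post = post, raw_shift = raw,
             signed_shift = ifelse(group == "left", -raw, raw))
}

#' One-sided one-sample t-test
#'
#' `t = mean / (sd / sqrt(n))` with `df = n - 1`; upper-tail p by default
#' (`direction = "greater"`), Cohen's d = mean/sd, and the lower bound of
#' the one-sided 95% confidence interval.
#'
#' @param x Numeric vector of (signed) shifts.
#' @param direction `"greater"` or `"less"`.
#' @param conf_level Confidence level for the one-sided bound.
#' @return List `t, df, p, cohens_d, ci_lower, mean, sd, n`.
#' @export
one_sample_t_one_sided <- function(x, direction = c("greater", "less"),
                                   conf_level = 0.95) {
  direction <- match.arg(direction)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 finite values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zero variance", call. = FALSE)
  m <- mean(x)
  tval <- m / (s / sqrt(n))
  df <- n - 1
  p <- if (direction == "greater") stats::pt(tval, df, lower.tail = FALSE)
       else stats::pt(tval, df)
  ci_lower <- m - stats::qt(conf_level, df) * s / sqrt(n)
  list(t = tval, df = df, p = p, cohens_d = m / s, ci_lower = ci_lower,
       mean = m, sd = s, n = n)
}

#' Fit a two-parameter logistic psychometric function
#'
#' Maximum-likelihood logistic regression of binary responses on bisection
#' offset, `P(right) = 1 / (1 + exp(-slope * (o - pse)))`; the PSE is the
#' offset at which both responses are equiprobable. No lapse or guess
#' parameters. Complete separation is flagged as non-converged and the PSE
#' falls back to the midpoint between the separating offsets.
#'
#' @param offsets Bisection offsets (degrees).
#' @param responses 0/1 responses (1 = "right longer").
#' @return List of class `psychometric_fit`: `pse`, `slope`, `converged`,
#'   `se_pse`.
#' @export
fit_psychometric <- function(offsets, responses) {
  stopifnot(length(offsets) == length(responses))
  responses <- as.integer(responses)
  if (length(unique(offsets)) < 2 || length(unique(responses)) < 2)
    stop("need >= 2 distinct offsets with mixed responses", call. = FALSE)
  # detect complete separation: all 0 below some point, all 1 above
  agg <- tapply(responses, offsets, mean)
  offs <- as.numeric(names(agg))
  sep <- all(agg %in% c(0, 1)) && !is.unsorted(agg, strictly = FALSE)
  if (sep) {
    hi <- which(agg == 1)[1]
    pse <- mean(offs[c(hi - 1, hi)])
    return(structure(list(pse = pse, slope = Inf, converged = FALSE,
                          se_pse = NA_real_), class = "psychometric_fit"))
  }
  fit <- suppressWarnings(
    stats::glm(responses ~ offsets, family = stats::binomial()))
  b <- stats::coef(fit)
  slope <- unname(b[2])
  if (abs(slope) < 1e-6) {    # flat function: PSE indeterminate, centre of range
    return(structure(list(pse = mean(offsets), slope = slope,
                          converged = FALSE, se_pse = NA_real_),
                     class = "psychometric_fit"))
  }
  pse <- unname(-b[1] / b[2])
  vc <- stats::vcov(fit)
  # delta method for se(pse), pse = -b0/b1
  g <- c(-1 / b[2], b[1] / b[2]^2)
  se_pse <- sqrt(drop(t(g) %*% vc %*% g))
  structure(list(pse = pse, slope = slope,
                 converged = fit$converged && abs(slope) < 1e3,
                 se_pse = se_pse),
            class = "psychometric_fit")
}

#' Congruent-bias index
#'
#' Absolute median horizontal position of fixations within the first second
#' of a pre-test record, signed positive when the side of that median
#' matches the participant's biased hemifield and negative when opposite.
#'
#' @param fixations Fixation data frame (`onset`, `x`).
#' @param group `"left"` or `"right"`.
#' @param window_s Early window (seconds from record onset).
#' @return Degrees (signed), or `NA` if no early fixations.
#' @export
congruent_bias <- function(fixations, group, window_s = 1.0) {
  stopifnot(group %in% c("left", "right"))
  early <- fixations[fixations$onset < window_s, , drop = FALSE]
  if (!nrow(early)) return(NA_real_)
  med <- stats::median(early$x)
  if (med == 0) return(0)
  side <- if (med < 0) "left" else "right"
  if (side == group) abs(med) else -abs(med)
}

#' Early-window saccadic landing position
#'
#' Median horizontal endpoint position of saccades launched within the first
#' `window_s` of a record; differencing pre vs post and sign correction are
#' done with [shift_measure()].
#'
#' @param saccades Saccade data frame with `onset` and endpoint `x_end`
#'   (degrees); if absent, the following fixation's `x` may be supplied as
#'   `x_end` by the caller.
#' @param window_s Window length from record onset (seconds).
#' @return Degrees, or `NA` if no early saccades.
#' @export
early_window_shift <- function(saccades, window_s = 1.0) {
  early <- saccades[saccades$onset < window_s, , drop = FALSE]
  if (!nrow(early)) return(NA_real_)
  stats::median(early$x_end)
}

#' Fixation density map
#'
#' Duration-weighted Gaussian kernel density of fixation centroids on a
#' regular grid over the screen, normalised to sum to 1. Fixations with
#' onset earlier than `exclude_initial_s` are excluded (removing the strong
#' initial central fixation), and left-bias-group coordinates can be folded
#' onto the right hemifield (`flip_x = TRUE`) before accumulation.
#'
#' @param fixations Data frame `onset, x, y, duration`.
#' @param xlim,ylim Grid limits in degrees.
#' @param spacing Grid spacing (degrees).
#' @param bandwidth Gaussian kernel SD (degrees).
#' @param exclude_initial_s Initial exclusion window (seconds).
#' @param flip_x Fold x to -x before accumulation.
#' @param duration_weighted Weight fixations by duration.
#' @return List of class `density_map`: `z` (matrix, rows = x), `x`, `y`.
#' @export
fixation_density_map <- function(fixations, xlim = c(-25, 25),
                                 ylim = c(-15, 15), spacing = 0.25,
                                 bandwidth = 1.0, exclude_initial_s = 0.75,
                                 flip_x = FALSE, duration_weighted = TRUE) {
  gx <- seq(xlim[1], xlim[2], by = spacing)
  gy <- seq(ylim[1], ylim[2], by = spacing)
  fx <- fixations[fixations$onset >= exclude_initial_s, , drop = FALSE]
  z <- matrix(0, length(gx), length(gy))
  if (nrow(fx) == 0) {
    warning("no fixations after exclusion window: returning uniform map")
    z[] <- 1
  } else {
    xs <- if (flip_x) -fx$x else fx$x
    w <- if (duration_weighted) fx$duration else rep(1, nrow(fx))
    for (i in seq_len(nrow(fx))) {
      kx <- stats::dnorm(gx, xs[i], bandwidth)
      ky <- stats::dnorm(gy, fx$y[i], bandwidth)
      z <- z + w[i] * outer(kx, ky)
    }
  }
  z <- z / sum(z)
  structure(list(z = z, x = gx, y = gy, bandwidth = bandwidth),
            class = "density_map")
}

#' Combine density maps by cellwise median
#'
#' Median across maps (e.g., one per unique horizontal target position),
#' renormalised to sum to 1.
#'
#' @param maps List of `density_map`s on identical grids.
#' @return A `density_map`.
#' @export
combine_density_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  arr <- simplify2array(lapply(maps, function(m) m$z))
  z <- apply(arr, c(1, 2), stats::median)
  z <- z / sum(z)
  structure(list(z = z, x = maps[[1]]$x, y = maps[[1]]$y,
                 bandwidth = maps[[1]]$bandwidth),
            class = "density_map")
}

#' Mass of a density map right of the midline
#' @param map A `density_map`.
#' @export
density_right_mass <- function(map) {
  sum(map$z[map$x > 0, ])
}

#' Three-way bias-direction alignment test
#'
#' Proportion of participants whose image-viewing and blank-screen shift
#' directions BOTH equal their search-task bias side, tested one-sided
#' against the chance level 0.25 (two independent fair binary signs) with an
#' exact binomial test.
#'
#' @param avs,ivt,bsv Character vectors of `"left"`/`"right"` per
#'   participant (`NA` allowed; incomplete triples are excluded).
#' @param p0 Chance probability.
#' @return List `proportion, k, n, p_one_sided, n_excluded`.
#' @export
alignment_test <- function(avs, ivt, bsv, p0 = 0.25) {
  stopifnot(length(avs) == length(ivt), length(ivt) == length(bsv))
  ok <- !(is.na(avs) | is.na(ivt) | is.na(bsv))
  n <- sum(ok)
  if (n < 1) stop("no complete triples", call. = FALSE)
  k <- sum(ivt[ok] == avs[ok] & bsv[ok] == avs[ok])
  p <- stats::binom.test(k, n, p0, alternative = "greater")$p.value
  list(proportion = k / n, k = k, n = n, p_one_sided = p,
       n_excluded = sum(!ok))
}

#' Bin gaze-target distance in 500-ms intervals
#'
#' Median distance within consecutive `bin_s` bins over the trial's live
#' span. Bins after trial end are absent. (Carry-forward padding of the
#' series after success, used for plotting, is available via
#' `pad_to_deadline`.)
#'
#' @param t Sample times (seconds).
#' @param distance Gaze-target distances (degrees); `NA` allowed.
#' @param bin_s Bin width (seconds).
#' @param pad_to_deadline If a deadline (seconds) is given, missing bins up
#'   to it are filled with the last recorded bin median (plotting option).
#' @return Data frame `bin_center_s, median_distance_deg`.
#' @export
bin_gaze_target_distance <- function(t, distance, bin_s = 0.5,
                                     pad_to_deadline = NULL) {
  ok <- !is.na(distance)
  if (!any(ok)) stop("no valid distance samples", call. = FALSE)
  t <- t[ok]; distance <- distance[ok]
  # left-open, right-closed bins: a sample exactly at k*bin_s belongs to the
  # k-th bin, so the sample at the deadline stays inside the trial range
  bin <- pmax(ceiling(t / bin_s) - 1, 0)
  med <- tapply(distance, bin, stats::median)
  centers <- (as.numeric(names(med)) + 0.5) * bin_s
  out <- data.frame(bin_center_s = centers,
                    median_distance_deg = as.numeric(med))
  if (!is.null(pad_to_deadline)) {
    all_centers <- seq(bin_s / 2, pad_to_deadline - bin_s / 2, by = bin_s)
    miss <- setdiff(round(all_centers, 9), round(out$bin_center_s, 9))
    if (length(miss)) {
      out <- rbind(out, data.frame(
        bin_center_s = miss,
        median_distance_deg = out$median_distance_deg[nrow(out)]))
      out <- out[order(out$bin_center_s), ]
    }
  }
  rownames(out) <- NULL
  out
}

#' Standardise a numeric vector
#'
#' Mean-centred and scaled to unit variance. The default scales by the
#' population standard deviation (divisor n); `sd_type = "sample"` uses the
#' n-1 divisor.
#'
#' @param v Numeric vector.
#' @param sd_type `"population"` or `"sample"`.
#' @return Z-scored vector.
#' @export
standardize <- function(v, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  m <- mean(v)
  s <- stats::sd(v)
  if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  if (!is.finite(s) || s == 0) stop("constant input", call. = FALSE)
  (v - m) / s
}

#' Gamma log-link learning-curve model
#'
#' Fixed-effects gamma GLM with log link for binned gaze-target distance:
#' `distance ~ bias * z_trial * z_time` where `z_trial` and `z_time` are the
#' standardised trial number and time-on-trial. Estimates are reported as
#' multiplicative factors (exp of coefficients) with 1-df likelihood-ratio
#' chi-square tests obtained by refitting without each column of the model
#' matrix. A random-slopes mixed-model backend can be plugged in behind the
#' same coefficient-table schema (see the package vignette).
#'
#' @param data Data frame with columns `distance` (positive, degrees),
#'   `bias` (factor or character, `"unbiased"`/`"biased"`), `z_trial`,
#'   `z_time`.
#' @return Data frame `term, estimate (multiplicative), chisq, df, p`.
#' @export
fit_learning_model <- function(data) {
  stopifnot(all(c("distance", "bias", "z_trial", "z_time") %in% names(data)))
  if (any(data$distance <= 0))
    stop("gamma model requires positive distances", call. = FALSE)
  data$bias <- stats::relevel(factor(data$bias), ref = "unbiased")
  form <- distance ~ bias * z_trial * z_time
  X <- stats::model.matrix(form, data)
  y <- data$distance
  fam <- stats::Gamma(link = "log")
  full <- stats::glm.fit(X, y, family = fam)
  # Pearson dispersion of the full model: the likelihood-ratio statistic for
  # a gamma GLM is the scaled deviance difference (as in anova.glm).
  disp <- sum((y - full$fitted.values)^2 / full$fitted.values^2) /
    (length(y) - ncol(X))
  terms <- colnames(X)
  rows <- lapply(seq_along(terms), function(j) {
    if (terms[j] == "(Intercept)")
      return(data.frame(term = "(Intercept)",
                        estimate = exp(full$coefficients[j]),
                        chisq = NA_real_, df = NA_integer_, p = NA_real_))
    red <- stats::glm.fit(X[, -j, drop = FALSE], y, family = fam)
    chisq <- max(0, (red$deviance - full$deviance) / disp)
    data.frame(term = terms[j], estimate = exp(full$coefficients[j]),
               chisq = chisq, df = 1L,
               p = stats::pchisq(chisq, 1, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multiple linear regression with classical t-tests
#'
#' Ordinary least squares of an outcome on a predictor matrix, with
#' estimate, t, df and p per coefficient. Rank deficiency is an error that
#' names the collinear columns.
#'
#' @param y Outcome vector.
#' @param X Data frame or matrix of predictors (intercept added).
#' @return Data frame `term, estimate, se, t, df, p`.
#' @export
ols_regression <- function(y, X) {
  X <- as.data.frame(X)
  if (length(y) <= ncol(X) + 1)
    stop("need n > number of predictors + 1", call. = FALSE)
  fit <- stats::lm(y ~ ., data = X)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             t = s[, 3], df = fit$df.residual, p = s[, 4],
             row.names = NULL)
}
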