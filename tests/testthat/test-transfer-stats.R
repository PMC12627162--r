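test_that("barycenter and shift sign-correction behave as specified", {
  fx <- data.frame(x = c(-2, 2), duration = c(1, 3))
  expect_equal(barycenter(fx), 0)
  expect_equal(barycenter(fx, duration_weighted = TRUE), 1)
  expect_equal(barycenter(data.frame(x = 3, duration = 1)), 3)
  expect_equal(barycenter(data.frame(x = -fx$x, duration = fx$duration),
                          duration_weighted = TRUE), -1)
  expect_true(is.na(barycenter(data.frame(x = numeric(0)))))
  sm <- shift_measure(pre = c(0, 0), post = c(1, 1), group = c("left", "right"))
  expect_equal(sm$raw_shift, c(1, 1))
  expect_equal(sm$signed_shift, c(-1, 1))
})

test_that("per-image collapse uses the median and is outlier-robust", {
  expect_equal(image_shift_collapse(c(1, 2, 3)), 2)
  expect_equal(image_shift_collapse(c(rep(0, 29), 10)), 0)
  expect_equal(image_shift_collapse(c(1, 2, 3, 4)), 2.5)
  # median minimises L1 distance (grid-search oracle)
  set.seed(40)
  v <- rnorm(31)
  grid <- seq(-3, 3, by = 0.001)
  l1 <- vapply(grid, function(g) sum(abs(v - g)), 0)
  expect_lt(abs(image_shift_collapse(v) - grid[which.min(l1)]), 1e-3)
})

test_that("one-sided t-test reproduces printed summary statistics", {
  # group-level shift summary: M = 0.49, SD = 1.61, n = 40
  x <- scale(rnorm(40))[, 1] * 1.61 + 0.49   # any sample with these moments
  res <- one_sample_t_one_sided(x)
  expect_equal(res$t, 0.49 / (1.61 / sqrt(40)), tolerance = 1e-9)
  expect_equal(res$t, 1.92, tolerance = 0.01)   # printed as 1.91 from raw data
  expect_equal(res$df, 39)
  expect_equal(round(res$cohens_d, 1), 0.3)
  expect_equal(res$p, pt(res$t, 39, lower.tail = FALSE))
  # cross-check against stats::t.test
  ref <- t.test(x, alternative = "greater")
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_equal(res$ci_lower, ref$conf.int[1], tolerance = 1e-9)
  expect_error(one_sample_t_one_sided(rep(0, 10)), "zero variance")
  # type-I error calibration at alpha = .05
  set.seed(41)
  rej <- replicate(2000, one_sample_t_one_sided(rnorm(40))$p < 0.05)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("psychometric fit recovers the generating PSE", {
  d <- landmark_design()
  # symmetric 50/50 responses at every offset -> PSE 0
  offs <- rep(d$offsets, each = 2)
  resp <- rep(c(0, 1), length(d$offsets))
  f0 <- fit_psychometric(offs, resp)
  expect_equal(f0$pse, 0, tolerance = 1e-6)
  # parameter recovery: pse = 0.2, slope = 10, 88 trials x 200 replicates
  set.seed(42)
  fits <- t(replicate(200, {
    s <- simulate_landmark_session(0.2, 10)
    ft <- fit_psychometric(s$offset, s$response)
    c(ft$pse, ft$se_pse)
  }))
  bias <- mean(fits[, 1]) - 0.2
  expect_lt(abs(bias), mean(fits[, 2]))          # bias below the typical SE
  expect_equal(mean(fits[, 1]), 0.2, tolerance = 0.05)
  # symmetry: (o -> -o, resp -> 1 - resp) negates the PSE
  set.seed(43)
  s <- simulate_landmark_session(0.15, 8)
  f1 <- fit_psychometric(s$offset, s$response)
  f2 <- fit_psychometric(-s$offset, 1 - s$response)
  expect_equal(f2$pse, -f1$pse, tolerance = 1e-6)
  # complete separation flagged, PSE at the separating midpoint
  sep_off <- rep(c(-0.2, 0.2), each = 4)
  sep_resp <- rep(c(0, 1), each = 4)
  fs <- fit_psychometric(sep_off, sep_resp)
  expect_false(fs$converged)
  expect_equal(fs$pse, 0)
})

test_that("congruent bias is positive when natural and trained sides agree", {
  fx <- data.frame(onset = c(0.2, 0.5, 1.4), x = c(-1.5, -1.5, 9))
  expect_equal(congruent_bias(fx, "left"), 1.5)
  expect_equal(congruent_bias(fx, "right"), -1.5)
  expect_equal(congruent_bias(data.frame(onset = 0.1, x = 0), "left"), 0)
  expect_true(is.na(congruent_bias(data.frame(onset = 2, x = 1), "left")))
})

test_that("early-window saccade statistic uses only the first second", {
  sc <- data.frame(onset = c(0.3, 1.2), x_end = c(4, -8))
  expect_equal(early_window_shift(sc), 4)
  expect_true(is.na(early_window_shift(data.frame(onset = 1.2, x_end = 1))))
})

test_that("density maps are normalised, peaked and mirror-symmetric", {
  one <- data.frame(onset = 1, x = 0, y = 0, duration = 0.5)
  m <- fixation_density_map(one)
  expect_equal(sum(m$z), 1, tolerance = 1e-9)
  peak <- arrayInd(which.max(m$z), dim(m$z))
  expect_equal(m$x[peak[1]], 0, tolerance = 0.26)
  expect_equal(m$y[peak[2]], 0, tolerance = 0.26)
  # mirror-symmetric input gives a symmetric map
  sym <- data.frame(onset = c(1, 1), x = c(-5, 5), y = c(0, 0),
                    duration = c(1, 1))
  ms <- fixation_density_map(sym)
  expect_equal(density_right_mass(ms), sum(ms$z[ms$x < 0, ]), tolerance = 1e-9)
  # initial-window exclusion and left-group flipping
  early <- data.frame(onset = c(0.2, 1), x = c(10, -5), y = c(0, 0),
                      duration = c(1, 1))
  mf <- fixation_density_map(early, flip_x = TRUE)
  expect_gt(density_right_mass(mf), 0.9)   # only the flipped -5 survives
  # cellwise-median combination stays normalised
  mc <- combine_density_maps(list(m, ms, mf))
  expect_equal(sum(mc$z), 1, tolerance = 1e-9)
  expect_warning(fixation_density_map(data.frame(onset = 0.1, x = 0, y = 0,
                                                 duration = 1)), "uniform")
})

test_that("right-biased synthetic cohorts put density mass right of midline", {
  set.seed(44)
  fx <- do.call(rbind, replicate(10, {
    f <- simulate_fixation_sequence(viewer_style_params(horiz_bias = 4), 20)
    f
  }, simplify = FALSE))
  m <- fixation_density_map(fx)
  expect_gt(density_right_mass(m), 0.5)
})

test_that("alignment test matches the closed-form binomial tail", {
  # printed cross-check: k = 18 of n = 40 at chance 0.25
  avs <- rep("right", 40)
  ivt <- c(rep("right", 18), rep("left", 22))
  bsv <- c(rep("right", 18), rep("left", 12), rep("right", 10))
  res <- alignment_test(avs, ivt, bsv)
  expect_equal(res$k, 18)
  expect_equal(res$proportion, 0.45)
  oracle <- sum(dbinom(18:40, 40, 0.25))   # direct tail sum
  expect_equal(res$p_one_sided, oracle, tolerance = 1e-12)
  expect_lt(res$p_one_sided, 0.01)         # printed as p = .004
  # all aligned: p = 0.25^n
  all_al <- alignment_test(rep("left", 5), rep("left", 5), rep("left", 5))
  expect_equal(all_al$p_one_sided, sum(dbinom(5, 5, 0.25)), tolerance = 1e-12)
  # incomplete triples are excluded and counted
  res2 <- alignment_test(c("left", NA, "right"), c("left", "left", "right"),
                         c("left", "left", "right"))
  expect_equal(res2$n, 2)
  expect_equal(res2$n_excluded, 1)
})

test_that("distance binning takes 500-ms medians over the live span", {
  t <- seq(0.01, 2, by = 0.01) - 0.005   # samples strictly inside (0, 2)
  b <- bin_gaze_target_distance(t, rep(5, length(t)))
  expect_equal(nrow(b), 4)
  expect_equal(b$median_distance_deg, rep(5, 4))
  expect_equal(b$bin_center_s, c(0.25, 0.75, 1.25, 1.75))
  # linear descent 10 -> 0 over 1 s: bin medians are the segment midpoints
  t2 <- seq(0.001, 1, by = 0.001) - 0.0005
  b2 <- bin_gaze_target_distance(t2, 10 * (1 - t2))
  expect_equal(b2$median_distance_deg, c(7.5, 2.5), tolerance = 0.02)
  # trial ending at 1.2 s has no bins beyond 1.5 s
  t3 <- seq(0.01, 1.2, by = 0.01)
  b3 <- bin_gaze_target_distance(t3, rep(3, length(t3)))
  expect_lte(max(b3$bin_center_s), 1.5)
  # carry-forward padding is available for plotting
  b4 <- bin_gaze_target_distance(t3, rep(3, length(t3)), pad_to_deadline = 10)
  expect_equal(nrow(b4), 20)
  expect_equal(b4$median_distance_deg[20], 3)
})

test_that("standardisation matches the closed form", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1) * sqrt(1.5),
               tolerance = 1e-9)
  z <- standardize(rnorm(50))
  expect_equal(standardize(z), z, tolerance = 1e-9)
  expect_equal(standardize(3 + 2 * z), z, tolerance = 1e-9)
  expect_equal(standardize(c(1, 2, 3), sd_type = "sample"), c(-1, 0, 1))
  expect_error(standardize(rep(1, 5)), "constant")
})

test_that("gamma learning model recovers a known time effect", {
  set.seed(45)
  n <- 6000
  dat <- data.frame(bias = sample(c("biased", "unbiased"), n, TRUE),
                    z_trial = standardize(runif(n)),
                    z_time = standardize(runif(n)))
  shape <- 8
  mu <- exp(2 - 0.2 * dat$z_time)
  dat$distance <- rgamma(n, shape, rate = shape / mu)
  tab <- fit_learning_model(dat)
  est <- tab$estimate[tab$term == "z_time"]
  expect_equal(est, exp(-0.2), tolerance = 0.02)
  expect_lt(tab$p[tab$term == "z_time"], 1e-6)
  # null predictors are not significant and have factor ~ 1
  expect_equal(tab$estimate[tab$term == "z_trial"], 1, tolerance = 0.03)
  expect_error(fit_learning_model(transform(dat, distance = distance - 100)),
               "positive")
})

test_that("learning-model likelihood-ratio test keeps its size under the null", {
  set.seed(46)
  rej <- replicate(300, {
    n <- 400
    dat <- data.frame(bias = sample(c("biased", "unbiased"), n, TRUE),
                      z_trial = standardize(runif(n)),
                      z_time = standardize(runif(n)))
    dat$distance <- rgamma(n, 5, rate = 1)
    tab <- fit_learning_model(dat)
    tab$p[tab$term == "z_time"] < 0.05
  })
  se <- sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(mean(rej) - 0.05), 3 * se + 0.01)
})

test_that("OLS regression is exact on noiseless data and permutation-invariant", {
  x <- rnorm(30)
  fit <- suppressWarnings(ols_regression(2 * x, data.frame(x = x)))
  expect_equal(fit$estimate[fit$term == "x"], 2, tolerance = 1e-10)
  expect_equal(fit$estimate[fit$term == "(Intercept)"], 0, tolerance = 1e-10)
  set.seed(47)
  X <- data.frame(a = rnorm(40), b = rnorm(40))
  y <- 1 + 0.5 * X$a - 0.3 * X$b + rnorm(40, 0, 0.1)
  f1 <- ols_regression(y, X)
  perm <- sample(40)
  f2 <- ols_regression(y[perm], X[perm, ])
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-9)
  expect_error(ols_regression(y, data.frame(a = X$a, a2 = 2 * X$a)),
               "collinear")
  # power check: negative congruent-bias coefficient is recovered
  set.seed(48)
  hits <- replicate(200, {
    cb <- rnorm(40)
    yy <- -0.5 * cb + rnorm(40, 0, 0.5)
    ft <- ols_regression(yy, data.frame(cb = cb))
    ft$estimate[ft$term == "cb"] < 0 & ft$p[ft$term == "cb"] < 0.05
  })
  expect_gt(mean(hits), 0.8)
})
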