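test_that("gaze steps are Euclidean displacements over valid pairs", {
  tr <- gaze_trace(1:5 / 10, x = c(0, 1, 1, 2, 2), y = c(0, 0, 1, 1, 2), fs = 10)
  expect_equal(gaze_steps(tr), rep(1, 4))
  still <- gaze_trace(1:4 / 10, rep(0, 4), rep(0, 4), fs = 10)
  expect_equal(gaze_steps(still), rep(0, 3))
  # invalid-adjacent pairs are skipped
  tr2 <- gaze_trace(1:4 / 10, c(0, 5, 1, 2), c(0, 0, 0, 0),
                    valid = c(TRUE, FALSE, TRUE, TRUE), fs = 10)
  expect_equal(gaze_steps(tr2), 1)
  expect_equal(gaze_steps(gaze_trace(1, 0, 0, fs = 10)), numeric(0))
  # triangle inequality: path length >= net displacement
  set.seed(30)
  tr3 <- gaze_trace(1:50 / 10, cumsum(rnorm(50)), cumsum(rnorm(50)), fs = 10)
  net <- sqrt(diff(range(tr3$x[c(1, 50)]))^2 + diff(range(tr3$y[c(1, 50)]))^2)
  expect_gte(sum(gaze_steps(tr3)), net)
})

test_that("gaze-flip rate counts movement inversions per axis", {
  fs <- 10
  ramp <- gaze_trace(1:10 / fs, 1:10, rep(0, 10), fs = fs)
  expect_equal(gaze_flip_rate(ramp, "horizontal"), 0)
  # strict zigzag of N samples has N - 2 sign changes
  n <- 9
  zig <- gaze_trace(1:n / fs, rep(c(0, 1), length.out = n), rep(0, n), fs = fs)
  expect_equal(gaze_flip_rate(zig, "horizontal"), (n - 2) / (n / fs))
  # pure vertical motion has zero horizontal flips
  vert <- gaze_trace(1:8 / fs, rep(0, 8), rep(c(0, 2), 4), fs = fs)
  expect_equal(gaze_flip_rate(vert, "horizontal"), 0)
  expect_gt(gaze_flip_rate(vert, "vertical"), 0)
  # zero displacements are transparent: 1,2,2,1 is one flip
  z <- gaze_trace(1:4 / fs, c(1, 2, 2, 1), rep(0, 4), fs = fs)
  expect_equal(gaze_flip_rate(z, "horizontal"), 1 / (4 / fs))
  # under the "break" policy the zero displacement interrupts the run
  expect_equal(gaze_flip_rate(z, "horizontal", zero_policy = "break"), 0)
})

test_that("feature vector matches hand-computed values on a known fixture", {
  fs <- 100
  # 5-s record with a hand-built segmentation: the feature arithmetic is
  # checked against values computed by hand.
  n <- 500
  x <- c(rep(0, 100), seq(0, 2, length.out = 3), rep(2, 397))
  tr <- gaze_trace(1:n / fs, x, rep(0, n), fs = fs)
  seg <- structure(list(
    fixations = data.frame(onset = c(0.01, 1.04, 3.8),
                           offset = c(1.0, 3.5, 5.0),
                           x = c(0, 2, 2), y = c(0, 0, 0),
                           duration = c(1.0, 2.5, 1.2)),
    saccades = data.frame(onset = c(1.01, 3.6), offset = c(1.03, 3.7),
                          amplitude = c(2, 0.4), peak_velocity = c(100, 40),
                          duration = c(0.03, 0.1)),
    valid_span_s = c(0.01, 5), fs = fs), class = "event_segmentation")
  fv <- build_feature_vector(tr, seg, "IVT")
  expect_equal(unname(fv["n_fixations"]), 3)
  expect_equal(unname(fv["mean_fix_dur_s"]), mean(c(1.0, 2.5, 1.2)))
  expect_equal(unname(fv["total_fix_dur_s"]), 4.7)
  # IVT windows: first 1.25 s (onsets 0.01, 1.04), last 1.25 s (onset 3.8)
  expect_equal(unname(fv["mean_fix_dur_first_window_s"]), mean(c(1.0, 2.5)))
  expect_equal(unname(fv["mean_fix_dur_last_window_s"]), 1.2)
  expect_equal(unname(fv["max_gaze_step_deg"]), 1)      # the 2-sample ramp
  expect_equal(unname(fv["mean_saccade_amp_deg"]), 1.2)
  expect_equal(unname(fv["saccade_rate_per_s"]), 2 / 5)
  expect_equal(unname(fv["flip_rate_horizontal_per_s"]), 0)  # monotone x
  expect_equal(length(fv), 12)
  expect_named(fv, feature_names())
  # time-reversal leaves step and flip features unchanged
  trr <- gaze_trace(1:n / fs, rev(x), rep(0, n), fs = fs)
  fvr <- build_feature_vector(trr, seg, "IVT")
  for (f in c("mean_gaze_step_deg", "sd_gaze_step_deg", "max_gaze_step_deg",
              "flip_rate_horizontal_per_s", "flip_rate_vertical_per_s"))
    expect_equal(fv[[f]], fvr[[f]])
})

test_that("single long fixation gives a degenerate but defined vector", {
  set.seed(31)
  tr <- gaze_trace(1:600 / 600, rnorm(600, 0, 0.01), rnorm(600, 0, 0.01))
  seg <- detect_saccades_ek(tr)
  fv <- build_feature_vector(tr, seg, "IVT")
  expect_equal(unname(fv["n_fixations"]), 1)
  expect_equal(unname(fv["total_fix_dur_s"]), 1, tolerance = 0.01)
  expect_true(is.na(fv["mean_saccade_amp_deg"]))
})

test_that("PCA reduction is standardised, sign-fixed and complete", {
  set.seed(32)
  # rank-1 structure: PC1 explains everything
  base <- rnorm(30)
  m1 <- outer(base, seq(0.5, 2, length.out = 5))
  colnames(m1) <- paste0("f", 1:5)
  p1 <- pca_reduce(m1, k = 2)
  expect_equal(p1$explained_variance_fraction[1], 1, tolerance = 1e-9)
  # explained fractions sum to 1 and are non-increasing
  m2 <- matrix(rnorm(50 * 12), 50, 12, dimnames = list(NULL, paste0("f", 1:12)))
  p2 <- pca_reduce(m2, k = 12)
  expect_equal(sum(p2$explained_variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(p2$explained_variance_fraction) <= 1e-12))
  # isotropic noise spreads variance roughly evenly
  m3 <- matrix(rnorm(4000 * 12), 4000, 12)
  p3 <- pca_reduce(m3, k = 3)
  expect_true(all(abs(p3$explained_variance_fraction - 1 / 12) < 0.02))
  # full reconstruction of the standardised matrix
  pr <- prcomp(m2, center = TRUE, scale. = TRUE)
  rec <- pr$x %*% t(pr$rotation)
  expect_equal(rec, scale(m2), tolerance = 1e-9, ignore_attr = TRUE)
  # sign convention: largest loading of each kept component is positive
  expect_true(all(apply(p2$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
  # constant column dropped with warning
  m4 <- cbind(m2[, 1:3], const = 1)
  expect_warning(p4 <- pca_reduce(m4, k = 2), "constant")
  expect_equal(nrow(p4$loadings), 3)
})

test_that("PC1 separates static from dynamic viewing styles", {
  set.seed(33)
  n_per <- 12
  styles <- c(rep("static", n_per), rep("dynamic", n_per))
  rows <- lapply(styles, function(s) {
    st <- if (s == "static")
      viewer_style_params(fix_dur_meanlog = log(0.5), fix_dur_sdlog = 0.3,
                          sacc_amp_shape = 4, sacc_amp_scale = 2,
                          blink_rate = 0)
    else
      viewer_style_params(fix_dur_meanlog = log(0.18), fix_dur_sdlog = 0.3,
                          sacc_amp_shape = 4, sacc_amp_scale = 0.6,
                          blink_rate = 0)
    tr <- simulate_free_viewing(st, 10)
    seg <- preprocess_trace(tr)
    build_feature_vector(tr, seg, "IVT")
  })
  mat <- do.call(rbind, rows)
  keep <- colSums(is.na(mat)) == 0
  p <- pca_reduce(mat[, keep], k = 3)
  grp <- as.numeric(styles == "static")
  r <- abs(cor(p$scores[, 1], grp))
  expect_gt(r, 0.8)
})
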