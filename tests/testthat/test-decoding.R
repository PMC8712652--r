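test_that("Fisher scores follow the criterion with degenerate conventions", {
  x <- cbind(c(0, 0, 1, 1))
  expect_identical(fisher_scores(x, c("a", "a", "b", "b")), Inf)
  x2 <- cbind(rep(c(1, 2), 4))
  expect_equal(fisher_scores(x2, rep(c("a", "b"), each = 4)), 0)
  x3 <- cbind(rep(2, 6))  # both variances zero, equal means
  expect_equal(fisher_scores(x3, rep(c("a", "b"), 3)), 0)
  expect_error(fisher_scores(x, rep("a", 4)), "two classes")
})

test_that("Fisher ranking matches a brute-force recomputation", {
  set.seed(41)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 50), 20, 50)
    y <- factor(rep(c("a", "b"), each = 10))
    fs <- fisher_scores(X, y)
    brute <- apply(X, 2, function(col) {
      m1 <- mean(col[1:10]); m2 <- mean(col[11:20])
      (m1 - m2)^2 / (var(col[1:10]) + var(col[11:20]))
    })
    expect_equal(fs, brute, tolerance = 1e-12)
    expect_identical(select_top(fs, 7), order(brute, decreasing = TRUE)[1:7])
  }
})

test_that("top-dim selection is deterministic under ties", {
  expect_identical(select_top(c(3, 1, 2), 2), c(1L, 3L))
  expect_identical(select_top(rep(1, 5), 2), c(1L, 2L))
  expect_identical(select_top(c(1, Inf, Inf), 2), c(2L, 3L))
  expect_error(select_top(c(1, 2), 0), "positive")
  expect_error(select_top(c(1, 2), 3), "exceeds")
})

test_that("separable data decodes perfectly and accuracies are 1/n multiples", {
  cfg <- simulation_config(seed = 21, n_reps = 10,
                           locations = c(-90L, 0L), intensities = 58L,
                           effects = effect_preset("high_snr"),
                           noise = quiet_noise())
  ft <- extract_features(
    preprocess_recording(simulate_session(cfg)$recording))
  res <- decode_contrast(ft, contrast_spec(-90, 0, 58, 58))
  expect_equal(res$best_accuracy, 1.0)
  expect_identical(res$n_obs, 20L)
  expect_true(all(abs(res$per_dim_accuracy * 20 -
                        round(res$per_dim_accuracy * 20)) < 1e-9))
})

test_that("training folds are blind to the held-out trial", {
  set.seed(55)
  n <- 14
  X <- matrix(rnorm(n * 30), n, 30)
  y <- factor(rep(c("a", "b"), each = n / 2))
  # the fold-i Fisher ranking and scaler depend on the training rows only:
  # garbling row i must leave them unchanged
  i <- 3
  tr <- setdiff(seq_len(n), i)
  rank_before <- select_top(fisher_scores(X[tr, ], y[tr]), 10)
  Xg <- X
  Xg[i, ] <- 1e6
  rank_after <- select_top(fisher_scores(Xg[tr, ], y[tr]), 10)
  expect_identical(rank_before, rank_after)

  # regression guard: ranking on all data (leaky) inflates null accuracy
  ftab <- structure(list(values = X,
                         info = data.frame(unit = 1L,
                                           start_s = seq_len(30),
                                           end_s = seq_len(30) + 1,
                                           stat = "mean"),
                         labels = data.frame(location_deg = 0L,
                                             intensity_db = 58L),
                         unit_kind = "roi"),
                    class = "nirs_features")
  honest <- replicate(15, {
    yp <- sample(y)
    loocv_svm(ftab, yp, dims = 1:5)$mean_dim_accuracy
  })
  leaky <- replicate(15, {
    yp <- sample(y)
    loocv_svm(ftab, yp, dims = 1:5, selection = "global")$mean_dim_accuracy
  })
  expect_gt(mean(leaky) - mean(honest), 0.15)
  expect_gt(mean(honest), 0.30)
  expect_lt(mean(honest), 0.65)
})

test_that("interhemispheric pairing picks the requested side per trial", {
  sess <- simulate_session(tiny_config(seed = 23, n_reps = 2,
                                       locations = c(-90L, 90L)))
  tt <- roi_average(segment(sess$recording))
  ips <- pair_hemispheres(tt, "ipsi")
  con <- pair_hemispheres(tt, "contra")
  expect_identical(dim(ips$data)[2], 5L)
  loc <- tt$labels$location_deg
  for (k in seq_along(loc)) {
    left <- tt$data[k, 1:5, ]
    right <- tt$data[k, 6:10, ]
    want_ipsi <- if (loc[k] == -90) left else right
    want_con <- if (loc[k] == -90) right else left
    expect_equal(ips$data[k, , ], want_ipsi)
    expect_equal(con$data[k, , ], want_con)
  }
  bad <- simulate_session(tiny_config(seed = 24, n_reps = 2))
  expect_error(pair_hemispheres(roi_average(segment(bad$recording))),
               "-90/\\+90")
})

test_that("sound-level decoding localizes an injected intensity effect", {
  cfg <- simulation_config(seed = 25, n_reps = 10, locations = -90L,
                           intensities = c(48L, 58L),
                           effects = effect_preset("intensity"))
  ft <- extract_features(
    preprocess_recording(simulate_session(cfg)$recording))
  sl <- sound_level_decoding(ft, -90, dims = 1:10)
  expect_length(sl$best_accuracy, 10L)
  expect_identical(names(which.max(sl$best_accuracy)), "roi4")
  expect_gt(sl$best_accuracy[["roi4"]],
            max(sl$best_accuracy[names(sl$best_accuracy) != "roi4"]))

  single <- simulate_session(tiny_config(seed = 26, n_reps = 2,
                                         locations = -90L))
  fts <- extract_features(preprocess_recording(single$recording))
  expect_error(sound_level_decoding(fts, -90), "both intensity classes")
})

test_that("accuracy summaries use an inclusive margin", {
  s <- summarize_accuracies(rep(0.70, 8))
  expect_identical(s$n_at_or_above, 8L)
  expect_equal(s$mean_pct, 70)
  s2 <- summarize_accuracies(c(65, 70, 75.5))
  expect_identical(s2$n_at_or_above, 2L)
  expect_equal(s2$mean_pct, 70.17)
  expect_error(summarize_accuracies(numeric(0)), "no accuracies")
})

test_that("condition comparisons behave at the degenerate and extreme ends", {
  x <- c(0.7, 0.75, 0.8, 0.65)
  same <- compare_conditions(x, x, "wilcoxon_signed_rank")
  expect_equal(same$p_value, 1)
  shift <- compare_conditions(rnorm(30), rnorm(30) + 10, "anova_oneway")
  expect_lt(shift$p_value, 0.001)
  expect_error(
    compare_conditions(1:3 / 10, 1:4 / 10, "wilcoxon_signed_rank"),
    "equal length")
})

test_that("one-way ANOVA holds its nominal type-I error rate", {
  set.seed(61)
  p <- replicate(400, {
    compare_conditions(rnorm(12), rnorm(12), "anova_oneway")$p_value
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
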