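# build a one-trial, one-unit epochs object from a raw 133-sample curve
curve_epochs <- function(x, fs = 13.3) {
  structure(list(data = array(x, dim = c(1, 1, length(x))),
                 labels = data.frame(location_deg = 0L, intensity_db = 58L),
                 fs_hz = fs, unit_kind = "roi", unit_ids = 1L,
                 window_s = 10),
            class = "nirs_epochs")
}

feat <- function(ft, start, end, stat) {
  ft$values[, ft$info$start_s == start & ft$info$end_s == end &
              ft$info$stat == stat]
}

test_that("window grid holds the fourteen analysis windows", {
  g <- window_grid()
  expect_identical(nrow(g), 14L)
  expect_identical(sum(g$end_s - g$start_s == 2), 7L)
  expect_identical(sum(g$end_s - g$start_s == 3), 4L)
  expect_identical(sum(g$end_s - g$start_s == 4), 3L)
  expect_true(all(g$start_s >= 0 & g$end_s <= 10))
})

test_that("analytic curves give the expected statistics", {
  fs <- 13.3
  t <- (0:132) / fs
  ramp <- curve_epochs(2 * t)
  ft <- extract_features(ramp)
  expect_identical(ncol(ft$values), 14L * 5L)
  expect_equal(unname(feat(ft, 4, 8, "slope")), 2, tolerance = 1e-10)
  expect_lt(abs(feat(ft, 4, 8, "skewness")), 1e-8)

  const <- extract_features(curve_epochs(rep(3.2, 133)))
  expect_equal(unname(feat(const, 2, 4, "variance")), 0)
  expect_equal(unname(feat(const, 2, 4, "slope")), 0)
  expect_equal(unname(feat(const, 2, 4, "skewness")), 0)
  expect_equal(unname(feat(const, 2, 4, "kurtosis")), 0)
  expect_equal(unname(feat(const, 5, 9, "mean")), 3.2)
})

test_that("each statistic matches a naive brute-force recomputation", {
  set.seed(31)
  sess <- simulate_session(tiny_config(seed = 31, n_reps = 2))
  tt <- roi_average(segment(sess$recording))
  ft <- extract_features(tt)
  g <- window_grid()
  fs <- tt$fs_hz
  for (pick in list(c(1, 1, 1), c(3, 5, 8), c(4, 10, 14))) {
    tr <- pick[1]; u <- pick[2]; w <- pick[3]
    idx <- (round(g$start_s[w] * fs) + 1):round(g$end_s[w] * fs)
    x <- tt$data[tr, u, idx]
    n <- length(x)
    m <- sum(x) / n
    m2 <- sum((x - m)^2) / n
    m3 <- sum((x - m)^3) / n
    m4 <- sum((x - m)^4) / n
    tsec <- (idx - 1) / fs
    slope <- unname(stats::coef(stats::lm(x ~ tsec))[2])
    col <- function(stat) {
      ft$values[tr, ft$info$unit == tt$unit_ids[u] &
                  ft$info$start_s == g$start_s[w] &
                  ft$info$end_s == g$end_s[w] & ft$info$stat == stat]
    }
    expect_equal(col("mean"), m, tolerance = 1e-12)
    expect_equal(col("variance"), m2 * n / (n - 1), tolerance = 1e-12)
    expect_equal(col("skewness"), m3 / m2^1.5, tolerance = 1e-12)
    expect_equal(col("kurtosis"), m4 / m2^2 - 3, tolerance = 1e-12)
    expect_equal(col("slope"), slope, tolerance = 1e-10)
  }
})

test_that("affine transformations act on the expected statistics only", {
  sess <- simulate_session(tiny_config(seed = 33, n_reps = 2))
  tt <- roi_average(segment(sess$recording))
  ft <- extract_features(tt)
  shifted <- tt; shifted$data <- tt$data + 5
  fts <- extract_features(shifted)
  is_mean <- fts$info$stat == "mean"
  expect_equal(fts$values[, is_mean], ft$values[, is_mean] + 5,
               tolerance = 1e-9)
  expect_equal(fts$values[, !is_mean], ft$values[, !is_mean],
               tolerance = 1e-9)

  scaled <- tt; scaled$data <- tt$data * 3
  ftc <- extract_features(scaled)
  st <- ftc$info$stat
  expect_equal(ftc$values[, st == "mean"], 3 * ft$values[, st == "mean"])
  expect_equal(ftc$values[, st == "slope"], 3 * ft$values[, st == "slope"])
  expect_equal(ftc$values[, st == "variance"],
               9 * ft$values[, st == "variance"])
  expect_equal(ftc$values[, st == "skewness"],
               ft$values[, st == "skewness"], tolerance = 1e-9)
  expect_equal(ftc$values[, st == "kurtosis"],
               ft$values[, st == "kurtosis"], tolerance = 1e-9)

  # permutation equivariance in trials
  perm <- c(3, 1, 4, 2)
  tp <- tt
  tp$data <- tt$data[perm, , , drop = FALSE]
  tp$labels <- tt$labels[perm, ]
  expect_equal(extract_features(tp)$values, ft$values[perm, ])
})

test_that("feature counts follow the granularity", {
  sess <- simulate_session(tiny_config(seed = 35, n_reps = 2))
  ch <- extract_features(segment(sess$recording))
  expect_identical(ncol(ch$values), 20L * 14L * 5L)
  ro <- extract_features(roi_average(segment(sess$recording)))
  expect_identical(ncol(ro$values), 10L * 14L * 5L)
  # descriptor order: unit, then window, then statistic
  expect_identical(ro$info$unit[1:70], rep(1L, 70))
  expect_identical(ro$info$stat[1:5],
                   c("mean", "variance", "skewness", "kurtosis", "slope"))
})

test_that("standardization uses subset statistics and zeroes degenerate features", {
  sess <- simulate_session(tiny_config(seed = 36, n_reps = 3))
  ft <- extract_features(roi_average(segment(sess$recording)))
  z <- standardize(ft)
  expect_lt(max(abs(colMeans(z$values))), 1e-12)
  expect_equal(unname(apply(z$values, 2, sd)), rep(1, ncol(z$values)),
               tolerance = 1e-9)

  ft2 <- ft
  ft2$values[, 1] <- 4.2
  expect_equal(unique(standardize(ft2)$values[, 1]), 0)

  # training-subset scaling applied to a held-out trial
  sub <- 1:(nrow(ft$values) - 1)
  z2 <- standardize(ft, stats_from = sub)
  mu <- mean(ft$values[sub, 2]); s <- sd(ft$values[sub, 2])
  held <- nrow(ft$values)
  expect_equal(z2$values[held, 2], (ft$values[held, 2] - mu) / s,
               tolerance = 1e-12)
})
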