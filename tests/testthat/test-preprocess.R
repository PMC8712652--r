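test_that("MBLL inversion recovers forward-projected concentrations", {
  E <- extinction_defaults()
  L <- 30
  # pure oxy change of 1: delta_OD = E %*% c(1, 0) * L
  od <- (as.matrix(E) %*% c(1, 0)) %*% t(rep(L, 5))
  res <- mbll_convert(od, E, pathlength_mm = L)
  expect_equal(res$oxy, rep(1, 5), tolerance = 1e-12)
  expect_equal(res$deoxy, rep(0, 5), tolerance = 1e-12)

  expect_equal(mbll_convert(matrix(0, 3, 4), E)$total, rep(0, 4))

  set.seed(5)
  dc <- matrix(rnorm(2 * 50), 2, 50)
  od <- as.matrix(E) %*% dc * L
  res <- mbll_convert(od, E, pathlength_mm = L)
  expect_lt(max(abs(rbind(res$oxy, res$deoxy) - dc)), 1e-10)
  expect_equal(res$total, res$oxy + res$deoxy)

  bad <- E; bad[, 2] <- 2 * bad[, 1]
  expect_error(mbll_convert(od, bad), "rank deficient")
})

test_that("CAR removes the channel mean at every time point", {
  rec <- toy_recording(n_samples = 500)
  out <- car_filter(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  expect_identical(dim(out$data), dim(rec$data))

  # zero-mean input is a fixed point
  x <- matrix(rnorm(300), 1, 300)
  two <- nirs_recording(rbind(x, -x),
                        channels = nirs_probe_map()[1:2, ])
  expect_equal(car_filter(two)$data, two$data)

  # identical channels go to zero
  same <- nirs_recording(rbind(x, x)[c(1, 2), ],
                         channels = nirs_probe_map()[1:2, ])
  expect_equal(max(abs(car_filter(same)$data)), 0)

  one <- nirs_recording(x, channels = nirs_probe_map()[1, , drop = FALSE])
  expect_error(car_filter(one), "single channel")
})

test_that("Butterworth chain stops cardiac rates and passes the response band", {
  fs <- 13.3
  t <- (0:11999) / fs
  settle <- 2000:10000
  mk_rec <- function(x) {
    nirs_recording(matrix(rep(x, 2), nrow = 2, byrow = TRUE),
                   channels = nirs_probe_map()[1:2, ])
  }
  cardiac <- sin(2 * pi * 1.2 * t)
  y <- bandpass(mk_rec(cardiac))$data[1, ]
  expect_lt(sd(y[settle]) / sd(cardiac), 0.01)

  slow <- sin(2 * pi * 0.1 * t)
  y2 <- bandpass(mk_rec(slow))$data[1, ]
  expect_lt(abs(sd(y2[settle]) / sd(slow[settle]) - 1), 0.1)

  dc <- rep(3, length(t))
  y3 <- bandpass(mk_rec(dc))$data[1, ]
  expect_lt(abs(mean(y3[settle])), 1e-6)

  expect_error(bandpass(mk_rec(slow), filter_spec(low_pass_hz = 7)),
               "Nyquist")
  expect_error(filter_spec(high_pass_hz = 0.3, low_pass_hz = 0.2),
               "high_pass")
})

test_that("segmentation yields 133-sample stimulus-locked epochs", {
  sess <- simulate_session(simulation_config(seed = 6, n_reps = 10))
  tt <- segment(sess$recording, baseline = "none")
  expect_identical(dim(tt$data), c(100L, 20L, 133L))
  expect_identical(nrow(tt$labels), 100L)

  # constant signal with pre-stimulus baseline -> all-zero trials
  const <- nirs_recording(
    matrix(7, 20, 800),
    events = data.frame(onset_s = c(15, 40), location_deg = 0L,
                        intensity_db = 58L, duration_s = 10))
  z <- segment(const, baseline = "pre_stim_mean")
  expect_equal(max(abs(z$data)), 0)

  # boundary: onset at exactly (len - 133)/fs fits, one sample later not
  fs <- 13.3
  len <- 400L
  ok_onset <- (len - 133L) / fs
  ev <- function(on) data.frame(onset_s = on, location_deg = 0L,
                                intensity_db = 58L, duration_s = 10)
  rec_ok <- nirs_recording(matrix(0, 20, len), events = ev(ok_onset))
  expect_identical(dim(segment(rec_ok, "none")$data), c(1L, 20L, 133L))
  rec_bad <- nirs_recording(matrix(0, 20, len),
                            events = ev(ok_onset + 1 / fs))
  expect_error(segment(rec_bad, "none"), "too close")
})

test_that("ROI averaging is the member mean and permutation invariant", {
  sess <- simulate_session(tiny_config(seed = 8, n_reps = 2))
  tt <- segment(sess$recording, baseline = "none")
  rt <- roi_average(tt)
  expect_identical(dim(rt$data)[2], 10L)
  # ROI 3 is channel 4 alone; ROI 1 averages channels 1, 2, 5, 8
  expect_equal(rt$data[, 3, ], tt$data[, 4, ])
  expect_equal(rt$data[, 1, ],
               apply(tt$data[, c(1, 2, 5, 8), , drop = FALSE], c(1, 3),
                     mean))

  # constants 1, 2, 3, 4 on ROI 1's channels -> constant 2.5
  cm <- matrix(0, 20, 800)
  cm[c(1, 2, 5, 8), ] <- c(1, 2, 3, 4)
  rec <- nirs_recording(cm, events = data.frame(
    onset_s = 20, location_deg = 0L, intensity_db = 58L, duration_s = 10))
  rr <- roi_average(segment(rec, "none"))
  expect_equal(unique(as.vector(rr$data[, 1, ])), 2.5)

  # permuting channel order leaves ROI series unchanged
  perm <- sample(20)
  tt_perm <- tt
  tt_perm$data <- tt$data[, perm, , drop = FALSE]
  tt_perm$unit_ids <- tt$unit_ids[perm]
  expect_equal(roi_average(tt_perm)$data, rt$data)

  expect_error(roi_average(rt), "channel-level")
})

test_that("filtering commutes with segmentation and the chain is deterministic", {
  cfg <- tiny_config(seed = 10, n_reps = 2)
  rec <- simulate_session(cfg)$recording
  a <- segment(bandpass(car_filter(rec)), baseline = "none")
  pre <- bandpass(car_filter(rec))
  b <- segment(pre, baseline = "none")
  expect_identical(a$data, b$data)
  # pure function: same input, same output
  rec2 <- simulate_session(cfg)$recording
  expect_identical(segment(bandpass(car_filter(rec2)), "none")$data,
                   a$data)
})

test_that("grand averages report mean and SEM per condition", {
  sess <- simulate_session(tiny_config(seed = 12, n_reps = 4))
  tt <- roi_average(segment(sess$recording))
  ga <- grand_average(tt)
  expect_identical(length(ga), 2L)
  one <- ga[[1]]
  expect_identical(dim(one$mean), c(10L, 133L))
  expect_true(all(one$sem >= 0))

  # identical trials -> zero SEM; {0-curve, 2-curve} -> mean 1
  tt2 <- tt
  tt2$data <- tt$data[c(1, 1), , , drop = FALSE]
  tt2$labels <- tt$labels[c(1, 1), ]
  expect_equal(max(grand_average(tt2)[[1]]$sem), 0)
  tt3 <- tt2
  tt3$data[1, , ] <- 0
  tt3$data[2, , ] <- 2
  g3 <- grand_average(tt3)[[1]]
  expect_equal(unique(as.vector(g3$mean)), 1)

  tt4 <- tt
  tt4$labels$location_deg[1] <- 30L  # singleton condition
  expect_error(grand_average(tt4), "at least 2 trials")
})

test_that("group-level grand average pools per-subject mean curves", {
  subj <- lapply(c(16, 17), function(s) {
    roi_average(segment(simulate_session(tiny_config(seed = s,
                                                     n_reps = 3))$recording))
  })
  gg <- grand_average(subj)
  per <- lapply(subj, grand_average)
  cond <- names(gg)[1]
  manual_mean <- (per[[1]][[cond]]$mean + per[[2]][[cond]]$mean) / 2
  expect_equal(gg[[cond]]$mean, manual_mean, tolerance = 1e-12)
  expect_identical(gg[[cond]]$n, 2L)
  # subject-level SEM: sd of the two subject means over sqrt(2)
  manual_sem <- abs(per[[1]][[cond]]$mean - per[[2]][[cond]]$mean) /
    sqrt(2) / sqrt(2)
  expect_equal(gg[[cond]]$sem, manual_sem, tolerance = 1e-10)
})
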