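make_trigger_tbl <- function(x, y, time, fs = 25, scale = 0.05) {
  ts <- tibble::tibble(channel = seq_along(x), x = as.integer(x),
                       y = as.integer(y), time = time, state = "up")
  attr(ts, "sampling_rate") <- fs
  attr(ts, "spatial_scale") <- scale
  class(ts) <- c("trigger_set", class(ts))
  ts
}

test_that("time-space ratio follows v0 / (rate * scale) and is linear in v0", {
  expect_identical(compute_time_space_ratio(10, 25, 0.05), 8)
  expect_identical(compute_time_space_ratio(20, 25, 0.05), 16)
  expect_identical(compute_time_space_ratio(2, 4, 0.5), 1)
  expect_error(compute_time_space_ratio(-1, 25, 0.05), "> 0")
  for (v0 in c(1, 7.5, 33)) {
    expect_equal(compute_time_space_ratio(2 * v0, 25, 0.05),
                 2 * compute_time_space_ratio(v0, 25, 0.05))
  }
})

test_that("density clustering obeys DBSCAN semantics on hand fixtures", {
  # a single isolated trigger with min_samples 5 is noise
  lone <- make_trigger_tbl(0, 0, 1)
  ws <- cluster_triggers_to_waves(lone, 1, neighbour_distance = 2,
                                  min_samples_per_wave = 5)
  expect_equal(ws$wave, NOISE_LABEL)

  # two dense groups far apart in scaled time form two waves
  g <- expand.grid(x = 0:3, y = 0:3)
  ts <- tibble::tibble(
    channel = rep(seq_len(16), 2),
    x = rep(g$x, 2), y = rep(g$y, 2),
    time = c(rep(1, 16), rep(1 + 10 * 2 / 1, 16)),  # 10x eps in scaled time
    state = "up"
  )
  attr(ts, "sampling_rate") <- 1
  class(ts) <- c("trigger_set", class(ts))
  ws <- cluster_triggers_to_waves(ts, 1, neighbour_distance = 2,
                                  min_samples_per_wave = 5)
  expect_equal(sort(unique(ws$wave)), c(1, 2))
  expect_true(all(ws$wave[ws$time == 1] == 1))  # ids ordered by onset
})

test_that("clustering recovers the exact ground-truth wave membership", {
  sim <- simulate_wave_recording(n_x = 8, n_y = 8, n_waves = 3, v0 = 15,
                                 theta = 0, noise_sd = 0, seed = 1)
  proc <- sim$recording |> detrend() |> zscore()
  ts <- detect_hilbert_triggers(proc)
  ratio <- compute_time_space_ratio(15, 25, 0.05)
  ws <- cluster_triggers_to_waves(ts, ratio, 3, 10)
  expect_equal(glance(ws)$n_waves, 3)
  expect_equal(glance(ws)$n_noise, 0)
  # every detected wave contains exactly the 64 channels of one true wave
  sizes <- table(ws$wave)
  expect_true(all(sizes == 64))
  # membership matches truth: triggers of wave k all lie near true wave k
  for (k in 1:3) {
    wk <- ws[ws$wave == k, ]
    true_k <- sim$truth[sim$truth$wave == k, ]
    m <- dplyr::inner_join(as.data.frame(wk), as.data.frame(true_k),
                           by = "channel", suffix = c("", ".t"))
    expect_true(all(abs(m$time - m$time.t) < 0.5))
  }
})

test_that("clustering is invariant to a global time shift", {
  sim <- simulate_wave_recording(n_x = 6, n_y = 6, n_waves = 2, v0 = 15,
                                 noise_sd = 0, seed = 1)
  proc <- sim$recording |> detrend() |> zscore()
  ts <- detect_hilbert_triggers(proc)
  shifted <- ts
  shifted$time <- shifted$time + 1000
  a <- cluster_triggers_to_waves(ts, 12, 3, 10)
  b <- cluster_triggers_to_waves(shifted, 12, 3, 10)
  expect_equal(a$wave, b$wave)
})

test_that("wave-membership recall stays >= 0.99 across noisy seeds", {
  recall <- vapply(1:5, function(seed) {
    sim <- simulate_wave_recording(n_x = 8, n_y = 8, n_waves = 3, v0 = 15,
                                   theta = 0, noise_sd = 0.05, seed = seed)
    proc <- process_calcium(sim$recording)
    ts <- detect_hilbert_triggers(proc)
    ws <- cluster_triggers_to_waves(ts, compute_time_space_ratio(15, 25, 0.05),
                                    neighbour_distance = 4,
                                    min_samples_per_wave = 10)
    m <- dplyr::inner_join(as.data.frame(ws[ws$wave != NOISE_LABEL, ]),
                           as.data.frame(sim$truth), by = "channel",
                           suffix = c("", ".t"), relationship = "many-to-many")
    m <- m[abs(m$time - m$time.t) < 0.5, ]
    hit <- unique(paste(m$wave.t, m$channel))
    length(hit) / nrow(sim$truth)
  }, numeric(1))
  expect_true(all(recall >= 0.99))
})

test_that("channel deduplication keeps the earliest trigger per wave", {
  ts <- make_trigger_tbl(c(0, 0, 1), c(0, 0, 0), c(1.0, 1.2, 1.05))
  ts$channel <- c(1L, 1L, 2L)
  ts$wave <- c(1L, 1L, 1L)
  class(ts) <- c("wave_set", class(ts))
  out <- dedupe_channel_triggers(ts)
  expect_equal(nrow(out), 2)
  expect_equal(out$time[out$channel == 1], 1.0)
  expect_identical(nrow(dedupe_channel_triggers(ts, "keep_all")), 3L)
  expect_error(build_delay_map(dedupe_channel_triggers(ts, "keep_all"), 1),
               "duplicated channels")
  # already-unique input passes through unchanged
  expect_equal(dedupe_channel_triggers(out)$time, out$time)
})

test_that("phase field is uniform for a common signal and NaN when masked", {
  fs <- 25
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  rec <- make_rec(3, 3, length(t), fill = function(n) 0)
  rec$signals <- matrix(rep(sin(2 * pi * t), each = 9), nrow = 9)
  rec$channel_mask[5] <- FALSE
  ph <- phase_field(rec)
  expect_equal(dim(ph), c(length(t), 3, 3))
  for (fr in c(10, 50)) {
    vals <- ph[fr, , ][is.finite(ph[fr, , ])]
    expect_lt(diff(range(vals)), 1e-9)
  }
  expect_true(all(is.nan(ph[, rec$coords$y[5] + 1, rec$coords$x[5] + 1])))
})

test_that("optical flow of a static field is zero", {
  fld <- array(rep(sin(outer(1:8, 1:8) / 5), each = 10), c(10, 8, 8))
  flow <- compute_optical_flow(fld, source = "amplitude")
  expect_lt(max(abs(flow$u), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(flow$v), na.rm = TRUE), 1e-6)
})

test_that("optical flow recovers a known phase-plane translation", {
  # phase plane moving +x at 1 site/frame: phi(x, t) = c (x - t)
  nx <- 12; nt <- 30; cc <- 0.7
  fld <- array(NA_real_, c(nt, nx, nx))
  for (tt in 1:nt) for (yy in 1:nx) {
    fld[tt, yy, ] <- ((cc * ((1:nx) - tt)) + pi) %% (2 * pi) - pi
  }
  attr(fld, "sampling_rate") <- 1
  flow <- compute_optical_flow(fld, max_iter = 2000)
  inner <- flow$u[10:20, 4:9, 4:9]
  innerv <- flow$v[10:20, 4:9, 4:9]
  ang <- atan2(innerv, inner)
  expect_lt(max(abs(ang)) * 180 / pi, 5)          # direction error < 5 deg
  expect_equal(mean(inner), 1, tolerance = 0.15)  # speed ~ 1 site/frame
})

test_that("a huge smoothness weight yields a spatially uniform flow", {
  nx <- 8; nt <- 10
  fld <- array(stats::rnorm(nt * nx * nx, sd = 0.1), c(nt, nx, nx))
  flow <- compute_optical_flow(fld, alpha = 1e4, source = "amplitude",
                               smooth_sigma = c(space = 0, time = 0))
  for (fr in c(2, 5)) {
    u <- flow$u[fr, , ]
    mag <- sqrt(mean(u^2) + mean(flow$v[fr, , ]^2))
    expect_lt(stats::var(as.numeric(u)), max(1e-3 * mag, 1e-9))
  }
})

test_that("flow on phase uses circular differences: +2pi changes nothing", {
  sim <- simulate_wave_recording(n_x = 6, n_y = 6, n_waves = 2, noise_sd = 0,
                                 seed = 1)
  proc <- sim$recording |> detrend() |> zscore()
  ph <- phase_field(proc)
  ph2 <- ph + 2 * pi
  attributes(ph2) <- attributes(ph)
  f1 <- compute_optical_flow(ph, max_iter = 50)
  f2 <- compute_optical_flow(ph2, max_iter = 50)
  expect_equal(f1$u, f2$u, tolerance = 1e-12)
  expect_equal(f1$v, f2$v, tolerance = 1e-12)
})

test_that("flow directions at triggers point along propagation", {
  # planar +x wave: all trigger directions ~ 0 rad
  sim <- recovery_sim(15, 0, seed = 1)
  proc <- process_calcium(sim$recording)
  ts <- detect_hilbert_triggers(proc)
  ws <- cluster_triggers_to_waves(ts, compute_time_space_ratio(15, 50, 0.5),
                                  3, 10) |> dedupe_channel_triggers()
  flow <- compute_optical_flow(phase_field(proc))
  wd <- wave_directions_from_flow(ws, flow)
  expect_lt(ang_diff(circ_mean_test(wd$direction), 0) * 180 / pi, 5)

  # radial wave: directions point outward from the origin
  simr <- recovery_sim(10, 0, seed = 1, pattern = "radial", n = 13)
  procr <- process_calcium(simr$recording)
  tsr <- detect_hilbert_triggers(procr)
  wsr <- cluster_triggers_to_waves(tsr, compute_time_space_ratio(10, 50, 0.5),
                                   3, 10) |> dedupe_channel_triggers()
  flowr <- compute_optical_flow(phase_field(procr))
  wdr <- wave_directions_from_flow(wsr, flowr)
  ctr <- c(6, 6)
  away <- dplyr::filter(wdr, sqrt((x - ctr[1])^2 + (y - ctr[2])^2) > 3)
  expected <- atan2(away$y - ctr[2], away$x - ctr[1])
  err <- ang_diff(away$direction, expected) * 180 / pi
  expect_lt(stats::median(err), 10)
})

test_that("wave modes separate opposite propagation directions exactly", {
  sim <- simulate_wave_recording(
    n_x = 8, n_y = 8, n_waves = 10, period = 4, v0 = 15,
    theta = rep(c(0, pi), 5), noise_sd = 0, seed = 1
  )
  proc <- sim$recording |> detrend() |> zscore()
  ts <- detect_hilbert_triggers(proc)
  ws <- cluster_triggers_to_waves(ts, compute_time_space_ratio(15, 25, 0.05),
                                  3, 10) |> dedupe_channel_triggers()
  wm <- cluster_wave_modes(ws, 2)
  lab <- dplyr::distinct(wm[wm$wave != NOISE_LABEL, ], wave, mode) |>
    dplyr::arrange(wave)
  # waves alternate direction, so modes must alternate in lockstep
  expect_length(unique(lab$mode[seq(1, 10, 2)]), 1)
  expect_length(unique(lab$mode[seq(2, 10, 2)]), 1)
  expect_false(lab$mode[1] == lab$mode[2])

  one <- cluster_wave_modes(ws, 1)
  expect_true(all(one$mode[one$wave != NOISE_LABEL] == 1))
  expect_error(cluster_wave_modes(ws, 99), "exceeds")
})

test_that("mode clustering terminates on degenerate identical waves", {
  # same delay pattern repeated: k = 2 must not loop or crash, and the
  # reported between-cluster separation is ~0
  ts <- purrr::map_dfr(1:4, function(k) {
    tibble::tibble(channel = 1:9,
                   x = rep(0:2, 3), y = rep(0:2, each = 3),
                   time = 10 * k + rep(0:2, 3) * 0.1, state = "up", wave = k)
  })
  attr(ts, "spatial_scale") <- 0.05
  class(ts) <- c("wave_set", class(ts))
  out <- cluster_wave_modes(ts, 2)
  expect_true(all(!is.na(out$mode)))
  expect_lt(attr(out, "mode_separation"), 1e-9)
})
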