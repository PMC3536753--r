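# Hand-built single-cell stacks for the extraction arithmetic ----------

mini_stack <- function(nuc_val, ring_val, frames = 5) {
  h <- 16; w <- 16
  reporter <- array(0, c(h, w, frames))
  labels <- array(0L, c(h, w, frames))
  rings <- array(0L, c(h, w, frames))
  labels[6:9, 6:9, ] <- 1L
  rings[12:14, 12:14, ] <- 1L
  for (f in seq_len(frames)) {
    reporter[, , f][labels[, , f] == 1] <- nuc_val[f]
    reporter[, , f][rings[, , f] == 1] <- ring_val[f]
  }
  list(reporter = reporter, labels = labels, rings = rings,
       track = list(track_id = 1, label = rep(1L, frames)))
}

test_that("trace normalization divides by the pre-stimulus ring mean", {
  st <- mini_stack(nuc_val = c(10, 10, 10, 30, 30),
                   ring_val = c(10, 10, 10, 5, 5))
  tr <- extract_trace(st$reporter, st$track, st$labels, st$rings,
                      stim_frame = 4, dt = 5, background = 0)
  expect_equal(tr$intensity[4], 3.0)
  # background subtracted from both before division
  tr2 <- extract_trace(st$reporter, st$track, st$labels, st$rings,
                       stim_frame = 4, dt = 5, background = 5)
  expect_equal(tr2$intensity[4], (30 - 5) / (10 - 5))
})

test_that("cells without pre-stimulus cytoplasm are excluded with a warning", {
  st <- mini_stack(nuc_val = rep(10, 5), ring_val = rep(10, 5))
  st$rings[] <- 0L
  expect_warning(
    out <- extract_trace(st$reporter, st$track, st$labels, st$rings,
                         stim_frame = 4, dt = 5, background = 0),
    "excluded")
  expect_null(out)
})

test_that("batch extraction equals single-track extraction", {
  cfg <- tiny_cfg()
  preset <- preparation_preset("Sigma")
  sim <- simulate_condition(preset, 0.5, n_cells = 4, cfg = cfg, seed = 17)
  res <- analyze_movie(sim$movie, background = cfg$background)
  one <- extract_trace(sim$movie$stack[, , 2, ], res$tracks[[1]],
                       res$stack$labels, res$stack$rings,
                       cfg$stim_frame, cfg$dt, background = cfg$background)
  expect_equal(res$traces[["1"]]$intensity, one$intensity)
})

test_that("activity classification respects threshold and run length", {
  tt <- seq(-5, 50, by = 5)
  base <- rep(1, length(tt))
  expect_false(classify_active(new_trace(1, tt, base)))
  bump <- function(k) {           # k consecutive frames at baseline + 0.25
    v <- base; v[3:(2 + k)] <- 1.25; new_trace(1, tt, v)
  }
  expect_true(classify_active(bump(3), theta = 0.2, m = 3))
  expect_false(classify_active(bump(2), theta = 0.2, m = 3))
})

test_that("peak statistics read off amplitude, timing and width", {
  tr <- new_trace(1, c(-5, 0, 5, 10, 15, 20), c(1, 1, 1, 2, 1, 1))
  ft <- peak_features(tr)
  expect_equal(ft$peak_amp, 2)
  expect_equal(ft$time_to_peak, 10)
  # hand-interpolated width: ramp 0-1-2-1-0, half level 1, crossings 5/15
  tr2 <- new_trace(1, c(-5, 0, 5, 10, 15, 20), c(0.1, 0, 1, 2, 1, 0))
  ft2 <- peak_features(tr2)
  expect_equal(ft2$half_level, 1.0)
  expect_equal(ft2$peak_width, 10)
  expect_false(ft2$width_censored)
})

test_that("widths are right-censored when the trace never re-descends", {
  tr <- new_trace(1, c(-5, 0, 5, 10, 15), c(1, 1, 1.5, 2, 2))
  ft <- peak_features(tr)
  expect_true(ft$width_censored)
})

test_that("noiseless central traces recover the preset parameters", {
  preset <- preparation_preset("Sigma")
  cfg <- imaging_config(n_frames = 120, height = 64, width = 64)
  p <- central_pulse_params(preset, 0.5, "transient")
  tt <- frame_times(cfg)
  ft <- peak_features(new_trace(1, tt, pulse_value(p, tt)))
  expect_lt(abs(ft$time_to_peak - p$tau), cfg$dt / 2)
  expect_lt(abs(ft$peak_amp - (p$baseline + p$amp)) / (p$baseline + p$amp),
            0.01)
})

test_that("secondary activations are counted by prominence and separation", {
  tt <- seq(-15, 580, by = 5)
  single <- pulse_params(amp = 1, tau = 50, shape = 4)
  expect_equal(count_secondary_peaks(new_trace(1, tt, pulse_value(single, tt))),
               0L)
  dbl <- pulse_params(amp = 1, tau = 50, shape = 4, secondary_amp = 1,
                      secondary_time = 170, secondary_rise = 45,
                      responder_class = "secondary")
  expect_equal(count_secondary_peaks(new_trace(1, tt, pulse_value(dbl, tt))),
               1L)
  # two pulses closer than min_separation are one event
  near <- pulse_params(amp = 1, tau = 50, shape = 8, secondary_amp = 1,
                       secondary_time = 60, secondary_rise = 20,
                       responder_class = "secondary")
  expect_equal(count_secondary_peaks(new_trace(1, tt, pulse_value(near, tt)),
                                     min_separation = 60), 0L)
})

test_that("features are invariant to a global gain on the reporter", {
  cfg <- tiny_cfg(background = 0, read_noise_sd = 0)
  preset <- preparation_preset("Sigma")
  sim <- simulate_condition(preset, 50, n_cells = 3, cfg = cfg, seed = 23)
  res1 <- analyze_movie(sim$movie, background = 0)
  gained <- sim$movie
  gained$stack[, , 2, ] <- gained$stack[, , 2, ] * 3.7
  res2 <- analyze_movie(gained, background = 0)
  f1 <- trace_features_table(res1$traces)
  f2 <- trace_features_table(res2$traces)
  expect_equal(f1$peak_amp, f2$peak_amp, tolerance = 1e-10)
  expect_equal(f1$time_to_peak, f2$time_to_peak)
  expect_equal(f1$peak_width, f2$peak_width, tolerance = 1e-10)
})

test_that("gap frames are excluded from features and break activity runs", {
  tt <- seq(-5, 45, by = 5)
  v <- c(1, 1, 5, 1.5, 1.5, 1, 1, 1, 1, 1, 1)
  valid <- rep(TRUE, 11); valid[3] <- FALSE      # the spike is a gap frame
  ft <- peak_features(new_trace(1, tt, v, valid))
  expect_equal(ft$peak_amp, 1.5)
})
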