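noiseless_cfg <- function(...) {
  imaging_config(n_frames = 30, height = 96, width = 96, motion_sd = 0,
                 shot_noise = FALSE, read_noise_sd = 0, background = 10, ...)
}

# extract with ground-truth masks: renderer fidelity isolated from
# segmentation quality
truth_trace <- function(out, cfg, cell_id = 1) {
  lab <- out$truth$labels
  TT <- dim(lab)[3]
  rings <- array(0L, dim(lab))
  for (f in seq_len(TT))
    rings[, , f] <- cytoplasm_ring(lab[, , f], r_in = 1, r_out = 6)
  track <- list(track_id = cell_id, label = rep(cell_id, TT))
  extract_trace(out$movie$stack[, , 2, ], track, lab, rings,
                cfg$stim_frame, cfg$dt, background = cfg$background)
}

test_that("noiseless motionless renders reproduce true traces within 2%", {
  cfg <- noiseless_cfg()
  preset <- preparation_preset("Sigma")
  set.seed(4)
  cells <- sample_population(preset, 50, n_cells = 2, cfg = cfg, seed = 4)
  out <- render_movie(cells, cfg)
  for (i in 1:2) {
    tr <- truth_trace(out, cfg, i)
    rel <- abs(tr$intensity - cells[[i]]$true_trace$intensity) /
      cells[[i]]$true_trace$intensity
    expect_lt(max(rel), 0.02)
  }
})

test_that("an inactive cell keeps a constant nuclear/cytoplasmic ratio", {
  cfg <- noiseless_cfg()
  preset <- preparation_preset("Sigma")
  set.seed(11)
  cells <- sample_population(preset, 0, n_cells = 1, cfg = cfg, seed = 11)
  expect_false(cells[[1]]$active)
  out <- render_movie(cells, cfg)
  tr <- truth_trace(out, cfg)
  expect_lt(diff(range(tr$intensity)), 0.02 * mean(tr$intensity))
})

test_that("reporter is conserved per cell in noiseless renders", {
  cfg <- noiseless_cfg()
  preset <- preparation_preset("UP")
  set.seed(6)
  cells <- sample_population(preset, 5, n_cells = 1, cfg = cfg, seed = 6)
  out <- render_movie(cells, cfg)
  tot <- vapply(seq_len(cfg$n_frames), function(f)
    sum(out$movie$stack[, , 2, f] - cfg$background), 0)
  expect_lt((max(tot) - min(tot)) / mean(tot), 0.01)
})

test_that("shot noise is Poisson: per-pixel variance matches the mean", {
  cfg <- imaging_config(n_frames = 6, stim_frame = 2, height = 128,
                        width = 128, background = 1000, read_noise_sd = 0,
                        motion_sd = 0)
  preset <- preparation_preset("Sigma")
  set.seed(8)
  cells <- sample_population(preset, 0.5, n_cells = 1, cfg = cfg, seed = 8)
  out <- render_movie(cells, cfg)
  # far corner of the field is a flat background patch at photon scale 1000
  patch <- out$movie$stack[1:30, 1:30, 1, ]
  expect_lt(abs(var(as.vector(patch)) / mean(patch) - 1), 0.1)
})

test_that("simulated conditions are bitwise reproducible by seed", {
  cfg <- tiny_cfg()
  preset <- preparation_preset("EB")
  a <- simulate_condition(preset, 0.5, n_cells = 3, cfg = cfg, seed = 99)
  b <- simulate_condition(preset, 0.5, n_cells = 3, cfg = cfg, seed = 99)
  expect_identical(a$movie$stack, b$movie$stack)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("no cells are active without ligand", {
  cfg <- tiny_cfg()
  preset <- preparation_preset("Sigma")
  sim <- simulate_condition(preset, 0, n_cells = 20, cfg = cfg, seed = 13)
  expect_false(any(vapply(sim$truth$cells, `[[`, TRUE, "active")))
})

test_that("active cell count far above K matches the binomial expectation", {
  cfg <- tiny_cfg()
  preset <- preparation_preset("Sigma")
  set.seed(21)
  cells <- sample_population(preset, 100, n_cells = 100, cfg = cfg)
  n_act <- sum(vapply(cells, `[[`, TRUE, "active"))
  p <- activation_probability(preset$dose, 100)
  se <- sqrt(100 * p * (1 - p))
  expect_lt(abs(n_act - 100 * p), 3 * se + 1)
})
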