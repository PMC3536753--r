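mk_trace <- function(id, tt, vv) new_trace(id, tt, vv)

test_that("average time course is the pointwise mean on the grid", {
  grid <- seq(0, 50, by = 5)
  tt <- seq(-5, 50, by = 5)
  a <- mk_trace(1, tt, seq(1, 2, length.out = 12))
  b <- mk_trace(2, tt, seq(2, 1, length.out = 12))
  expect_equal(average_time_course(list(a, a), grid),
               approx(a$time, a$intensity, grid, rule = 2)$y)
  avg <- average_time_course(list(a, b), grid)
  expect_equal(avg, (approx(a$time, a$intensity, grid, rule = 2)$y +
                       approx(b$time, b$intensity, grid, rule = 2)$y) / 2)
})

test_that("resampling a 6-min acquisition to the 5-min grid interpolates linearly", {
  tr <- mk_trace(1, c(-6, 0, 6, 12), c(1, 1, 2, 1))
  out <- average_time_course(list(tr), grid = c(0, 5, 10))
  expect_equal(out, c(1, 1 + 5 / 6, 2 - 4 / 6))
})

test_that("averaging is permutation invariant and flags empty conditions", {
  tt <- seq(-5, 30, by = 5)
  trs <- lapply(1:4, function(i) mk_trace(i, tt, runif(8, 1, 2)))
  g <- seq(0, 30, by = 5)
  expect_equal(average_time_course(trs, g),
               average_time_course(rev(trs), g))
  empty <- average_time_course(list(), g)
  expect_length(empty, 0)
  expect_true(attr(empty, "empty"))
})

test_that("cosine distance satisfies its identities", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 2, 3), c(2, 4, 6)), 0)
  expect_error(cosine_distance(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_distance(1:3, 1:4), "equal length")
  set.seed(5)
  for (i in 1:20) {     # scale invariance and symmetry
    u <- rnorm(30); v <- rnorm(30); cpos <- runif(1, 0.01, 100)
    expect_equal(cosine_distance(u, cpos * v), cosine_distance(u, v))
    expect_equal(cosine_distance(u, v), cosine_distance(v, u))
    expect_true(cosine_distance(u, v) >= 0 && cosine_distance(u, v) <= 2)
  }
})

sim_summary <- function(preset_name, conc, seed, n = 12, stnfr = FALSE) {
  # window long enough for the slow EB peak (~143 min) to register
  cfg <- imaging_config(n_frames = 70, height = 96, width = 96)
  preset <- preparation_preset(preset_name)
  set.seed(seed)
  cells <- sample_population(preset, conc, stnfr, n_cells = n, cfg = cfg)
  traces <- lapply(cells, `[[`, "true_trace")
  names(traces) <- vapply(cells, function(cl) as.character(cl$cell_id), "")
  ft <- trace_features_table(traces)
  condition_summary(ft, traces, preset_name, conc, stnfr,
                    grid = seq(0, 330, by = 5))
}

test_that("similarity matrix is symmetric, zero-diagonal and ordered", {
  s <- list(sim_summary("Sigma", 0.5, 1), sim_summary("Sigma", 0.05, 2),
            sim_summary("EB", 0.5, 3), sim_summary("EB", 0.05, 4))
  m <- similarity_matrix(s)
  expect_true(isSymmetric(m$distance))
  expect_true(all(diag(m$distance) == 0))
  expect_true(all(m$distance >= 0 & m$distance <= 2))
  # grouped by preparation, descending concentration within the block
  expect_equal(m$labels, c("Sigma_0.5", "Sigma_0.05", "EB_0.5", "EB_0.05"))
})

test_that("duplicated conditions sit at distance zero", {
  a <- sim_summary("Sigma", 0.5, 9)
  m <- similarity_matrix(list(a, a))
  expect_equal(m$distance[1, 2], 0)
})

test_that("same-preparation replicates are closer than cross-preparation pairs", {
  s_sig1 <- sim_summary("Sigma", 0.5, 11, n = 25)
  s_sig2 <- sim_summary("Sigma", 0.5, 12, n = 25)
  s_eb <- sim_summary("EB", 0.5, 13, n = 25)
  d_within <- cosine_distance(s_sig1$average_course, s_sig2$average_course)
  d_cross1 <- cosine_distance(s_sig1$average_course, s_eb$average_course)
  d_cross2 <- cosine_distance(s_sig2$average_course, s_eb$average_course)
  expect_lt(d_within, min(d_cross1, d_cross2))
})

test_that("fraction active counts exactly", {
  expect_equal(fraction_active(rep(FALSE, 100))$fraction, 0)
  expect_equal(fraction_active(rep(TRUE, 100))$fraction, 1)
  f <- fraction_active(data.frame(active = c(TRUE, TRUE, FALSE)))
  expect_equal(f$n_active, 2); expect_equal(f$n_total, 3)
})

test_that("simulated dose-response is monotone within binomial noise", {
  preset <- preparation_preset("Sigma")
  cfg <- imaging_config(n_frames = 6, stim_frame = 2, height = 64, width = 64)
  cgrid <- 5 * 10^seq(-7, 1, by = 2)
  set.seed(71)
  n <- 150
  fr <- vapply(cgrid, function(cn) {
    mean(vapply(sample_population(preset, cn, n_cells = n, cfg = cfg),
                `[[`, TRUE, "active"))
  }, 0)
  se <- sqrt(0.25 / n)
  expect_true(all(diff(fr) >= -3 * se * sqrt(2)))
})

test_that("receptor effect pairs arms and flags empty conditions", {
  a <- sim_summary("Sigma", 0.5, 21, n = 20)
  b <- sim_summary("Sigma", 0.5, 22, n = 20, stnfr = TRUE)
  re <- receptor_effect(a, b)
  expect_false(re$empty)
  expect_true(re$distance >= 0 && re$distance <= 2)
  expect_error(receptor_effect(a, sim_summary("EB", 0.5, 23)),
               "share preparation")
  empty <- sim_summary("Sigma", 0, 24, n = 5)       # no ligand: no active cells
  empty_arm <- sim_summary("Sigma", 0, 25, n = 5, stnfr = TRUE)
  re0 <- receptor_effect(empty, empty_arm)
  expect_true(re0$empty)
  expect_true(is.na(re0$distance))
})
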