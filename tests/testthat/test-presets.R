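test_that("Hill activation probability has midpoint, zero and ceiling", {
  d <- dose_model(pmax = 0.8, K = 0.01, h = 1.5)
  expect_equal(activation_probability(d, 0.01), 0.4)
  expect_equal(activation_probability(d, 0), 0)
  expect_error(activation_probability(d, -1), ">= 0")
})

test_that("activation probability is nondecreasing in concentration", {
  set.seed(7)
  for (i in 1:20) {
    d <- dose_model(pmax = runif(1), K = 10^runif(1, -8, 1),
                    h = runif(1, 0.3, 3))
    cgrid <- sort(10^runif(30, -9, 2))
    p <- activation_probability(d, cgrid)
    expect_true(all(diff(p) >= -1e-12))
    expect_true(all(p >= 0 & p <= d$pmax))
  }
})

test_that("shipped dose models reproduce each preparation's potency window", {
  sig <- preparation_preset("Sigma")
  eb <- preparation_preset("EB")
  up <- preparation_preset("UP")
  # Sigma near-maximal by 5e-3 ug/mL
  expect_gte(activation_probability(sig$dose, 5e-3), 0.9 * sig$dose$pmax)
  # UP essentially inert at the lowest dose, peaking only at 0.5-5 ug/mL
  expect_lt(activation_probability(up$dose, 5e-7), 0.01)
  expect_lt(activation_probability(up$dose, 0.05), 0.9 * up$dose$pmax)
  expect_gte(activation_probability(up$dose, 5), 0.9 * up$dose$pmax)
  # EB activates almost all cells even at the lowest dose simulated
  expect_gte(activation_probability(eb$dose, 5e-7), 0.9 * eb$dose$pmax)
})

test_that("central preset traces encode the cross-preparation anchors", {
  sig <- preparation_preset("Sigma")
  eb <- preparation_preset("EB")
  up <- preparation_preset("UP")
  tt <- seq(-10, 900, by = 0.05)
  feat <- function(preset, conc) {
    p <- central_pulse_params(preset, conc, "transient")
    peak_features(new_trace(1, tt, pulse_value(p, tt)))
  }
  fs <- feat(sig, 0.5); fe <- feat(eb, 0.5); fu <- feat(up, 0.5)
  amp <- function(f) f$peak_amp - f$baseline
  expect_equal(amp(fe) / amp(fs), 0.49, tolerance = 1e-3)
  expect_equal(fe$time_to_peak / fs$time_to_peak, 3.0, tolerance = 2e-3)
  expect_equal(amp(fu) / amp(fs), 1.17, tolerance = 1e-3)
  expect_equal(fu$time_to_peak / fs$time_to_peak, 1.45, tolerance = 2e-3)
  expect_equal(fs$peak_width / fe$peak_width, 1.475, tolerance = 5e-3)
  # UP time-to-peak rises as concentration falls: 52 / 69 / 129 min
  expect_equal(feat(up, 5)$time_to_peak, 52, tolerance = 1e-3)
  expect_equal(feat(up, 0.5)$time_to_peak, 69, tolerance = 1e-3)
  expect_equal(feat(up, 0.05)$time_to_peak, 129, tolerance = 1e-3)
})

test_that("preset loading validates names and applies overrides", {
  expect_error(preparation_preset("Invitrogen"), "available: Sigma, EB, UP")
  ov <- preparation_preset("Sigma",
                           overrides = list(dose = list(K = 0.5),
                                            pulse = list(amp = 2)))
  expect_equal(ov$dose$K, 0.5)
  expect_equal(ov$pulse$amp, 2)
  expect_equal(ov$dose$pmax, 0.95)  # untouched fields survive
  expect_setequal(list_presets(), c("Sigma", "EB", "UP"))
})

test_that("heterogeneity class mix must be a probability vector", {
  expect_error(heterogeneity_params(class_mix = c(transient = 0.7,
                                                  persistent = 0.7,
                                                  secondary = 0)),
               "sum to 1")
  expect_error(heterogeneity_params(cv_amp = -0.1), ">= 0")
})
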