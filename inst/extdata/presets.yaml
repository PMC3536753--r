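# Preparation presets for the single-cell NF-kB response model.
# schema_version 1.
#
# Units: times in minutes, concentrations in ug/mL, intensities are
# dimensionless normalized nuclear localization (nuclear mean / initial
# cytoplasmic mean). Central parameters encode the measured cross-
# preparation population statistics at the 0.5 ug/mL reference
# concentration: relative to Sigma, EB has 0.49x the amplitude, 3.0x the
# time-to-peak, and 1/1.475x the peak width; UP has 1.17x the amplitude
# and 1.45x the time-to-peak. The UP time-to-peak falls from 52 to 69 to
# 129 minutes at 5, 0.5, 0.05 ug/mL (log-linear in concentration between
# anchors, clamped outside). Dose-response curves are Hill-shaped and
# reproduce each preparation's potency window: Sigma near-maximal by
# 5e-4..5e-3 ug/mL, UP peaking only at 0.5-5 ug/mL and inert at the
# lowest doses, EB active even at the lowest dose simulated.
schema_version: 1
presets:
  Sigma:
    dose: {pmax: 0.95, K: 1.0e-4, h: 1.0}
    pulse:
      baseline: 1.0
      amp: 1.0
      tau: 47.5862069        # 69 / 1.45
      width: 89.975          # 1.475 x EB width
      plateau_amp: 0.15
      plateau_rise: 120
      secondary_amp_frac: 0.6
      secondary_delay: 180   # secondary onset = tau + delay
      secondary_rise: 45
    heterogeneity:
      cv_amp: 0.25
      cv_tau: 0.25
      cv_baseline: 0.05
      class_mix: {transient: 0.5, persistent: 0.5, secondary: 0.0}
    stnfr_modifier: {persistent_prob: 0.1, plateau_amp: 0.2}
  EB:
    dose: {pmax: 0.95, K: 1.0e-8, h: 0.7}
    pulse:
      baseline: 1.0
      amp: 0.49              # 51% lower-intensity activation than Sigma
      tau: 142.7586207       # 3.0 x Sigma tau
      width: 61.0
      plateau_amp: 0.15
      plateau_rise: 120
      secondary_amp_frac: 0.6
      secondary_delay: 180
      secondary_rise: 45
    heterogeneity:
      cv_amp: 0.25
      cv_tau: 0.25
      cv_baseline: 0.05
      class_mix: {transient: 0.35, persistent: 0.05, secondary: 0.6}
    stnfr_modifier: {persistent_prob: 0.1, plateau_amp: 0.2}
  UP:
    dose: {pmax: 0.95, K: 0.15, h: 1.2}
    pulse:
      baseline: 1.0
      amp: 1.17              # 17% higher than Sigma
      tau: 69.0              # 1.45 x Sigma tau, at the 0.5 ug/mL reference
      width: 61.0
      plateau_amp: 0.15
      plateau_rise: 120
      secondary_amp_frac: 0.6
      secondary_delay: 180
      secondary_rise: 45
      tau_anchors:
        conc: [5.0, 0.5, 0.05]
        tau: [52.0, 69.0, 129.0]
    heterogeneity:
      cv_amp: 0.25
      cv_tau: 0.25
      cv_baseline: 0.05
      class_mix: {transient: 0.8, persistent: 0.2, secondary: 0.0}
    stnfr_modifier: {persistent_prob: 0.1, plateau_amp: 0.2}
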