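#' Hill dose-response model of the fraction of responding cells
#'
#' @param pmax Maximal fraction of cells activated, in \[0, 1\].
#' @param K Half-activation concentration, ug/mL (> 0).
#' @param h Hill coefficient (> 0).
#' @return An object of class \code{"dose_model"}.
#' @export
dose_model <- function(pmax, K, h) {
  if (!is.finite(pmax) || pmax < 0 || pmax > 1)
    stop("dose_model: pmax must be in [0, 1]")
  if (!is.finite(K) || K <= 0) stop("dose_model: K must be > 0")
  if (!is.finite(h) || h <= 0) stop("dose_model: h must be > 0")
  structure(list(pmax = pmax, K = K, h = h), class = "dose_model")
}

#' Activation probability at a ligand concentration
#'
#' Hill activation curve \eqn{p(c) = p_{max} c^h / (c^h + K^h)};
#' monotone nondecreasing in concentration, \eqn{p(K) = p_{max}/2}, and
#' \eqn{p(0) = 0}.
#'
#' @param dose A [dose_model()] object.
#' @param conc Concentration(s), ug/mL (>= 0).
#' @return Probability vector, same length as \code{conc}.
#' @export
activation_probability <- function(dose, conc) {
  if (!inherits(dose, "dose_model"))
    stop("activation_probability: dose must be a dose_model")
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0))
    stop("activation_probability: conc must be finite and >= 0")
  ch <- conc^dose$h
  p <- dose$pmax * ch / (ch + dose$K^dose$h)
  p[conc == 0] <- 0
  p
}

#' Cell-to-cell heterogeneity parameters
#'
#' Lognormal coefficients of variation for per-cell perturbation of the
#' central amplitude, time-to-peak and baseline, and the mixture of
#' responder classes among active cells.
#'
#' @param cv_amp,cv_tau,cv_baseline Lognormal CVs (>= 0).
#' @param class_mix Named probabilities over \code{transient},
#'   \code{persistent}, \code{secondary}; must sum to 1.
#' @return An object of class \code{"heterogeneity_params"}.
#' @export
heterogeneity_params <- function(cv_amp = 0.25, cv_tau = 0.25,
                                 cv_baseline = 0.05,
                                 class_mix = c(transient = 0.5,
                                               persistent = 0.5,
                                               secondary = 0)) {
  cvs <- c(cv_amp, cv_tau, cv_baseline)
  if (any(!is.finite(cvs)) || any(cvs < 0))
    stop("heterogeneity_params: CVs must be finite and >= 0")
  cm <- unlist(class_mix)
  need <- c("transient", "persistent", "secondary")
  if (!all(need %in% names(cm)))
    stop("heterogeneity_params: class_mix needs transient/persistent/secondary")
  cm <- cm[need]
  if (any(cm < 0) || any(cm > 1) || abs(sum(cm) - 1) > 1e-8)
    stop("heterogeneity_params: class_mix entries must be in [0,1] and sum to 1")
  structure(list(cv_amp = cv_amp, cv_tau = cv_tau,
                 cv_baseline = cv_baseline, class_mix = cm),
            class = "heterogeneity_params")
}

preset_file_default <- function() {
  system.file("extdata", "presets.yaml", package = "nfkbtrace",
              mustWork = TRUE)
}

#' Names of the shipped preparation presets
#' @param file Optional path to an alternative preset YAML file.
#' @return Character vector of preset names.
#' @export
list_presets <- function(file = preset_file_default()) {
  names(yaml::read_yaml(file)$presets)
}

#' Load a lipopolysaccharide preparation preset
#'
#' A preset bundles, for one LPS preparation, (i) the Hill dose-response
#' of the fraction of responding cells, (ii) central single-cell pulse
#' parameters as a function of concentration, (iii) cell-to-cell
#' heterogeneity (lognormal CVs and responder-class mixture), and (iv)
#' the effect of soluble TNF receptor II (sTNFRII), which sequesters
#' secreted TNF and thereby suppresses persistent responses (modelled as
#' multiplicative factors on the persistent-class probability and the
#' plateau amplitude). The shipped presets (\code{"Sigma"}, \code{"EB"},
#' \code{"UP"}) encode the measured cross-preparation population
#' statistics; see the package vignette.
#'
#' Presets live in a human-readable YAML file
#' (\code{inst/extdata/presets.yaml}); any field can be overridden via
#' \code{overrides} (a nested list merged over the file entry).
#'
#' @param name Preset name (one of [list_presets()]).
#' @param file Optional path to an alternative preset YAML file.
#' @param overrides Nested list of fields to override.
#' @return An object of class \code{"preparation_preset"}.
#' @export
preparation_preset <- function(name, file = preset_file_default(),
                               overrides = NULL) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$presets[[name]]))
    stop(sprintf("preparation_preset: unknown preset '%s'; available: %s",
                 name, paste(names(cfg$presets), collapse = ", ")))
  p <- modify_list_deep(cfg$presets[[name]], overrides)
  dm <- dose_model(p$dose$pmax, p$dose$K, p$dose$h)
  het <- heterogeneity_params(p$heterogeneity$cv_amp,
                              p$heterogeneity$cv_tau,
                              p$heterogeneity$cv_baseline,
                              p$heterogeneity$class_mix)
  sm <- list(persistent_prob = p$stnfr_modifier$persistent_prob,
             plateau_amp = p$stnfr_modifier$plateau_amp)
  if (any(!is.finite(unlist(sm))) || any(unlist(sm) < 0))
    stop("preparation_preset: stnfr_modifier factors must be finite and >= 0")
  structure(list(name = name, dose = dm, pulse = p$pulse,
                 heterogeneity = het, stnfr_modifier = sm,
                 schema_version = cfg$schema_version),
            class = "preparation_preset")
}

modify_list_deep <- function(base, over) {
  if (is.null(over)) return(base)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_list_deep(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

# Central time-to-peak at a concentration: log-linear interpolation
# between tau anchors if the preset has them, otherwise the fixed tau.
central_tau <- function(preset, conc) {
  an <- preset$pulse$tau_anchors
  if (is.null(an)) return(preset$pulse$tau)
  lc <- log10(unlist(an$conc)); tv <- unlist(an$tau)
  o <- order(lc); lc <- lc[o]; tv <- tv[o]
  if (conc <= 0) return(tv[length(tv)])   # lowest dose -> slowest anchor
  stats::approx(lc, tv, xout = log10(conc), rule = 2)$y
}

#' Central (noise-free) pulse parameters of a preset at a concentration
#'
#' Returns the central [pulse_params()] a cell of the given responder
#' class draws around, before cell-to-cell lognormal perturbation. The
#' pulse shape is solved from the preset's stated peak width at half-max.
#'
#' @param preset A [preparation_preset()].
#' @param conc Concentration, ug/mL.
#' @param responder_class Responder class of the cell.
#' @param stnfr Logical; TNF blocking on (scales the plateau amplitude of
#'   persistent cells by the preset's modifier).
#' @return A [pulse_params()] object.
#' @export
central_pulse_params <- function(preset, conc,
                                 responder_class = "transient",
                                 stnfr = FALSE) {
  stopifnot(inherits(preset, "preparation_preset"))
  pu <- preset$pulse
  tau <- central_tau(preset, conc)
  s <- solve_shape_for_width(tau, pu$width)
  if (responder_class == "inactive")
    return(pulse_params(baseline = pu$baseline, amp = 0, tau = tau,
                        shape = s, responder_class = "inactive"))
  plat <- if (responder_class == "persistent") {
    pu$plateau_amp * if (stnfr) preset$stnfr_modifier$plateau_amp else 1
  } else 0
  sec <- if (responder_class == "secondary") pu$secondary_amp_frac * pu$amp else 0
  pulse_params(baseline = pu$baseline, amp = pu$amp, tau = tau, shape = s,
               plateau_amp = plat, plateau_rise = pu$plateau_rise,
               secondary_amp = sec, secondary_time = tau + pu$secondary_delay,
               secondary_rise = pu$secondary_rise,
               responder_class = responder_class)
}

#' @export
print.preparation_preset <- function(x, ...) {
  cat(sprintf("preparation_preset '%s'\n", x$name))
  cat(sprintf("  dose: pmax %.2f, K %.3g ug/mL, h %.2f\n",
              x$dose$pmax, x$dose$K, x$dose$h))
  cat(sprintf("  central pulse: amp %.3g, tau %.4g min, width %.4g min\n",
              x$pulse$amp, x$pulse$tau, x$pulse$width))
  cat(sprintf("  class mix: %s\n",
              paste(sprintf("%s %.2f", names(x$heterogeneity$class_mix),
                            x$heterogeneity$class_mix), collapse = ", ")))
  invisible(x)
}
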