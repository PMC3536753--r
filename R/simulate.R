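#' Imaging configuration for synthetic two-channel time-lapse movies
#'
#' Describes the simulated acquisition: 120 frames every 5 minutes with
#' the stimulus added after the third frame, mirroring the live-cell
#' setup the pipeline targets (a constitutive nuclear marker channel for
#' segmentation/tracking and a translocation reporter channel for
#' measurement). All intensities are in expected photons per pixel.
#'
#' @param n_frames Number of frames (>= 2). Default 120.
#' @param dt Frame interval, minutes (> 0). Default 5.
#' @param stim_frame 1-based index of the first post-stimulus frame;
#'   frames \code{1..(stim_frame-1)} are pre-stimulus. Default 4.
#' @param height,width Image size in pixels.
#' @param nucleus_axes Range (min, max) of nucleus semi-axes, pixels.
#' @param cyto_extent Width of the cytoplasmic shell beyond the nuclear
#'   boundary, pixels.
#' @param background Background level, photons.
#' @param photon_scale Pre-stimulus cytoplasmic reporter brightness,
#'   photons per pixel; sets the shot-noise scale.
#' @param nuclear_brightness Nuclear-marker brightness, photons.
#' @param read_noise_sd Gaussian read noise standard deviation, photons.
#' @param motion_sd Per-frame random-walk step standard deviation, pixels.
#' @param min_separation Minimum center-to-center distance between cells
#'   at placement, pixels (nuclei are adherent and do not
#'   interpenetrate); applied by [sample_population()].
#' @param shot_noise Logical; apply Poisson shot noise.
#' @param edge_width Anti-alias edge width of rasterized nuclei in pixels
#'   (0 = hard pixel-center rasterization, the default; the measurement
#'   model is then exact).
#' @return An object of class \code{"imaging_config"}.
#' @export
imaging_config <- function(n_frames = 120, dt = 5, stim_frame = 4,
                           height = 512, width = 512,
                           nucleus_axes = c(5, 7), cyto_extent = 8,
                           background = 20, photon_scale = 150,
                           nuclear_brightness = 300, read_noise_sd = 3,
                           motion_sd = 0.75, shot_noise = TRUE,
                           min_separation = 22,
                           edge_width = 0) {
  stopifnot(n_frames >= 2, dt > 0,
            stim_frame >= 2, stim_frame <= n_frames,
            height >= 16, width >= 16,
            length(nucleus_axes) == 2, all(nucleus_axes > 0),
            cyto_extent > 0, background >= 0, photon_scale > 0,
            nuclear_brightness > 0, read_noise_sd >= 0, motion_sd >= 0,
            min_separation >= 0, edge_width >= 0)
  if (2 * (max(nucleus_axes) + cyto_extent) + 2 > min(height, width))
    stop("imaging_config: image too small to fit a nucleus with its cytoplasm")
  structure(list(n_frames = n_frames, dt = dt, stim_frame = stim_frame,
                 height = height, width = width,
                 nucleus_axes = nucleus_axes, cyto_extent = cyto_extent,
                 background = background, photon_scale = photon_scale,
                 nuclear_brightness = nuclear_brightness,
                 read_noise_sd = read_noise_sd, motion_sd = motion_sd,
                 shot_noise = shot_noise, min_separation = min_separation,
                 edge_width = edge_width),
            class = "imaging_config")
}

#' Time grid of a movie configuration
#'
#' Frame times in minutes relative to stimulation (t = 0 at
#' \code{stim_frame}).
#' @param cfg An [imaging_config()].
#' @return Numeric vector of length \code{n_frames}.
#' @export
frame_times <- function(cfg) {
  (seq_len(cfg$n_frames) - cfg$stim_frame) * cfg$dt
}

# Mean-preserving lognormal multiplier: E[m] = 1, CV = cv.
lognormal_multiplier <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdl^2 / 2, sdl))
}

#' Sample one simulated cell from a preparation preset
#'
#' Draws activity (Bernoulli at the preset's Hill activation
#' probability), a responder class from the heterogeneity mixture (the
#' persistent-class probability is multiplied by the sTNFRII modifier
#' and renormalized when TNF blocking is on), lognormally perturbed
#' pulse parameters (mean-preserving, so population means match the
#' central parameters), nucleus geometry, and a reflected-random-walk
#' motion path. The ground-truth trace is evaluated on the movie time
#' grid and its features are computed with the same trace-feature
#' operations the analysis pipeline uses.
#'
#' @param preset A [preparation_preset()].
#' @param conc Concentration, ug/mL (>= 0).
#' @param stnfr Logical; soluble-TNF-receptor (TNF blocking) arm.
#' @param cfg An [imaging_config()].
#' @param seed Optional integer seed (reproducible draws).
#' @param cell_id Integer id for the cell.
#' @param start Optional starting centroid \code{c(row, col)}; drawn
#'   uniformly inside the field margin when NULL.
#' @return An object of class \code{"simulated_cell"}.
#' @export
sample_cell <- function(preset, conc, stnfr = FALSE,
                        cfg = imaging_config(), seed = NULL, cell_id = 1L,
                        start = NULL) {
  stopifnot(inherits(preset, "preparation_preset"), conc >= 0)
  if (!is.null(seed)) set.seed(seed)
  het <- preset$heterogeneity
  p_act <- activation_probability(preset$dose, conc)
  active <- stats::runif(1) < p_act
  if (active) {
    mix <- het$class_mix
    if (stnfr) {
      mix["persistent"] <- mix["persistent"] * preset$stnfr_modifier$persistent_prob
      mix <- mix / sum(mix)
    }
    cls <- sample(names(mix), 1, prob = mix)
  } else cls <- "inactive"

  central <- central_pulse_params(preset, conc, cls, stnfr)
  m_amp <- lognormal_multiplier(1, het$cv_amp)
  m_tau <- lognormal_multiplier(1, het$cv_tau)
  m_b <- lognormal_multiplier(1, het$cv_baseline)
  params <- pulse_params(
    baseline = central$baseline * m_b,
    amp = central$amp * m_amp,
    tau = central$tau * m_tau,
    shape = central$shape,
    plateau_amp = central$plateau_amp * m_amp,
    plateau_rise = central$plateau_rise,
    secondary_amp = central$secondary_amp * m_amp,
    secondary_time = central$tau * m_tau + preset$pulse$secondary_delay,
    secondary_rise = central$secondary_rise,
    responder_class = cls)

  ax <- sort(stats::runif(2, cfg$nucleus_axes[1], cfg$nucleus_axes[2]),
             decreasing = TRUE)
  angle <- stats::runif(1, 0, pi)
  margin <- max(ax) + cfg$cyto_extent + 1
  if (is.null(start))
    start <- c(stats::runif(1, margin, cfg$height - margin),
               stats::runif(1, margin, cfg$width - margin))
  steps <- matrix(stats::rnorm(2 * cfg$n_frames, 0, cfg$motion_sd),
                  ncol = 2)
  steps[1, ] <- 0
  path <- apply(steps, 2, cumsum)
  path[, 1] <- reflect_into(start[1] + path[, 1], margin, cfg$height - margin)
  path[, 2] <- reflect_into(start[2] + path[, 2], margin, cfg$width - margin)
  colnames(path) <- c("row", "col")

  tt <- frame_times(cfg)
  trace <- new_trace(cell_id, tt, pulse_value(params, tt))
  feats <- peak_features(trace)
  feats$active <- classify_active(trace)
  feats$n_secondary <- if (feats$active) count_secondary_peaks(trace) else 0L

  structure(list(cell_id = cell_id, responder_class = cls, active = active,
                 params = params, true_trace = trace, true_features = feats,
                 path = path, semi_axes = ax, angle = angle),
            class = "simulated_cell")
}

# Reflect coordinates into [lo, hi].
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  lo + y
}

#' Sample a population of cells
#'
#' Cells are placed by dart throwing: starting positions keep at least
#' \code{cfg$min_separation} pixels between centers (up to 200 redraws
#' per cell, after which the last candidate is accepted so crowded
#' configurations still complete).
#'
#' @inheritParams sample_cell
#' @param n_cells Number of cells (>= 1).
#' @return List of [sample_cell()] results with ids \code{1..n_cells}.
#' @export
sample_population <- function(preset, conc, stnfr = FALSE, n_cells = 60,
                              cfg = imaging_config(), seed = NULL) {
  stopifnot(n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  margin <- max(cfg$nucleus_axes) + cfg$cyto_extent + 1
  placed <- matrix(numeric(0), ncol = 2)
  lapply(seq_len(n_cells), function(i) {
    for (try in seq_len(200)) {
      cand <- c(stats::runif(1, margin, cfg$height - margin),
                stats::runif(1, margin, cfg$width - margin))
      if (!nrow(placed)) break
      d2 <- (placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2
      if (min(d2) >= cfg$min_separation^2) break
    }
    placed <<- rbind(placed, cand)
    sample_cell(preset, conc, stnfr, cfg, seed = NULL, cell_id = i,
                start = cand)
  })
}
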