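# Rasterize one cell at one frame: nucleus and cytoplasm pixel indices
# within the image. Pixels are classified at their centers (1-based
# row/col). With edge_width > 0 the nucleus gets a linear anti-alias
# coverage ramp of that width (in pixels) across the boundary; coverage
# is returned alongside the indices.
rasterize_cell <- function(center, semi_axes, angle, cyto_extent,
                           height, width, edge_width = 0) {
  a <- semi_axes[1]; b <- semi_axes[2]
  rmax <- ceiling(max(a, b) + cyto_extent + edge_width + 1)
  r0 <- max(1, floor(center[1] - rmax)); r1 <- min(height, ceiling(center[1] + rmax))
  c0 <- max(1, floor(center[2] - rmax)); c1 <- min(width, ceiling(center[2] + rmax))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - center[1]; dx <- cols - center[2]
  DY <- matrix(dy, length(rows), length(cols))
  DX <- matrix(dx, length(rows), length(cols), byrow = TRUE)
  ca <- cos(angle); sa <- sin(angle)
  u <- DY * ca + DX * sa
  v <- -DY * sa + DX * ca
  rn <- sqrt((u / a)^2 + (v / b)^2)                 # normalized nucleus radius
  rc <- sqrt((u / (a + cyto_extent))^2 + (v / (b + cyto_extent))^2)
  if (edge_width > 0) {
    ew <- edge_width / min(a, b)                    # edge width in normalized units
    cov <- pmin(1, pmax(0, (1 + ew / 2 - rn) / ew))
  } else cov <- as.numeric(rn <= 1)
  nuc <- which(cov > 0)
  cyt <- which(rc <= 1 & cov < 1)
  idx <- function(k) {
    rr <- rows[(k - 1) %% length(rows) + 1]
    cc <- cols[(k - 1) %/% length(rows) + 1]
    (cc - 1) * height + rr                           # linear index into H x W
  }
  list(nuc = idx(nuc), nuc_cov = cov[nuc],
       cyto = idx(cyt), cyto_cov = 1 - cov[cyt])
}

#' Render a cell population into a two-channel time-lapse movie
#'
#' The nuclear-marker channel paints each nucleus at constant
#' brightness; the reporter channel redistributes a conserved amount of
#' reporter between nucleus and cytoplasm so that, per cell, the nuclear
#' mean divided by the pre-stimulus cytoplasmic mean equals the cell's
#' ground-truth trace at every frame, and nuclear + cytoplasmic totals
#' stay constant over time. Poisson shot noise (at the photon scale) and
#' Gaussian read noise are then applied, and intensities are quantized
#' to 1/16 photon (ceiling 4095.94) so movies survive 16-bit TIFF
#' round trips losslessly.
#'
#' @param cells List of [sample_cell()] objects.
#' @param cfg An [imaging_config()].
#' @return List with \code{movie} (class \code{"nt_movie"}: stack array
#'   \code{[height, width, 2, n_frames]} with channel 1 = nuclear
#'   marker, channel 2 = reporter, plus metadata) and \code{truth}
#'   (class \code{"nt_ground_truth"}: per-frame true label images, the
#'   cells, and an overlap flag).
#' @export
render_movie <- function(cells, cfg) {
  stopifnot(length(cells) >= 1, inherits(cfg, "imaging_config"))
  H <- cfg$height; W <- cfg$width; TT <- cfg$n_frames
  C0 <- cfg$photon_scale
  stack <- array(0, c(H, W, 2, TT))
  labels <- array(0L, c(H, W, TT))
  overlap <- FALSE
  r_tot <- rep(NA_real_, length(cells))
  # frame-major rendering keeps every temporary at single-frame size
  for (f in seq_len(TT)) {
    nuc_f <- matrix(0, H, W)
    rep_f <- matrix(0, H, W)
    lab_f <- matrix(0L, H, W)
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      r <- rasterize_cell(cell$path[f, ], cell$semi_axes, cell$angle,
                          cfg$cyto_extent, H, W, cfg$edge_width)
      a_n <- sum(r$nuc_cov); a_c <- sum(r$cyto_cov)
      if (f == 1) {
        if (a_n < 1 || a_c < 1)
          stop("render_movie: geometry cannot fit a nucleus with cytoplasm")
        r_tot[ci] <- cell$params$baseline * C0 * a_n + C0 * a_c
      }
      n_f <- cell$true_trace$intensity[f] * C0
      c_f <- max(0, (r_tot[ci] - n_f * a_n) / a_c)
      rep_f[r$nuc] <- rep_f[r$nuc] + n_f * r$nuc_cov
      rep_f[r$cyto] <- rep_f[r$cyto] + c_f * r$cyto_cov
      nuc_f[r$nuc] <- nuc_f[r$nuc] + cfg$nuclear_brightness * r$nuc_cov
      solid <- r$nuc[r$nuc_cov >= 0.5]
      prev <- lab_f[solid]
      if (any(prev != 0 & prev != ci)) overlap <- TRUE
      lab_f[solid] <- ci
    }
    nuc_f <- nuc_f + cfg$background
    rep_f <- rep_f + cfg$background
    if (cfg$shot_noise) {
      nuc_f[] <- stats::rpois(length(nuc_f), nuc_f)
      rep_f[] <- stats::rpois(length(rep_f), rep_f)
    }
    if (cfg$read_noise_sd > 0) {
      nuc_f <- nuc_f + stats::rnorm(length(nuc_f), 0, cfg$read_noise_sd)
      rep_f <- rep_f + stats::rnorm(length(rep_f), 0, cfg$read_noise_sd)
    }
    stack[, , 1, f] <- quantize_photons(nuc_f)
    stack[, , 2, f] <- quantize_photons(rep_f)
    labels[, , f] <- lab_f
  }
  movie <- structure(list(stack = stack, dt = as.numeric(cfg$dt),
                          stim_frame = as.integer(cfg$stim_frame),
                          channels = c("nuclear_marker", "reporter"),
                          meta = list()),
                     class = "nt_movie")
  truth <- structure(list(labels = labels, cells = cells,
                          overlap = overlap, cfg = cfg),
                     class = "nt_ground_truth")
  list(movie = movie, truth = truth)
}

# Quantize to 1/16 photon on [0, 4095.9375]: exactly representable in
# the 16-bit TIFF encoding used by write_movie.
quantize_photons <- function(x) {
  x <- round(x * 16) / 16
  x[x < 0] <- 0
  x[x > 65535 / 16] <- 65535 / 16
  x
}

#' @export
print.nt_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("nt_movie: %d frames, %d x %d px, channels %s, dt %g min, stim frame %d\n",
              d[4], d[1], d[2], paste(x$channels, collapse = "/"),
              x$dt, x$stim_frame))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Simulate one experimental condition end to end
#'
#' Samples a cell population for (preset, concentration, sTNFRII arm)
#' and renders it into a noisy two-channel movie with ground truth.
#' Deterministic for a given seed.
#'
#' @inheritParams sample_population
#' @param seed Integer seed controlling all randomness of the condition.
#' @return As [render_movie()], with condition metadata attached to the
#'   movie.
#' @export
simulate_condition <- function(preset, conc, stnfr = FALSE, n_cells = 60,
                               cfg = imaging_config(), seed = 1) {
  set.seed(seed)
  cells <- sample_population(preset, conc, stnfr, n_cells, cfg, seed = NULL)
  out <- render_movie(cells, cfg)
  out$movie$meta <- list(preset = preset$name, conc = conc, stnfr = stnfr,
                         n_cells = n_cells, seed = seed)
  out
}
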