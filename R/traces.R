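#' Construct a normalized nuclear-localization trace
#'
#' A trace is the per-cell time course of relative nuclear localization:
#' mean nuclear reporter intensity divided by the cell's pre-stimulus
#' cytoplasmic mean (dimensionless). Times are minutes relative to
#' stimulation at t = 0; frames where the cell's track has a gap are
#' flagged invalid.
#'
#' @param id Cell/track identifier.
#' @param time Strictly increasing numeric time grid (minutes); must
#'   include at least one pre-stimulus point (t < 0).
#' @param intensity Normalized intensity values.
#' @param valid Logical validity flags (default all valid).
#' @return An object of class \code{"nt_trace"}.
#' @export
new_trace <- function(id, time, intensity, valid = rep(TRUE, length(time))) {
  stopifnot(length(time) == length(intensity),
            length(valid) == length(time))
  if (any(diff(time) <= 0)) stop("new_trace: time grid must be strictly increasing")
  if (!any(time < 0)) stop("new_trace: at least one pre-stimulus frame required")
  valid <- valid & is.finite(intensity)
  structure(list(id = id, time = time, intensity = intensity, valid = valid),
            class = "nt_trace")
}

#' @export
print.nt_trace <- function(x, ...) {
  cat(sprintf("nt_trace id %s: %d frames (%d valid), t in [%g, %g] min\n",
              format(x$id), length(x$time), sum(x$valid),
              min(x$time), max(x$time)))
  invisible(x)
}

#' @export
plot.nt_trace <- function(x, ...) {
  plot(x$time[x$valid], x$intensity[x$valid], type = "l",
       xlab = "time since stimulation (min)",
       ylab = "nuclear / pre-stimulus cytoplasmic mean", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

trace_baseline <- function(trace) {
  pre <- trace$time < 0 & trace$valid
  if (!any(pre)) stop("trace has no valid pre-stimulus frames")
  mean(trace$intensity[pre])
}

#' Classify a cell as active
#'
#' Automated surrogate for visual activity curation: a cell is active
#' when its normalized nuclear localization stays at least \code{theta}
#' above its pre-stimulus baseline for \code{m} consecutive valid
#' post-stimulus frames (the nucleus is sustainedly brighter than before
#' stimulation).
#'
#' @param trace An [new_trace()] object.
#' @param theta Intensity threshold above baseline (default 0.2).
#' @param m Required consecutive frames (default 3).
#' @return Logical flag.
#' @export
classify_active <- function(trace, theta = 0.2, m = 3) {
  stopifnot(inherits(trace, "nt_trace"), theta >= 0, m >= 1)
  base <- trace_baseline(trace)
  post <- trace$time >= 0
  hit <- (trace$intensity >= base + theta) & trace$valid & post
  hit[!trace$valid & post] <- NA          # gaps break a run
  run <- 0
  for (v in hit[post]) {
    if (isTRUE(v)) {
      run <- run + 1
      if (run >= m) return(TRUE)
    } else run <- 0
  }
  FALSE
}

#' Per-cell peak statistics of a trace
#'
#' Computes the per-cell summary statistics of a nuclear-localization
#' time course: \code{peak_amp}, the maximum normalized intensity over
#' valid post-stimulus frames; \code{time_to_peak}, minutes from
#' stimulation to that maximum (first occurrence on ties);
#' \code{peak_width}, the duration around the peak during which the
#' linearly interpolated trace exceeds the level halfway between the
#' post-stimulus minimum and maximum (boundary crossings located by
#' linear interpolation); and \code{baseline}, the pre-stimulus mean.
#' If the trace never falls back below the half level after the peak,
#' the width is right-censored at the last valid frame and flagged.
#'
#' @param trace An [new_trace()] object with >= 2 valid post-stimulus
#'   frames.
#' @return An object of class \code{"trace_features"}: a list with
#'   \code{active} (NA here; see [classify_active()]), \code{peak_amp},
#'   \code{time_to_peak}, \code{peak_width}, \code{width_censored},
#'   \code{n_secondary} (NA here; see [count_secondary_peaks()]) and
#'   \code{baseline}.
#' @export
peak_features <- function(trace) {
  stopifnot(inherits(trace, "nt_trace"))
  ok <- trace$valid & trace$time >= 0
  if (sum(ok) < 2) stop("peak_features: need >= 2 valid post-stimulus frames")
  tt <- trace$time[ok]; vv <- trace$intensity[ok]
  n <- length(vv)
  imax <- which.max(vv)                  # first occurrence on ties
  peak <- vv[imax]
  half <- (min(vv) + peak) / 2
  # walk outwards from the peak to the half-level crossings
  j <- imax
  while (j > 1 && vv[j - 1] >= half) j <- j - 1
  left <- if (j > 1) {
    tt[j - 1] + (tt[j] - tt[j - 1]) * (half - vv[j - 1]) / (vv[j] - vv[j - 1])
  } else tt[1]
  j <- imax
  while (j < n && vv[j + 1] >= half) j <- j + 1
  censored <- j == n
  right <- if (!censored) {
    tt[j] + (tt[j + 1] - tt[j]) * (half - vv[j]) / (vv[j + 1] - vv[j])
  } else tt[n]
  structure(list(active = NA, peak_amp = peak, time_to_peak = tt[imax],
                 peak_width = right - left, width_censored = censored,
                 half_level = half, n_secondary = NA,
                 baseline = trace_baseline(trace)),
            class = "trace_features")
}

#' @export
print.trace_features <- function(x, ...) {
  cat(sprintf(
    "trace_features: peak_amp %.3f, time_to_peak %.1f min, width %.1f min%s, baseline %.3f\n",
    x$peak_amp, x$time_to_peak, x$peak_width,
    if (isTRUE(x$width_censored)) " (right-censored)" else "", x$baseline))
  invisible(x)
}

#' Count secondary activations in a trace
#'
#' Counts local maxima lying outside the primary peak's half-max
#' interval whose prominence (height above the lowest valley separating
#' them from the primary peak) is at least \code{rho} times the primary
#' amplitude above baseline, and whose time is at least
#' \code{min_separation} minutes from the primary peak.
#'
#' @param trace An [new_trace()] object (an active cell).
#' @param rho Relative prominence threshold (default 0.5).
#' @param min_separation Minimum separation from the primary peak,
#'   minutes (default 60).
#' @return Integer count (>= 0).
#' @export
count_secondary_peaks <- function(trace, rho = 0.5, min_separation = 60) {
  stopifnot(inherits(trace, "nt_trace"), rho > 0, min_separation >= 0)
  pf <- peak_features(trace)
  ok <- trace$valid & trace$time >= 0
  tt <- trace$time[ok]; vv <- trace$intensity[ok]
  n <- length(vv)
  if (n < 3) return(0L)
  imax <- which.max(vv)
  left <- pf$time_to_peak - pf$peak_width   # conservative window bounds
  is_max <- c(FALSE, vv[2:(n - 1)] > vv[1:(n - 2)] &
                vv[2:(n - 1)] >= vv[3:n], FALSE)
  thresh <- rho * (pf$peak_amp - pf$baseline)
  cnt <- 0L
  for (i in which(is_max)) {
    if (i == imax) next
    sep <- abs(tt[i] - pf$time_to_peak)
    if (sep < min_separation) next
    inside <- tt[i] >= pf$time_to_peak - pf$peak_width &&
      tt[i] <= pf$time_to_peak + pf$peak_width
    if (inside) next
    valley <- if (i < imax) min(vv[i:imax]) else min(vv[imax:i])
    if (vv[i] - valley >= thresh) cnt <- cnt + 1L
  }
  cnt
}

#' Extract a single cell's normalized trace from a movie
#'
#' Implements the measurement model of the reporter channel: at each
#' frame where the track has a segmented nucleus, the trace value is the
#' mean reporter intensity over the cell's nuclear pixels divided by its
#' mean reporter intensity over the cytoplasmic-ring pixels averaged
#' across all pre-stimulus frames; the background level is subtracted
#' from both before division. Gap frames are flagged invalid.
#'
#' @param reporter 3-D array (height x width x frames): reporter channel.
#' @param track A track as returned by [link_tracks()].
#' @param labels Integer label array (height x width x frames): nuclei.
#' @param rings Integer label array of the cytoplasmic rings, same label
#'   ids as \code{labels} per frame.
#' @param stim_frame 1-based first post-stimulus frame.
#' @param dt Frame interval, minutes.
#' @param background Background level (photons) subtracted before
#'   normalization; a constant, or NULL to estimate it as the median of
#'   the four 8x8 image corners of the first frame.
#' @return An [new_trace()] object, or NULL (with a message attribute
#'   logged via a warning) if the cell has no usable pre-stimulus
#'   cytoplasm.
#' @export
extract_trace <- function(reporter, track, labels, rings, stim_frame, dt,
                          background = NULL) {
  n_frames <- dim(reporter)[3]
  if (is.null(background)) background <- corner_background(reporter[, , 1])
  nucmean <- rep(NA_real_, n_frames)
  ringmean <- rep(NA_real_, n_frames)
  for (f in seq_len(n_frames)) {
    lbl <- track$label[f]
    if (is.na(lbl)) next
    frm <- reporter[, , f]
    nm <- frm[labels[, , f] == lbl]
    rm_ <- frm[rings[, , f] == lbl]
    if (length(nm)) nucmean[f] <- mean(nm)
    if (length(rm_)) ringmean[f] <- mean(rm_)
  }
  pre <- seq_len(stim_frame - 1)
  cpre <- mean(ringmean[pre], na.rm = TRUE) - background
  if (!is.finite(cpre) || cpre <= 0) {
    warning(sprintf("track %s: no valid pre-stimulus cytoplasm; cell excluded",
                    format(track$track_id)))
    return(NULL)
  }
  tt <- (seq_len(n_frames) - stim_frame) * dt
  inten <- (nucmean - background) / cpre
  new_trace(track$track_id, tt, inten, valid = !is.na(nucmean))
}

# NA out everything after the first run of more than max_run
# consecutive NAs (identity cannot be guaranteed across long episodes).
truncate_after_run <- function(x, max_run) {
  if (!is.finite(max_run)) return(x)
  bad <- is.na(x)
  run <- 0
  for (f in seq_along(x)) {
    if (bad[f]) {
      run <- run + 1
      if (run > max_run) {
        if (f < length(x)) x[(f + 1):length(x)] <- NA
        return(x)
      }
    } else run <- 0
  }
  x
}

corner_background <- function(frame, k = 8) {
  h <- nrow(frame); w <- ncol(frame)
  stats::median(c(frame[1:k, 1:k], frame[1:k, (w - k + 1):w],
                  frame[(h - k + 1):h, 1:k],
                  frame[(h - k + 1):h, (w - k + 1):w]))
}

#' Extract traces for all tracks of a movie (batch)
#'
#' Batch equivalent of [extract_trace()] using per-frame label-wise
#' aggregation; identical results, one pass per frame.
#'
#' @param reporter The reporter channel: a 3-D array or an
#'   \code{"nt_movie"} (channel 2 is used, sliced per frame).
#' @param labels,rings As in [extract_trace()].
#' @param tracks List of tracks from [link_tracks()].
#' @param excluded Optional per-frame list of label ids whose
#'   measurements are invalid at that frame (e.g. proximity quality
#'   control: see [proximity_exclusions()]); such frames are treated as
#'   gaps.
#' @param max_invalid_run Identity guard: after the first run of more
#'   than this many consecutive invalid frames (a long close-encounter
#'   or detection-loss episode, across which track identity cannot be
#'   guaranteed), all later frames of the track are discarded. Set to
#'   \code{Inf} to disable.
#' @inheritParams extract_trace
#' @return Named list of [new_trace()] objects (tracks without usable
#'   pre-stimulus cytoplasm are dropped; their ids are in
#'   \code{attr(, "excluded")}).
#' @export
extract_traces <- function(reporter, tracks, labels, rings, stim_frame, dt,
                           background = NULL, excluded = NULL,
                           max_invalid_run = 2) {
  get_frame <- frame_accessor(reporter, 2)
  n_frames <- frame_dims(reporter)[3]
  if (is.null(background)) background <- corner_background(get_frame(1))
  # per-frame mean intensity per label, for nuclei and rings
  nuc_by <- vector("list", n_frames); ring_by <- vector("list", n_frames)
  label_means <- function(frm, lv) {
    nz <- lv > 0
    s <- rowsum(cbind(frm[nz], 1), lv[nz])
    stats::setNames(s[, 1] / s[, 2], rownames(s))
  }
  for (f in seq_len(n_frames)) {
    frm <- as.vector(get_frame(f))
    nuc_by[[f]] <- label_means(frm, as.vector(labels[, , f]))
    ring_by[[f]] <- label_means(frm, as.vector(rings[, , f]))
  }
  tt <- (seq_len(n_frames) - stim_frame) * dt
  pre <- seq_len(stim_frame - 1)
  out <- list(); dropped <- character()
  for (tr in tracks) {
    nucmean <- rep(NA_real_, n_frames); ringmean <- rep(NA_real_, n_frames)
    for (f in seq_len(n_frames)) {
      lbl <- tr$label[f]
      if (is.na(lbl)) next
      if (!is.null(excluded) && lbl %in% excluded[[f]]) next
      key <- as.character(lbl)
      nucmean[f] <- nuc_by[[f]][key]
      ringmean[f] <- ring_by[[f]][key]
    }
    nucmean <- truncate_after_run(nucmean, max_invalid_run)
    ringmean[is.na(nucmean)] <- NA
    cpre <- mean(ringmean[pre], na.rm = TRUE) - background
    if (!is.finite(cpre) || cpre <= 0) {
      dropped <- c(dropped, as.character(tr$track_id))
      next
    }
    out[[as.character(tr$track_id)]] <-
      new_trace(tr$track_id, tt, (nucmean - background) / cpre,
                valid = !is.na(nucmean))
  }
  attr(out, "excluded") <- dropped
  out
}

#' Feature table for a set of traces
#'
#' Applies [classify_active()], [peak_features()] and
#' [count_secondary_peaks()] to each trace and assembles one row per
#' cell.
#'
#' @param traces List of [new_trace()] objects.
#' @param theta,m Activity-classification parameters.
#' @param rho,min_separation Secondary-peak parameters.
#' @return data.frame with columns \code{id, active, peak_amp,
#'   time_to_peak, peak_width, width_censored, n_secondary, baseline}.
#' @export
trace_features_table <- function(traces, theta = 0.2, m = 3, rho = 0.5,
                                 min_separation = 60) {
  rows <- lapply(traces, function(tr) {
    ft <- tryCatch(peak_features(tr), error = function(e) NULL)
    if (is.null(ft)) return(NULL)
    act <- classify_active(tr, theta, m)
    data.frame(id = as.character(tr$id), active = act,
               peak_amp = ft$peak_amp, time_to_peak = ft$time_to_peak,
               peak_width = ft$peak_width,
               width_censored = ft$width_censored,
               n_secondary = if (act) count_secondary_peaks(tr, rho, min_separation) else 0L,
               baseline = ft$baseline, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
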