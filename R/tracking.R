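#' Link segmented nuclei across frames into single-cell tracks
#'
#' Greedy nearest-centroid linking: at each frame, (track, region)
#' pairs are assigned in ascending order of centroid distance (mutual
#' exclusivity enforced by removal after each assignment), rejecting
#' pairs farther than \code{max_disp}. Unmatched tracks survive up to
#' \code{max_gap} missed frames and then terminate; unmatched regions
#' start new tracks. Deterministic: distance ties are broken by smaller
#' region label, then smaller track id.
#'
#' @param stack An \code{"nt_label_stack"} from [segment_movie()], or a
#'   list of per-frame region tables.
#' @param max_disp Maximum linking displacement, pixels.
#' @param max_gap Maximum tolerated gap, frames (0 = none).
#' @return List of tracks, each of class \code{"nt_track"}: list with
#'   \code{track_id}, \code{label} (per-frame label or NA), \code{row},
#'   \code{col} (per-frame centroid or NA), \code{start}, \code{end}.
#' @export
link_tracks <- function(stack, max_disp = 10, max_gap = 2) {
  regions <- if (inherits(stack, "nt_label_stack")) stack$regions else stack
  stopifnot(length(regions) >= 1, max_disp > 0, max_gap >= 0)
  TT <- length(regions)
  tracks <- list()          # finished + live; each has state fields
  live <- integer()         # indices into tracks
  next_id <- 1L
  for (f in seq_len(TT)) {
    reg <- regions[[f]]
    nr <- if (is.null(reg)) 0L else nrow(reg)
    assigned_reg <- rep(FALSE, nr)
    if (length(live) && nr) {
      tr_row <- vapply(tracks[live], function(t) t$last_row, 0)
      tr_col <- vapply(tracks[live], function(t) t$last_col, 0)
      D <- sqrt(outer(tr_row, reg$row, "-")^2 + outer(tr_col, reg$col, "-")^2)
      free_t <- rep(TRUE, length(live))
      repeat {
        Dm <- D
        Dm[!free_t, ] <- Inf; Dm[, assigned_reg] <- Inf
        if (all(!is.finite(Dm))) break
        dmin <- min(Dm)
        if (dmin > max_disp) break
        hits <- which(Dm == dmin, arr.ind = TRUE)
        # ties: smaller region label, then smaller track id
        hits <- hits[order(reg$label[hits[, 2]],
                           vapply(tracks[live[hits[, 1]]],
                                  function(t) t$track_id, 0L)), , drop = FALSE]
        ti <- hits[1, 1]; rj <- hits[1, 2]
        k <- live[ti]
        tracks[[k]]$label[f] <- reg$label[rj]
        tracks[[k]]$row[f] <- reg$row[rj]
        tracks[[k]]$col[f] <- reg$col[rj]
        tracks[[k]]$last_row <- reg$row[rj]
        tracks[[k]]$last_col <- reg$col[rj]
        tracks[[k]]$last_frame <- f
        tracks[[k]]$end <- f
        free_t[ti] <- FALSE; assigned_reg[rj] <- TRUE
      }
    }
    # terminate tracks that exceeded the gap allowance
    if (length(live))
      live <- live[vapply(tracks[live],
                          function(t) f - t$last_frame <= max_gap, TRUE)]
    # new tracks for unmatched regions (ascending label order)
    if (nr) for (rj in which(!assigned_reg)) {
      tr <- list(track_id = next_id,
                 label = rep(NA_integer_, TT),
                 row = rep(NA_real_, TT), col = rep(NA_real_, TT),
                 start = f, end = f,
                 last_row = reg$row[rj], last_col = reg$col[rj],
                 last_frame = f)
      tr$label[f] <- reg$label[rj]
      tr$row[f] <- reg$row[rj]; tr$col[f] <- reg$col[rj]
      tracks[[length(tracks) + 1L]] <- structure(tr, class = "nt_track")
      live <- c(live, length(tracks))
      next_id <- next_id + 1L
    }
  }
  lapply(tracks, function(t) {
    t$last_row <- t$last_col <- t$last_frame <- NULL
    t
  })
}

#' @export
print.nt_track <- function(x, ...) {
  cat(sprintf("nt_track %d: frames %d-%d, %d observed\n",
              x$track_id, x$start, x$end, sum(!is.na(x$label))))
  invisible(x)
}

#' Tracks as a tidy data.frame
#'
#' @param tracks List of tracks from [link_tracks()].
#' @return data.frame with columns \code{track_id, frame, label, row,
#'   col} (observed frames only).
#' @export
tracks_to_df <- function(tracks) {
  do.call(rbind, lapply(tracks, function(t) {
    obs <- which(!is.na(t$label))
    data.frame(track_id = t$track_id, frame = obs, label = t$label[obs],
               row = t$row[obs], col = t$col[obs])
  }))
}
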