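# Shared test helpers: small imaging configurations, dense-grid oracles
# and ground-truth matching utilities.

tiny_cfg <- function(...) {
  imaging_config(n_frames = 20, height = 96, width = 96, ...)
}

# Dense-grid oracle for the width of the region where f(t) > level.
grid_width_above <- function(f, level, t_max = 2000, dt = 0.01) {
  tt <- seq(0, t_max, by = dt)
  above <- f(tt) > level
  sum(above) * dt
}

# Greedy IoU matching of predicted labels against true labels.
# Returns data.frame(true, pred, iou), best match per true label.
match_labels_iou <- function(true_lab, pred_lab) {
  tr_ids <- setdiff(unique(as.vector(true_lab)), 0)
  out <- lapply(tr_ids, function(ti) {
    tmask <- true_lab == ti
    cand <- setdiff(unique(pred_lab[tmask]), 0)
    if (!length(cand)) return(data.frame(true = ti, pred = NA, iou = 0))
    ious <- vapply(cand, function(pi) {
      pmask <- pred_lab == pi
      sum(tmask & pmask) / sum(tmask | pmask)
    }, 0)
    data.frame(true = ti, pred = cand[which.max(ious)], iou = max(ious))
  })
  do.call(rbind, out)
}

# Match each track to the ground-truth cell with nearest mean path
# distance over the track's observed frames.
match_track_to_cell <- function(track, cells) {
  obs <- which(!is.na(track$row))
  d <- vapply(cells, function(cl)
    mean(sqrt((cl$path[obs, 1] - track$row[obs])^2 +
                (cl$path[obs, 2] - track$col[obs])^2)), 0)
  which.min(d)
}

# Track purity: fraction of observations whose nearest true cell (by
# per-frame centroid distance) equals the track's majority assignment.
track_purity <- function(tracks, cells) {
  hits <- 0; total <- 0
  for (tr in tracks) {
    obs <- which(!is.na(tr$row))
    near <- vapply(obs, function(f) {
      d <- vapply(cells, function(cl)
        sqrt((cl$path[f, 1] - tr$row[f])^2 + (cl$path[f, 2] - tr$col[f])^2), 0)
      which.min(d)
    }, 0L)
    maj <- as.integer(names(which.max(table(near))))
    hits <- hits + sum(near == maj)
    total <- total + length(near)
  }
  hits / total
}

# Per-cell recovery/error table for one simulated + analyzed movie.
recovery_table <- function(sim, res, theta = 0.2, m = 3) {
  ft <- trace_features_table(res$traces, theta = theta, m = m)
  rows <- lapply(seq_len(nrow(ft)), function(i) {
    tr <- res$tracks[[as.integer(ft$id[i])]]
    cl <- sim$truth$cells[[match_track_to_cell(tr, sim$truth$cells)]]
    data.frame(cell = cl$cell_id, true_active = cl$active,
               est_active = ft$active[i],
               true_amp = cl$true_features$peak_amp,
               est_amp = ft$peak_amp[i],
               true_ttp = cl$true_features$time_to_peak,
               est_ttp = ft$time_to_peak[i],
               true_width = cl$true_features$peak_width,
               est_width = ft$peak_width[i])
  })
  do.call(rbind, rows)
}
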