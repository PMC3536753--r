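`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic expansion of one global seed into per-(condition, movie)
# seeds: a small string hash of the condition key mixed with the global
# seed, kept below 2^31. Adding conditions never shifts the seeds of
# existing ones.
condition_seed <- function(global_seed, preset, conc, stnfr, movie) {
  key <- sprintf("%s|%.12g|%d|%d", preset, conc, as.integer(stnfr),
                 as.integer(movie))
  h <- 0
  for (k in utf8ToInt(key)) h <- (h * 131 + k) %% 1987654321
  as.integer((h + as.numeric(global_seed) * 7654321) %% 2147483647L)
}

#' Pipeline configuration
#'
#' Declares the full simulated experiment: which preparation presets to
#' run, the concentration grid (default nine decades), whether to run
#' the TNF-blocking arm, movies per condition and cells per movie, the
#' global seed, and the per-stage parameter blocks.
#'
#' @param presets Character vector of preset names.
#' @param concentrations Concentration grid, ug/mL.
#' @param stnfr_arms Logical vector of sTNFRII arms to run.
#' @param n_cells Cells per movie.
#' @param movies_per_condition Replicate movies per condition.
#' @param seed Global integer seed; expanded deterministically into
#'   per-condition, per-movie seeds.
#' @param imaging Named list of [imaging_config()] overrides.
#' @param segmentation Named list: \code{sigma, threshold, min_area,
#'   max_area, ws_tolerance, r_in, r_out, max_disp, max_gap}.
#' @param features Named list: \code{theta, m, rho, min_separation}.
#' @param analysis Named list: \code{grid} (common time grid, minutes).
#' @param preset_file Preset YAML path (default the shipped presets).
#' @param preset_overrides Nested list of preset field overrides.
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(presets = c("Sigma", "EB", "UP"),
                            concentrations = 5 * 10^seq(-7, 1),
                            stnfr_arms = c(FALSE, TRUE),
                            n_cells = 60, movies_per_condition = 3,
                            seed = 1,
                            imaging = list(),
                            segmentation = list(),
                            features = list(),
                            analysis = list(),
                            preset_file = preset_file_default(),
                            preset_overrides = NULL) {
  seg_def <- list(sigma = 1, threshold = NULL, min_area = 40,
                  max_area = 200, ws_tolerance = 1,
                  r_in = 2, r_out = 8, max_disp = 10, max_gap = 2,
                  exclusion_radius = 16, marker_qc_factor = 1.08,
                  max_invalid_run = 2)
  feat_def <- list(theta = 0.2, m = 3, rho = 0.5, min_separation = 60)
  cfg <- structure(list(
    presets = presets, concentrations = concentrations,
    stnfr_arms = stnfr_arms, n_cells = n_cells,
    movies_per_condition = movies_per_condition, seed = seed,
    imaging = imaging,
    segmentation = utils::modifyList(seg_def, segmentation),
    features = utils::modifyList(feat_def, features),
    analysis = utils::modifyList(list(grid = NULL), analysis),
    preset_file = preset_file, preset_overrides = preset_overrides),
    class = "pipeline_config")
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema, range and preset-existence checks; report-based (never
#' throws).
#'
#' @param config A [pipeline_config()] (or plain list).
#' @return data.frame with columns \code{field} and \code{problem};
#'   zero rows when the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(field, problem)
    v[[length(v) + 1]] <<- data.frame(field = field, problem = problem)
  avail <- tryCatch(list_presets(config$preset_file), error = function(e) character())
  for (p in config$presets)
    if (!p %in% avail)
      bad("presets", sprintf("unknown preset '%s'; available: %s", p,
                             paste(avail, collapse = ", ")))
  if (!length(config$concentrations))
    bad("concentrations", "concentration grid is empty")
  else if (any(!is.finite(config$concentrations) | config$concentrations < 0))
    bad("concentrations", "concentrations must be finite and >= 0")
  if (!is.numeric(config$n_cells) || config$n_cells < 1)
    bad("n_cells", "need at least one cell per movie")
  if (!is.numeric(config$movies_per_condition) || config$movies_per_condition < 1)
    bad("movies_per_condition", "need at least one movie per condition")
  if (!is.numeric(config$seed) || !is.finite(config$seed))
    bad("seed", "seed must be a finite number")
  ic <- tryCatch({ do.call(imaging_config, config$imaging); NULL },
                 error = function(e) conditionMessage(e))
  if (!is.null(ic)) bad("imaging", ic)
  sg <- config$segmentation
  if (!is.null(sg$r_in) && !is.null(sg$r_out) && sg$r_out <= sg$r_in)
    bad("segmentation", "r_out must exceed r_in")
  if (length(v)) do.call(rbind, v)
  else data.frame(field = character(), problem = character())
}

cond_tag <- function(preset, conc, stnfr, movie)
  sprintf("%s_c%g%s_m%d", preset, conc, if (stnfr) "_stnfr" else "", movie)

pipeline_grid <- function(config) {
  g <- expand.grid(movie = seq_len(config$movies_per_condition),
                   stnfr = config$stnfr_arms,
                   conc = config$concentrations,
                   preset = config$presets,
                   stringsAsFactors = FALSE)
  g$tag <- mapply(cond_tag, g$preset, g$conc, g$stnfr, g$movie)
  g$seed <- mapply(condition_seed, config$seed, g$preset, g$conc,
                   g$stnfr, g$movie)
  g
}

write_traces_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.frame(id = as.character(tr$id), time = tr$time,
               intensity = tr$intensity, valid = tr$valid))
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(id = character(), time = numeric(),
                     intensity = numeric(), valid = logical())
  utils::write.csv(df, path, row.names = FALSE)
}

read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(list())
  out <- lapply(split(df, df$id), function(d) {
    d <- d[order(d$time), ]
    new_trace(d$id[1], d$time, d$intensity, d$valid)
  })
  out[order(as.integer(names(out)))]
}

#' Run the image-analysis stages on one movie
#'
#' Segments the nuclear-marker channel, builds cytoplasmic rings, links
#' tracks, and extracts normalized traces.
#'
#' @param movie An \code{"nt_movie"}.
#' @param segmentation Stage parameters (see [pipeline_config()]).
#' @param background Background level for trace normalization; NULL to
#'   estimate from image corners.
#' @return List with \code{stack} (labels/rings/regions), \code{tracks}
#'   and \code{traces}.
#' @export
analyze_movie <- function(movie, segmentation = pipeline_config()$segmentation,
                          background = NULL) {
  sg <- segmentation
  stack <- segment_movie(movie, sigma = sg$sigma,
                         threshold = sg$threshold, min_area = sg$min_area,
                         max_area = sg$max_area,
                         ws_tolerance = sg$ws_tolerance,
                         r_in = sg$r_in, r_out = sg$r_out,
                         exclusion_radius = sg$exclusion_radius %||% 16,
                         marker_qc_factor = sg$marker_qc_factor %||% 1.08)
  tracks <- link_tracks(stack, max_disp = sg$max_disp, max_gap = sg$max_gap)
  traces <- extract_traces(movie, tracks, stack$labels,
                           stack$rings, movie$stim_frame, movie$dt,
                           background = background,
                           excluded = stack$excluded,
                           max_invalid_run = sg$max_invalid_run %||% 2)
  list(stack = stack, tracks = tracks, traces = traces)
}

#' Run the full simulation and analysis pipeline
#'
#' Simulate movies for every (preset, concentration, sTNFRII, replicate)
#' condition, segment and track them, extract traces and per-cell
#' features, and aggregate population summaries, the cosine-distance
#' similarity matrix, and the TNF-blocking effect distances. Every stage
#' persists standard-format intermediates (TIFF / CSV / JSON) under
#' \code{out_dir} and is skipped when its outputs already exist, so a
#' deleted downstream artifact is recomputed from the persisted
#' intermediates. A resolved-config snapshot and a run log are written
#' alongside.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the summaries, the similarity matrix
#'   (when computable), receptor-effect rows, and the output paths.
#' @export
run_full <- function(config, out_dir, quiet = FALSE) {
  viol <- validate_config(config)
  if (nrow(viol))
    stop("run_full: invalid config:\n",
         paste(sprintf("  %s: %s", viol$field, viol$problem), collapse = "\n"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("movies", "labels", "tracks", "traces"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", sep = "",
        file = logf, append = TRUE)
    if (!quiet) message(msg)
  }
  yaml::write_yaml(rapply(unclass(config), identity, how = "replace"),
                   file.path(out_dir, "resolved_config.yaml"))
  icfg <- do.call(imaging_config, config$imaging)
  presets <- stats::setNames(lapply(config$presets, preparation_preset,
                                    file = config$preset_file,
                                    overrides = config$preset_overrides),
                             config$presets)
  grid <- pipeline_grid(config)
  log_line("pipeline: %d conditions x %d movies (%d runs), seed %s",
           nrow(grid) / config$movies_per_condition,
           config$movies_per_condition, nrow(grid), format(config$seed))

  # stage 1-3: per movie
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    mv_path <- file.path(out_dir, "movies", paste0(g$tag, ".tif"))
    gt_path <- file.path(out_dir, "movies", paste0(g$tag, "_truth.json"))
    tr_path <- file.path(out_dir, "traces", paste0(g$tag, ".csv"))
    tk_path <- file.path(out_dir, "tracks", paste0(g$tag, ".csv"))
    lb_path <- file.path(out_dir, "labels", paste0(g$tag, "_nuclei.tif"))
    rg_path <- file.path(out_dir, "labels", paste0(g$tag, "_rings.tif"))
    ex_path <- file.path(out_dir, "labels", paste0(g$tag, "_excluded.csv"))
    if (!file.exists(mv_path)) {
      log_line("simulate %s (seed %d)", g$tag, g$seed)
      sim <- simulate_condition(presets[[g$preset]], g$conc, g$stnfr,
                                config$n_cells, icfg, seed = g$seed)
      write_movie(sim$movie, mv_path)
      write_ground_truth(sim$truth, gt_path)
    }
    if (!file.exists(tr_path)) {
      movie <- read_movie(mv_path)
      if (!file.exists(tk_path) || !file.exists(lb_path)) {
        log_line("segment+track %s", g$tag)
        res <- analyze_movie(movie, config$segmentation,
                             background = icfg$background)
        write_label_stack(res$stack$labels, lb_path)
        write_label_stack(res$stack$rings, rg_path)
        ex_df <- do.call(rbind, lapply(seq_along(res$stack$excluded),
                                       function(f) {
          ids <- res$stack$excluded[[f]]
          if (!length(ids)) NULL else data.frame(frame = f, label = ids)
        }))
        if (is.null(ex_df)) ex_df <- data.frame(frame = integer(),
                                                label = integer())
        utils::write.csv(ex_df, ex_path, row.names = FALSE)
        utils::write.csv(tracks_to_df(res$tracks), tk_path, row.names = FALSE)
        traces <- res$traces
      } else {
        log_line("trace %s (from persisted labels/tracks)", g$tag)
        labels <- read_label_stack(lb_path)
        rings <- read_label_stack(rg_path)
        tracks <- df_to_tracks(utils::read.csv(tk_path), dim(labels)[3])
        ex_df <- if (file.exists(ex_path)) utils::read.csv(ex_path)
        else data.frame(frame = integer(), label = integer())
        excl <- lapply(seq_len(dim(labels)[3]), function(f)
          ex_df$label[ex_df$frame == f])
        traces <- extract_traces(movie, tracks, labels,
                                 rings, movie$stim_frame, movie$dt,
                                 background = icfg$background,
                                 excluded = excl)
      }
      write_traces_csv(traces, tr_path)
    }
  }

  # stage 4: features
  feat_path <- file.path(out_dir, "features.csv")
  if (!file.exists(feat_path)) {
    log_line("features: %d trace files", nrow(grid))
    ft <- config$features
    feats <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      traces <- read_traces_csv(file.path(out_dir, "traces",
                                          paste0(g$tag, ".csv")))
      tb <- trace_features_table(traces, theta = ft$theta, m = ft$m,
                                 rho = ft$rho,
                                 min_separation = ft$min_separation)
      if (is.null(tb)) return(NULL)
      cbind(preset = g$preset, conc = g$conc, stnfr = g$stnfr,
            movie = g$movie, tb)
    })
    utils::write.csv(do.call(rbind, feats), feat_path, row.names = FALSE)
  }
  features <- utils::read.csv(feat_path, stringsAsFactors = FALSE)

  # stage 5: per-condition summaries
  grid_time <- if (is.null(config$analysis$grid))
    seq(0, (icfg$n_frames - icfg$stim_frame) * icfg$dt, by = icfg$dt)
  else config$analysis$grid
  conds <- unique(grid[c("preset", "conc", "stnfr")])
  summaries <- list()
  for (i in seq_len(nrow(conds))) {
    cd <- conds[i, ]
    sel <- grid$preset == cd$preset & grid$conc == cd$conc &
      grid$stnfr == cd$stnfr
    traces <- list()
    for (tag in grid$tag[sel]) {
      trs <- read_traces_csv(file.path(out_dir, "traces", paste0(tag, ".csv")))
      names(trs) <- paste(tag, names(trs), sep = ":")
      trs <- lapply(trs, function(tr) { tr$id <- paste(tag, tr$id, sep = ":"); tr })
      traces <- c(traces, trs)
    }
    fsel <- features$preset == cd$preset & features$conc == cd$conc &
      features$stnfr == cd$stnfr
    fts <- features[fsel, , drop = FALSE]
    if (!nrow(fts)) next
    fts$id <- paste(mapply(cond_tag, fts$preset, fts$conc, fts$stnfr,
                           fts$movie), fts$id, sep = ":")
    summaries[[length(summaries) + 1]] <-
      condition_summary(fts, traces, cd$preset, cd$conc, cd$stnfr,
                        grid = grid_time)
  }
  sum_df <- do.call(rbind, lapply(summaries, function(s)
    data.frame(preset = s$preparation, conc = s$conc, stnfr = s$stnfr,
               n_total = s$n_total, n_active = s$n_active,
               fraction_active = s$n_active / max(1, s$n_total),
               amp_mean = s$amp_above_baseline["mean"],
               amp_sd = s$amp_above_baseline["sd"],
               ttp_mean = s$time_to_peak["mean"],
               ttp_sd = s$time_to_peak["sd"],
               width_mean = s$peak_width["mean"],
               width_sd = s$peak_width["sd"],
               mean_secondary = s$mean_secondary)))
  utils::write.csv(sum_df, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  courses <- do.call(rbind, lapply(summaries, function(s)
    if (length(s$average_course))
      data.frame(preset = s$preparation, conc = s$conc, stnfr = s$stnfr,
                 time = s$grid, intensity = s$average_course)))
  utils::write.csv(courses, file.path(out_dir, "average_courses.csv"),
                   row.names = FALSE)

  # stage 6: similarity matrix (no-sTNFRII arm) + receptor effects
  sim_mat <- NULL
  no_arm <- Filter(function(s) !s$stnfr && s$n_active > 0, summaries)
  if (length(no_arm) >= 2) {
    sim_mat <- similarity_matrix(no_arm)
    m <- sim_mat$distance
    utils::write.csv(data.frame(label = rownames(m), m,
                                check.names = FALSE),
                     file.path(out_dir, "similarity.csv"),
                     row.names = FALSE)
  }
  receptor <- NULL
  if (any(grid$stnfr)) {
    rows <- list()
    for (s in Filter(function(s) !s$stnfr, summaries)) {
      mate <- Filter(function(x) x$stnfr &&
                       identical(x$preparation, s$preparation) &&
                       isTRUE(all.equal(x$conc, s$conc)), summaries)
      if (!length(mate)) next
      re <- receptor_effect(s, mate[[1]])
      rows[[length(rows) + 1]] <-
        data.frame(preset = re$preparation, conc = re$conc,
                   distance = re$distance, empty = re$empty)
    }
    receptor <- do.call(rbind, rows)
    if (!is.null(receptor))
      utils::write.csv(receptor, file.path(out_dir, "receptor_effect.csv"),
                       row.names = FALSE)
  }
  log_line("done: %d summaries", length(summaries))
  invisible(list(summaries = summaries, similarity = sim_mat,
                 receptor = receptor, features = features,
                 out_dir = out_dir))
}

df_to_tracks <- function(df, n_frames) {
  lapply(split(df, df$track_id), function(d) {
    t <- list(track_id = d$track_id[1],
              label = rep(NA_integer_, n_frames),
              row = rep(NA_real_, n_frames), col = rep(NA_real_, n_frames),
              start = min(d$frame), end = max(d$frame))
    t$label[d$frame] <- d$label
    t$row[d$frame] <- d$row; t$col[d$frame] <- d$col
    structure(t, class = "nt_track")
  })
}
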