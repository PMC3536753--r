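#' Average activation time course of active cells
#'
#' Each trace is linearly resampled onto the common grid (valid frames
#' only; edge values held beyond the first/last valid frame), then
#' averaged pointwise.
#'
#' @param traces List of [new_trace()] objects (active cells).
#' @param grid Common time grid, minutes (default 0 to 580 by 5).
#' @return Numeric vector on \code{grid}; if \code{traces} is empty, an
#'   empty-condition marker: a zero-length numeric with attribute
#'   \code{empty = TRUE} (see [receptor_effect()] for how downstream
#'   consumers treat it).
#' @export
average_time_course <- function(traces, grid = seq(0, 580, by = 5)) {
  if (!length(traces)) {
    out <- numeric(0); attr(out, "empty") <- TRUE
    return(out)
  }
  mat <- vapply(traces, function(tr) {
    ok <- tr$valid
    if (sum(ok) < 2) stop("average_time_course: trace with < 2 valid frames")
    stats::approx(tr$time[ok], tr$intensity[ok], xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  rowMeans(mat)
}

#' Cosine distance between two time-course vectors
#'
#' \eqn{1 - u \cdot v / (\lVert u\rVert \lVert v\rVert)}; 0 for
#' proportional profiles, in \[0, 2\] generally; symmetric and invariant
#' to positive rescaling of either argument.
#'
#' @param u,v Equal-length nonzero numeric vectors.
#' @return Dimensionless distance.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v))
    stop("cosine_distance: vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine_distance: zero vector has no direction")
  1 - sum(u * v) / (nu * nv)
}

#' Per-condition summary of single-cell results
#'
#' Collects, for one (preparation, concentration, sTNFRII) condition,
#' the active/total counts, the average time course of active cells on
#' a common grid, and means/SDs of the per-cell statistics.
#'
#' @param features Feature table ([trace_features_table()]) for the
#'   condition's cells.
#' @param traces The matching list of traces (named by cell id).
#' @param preparation,conc,stnfr Condition labels.
#' @param grid Common time grid for the average course.
#' @param exclude_censored_width Exclude right-censored widths from the
#'   width mean/SD (default TRUE).
#' @return An object of class \code{"condition_summary"}.
#' @export
condition_summary <- function(features, traces, preparation, conc,
                              stnfr = FALSE, grid = seq(0, 580, by = 5),
                              exclude_censored_width = TRUE) {
  act_ids <- features$id[features$active]
  act <- features[features$active, , drop = FALSE]
  avg <- average_time_course(traces[act_ids], grid)
  wid <- if (exclude_censored_width)
    act$peak_width[!act$width_censored] else act$peak_width
  stat <- function(x) c(mean = mean(x), sd = stats::sd(x))
  structure(list(preparation = preparation, conc = conc, stnfr = stnfr,
                 n_total = nrow(features), n_active = nrow(act),
                 grid = grid, average_course = avg,
                 peak_amp = stat(act$peak_amp),
                 amp_above_baseline = stat(act$peak_amp - act$baseline),
                 time_to_peak = stat(act$time_to_peak),
                 peak_width = stat(wid),
                 mean_secondary = if (nrow(act)) mean(act$n_secondary) else NA),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("condition_summary: %s at %g ug/mL%s\n", x$preparation,
              x$conc, if (x$stnfr) " + sTNFRII" else ""))
  cat(sprintf("  active %d / %d (%.2f)\n", x$n_active, x$n_total,
              x$n_active / max(1, x$n_total)))
  if (x$n_active)
    cat(sprintf("  peak_amp %.3f +- %.3f | time_to_peak %.1f +- %.1f min | width %.1f +- %.1f min\n",
                x$peak_amp["mean"], x$peak_amp["sd"],
                x$time_to_peak["mean"], x$time_to_peak["sd"],
                x$peak_width["mean"], x$peak_width["sd"]))
  invisible(x)
}

#' Fraction of active cells in a condition
#'
#' @param features Feature table with an \code{active} column, or a
#'   logical vector of activity flags.
#' @return List with integer \code{n_active}, \code{n_total} and
#'   \code{fraction}.
#' @export
fraction_active <- function(features) {
  act <- if (is.data.frame(features)) features$active else features
  n <- length(act)
  if (n < 1) stop("fraction_active: need at least one cell")
  list(n_active = sum(act), n_total = n, fraction = sum(act) / n)
}

#' Pairwise cosine-distance matrix of condition average time courses
#'
#' Conditions are ordered by preparation (block order of first
#' appearance) and, within a preparation, by descending concentration;
#' entries are [cosine_distance()] between average activation profiles.
#'
#' @param summaries List of [condition_summary()] objects with
#'   non-empty average courses on a common grid.
#' @return An object of class \code{"similarity_matrix"}: list with the
#'   symmetric \code{distance} matrix (zero diagonal) and the ordered
#'   \code{labels}.
#' @export
similarity_matrix <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  grids <- lapply(summaries, `[[`, "grid")
  if (!all(vapply(grids, identical, TRUE, grids[[1]])))
    stop("similarity_matrix: condition summaries are on different time grids")
  prep <- vapply(summaries, `[[`, "", "preparation")
  conc <- vapply(summaries, `[[`, 0, "conc")
  stnfr <- vapply(summaries, function(s) isTRUE(s$stnfr), TRUE)
  o <- order(match(prep, unique(prep)), -conc, stnfr)
  summaries <- summaries[o]
  labs <- sprintf("%s_%g%s", prep[o], conc[o], ifelse(stnfr[o], "_sTNFRII", ""))
  courses <- lapply(summaries, `[[`, "average_course")
  if (any(vapply(courses, length, 0L) == 0))
    stop("similarity_matrix: condition with no active cells cannot enter the matrix")
  n <- length(courses)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i < j) m[i, j] <- m[j, i] <- cosine_distance(courses[[i]], courses[[j]])
  structure(list(distance = m, labels = labs,
                 ordering = "preparation blocks, descending concentration"),
            class = "similarity_matrix")
}

#' @export
plot.similarity_matrix <- function(x, ...) {
  n <- nrow(x$distance)
  graphics::image(seq_len(n), seq_len(n), t(x$distance[n:1, ]),
                  col = grDevices::hcl.colors(64, "Grays", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "cosine distance between average time courses", ...)
  graphics::axis(1, seq_len(n), x$labels, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(x$labels), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix (cosine distance), order:", x$ordering, "\n")
  print(round(x$distance, 4))
  invisible(x)
}

#' Effect of TNF blocking on a condition's average time course
#'
#' Cosine distance between the average activation time courses of the
#' same (preparation, concentration) condition with and without
#' sTNFRII. Conditions with no active cells in either arm yield a
#' flagged non-numeric result rather than an error, since an average
#' course of zero cells is not statistically meaningful.
#'
#' @param summary_no,summary_yes [condition_summary()] objects for the
#'   untreated and sTNFRII arms of the same condition.
#' @return List with \code{distance} (NA when flagged), \code{empty}
#'   flag, and the condition labels.
#' @export
receptor_effect <- function(summary_no, summary_yes) {
  if (!identical(summary_no$preparation, summary_yes$preparation) ||
      !isTRUE(all.equal(summary_no$conc, summary_yes$conc)))
    stop("receptor_effect: the two arms must share preparation and concentration")
  if (!identical(summary_no$grid, summary_yes$grid))
    stop("receptor_effect: the two arms must share the time grid")
  if (summary_no$n_active == 0 || summary_yes$n_active == 0)
    return(list(preparation = summary_no$preparation,
                conc = summary_no$conc, distance = NA_real_, empty = TRUE))
  list(preparation = summary_no$preparation, conc = summary_no$conc,
       distance = cosine_distance(summary_no$average_course,
                                  summary_yes$average_course),
       empty = FALSE)
}
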