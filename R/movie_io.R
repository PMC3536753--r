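# Movies are stored as multi-page 16-bit TIFF plus a JSON sidecar.
# Page order is frame-major: page (f-1)*2 + ch, ch 1 = nuclear marker,
# ch 2 = reporter. Pixel encoding: stored = (photons * 16) / 65535,
# i.e. integer sixteenths of a photon, which round-trips renderer
# output (already quantized to 1/16 photon) bitwise.

photons_to_stored <- function(x) round(x * 16) / 65535
stored_to_photons <- function(x) round(x * 65535) / 16

sidecar_path <- function(path) sub("\\.tiff?$", "", path, ignore.case = TRUE)

#' Write a movie to disk (multi-page TIFF + JSON sidecar)
#'
#' @param movie An \code{"nt_movie"} object.
#' @param path Output TIFF path (\code{.tif}); the sidecar is written
#'   next to it with extension \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "nt_movie"))
  d <- dim(movie$stack)
  pages <- vector("list", d[3] * d[4])
  for (f in seq_len(d[4])) for (ch in seq_len(d[3]))
    pages[[(f - 1) * d[3] + ch]] <- photons_to_stored(movie$stack[, , ch, f])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(format = "nfkbtrace-movie", version = 1L,
               height = d[1], width = d[2], n_channels = d[3],
               n_frames = d[4], channels = movie$channels,
               page_order = "frame-major (frame, then channel)",
               photon_quantum = 1 / 16,
               dt = movie$dt, stim_frame = movie$stim_frame,
               meta = movie$meta)
  jsonlite::write_json(meta, paste0(sidecar_path(path), ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path.
#' @return An \code{"nt_movie"} object, bitwise identical to the one
#'   written.
#' @export
read_movie <- function(path) {
  side <- paste0(sidecar_path(path), ".json")
  if (!file.exists(side))
    stop(sprintf("read_movie: missing metadata sidecar '%s'", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$format, "nfkbtrace-movie"))
    stop("read_movie: sidecar is not nfkbtrace movie metadata")
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- meta$n_channels
  if (nch != 2)
    stop(sprintf("read_movie: two channels (nuclear marker + reporter) required, sidecar declares %d", nch))
  if (length(pages) != meta$n_frames * nch)
    stop(sprintf("read_movie: expected %d pages (%d frames x %d channels), found %d; page %d is the first missing",
                 meta$n_frames * nch, meta$n_frames, nch, length(pages),
                 length(pages) + 1L))
  stack <- array(0, c(meta$height, meta$width, nch, meta$n_frames))
  for (f in seq_len(meta$n_frames)) for (ch in seq_len(nch))
    stack[, , ch, f] <- stored_to_photons(pages[[(f - 1) * nch + ch]])
  structure(list(stack = stack, dt = as.numeric(meta$dt),
                 stim_frame = as.integer(meta$stim_frame),
                 channels = meta$channels, meta = as.list(meta$meta)),
            class = "nt_movie")
}

#' Write / read a per-frame integer label stack as multi-page TIFF
#'
#' @param labels Integer array (height x width x frames), values in
#'   0..65535.
#' @param path Output TIFF path.
#' @return \code{path} invisibly / the label array.
#' @export
write_label_stack <- function(labels, path) {
  stopifnot(max(labels) <= 65535, min(labels) >= 0)
  pages <- lapply(seq_len(dim(labels)[3]),
                  function(f) labels[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_label_stack
#' @export
read_label_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages))
    arr[, , f] <- as.integer(round(pages[[f]] * 65535))
  arr
}

#' Export ground truth to JSON (+ label TIFF)
#'
#' Writes the ground-truth cell table (classes, sampled pulse
#' parameters, motion paths, true traces and features) as JSON and the
#' per-frame true label images as a multi-page TIFF.
#'
#' @param truth An \code{"nt_ground_truth"} object.
#' @param json_path Output JSON path.
#' @param labels_path Optional output TIFF path for the label stack.
#' @return \code{json_path}, invisibly.
#' @export
write_ground_truth <- function(truth, json_path, labels_path = NULL) {
  stopifnot(inherits(truth, "nt_ground_truth"))
  cells <- lapply(truth$cells, function(cl) {
    list(cell_id = cl$cell_id, responder_class = cl$responder_class,
         active = cl$active,
         params = unclass(cl$params),
         semi_axes = cl$semi_axes, angle = cl$angle,
         path = list(row = cl$path[, 1], col = cl$path[, 2]),
         true_trace = list(time = cl$true_trace$time,
                           intensity = cl$true_trace$intensity),
         true_features = unclass(cl$true_features))
  })
  jsonlite::write_json(list(format = "nfkbtrace-ground-truth", version = 1L,
                            overlap = truth$overlap, cells = cells),
                       json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(labels_path)) write_label_stack(truth$labels, labels_path)
  invisible(json_path)
}
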