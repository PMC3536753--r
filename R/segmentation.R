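#' Segment nuclei in one nuclear-marker frame
#'
#' Pipeline: Gaussian smoothing, global Otsu threshold (or a fixed
#' override), hole filling, distance-transform watershed to split
#' touching nuclei, and an area filter. Regions use 8-connectivity;
#' labels are compacted to 1..n in raster order of first occurrence.
#'
#' @param frame 2-D nonnegative numeric matrix (nuclear-marker channel).
#' @param sigma Gaussian smoothing sigma, pixels (default 1).
#' @param threshold Fixed intensity threshold; NULL (default) for Otsu.
#' @param min_area,max_area Area bounds in pixels for accepted nuclei.
#'   The defaults (40, 200) bracket single nuclei of the default 5-7 px
#'   semi-axes; the ceiling doubles as quality control, rejecting
#'   two-nucleus merges that the watershed cannot split once pixel
#'   quantization has erased the distance-map saddle (such frames become
#'   track gaps instead of contaminated measurements).
#' @param ws_tolerance Watershed tolerance (default 1).
#' @return An object of class \code{"nt_labels"}: list with
#'   \code{labels} (integer matrix, 0 = background) and \code{regions}
#'   (data.frame: label, area, row, col centroids).
#' @export
segment_nuclei <- function(frame, sigma = 1, threshold = NULL,
                           min_area = 40, max_area = 200,
                           ws_tolerance = 1) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("segment_nuclei: frame must be a 2-D numeric matrix")
  if (any(frame < 0)) stop("segment_nuclei: frame must be nonnegative")
  blank <- matrix(FALSE, nrow(frame), ncol(frame))
  mx <- max(frame)
  if (mx == min(frame))            # blank image: no nuclei, not an error
    return(new_labels(matrix(0L, nrow(frame), ncol(frame)), mask = blank))
  img <- EBImage::Image(frame / mx)
  sm <- if (sigma > 0) EBImage::gblur(img, sigma = sigma) else img
  thr <- if (is.null(threshold)) EBImage::otsu(sm, range = c(0, 1)) else threshold / mx
  mask <- sm > thr
  mask <- EBImage::fillHull(mask)
  if (!any(mask))
    return(new_labels(matrix(0L, nrow(frame), ncol(frame)), mask = blank))
  # plain connected components first; the watershed split is only needed
  # when some component is large enough to be two touching nuclei
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  cc_areas <- tabulate(lab[lab > 0])
  if (any(cc_areas > max_area)) {
    dm <- EBImage::distmap(mask)
    ws <- EBImage::watershed(dm, tolerance = ws_tolerance, ext = 1)
    lab <- EBImage::imageData(ws)
  }
  areas <- tabulate(lab[lab > 0])
  bad <- which(areas < min_area | areas > max_area)
  if (length(bad)) lab[lab %in% bad] <- 0
  new_labels(compact_labels(lab), mask = EBImage::imageData(mask) > 0)
}

compact_labels <- function(lab) {
  ids <- unique(as.vector(lab[lab > 0]))
  if (!length(ids)) return(matrix(0L, nrow(lab), ncol(lab)))
  ids <- ids[order(match(ids, as.vector(lab)))]   # raster order of first pixel
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- match(as.vector(lab[lab > 0]), ids)
  out
}

new_labels <- function(lab, mask = lab > 0) {
  structure(list(labels = lab, regions = region_table(lab), mask = mask),
            class = "nt_labels")
}

#' Region table of a label image
#'
#' @param lab Integer label matrix (0 = background).
#' @return data.frame with one row per label: \code{label, area, row,
#'   col} (area-weighted centroids, 1-based pixel centers).
#' @export
region_table <- function(lab) {
  nz <- which(lab > 0)
  if (!length(nz))
    return(data.frame(label = integer(), area = integer(),
                      row = numeric(), col = numeric()))
  l <- lab[nz]
  rr <- (nz - 1) %% nrow(lab) + 1
  cc <- (nz - 1) %/% nrow(lab) + 1
  s <- rowsum(cbind(1, rr, cc), l)
  data.frame(label = as.integer(rownames(s)),
             area = as.integer(s[, 1]),
             row = s[, 2] / s[, 1],
             col = s[, 3] / s[, 1])
}

#' Cytoplasmic measurement rings around segmented nuclei
#'
#' For each nucleus, the ring is the band of background pixels whose
#' distance to the nearest nuclear pixel lies in \code{(r_in, r_out]};
#' nuclear pixels of every cell are excluded, and pixels contested
#' between neighbours are claimed by the nucleus with the nearest
#' centroid. The ring supplies the representative cytoplasmic mean used
#' to normalize nuclear reporter intensity.
#'
#' @param labels An \code{"nt_labels"} object or integer label matrix.
#' @param r_in Inner margin from the nuclear boundary, pixels (>= 0).
#' @param r_out Outer reach from the nuclear boundary, pixels
#'   (> \code{r_in}).
#' @return Integer ring label matrix (same ids as the nuclei).
#' @export
cytoplasm_ring <- function(labels, r_in = 2, r_out = 8) {
  if (inherits(labels, "nt_labels")) {
    reg <- labels$regions; lab <- labels$labels
  } else {
    lab <- labels; reg <- region_table(lab)
  }
  if (!(r_out > r_in && r_in >= 0))
    stop("cytoplasm_ring: need r_out > r_in >= 0")
  ring <- matrix(0L, nrow(lab), ncol(lab))
  if (!nrow(reg)) return(ring)
  bg <- EBImage::Image((lab == 0) * 1)
  d <- EBImage::imageData(EBImage::distmap(bg))  # bg distance to nearest nucleus
  band <- which(d > r_in & d <= r_out & lab == 0)
  if (!length(band)) return(ring)
  rr <- (band - 1) %% nrow(lab) + 1
  cc <- (band - 1) %/% nrow(lab) + 1
  d2 <- outer(rr^2 + cc^2, rep(1, nrow(reg))) -
    2 * (outer(rr, reg$row) + outer(cc, reg$col)) +
    matrix(reg$row^2 + reg$col^2, length(band), nrow(reg), byrow = TRUE)
  ring[band] <- reg$label[max.col(-d2, ties.method = "first")]
  ring
}

#' Proximity quality control for measurement frames
#'
#' Cells whose intensities overlap contaminate each other's nuclear and
#' ring means (the renderer, like a real monolayer, lets adjacent
#' cytoplasms encroach on a neighbour's measurement regions). In the
#' original workflow such cells were removed by visual curation; the
#' automated surrogate flags every nucleus that has foreign foreground
#' within \code{radius} pixels of its centroid — any thresholded
#' nuclear-marker pixel that does not belong to the nucleus itself,
#' which also catches neighbours the area filter rejected (e.g. merged
#' pairs). Flagged frames are treated as measurement gaps.
#'
#' @param seg An \code{"nt_labels"} object (one frame).
#' @param radius Exclusion radius in pixels (default 16: a neighbour's
#'   cytoplasm reaches a nucleus once foreign nuclear pixels are within
#'   about the cytoplasm extent plus a nuclear semi-axis).
#' @return Integer vector of excluded label ids.
#' @export
proximity_exclusions <- function(seg, radius = 16) {
  stopifnot(inherits(seg, "nt_labels"))
  reg <- seg$regions
  if (!nrow(reg)) return(integer())
  lab <- seg$labels; mask <- seg$mask
  h <- nrow(lab); w <- ncol(lab)
  out <- integer()
  for (i in seq_len(nrow(reg))) {
    r0 <- max(1, floor(reg$row[i] - radius)); r1 <- min(h, ceiling(reg$row[i] + radius))
    c0 <- max(1, floor(reg$col[i] - radius)); c1 <- min(w, ceiling(reg$col[i] + radius))
    win_mask <- mask[r0:r1, c0:c1]
    win_lab <- lab[r0:r1, c0:c1]
    foreign <- win_mask & win_lab != reg$label[i]
    if (!any(foreign)) next
    rr <- ((which(foreign) - 1) %% (r1 - r0 + 1)) + r0
    cc <- ((which(foreign) - 1) %/% (r1 - r0 + 1)) + c0
    if (min((rr - reg$row[i])^2 + (cc - reg$col[i])^2) <= radius^2)
      out <- c(out, reg$label[i])
  }
  out
}

#' Segment a whole movie's nuclear-marker channel
#'
#' Applies [segment_nuclei()] and [cytoplasm_ring()] to every frame.
#'
#' @param nuc The nuclear-marker channel: a 3-D array (height x width x
#'   frames) or an \code{"nt_movie"} (channel 1 is used, sliced frame by
#'   frame to avoid a full-channel copy).
#' @param ... Passed to [segment_nuclei()].
#' @param r_in,r_out Ring geometry (see [cytoplasm_ring()]).
#' @param exclusion_radius Proximity-QC radius in pixels (see
#'   [proximity_exclusions()]); 0 disables the check.
#' @param marker_qc_factor Brightness-QC factor: the nuclear marker is
#'   constitutive, so a label whose mean marker intensity exceeds this
#'   multiple of the frame's median label brightness is two overlapped
#'   nuclei segmented as one (their intensities add) and is excluded for
#'   that frame. 0 disables the check.
#' @return An object of class \code{"nt_label_stack"}: list with
#'   \code{labels} and \code{rings} (integer arrays height x width x
#'   frames), \code{regions} (list of per-frame region tables) and
#'   \code{excluded} (list of per-frame QC-excluded label ids).
#' @export
segment_movie <- function(nuc, ..., r_in = 2, r_out = 8,
                          exclusion_radius = 16, marker_qc_factor = 1.08) {
  get_frame <- frame_accessor(nuc, 1)
  d <- frame_dims(nuc)
  TT <- d[3]
  labels <- array(0L, d); rings <- array(0L, d)
  regions <- vector("list", TT)
  excluded <- vector("list", TT)
  for (f in seq_len(TT)) {
    frm <- get_frame(f)
    seg <- segment_nuclei(frm, ...)
    labels[, , f] <- seg$labels
    rings[, , f] <- cytoplasm_ring(seg, r_in = r_in, r_out = r_out)
    regions[[f]] <- seg$regions
    ex <- if (exclusion_radius > 0)
      proximity_exclusions(seg, exclusion_radius) else integer()
    if (marker_qc_factor > 0 && nrow(seg$regions) > 1) {
      nz <- seg$labels > 0
      s <- rowsum(cbind(frm[nz], 1), seg$labels[nz])
      mns <- s[, 1] / s[, 2]
      bright <- as.integer(rownames(s))[mns > marker_qc_factor *
                                          stats::median(mns)]
      ex <- union(ex, bright)
    }
    excluded[[f]] <- ex
  }
  structure(list(labels = labels, rings = rings, regions = regions,
                 excluded = excluded),
            class = "nt_label_stack")
}

# Uniform per-frame access to a 3-D channel array or an nt_movie channel.
frame_accessor <- function(x, channel) {
  if (inherits(x, "nt_movie")) function(f) x$stack[, , channel, f]
  else function(f) x[, , f]
}

frame_dims <- function(x) {
  if (inherits(x, "nt_movie")) dim(x$stack)[c(1, 2, 4)] else dim(x)
}
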