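# Synthetic frame builders ---------------------------------------------

disk_frame <- function(centers, radius, h = 128, w = 128, fg = 300, bg = 20) {
  img <- matrix(bg, h, w)
  lab <- matrix(0L, h, w)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(nrow(centers))) {
    m <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius^2
    img[m] <- img[m] + fg
    lab[m] <- i
  }
  list(img = img, lab = lab)
}

test_that("well-separated nuclei are all recovered with IoU >= 0.7", {
  set.seed(15)
  centers <- as.matrix(expand.grid(seq(20, 110, by = 22),
                                   seq(20, 110, by = 22)))[1:20, ]
  fx <- disk_frame(centers, radius = 6)
  noisy <- matrix(rpois(length(fx$img), fx$img), nrow(fx$img)) +
    rnorm(length(fx$img), 0, 3)
  noisy[noisy < 0] <- 0
  seg <- segment_nuclei(noisy)
  expect_equal(nrow(seg$regions), 20)
  m <- match_labels_iou(fx$lab, seg$labels)
  expect_true(all(m$iou >= 0.7))
})

test_that("watershed splits two overlapping nuclei 1.2 semi-axes apart", {
  fx <- disk_frame(rbind(c(60, 60), c(60, 60 + 1.2 * 10)), radius = 10)
  seg <- segment_nuclei(fx$img, max_area = 400)
  expect_equal(nrow(seg$regions), 2)
})

test_that("watershed never merges nuclei beyond two semi-axes separation", {
  for (sep in c(2.2, 2.5, 3, 4)) {
    fx <- disk_frame(rbind(c(60, 50), c(60, 50 + sep * 6)), radius = 6)
    seg <- segment_nuclei(fx$img)
    expect_equal(nrow(seg$regions), 2)
  }
})

test_that("blank and malformed frames are handled per contract", {
  seg <- segment_nuclei(matrix(0, 64, 64))
  expect_equal(nrow(seg$regions), 0)
  expect_true(all(seg$labels == 0))
  expect_error(segment_nuclei(array(0, c(4, 4, 4))), "2-D")
  expect_error(segment_nuclei(matrix(-1, 8, 8)), "nonnegative")
})

test_that("area filter rejects specks and blobs", {
  fx <- disk_frame(rbind(c(30, 30), c(90, 90)), radius = 6)
  fx$img[60, 60] <- 400          # 1-px speck
  seg <- segment_nuclei(fx$img, min_area = 30, max_area = 200)
  expect_equal(nrow(seg$regions), 2)
})

test_that("cytoplasm ring matches annulus geometry on a rasterized disk", {
  fx <- disk_frame(matrix(c(64, 64), 1), radius = 10)
  seg <- segment_nuclei(fx$img, sigma = 0, threshold = 100, max_area = 400)
  ring <- cytoplasm_ring(seg, r_in = 2, r_out = 6)
  area <- sum(ring == 1)
  expect_lt(abs(area - pi * (16^2 - 12^2)) / (pi * (16^2 - 12^2)), 0.05)
})

test_that("rings of adjacent nuclei partition the contested band", {
  fx <- disk_frame(rbind(c(64, 50), c(64, 78)), radius = 8)
  seg <- segment_nuclei(fx$img, sigma = 0, threshold = 100, max_area = 400)
  ring <- cytoplasm_ring(seg, r_in = 0, r_out = 6)
  expect_setequal(setdiff(unique(as.vector(ring)), 0), c(1, 2))
  # rings abut but never include nuclear pixels
  expect_true(all(seg$labels[ring > 0] == 0))
  # contested pixels go to the nearer centroid
  reg <- seg$regions
  nz <- which(ring > 0)
  rr <- (nz - 1) %% 128 + 1; cc <- (nz - 1) %/% 128 + 1
  d1 <- sqrt((rr - reg$row[1])^2 + (cc - reg$col[1])^2)
  d2 <- sqrt((rr - reg$row[2])^2 + (cc - reg$col[2])^2)
  nearer <- ifelse(d1 <= d2, reg$label[1], reg$label[2])
  expect_true(all(ring[nz] == nearer))
})

test_that("ring radii are validated", {
  fx <- disk_frame(matrix(c(64, 64), 1), radius = 10)
  seg <- segment_nuclei(fx$img, max_area = 400)
  expect_error(cytoplasm_ring(seg, r_in = 6, r_out = 6), "r_out > r_in")
})
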