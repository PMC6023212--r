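# Roberts gradient, gradient thresholding, two-stage circular Hough and
# detection filtering.

test_that("Roberts gradient matches its kernel definition", {
  # flat field: zero everywhere except the zero-padded last row/column,
  # which responds to the image border itself
  g <- roberts_gradient(matrix(0.5, 8, 9))
  expect_equal(g[1:7, 1:8], matrix(0, 7, 8))
  expect_true(all(g[8, ] > 0) && all(g[, 9] > 0))
  # vertical unit step: magnitude sqrt(2) one column left of the step
  img <- matrix(0, 10, 10); img[, 6:10] <- 1
  g <- roberts_gradient(img)
  expect_equal(g[3, 5], sqrt(2))
  expect_equal(g[3, 4], 0)
  # 2x2 worked example: Gx = -1, Gy = 0 at (1,1)
  img <- rbind(c(0, 1), c(1, 1))
  expect_equal(roberts_gradient(img)[1, 1], 1)
  # zero-padded borders and full grid against the brute-force oracle
  for (s in 1:10) {
    set.seed(s)
    img <- matrix(runif(20 * 17), 20, 17)
    expect_equal(roberts_gradient(img), oracle_roberts(img), tolerance = 1e-12)
  }
})

test_that("gradient thresholding is strict", {
  g <- matrix(0, 4, 4)
  expect_false(any(threshold_gradient(g, 0.015)))
  g[2, 2] <- 0.015; g[3, 3] <- 0.0151
  b <- threshold_gradient(g, 0.015)
  expect_false(b[2, 2])  # boundary value excluded by convention
  expect_true(b[3, 3])
  expect_error(threshold_gradient(g, -1))
})

make_ring <- function(shape, cx, cy, r, width = 1.5) {
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d <- sqrt((xx - cx)^2 + (yy - cy)^2)
  abs(d - r) <= width
}

test_that("detect_circles finds ideal rings with sub-pixel accuracy", {
  expect_equal(nrow(detect_circles(matrix(FALSE, 50, 50))), 0L)
  ring <- make_ring(c(600, 700), cx = 300, cy = 400, r = 83)
  # at the permissive reference sensitivity the raw transform also emits
  # weak side peaks; the strongest peak is the true circle and the
  # false-positive filter reduces the list to exactly one detection
  draw <- detect_circles(ring)
  expect_gte(nrow(draw), 1L)
  expect_lt(abs(draw$cx[1] - 300), 2)
  expect_lt(abs(draw$cy[1] - 400), 2)
  d <- filter_detections(draw, c(600, 700))
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$cx - 300), 2)
  expect_lt(abs(d$cy - 400), 2)
  expect_lt(abs(d$r - 83), 2)
  expect_gt(d$strength, 0)
  # two rings at the well pitch: exactly two survive the filters
  two <- make_ring(c(500, 750), 250, 250, 83) |
    (make_ring(c(500, 750), 475, 250, 83))
  d2 <- filter_detections(detect_circles(two), c(500, 750))
  expect_equal(nrow(d2), 2L)
  ord <- order(d2$cx)
  expect_lt(max(abs(d2$cx[ord] - c(250, 475))), 2)
  expect_error(detect_circles(ring, r_min = 90, r_max = 80))
})

test_that("detect_circles is deterministic", {
  ring <- make_ring(c(400, 400), 200, 180, 82)
  expect_identical(detect_circles(ring), detect_circles(ring))
})

test_that("filter_detections applies strength, spacing and containment", {
  det <- data.frame(cx = c(300, 320, 600), cy = c(300, 300, 300),
                    r = 83, strength = c(1000, 100, 900))
  # weak duplicate 20 px away is suppressed (strength filter or spacing)
  f <- filter_detections(det, c(900, 900))
  expect_equal(sort(f$cx), c(300, 600))
  # equal strengths on a proper grid: all kept
  det2 <- data.frame(cx = c(200, 425, 650), cy = 200, r = 83, strength = 500)
  expect_equal(nrow(filter_detections(det2, c(900, 900))), 3L)
  # containment: centre 50 px from the edge with radius 83 is dropped
  det3 <- data.frame(cx = c(50, 450), cy = c(450, 450), r = 83,
                     strength = c(800, 800))
  f3 <- filter_detections(det3, c(900, 900))
  expect_equal(f3$cx, 450)
  # empty input is passed through, not an error
  expect_equal(nrow(filter_detections(det3[0, ], c(900, 900))), 0L)
})

test_that("filter_detections is idempotent", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(3:12, 1)
    det <- data.frame(cx = runif(n, 100, 800), cy = runif(n, 100, 800),
                      r = 83, strength = runif(n, 10, 2000))
    f1 <- filter_detections(det, c(900, 900))
    f2 <- filter_detections(f1, c(900, 900))
    expect_identical(f1, f2)
  }
})

test_that("noise-free phantom wells are detected exactly", {
  # a handful of random layouts here; the 100-layout sweep runs in the
  # acceptance suite
  errs <- c()
  for (s in 1:6) {
    sp <- phantom_spec(image_shape = c(420, 640), seed = 100 + s,
                       noise_sigma = 0,
                       size_class = if (s %% 2) "small" else "large")
    g <- generate_frame(sp, 0L)
    det <- detect_wells(g$frame)
    tw <- g$truth$wells[g$truth$wells$fully_visible, ]
    expect_equal(nrow(det), nrow(tw))
    for (i in seq_len(nrow(tw))) {
      d <- sqrt((det$cx - tw$cx[i])^2 + (det$cy - tw$cy[i])^2)
      errs <- c(errs, min(d))
      expect_lt(min(d), 2)
      expect_lt(abs(det$r[which.min(d)] - tw$r_outer[i]), 2)
    }
  }
  expect_lt(sqrt(mean(errs^2)), 2)  # RMS centre error
})
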