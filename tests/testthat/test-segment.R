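# Well mask, Otsu thresholding, morphology primitives and the per-well
# segmentation chain.

test_that("well_mask follows the closed-disk definition", {
  m <- well_mask(c(80, 80), 75, c(160, 160))
  expect_equal(sum(m), 17665)  # lattice points with dx^2+dy^2 <= 75^2
  # clipping at a corner is silent
  mc <- well_mask(c(1, 1), 10, c(40, 40))
  expect_true(sum(mc) > 0 && sum(mc) < sum(well_mask(c(20, 20), 10, c(40, 40))))
  # half-pixel radius selects the single centre pixel
  expect_equal(sum(well_mask(c(5, 5), 0.5, c(9, 9))), 1)
  expect_true(well_mask(c(5, 5), 0.5, c(9, 9))[5, 5])
})

test_that("otsu_threshold maximises between-class variance", {
  # perfectly bimodal: threshold strictly between the modes, classes pure
  v <- c(rep(0, 50), rep(1, 50))
  ot <- otsu_threshold(v)
  expect_false(ot$degenerate)
  expect_gt(ot$threshold, 0); expect_lt(ot$threshold, 1)
  expect_true(all(v[v <= ot$threshold] == 0), all(v[v > ot$threshold] == 1))
  # two separated Gaussian modes
  set.seed(11)
  v <- pmin(pmax(c(rnorm(4000, 0.3, 0.05), rnorm(4000, 0.7, 0.05)), 0), 1)
  ot <- otsu_threshold(v)
  expect_gt(ot$threshold, 0.3); expect_lt(ot$threshold, 0.7)
  expect_equal(ot$threshold, oracle_otsu(v))
  # degenerate input
  expect_identical(otsu_threshold(rep(0.4, 10)),
                   list(threshold = 0.4, degenerate = TRUE))
  expect_error(otsu_threshold(numeric(0)))
  # random inputs against the exhaustive oracle
  for (s in 1:25) {
    set.seed(s)
    v <- runif(200)
    expect_equal(otsu_threshold(v)$threshold, oracle_otsu(v))
  }
})

blob_at <- function(shape, r0, c0, h, w) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  m
}

test_that("bridge_pixels implements the two-disconnected-groups rule", {
  m <- matrix(FALSE, 3, 3); m[1, 1] <- m[1, 3] <- TRUE
  b <- bridge_pixels(m)
  expect_true(b[1, 2])          # canonical bridge
  expect_true(b[2, 2])          # also sees two disconnected neighbours
  expect_equal(sum(b), 4)
  solid <- blob_at(c(8, 8), 3, 3, 4, 4)
  expect_identical(bridge_pixels(solid), solid)  # convex solids unchanged
  empty <- matrix(FALSE, 5, 5)
  expect_identical(bridge_pixels(empty), empty)
  for (s in 1:20)
    expect_identical(bridge_pixels(random_mask(s, 16, 16)),
                     oracle_bridge(random_mask(s, 16, 16)))
})

test_that("diagonal_fill removes diagonal-only background connectivity", {
  m <- matrix(FALSE, 2, 2); m[1, 1] <- m[2, 2] <- TRUE
  f <- diagonal_fill(m)
  expect_true(all(f))
  # 4-connected line unchanged
  line <- matrix(FALSE, 5, 5); line[3, ] <- TRUE
  expect_identical(diagonal_fill(line), line)
  # 3x3 checkerboard: background 8-connectivity across diagonals eliminated
  cb <- matrix(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
               3, 3)
  f <- diagonal_fill(cb)
  expect_false(has_diagonal_pattern(f))
  # the two background pixels that survive must not be diagonal neighbours
  expect_identical(f, oracle_diagonal_fixpoint(cb))
  for (s in 1:20) {
    m <- random_mask(s, 16, 16, density = 0.3, smooth = FALSE)
    f <- diagonal_fill(m)
    expect_identical(f, oracle_diagonal_fixpoint(m))
    expect_false(has_diagonal_pattern(f))
  }
})

test_that("fill_holes respects the area bound and the border rule", {
  ring <- matrix(FALSE, 20, 20)
  ring[4:17, 4:17] <- TRUE
  ring[5:16, 5:16] <- FALSE   # 144-px hole
  expect_true(all(fill_holes(ring, 150)[4:17, 4:17]))
  big <- matrix(FALSE, 22, 22)
  big[4:19, 4:19] <- TRUE
  big[5:18, 5:18] <- FALSE    # 196-px hole
  expect_identical(fill_holes(big, 150), big)
  expect_true(all(fill_holes(big, Inf)[4:19, 4:19]))
  # boundary-inclusive: hole of exactly max_area is filled
  m <- matrix(FALSE, 7, 12); m[2:6, 2:11] <- TRUE; m[3:5, 3:10] <- FALSE
  expect_equal(sum(!m[3:5, 3:10]), 24)
  expect_true(all(fill_holes(m, 24)[2:6, 2:11]))
  expect_identical(fill_holes(m, 23), m)
  # a border-touching concavity is never a hole
  conc <- matrix(TRUE, 6, 6); conc[1:3, 3] <- FALSE
  expect_identical(fill_holes(conc, Inf), conc)
  for (s in 1:15) {
    m <- random_mask(s, 20, 20)
    expect_identical(fill_holes(m, 10), oracle_fill_holes(m, 10))
    expect_identical(fill_holes(m, Inf), oracle_fill_holes(m, Inf))
  }
})

test_that("erosion and dilation use the Euclidean disk element", {
  sq <- blob_at(c(9, 9), 3, 3, 5, 5)
  er <- mask_erode(sq, 2)
  expect_equal(which(er, arr.ind = TRUE), cbind(row = 5L, col = 5L))
  expect_identical(er, oracle_erode(sq, 2))
  px <- matrix(FALSE, 7, 7); px[4, 4] <- TRUE
  di <- mask_dilate(px, 2)
  expect_equal(sum(di), 13)   # 13-pixel disk at r = 2
  expect_identical(di, oracle_dilate(px, 2))
  # opening is anti-extensive on a large disk
  disk <- well_mask(c(20, 20), 14, c(40, 40))
  op <- mask_dilate(mask_erode(disk, 2), 2)
  expect_true(all(!op | disk))
  expect_gt(sum(op), 0.95 * sum(disk))
  for (s in 1:15) {
    m <- random_mask(s, 18, 18)
    expect_identical(mask_erode(m, 2), oracle_erode(m, 2))
    expect_identical(mask_dilate(m, 2), oracle_dilate(m, 2))
  }
})

test_that("morph_cleanup executes steps i-iv in order", {
  # step i: isolated 30-px object removed before bridging can attach it,
  # isolated 20-px object kept in step i (then removed by the step-iii
  # opening unless connected)
  m <- matrix(FALSE, 60, 110)
  m[10:40, 10:40] <- TRUE                 # main blob
  m[20:25, 44:48] <- TRUE                 # 30 px, 3-px gap: dropped step i
  out <- morph_cleanup(m)
  expect_false(any(out[, 44:48]))
  # a small (<= 25 px) object within bridging distance is merged instead
  m2 <- matrix(FALSE, 60, 110)
  m2[10:40, 10:40] <- TRUE
  m2[20:24, 42:45] <- TRUE                # 20 px, 1-px gap: bridged in ii
  out2 <- morph_cleanup(m2)
  expect_true(any(out2[, 43]))
  # while a >25 px object at the same distance is removed in step i
  m3 <- matrix(FALSE, 60, 110)
  m3[10:40, 10:40] <- TRUE
  m3[18:26, 42:45] <- TRUE                # 36 px, same 1-px gap
  out3 <- morph_cleanup(m3)
  expect_false(any(out3[, 44:45]))
  # holes: 100-px hole filled in step iii, 300-px hole in step iv
  h1 <- matrix(FALSE, 40, 40); h1[5:34, 5:34] <- TRUE
  h1[10:19, 10:19] <- FALSE
  expect_true(all(morph_cleanup(h1)[10:19, 10:19]))
  h2 <- matrix(FALSE, 50, 50); h2[5:44, 5:44] <- TRUE
  h2[10:27, 10:27] <- FALSE  # 324 px
  expect_true(all(morph_cleanup(h2)[10:27, 10:27]))
  # empty input stays empty
  expect_identical(morph_cleanup(matrix(FALSE, 5, 5)), matrix(FALSE, 5, 5))
})

test_that("segment_spheroid output is contained, single and hole-free", {
  sp <- phantom_spec(image_shape = c(420, 420), seed = 7,
                     size_class = "large")
  g <- generate_frame(sp, 0L)
  grad <- roberts_gradient(g$frame)
  tw <- g$truth$wells
  for (i in seq_len(nrow(tw))) {
    sm <- segment_spheroid(g$frame, grad,
                           data.frame(cx = tw$cx[i], cy = tw$cy[i]))
    expect_false(sm$empty_flag)
    # containment in the inner disk
    ctr <- c(tw$cx[i] - sm$offset[2], tw$cy[i] - sm$offset[1])
    wm <- well_mask(ctr, 75, dim(sm$pixels))
    expect_true(all(!sm$pixels | wm))
    # single 8-connected component
    expect_equal(max(label_components(sm$pixels)), 1L)
    # hole-free
    expect_identical(sm$pixels, fill_holes(sm$pixels, Inf))
  }
})

test_that("compact noise-free phantoms are recovered almost exactly", {
  sp <- phantom_spec(image_shape = c(420, 420), seed = 12,
                     noise_sigma = 0, size_class = "small")
  sp$aggregation$rate_per_hour <- Inf  # steady state = compact blobs
  sp$layout <- spheromon:::compile_layout(sp)
  g <- generate_frame(sp, 0L)
  grad <- roberts_gradient(g$frame)
  tw <- g$truth$wells
  for (i in seq_len(nrow(tw))) {
    tm <- g$truth$masks[[as.character(tw$well_id[i])]]
    sm <- segment_spheroid(g$frame, grad,
                           data.frame(cx = tw$cx[i], cy = tw$cy[i]))
    expect_gte(mask_iou(tm, sm), 0.95)
  }
})

test_that("an empty well yields an empty flagged mask", {
  sp <- phantom_spec(image_shape = c(420, 420), seed = 5)
  sp$aggregation$n_fragments <- 0L       # cell-free wells
  sp$layout <- spheromon:::compile_layout(sp)
  g <- generate_frame(sp, 0L)
  grad <- roberts_gradient(g$frame)
  tw <- g$truth$wells
  sm <- segment_spheroid(g$frame, grad,
                         data.frame(cx = tw$cx[1], cy = tw$cy[1]))
  expect_true(sm$empty_flag)
  expect_false(any(sm$pixels))
  expect_true(extract_features(sm)$empty_flag)
})
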