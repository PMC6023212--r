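# Synthetic phantom: determinism, truth containment and self-consistency,
# aggregation kinetics, presets and the four-set validation benchmark.

small_spec <- function(seed = 3, ...) {
  phantom_spec(image_shape = c(200, 200), seed = seed, ...)
}

test_that("the spec validates its invariants", {
  expect_error(phantom_spec(well_inner_radius = 90, well_outer_radius = 83),
               "invariant")
  expect_error(phantom_spec(well_pitch = 160), "invariant")
  expect_error(phantom_spec(noise_sigma = -0.1))
  expect_error(phantom_spec(cell_darkness = 1.2))
  expect_error(phantom_spec(n_frames = 0))
  expect_error(generate_frame(small_spec(), 1L), "out of range")
})

test_that("identical spec and seed give bit-identical output", {
  g1 <- generate_frame(small_spec(seed = 21), 0L)
  g2 <- generate_frame(small_spec(seed = 21), 0L)
  expect_identical(g1$frame$pixels, g2$frame$pixels)
  expect_identical(g1$truth$masks[[1]]$pixels, g2$truth$masks[[1]]$pixels)
  g3 <- generate_frame(small_spec(seed = 22), 0L)
  expect_false(identical(g1$frame$pixels, g3$frame$pixels))
})

test_that("a single-fragment steady-state well renders one clean disk", {
  sp <- small_spec(seed = 5, noise_sigma = 0)
  sp$aggregation$n_fragments <- 1L
  sp$aggregation$rate_per_hour <- Inf
  sp$layout <- spheromon:::compile_layout(sp)
  g <- generate_frame(sp, 0L)
  tm <- g$truth$masks[[1]]
  # truth equals the rendered disk: pixels within lambda * rho of centre
  lay <- sp$layout[[1]]
  st <- spheromon:::well_state(lay, 0)
  half <- lay$half
  gs <- seq(-half, half)
  dd <- sqrt(outer(gs^2, gs^2, "+"))
  expect_identical(tm$pixels, dd <= st$lambda * lay$rho)
  expect_equal(max(label_components(tm$pixels)), 1L)
  # and it is the only dark in-well object: dark pixels outside the rim
  # ring all belong to the truth disk
  px <- g$frame$pixels
  ctr <- c(g$truth$wells$cx[1], g$truth$wells$cy[1])
  wm <- well_mask(ctr, 68, dim(px))
  dark <- px < sp$background_level - 0.5 * sp$cell_darkness & wm
  tr_full <- matrix(FALSE, nrow(px), ncol(px))
  tr_full[tm$offset[1] + seq_len(nrow(tm$pixels)),
          tm$offset[2] + seq_len(ncol(tm$pixels))] <- tm$pixels
  expect_true(all(!dark | tr_full))
})

test_that("truth masks are contained in the inner disk and self-consistent", {
  sp <- phantom_spec(image_shape = c(420, 420), seed = 9,
                     size_class = "large")
  g <- generate_frame(sp, 0L)
  for (w in seq_len(nrow(g$truth$wells))) {
    tw <- g$truth$wells[w, ]
    tm <- g$truth$masks[[as.character(tw$well_id)]]
    idx <- which(tm$pixels, arr.ind = TRUE)
    d <- sqrt((idx[, 2] + tm$offset[2] - tw$cx)^2 +
                (idx[, 1] + tm$offset[1] - tw$cy)^2)
    expect_lte(max(d), sp$well_inner_radius)   # containment
    expect_gt(nrow(idx), 0)                    # non-empty
    # stored truth features equal the features module output, exactly
    ft <- g$truth$features[g$truth$features$well_id == tw$well_id, ]
    fm <- extract_features(tm)
    for (k in names(fm)) expect_identical(ft[[k]], fm[[k]])
  }
})

test_that("aggregation kinetics are monotone toward the steady state", {
  sp <- small_spec(seed = 31, n_frames = 16L, frame_interval = 40)
  tl <- generate_timelapse(sp)
  areas <- vapply(tl$truth, function(tr) tr$features$area_px[1], 0)
  circ <- vapply(tl$truth, function(tr) tr$features$circularity[1], 0)
  # area non-increasing, circularity non-decreasing, within one rendering
  # quantisation step (16 px^2 / 0.02; see the methods vignette)
  expect_true(all(diff(areas) <= 16))
  expect_true(all(diff(circ) >= -0.02))
  expect_gt(areas[1], areas[16])
  expect_lt(circ[1], circ[16])
  # the end state approaches the configured steady state
  lay <- sp$layout[[1]]
  expect_lt(abs(areas[16] - lay$ass) / lay$ass, 0.05)
})

test_that("an infinite rate constant pins every frame at steady state", {
  sp <- small_spec(seed = 8, n_frames = 3L, noise_sigma = 0)
  sp$aggregation$rate_per_hour <- Inf
  sp$layout <- spheromon:::compile_layout(sp)
  tl <- generate_timelapse(sp)
  expect_identical(tl$frames[[1]]$pixels, tl$frames[[2]]$pixels)
  expect_identical(tl$frames[[2]]$pixels, tl$frames[[3]]$pixels)
  expect_identical(tl$truth[[1]]$masks[[1]]$pixels,
                   tl$truth[[3]]$masks[[1]]$pixels)
})

test_that("drift accumulates when enabled and vanishes when zero", {
  sp0 <- small_spec(seed = 4, n_frames = 3L)
  tl0 <- generate_timelapse(sp0)
  cx <- vapply(tl0$truth, function(tr) tr$wells$cx[1], 0)
  cy <- vapply(tl0$truth, function(tr) tr$wells$cy[1], 0)
  expect_true(all(cx == cx[1]) && all(cy == cy[1]))
  spd <- small_spec(seed = 4, n_frames = 3L, drift_per_frame = 2)
  tld <- generate_timelapse(spd)
  cxd <- vapply(tld$truth, function(tr) tr$wells$cx[1], 0)
  cyd <- vapply(tld$truth, function(tr) tr$wells$cy[1], 0)
  step <- sqrt(diff(cxd)^2 + diff(cyd)^2)
  expect_true(all(step > 0))
  expect_true(all(step <= 2 + 1e-9))   # bounded per frame
})

test_that("the reference time-lapse preset matches the protocol", {
  sp <- phantom_preset_timelapse(seed = 2)
  expect_equal(sp$n_frames, 193L)
  expect_equal(sp$frame_interval, 5)
  expect_equal((sp$n_frames - 1) * sp$frame_interval, 960)  # 16 h
  expect_equal(sp$image_shape, c(1532L, 2048L))
  expect_gte(nrow(sp$wells), 50)  # about 60 wells in the field of view
})

test_that("the validation benchmark has four sets of ~60 valid wells", {
  bench <- bench_fixture()
  expect_length(bench, 4L)
  expect_equal(vapply(bench, `[[`, "", "stage"),
               c(`Set 1` = "initial", `Set 2` = "final",
                 `Set 3` = "initial", `Set 4` = "final"))
  for (s in bench) {
    n <- 0L
    for (tr in s$truth) {
      vis <- tr$wells[tr$wells$fully_visible, ]
      for (id in vis$well_id) {
        m <- tr$masks[[as.character(id)]]
        expect_false(m$empty_flag)       # every truth mask non-empty
        n <- n + 1L
      }
    }
    expect_gte(n, 55); expect_lte(n, 65)
  }
  # final-stage sets are rounder than initial-stage sets
  mean_circ <- function(s) {
    v <- unlist(lapply(s$truth, function(tr) tr$features$circularity))
    mean(v, na.rm = TRUE)
  }
  expect_gt(mean_circ(bench[["Set 2"]]), mean_circ(bench[["Set 1"]]))
  expect_gt(mean_circ(bench[["Set 4"]]), mean_circ(bench[["Set 3"]]))
  # steady-state areas cover the stated small/large ranges
  area3 <- unlist(lapply(bench[["Set 2"]]$truth,
                         function(tr) tr$features$area_px))
  expect_gt(min(area3), 2500); expect_lt(max(area3), 8500)
})

test_that("segmentation recovers compact benchmark wells at IoU >= 0.9", {
  bench <- bench_fixture()
  s <- bench[["Set 2"]]
  frame <- s$frames[[1]]; tr <- s$truth[[1]]
  grad <- roberts_gradient(frame)
  tw <- tr$wells[tr$wells$fully_visible, ][1:8, ]
  for (i in seq_len(nrow(tw))) {
    tm <- tr$masks[[as.character(tw$well_id[i])]]
    pm <- segment_spheroid(frame, grad,
                           data.frame(cx = tw$cx[i], cy = tw$cy[i]))
    expect_gte(mask_iou(tm, pm), 0.9)
  }
})

test_that("raising the noise never improves segmentation fidelity", {
  # 5-point noise ladder at fixed seed; mean IoU must be non-increasing up
  # to a small jitter allowance
  ious <- vapply(c(0, 0.005, 0.01, 0.02, 0.04), function(ns) {
    sp <- phantom_spec(image_shape = c(200, 200), seed = 77,
                       noise_sigma = ns)
    g <- generate_frame(sp, 0L)
    grad <- roberts_gradient(g$frame)
    tw <- g$truth$wells
    mask_iou(g$truth$masks[[1]],
             segment_spheroid(g$frame, grad,
                              data.frame(cx = tw$cx[1], cy = tw$cy[1])))
  }, 0)
  expect_true(all(diff(ious) <= 0.005))
  expect_lt(ious[5], ious[1])
})
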