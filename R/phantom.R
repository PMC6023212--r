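## Synthetic bright-field microwell-array phantom with exact ground truth.
##
## The phantom states a complete imaging world: a grid of cylindrical
## microwells (dark rims of irregular thickness on a bright agarose
## background), each containing 0-1 aggregating spheroids rendered as a
## connected union of feathered cell-cluster disks. The union's hole-filled
## support IS the ground-truth mask (emulating a manual rater tracing the
## outer visible edge with a single closed curve), and the material darkness
## feathers to zero exactly at that support, so image evidence and truth
## coincide. Aggregation follows a first-order exponential approach to a
## stated steady state: fragment centres contract towards the well centre by
## a constant fraction per frame while a per-frame radius scale is solved
## (monotone bisection on the rendered truth area) so the true area tracks
## the exponential target exactly up to pixel quantisation.

#' Phantom specification
#'
#' Describes a synthetic microwell-array acquisition. Geometry defaults
#' follow the reference setup: 200-um wells (150 px inner diameter, i.e.
#' 0.75 px/um) at 300-um pitch (225 px), rim outer radius 83 px.
#'
#' @param image_shape integer `c(rows, cols)` of every frame.
#' @param n_frames number of frames (193 for the reference 16-h protocol).
#' @param frame_interval minutes between frames (default 5).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @param well_pitch centre-to-centre well spacing, px.
#' @param well_inner_radius,well_outer_radius rim inner/outer radius, px.
#' @param rim_darkness intensity drop of the rim annulus, in `[0, 1]`.
#' @param background_level agarose background intensity, in `[0, 1]`.
#' @param cell_darkness peak intensity drop of cellular material.
#' @param edge_feather width (px) over which cell darkness ramps from full
#'   to zero, measured inward from the truth boundary.
#' @param rim_feather rim edge ramp width, px.
#' @param rim_wobble amplitude (px) of the sinusoidal rim-thickness
#'   irregularity.
#' @param noise_sigma SD of additive Gaussian intensity noise.
#' @param blur_sigma Gaussian optical blur SD, px.
#' @param shading_amp amplitude of the linear shading ramp across the field.
#' @param drift_per_frame magnitude (px) of the per-frame global stage
#'   drift (cumulative over time; 0 disables drift).
#' @param wells optional data frame `well_id, cx0, cy0` of base well
#'   centres; by default a centred grid of fully visible wells is laid out.
#' @param aggregation optional per-well aggregation parameters: data frame
#'   with columns `well_id, n_fragments, scatter0, steady_area,
#'   steady_circularity, rate_per_hour` (see
#'   [aggregation_defaults()]); `n_fragments = 0` leaves a well empty.
#' @param size_class `"small"` or `"large"`; sets the default aggregation
#'   parameter ranges (spheroids of ~100 vs ~250 cells).
#' @return An object of class `phantom_spec` with the per-well fragment
#'   layouts compiled in.
#' @export
phantom_spec <- function(image_shape = c(1090, 1315),
                         n_frames = 1L, frame_interval = 5, seed = 1L,
                         well_pitch = 225, well_inner_radius = 75,
                         well_outer_radius = 83,
                         rim_darkness = 0.45, background_level = 0.82,
                         cell_darkness = 0.26, edge_feather = 7,
                         rim_feather = 1.5, rim_wobble = 2,
                         noise_sigma = 0.004, blur_sigma = 0.5,
                         shading_amp = 0.02, drift_per_frame = 0,
                         wells = NULL, aggregation = NULL,
                         size_class = c("small", "large")) {
  size_class <- match.arg(size_class)
  if (!(well_inner_radius < well_outer_radius &&
        well_outer_radius < well_pitch / 2))
    stop("geometry invariant violated: need inner < outer < pitch/2")
  for (v in c(rim_darkness, background_level, cell_darkness, shading_amp))
    if (v < 0 || v > 1) stop("intensity parameters must lie in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (is.null(wells))
    wells <- well_grid(image_shape, well_pitch, well_outer_radius)
  if (is.null(aggregation))
    aggregation <- aggregation_defaults(nrow(wells), size_class,
                                        derive_seed(seed, 11L))
  if (nrow(aggregation) != nrow(wells))
    stop("`aggregation` must have one row per well")
  aggregation$well_id <- wells$well_id
  spec <- structure(
    list(image_shape = as.integer(image_shape), n_frames = as.integer(n_frames),
         frame_interval = frame_interval, seed = as.integer(seed),
         well_pitch = well_pitch, well_inner_radius = well_inner_radius,
         well_outer_radius = well_outer_radius, rim_darkness = rim_darkness,
         background_level = background_level, cell_darkness = cell_darkness,
         edge_feather = edge_feather, rim_feather = rim_feather,
         rim_wobble = rim_wobble, noise_sigma = noise_sigma,
         blur_sigma = blur_sigma, shading_amp = shading_amp,
         drift_per_frame = drift_per_frame, wells = wells,
         aggregation = aggregation),
    class = "phantom_spec")
  spec$layout <- compile_layout(spec)
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %dx%d px, %d wells, %d frame(s) @ %g",
                     " min, seed %d\n"),
              x$image_shape[1], x$image_shape[2], nrow(x$wells), x$n_frames,
              x$frame_interval, x$seed))
  invisible(x)
}

# centred grid of wells whose rims fit completely inside the frame
well_grid <- function(image_shape, pitch, outer_radius, margin = 8) {
  lim <- outer_radius + margin
  nr <- floor((image_shape[1] - 2 * lim) / pitch) + 1
  nc <- floor((image_shape[2] - 2 * lim) / pitch) + 1
  if (nr < 1 || nc < 1) stop("image too small for a single well")
  y0 <- (image_shape[1] - (nr - 1) * pitch) / 2
  x0 <- (image_shape[2] - (nc - 1) * pitch) / 2
  g <- expand.grid(gy = seq_len(nr) - 1, gx = seq_len(nc) - 1)
  data.frame(well_id = seq_len(nrow(g)),
             cx0 = x0 + g$gx * pitch, cy0 = y0 + g$gy * pitch)
}

#' Default per-well aggregation parameters
#'
#' Draws steady-state areas from the stated validation ranges
#' (3000-8000 px^2 for small-sized spheroids, 5000-12000 px^2 for
#' large-sized ones), first-order rate constants of 0.3-0.8 per hour (so
#' aggregation reaches steady state well within the 16-h protocol),
#' steady-state circularities of 0.68-0.85, and fragment counts matching
#' loose multi-cellular masses (more fragments for larger spheroids).
#'
#' @param n_wells number of wells.
#' @param size_class `"small"` or `"large"`.
#' @param seed integer seed.
#' @return A data frame with one row per well.
#' @export
aggregation_defaults <- function(n_wells, size_class = c("small", "large"),
                                 seed = 1L) {
  size_class <- match.arg(size_class)
  with_seed(seed, {
    steady_area <- if (size_class == "small") runif(n_wells, 3000, 8000)
                   else runif(n_wells, 5000, 12000)
    data.frame(
      well_id = seq_len(n_wells),
      n_fragments = sample(if (size_class == "small") 8:14 else 14:22,
                           n_wells, replace = TRUE),
      steady_area = steady_area,
      # loose initial masses cannot exceed the well capacity: densely
      # seeded wells start near-compact and mostly change shape
      initial_area = pmax(steady_area, pmin(1.45 * steady_area, 10800)),
      steady_circularity = runif(n_wells, 0.68, 0.85),
      rate_per_hour = runif(n_wells, 0.3, 0.8),
      n_debris = sample(0:2, n_wells, replace = TRUE))
  })
}

## ---- fragment layout -------------------------------------------------

# maximum extent of cellular material from the well centre; leaves a gap to
# the (wobbling) inner rim so masses never touch the rim
well_content_radius <- function(spec) {
  spec$well_inner_radius - spec$rim_wobble - 7
}

# place n fragments as a random connected tree in unit-radius coordinates
place_fragments <- function(n, seed) {
  with_seed(seed, {
    u <- runif(n, 0.6, 1)          # relative fragment radii
    px <- py <- numeric(n)
    for (j in seq_len(n)[-1]) {
      i <- if (j == 2L) 1L else sample(j - 1L, 1L)
      a <- runif(1, 0, 2 * pi)
      d <- 0.78 * (u[i] + u[j]) * runif(1, 0.9, 1.1)
      px[j] <- px[i] + d * cos(a)
      py[j] <- py[i] + d * sin(a)
    }
    list(px = px - mean(px), py = py - mean(py), u = u)
  })
}

# distance field helper: Q[p] = min_j dist(p, c_j) / rho_j over a crop grid
# centred on the well; union(lambda) == (Q <= lambda)
fragment_q <- function(fx, fy, rho, half) {
  gs <- seq(-half, half)
  n <- length(gs)
  q <- matrix(Inf, n, n)
  xx <- matrix(gs, n, n, byrow = TRUE)
  yy <- matrix(gs, n, n)
  for (j in seq_along(fx))
    q <- pmin(q, sqrt((xx - fx[j])^2 + (yy - fy[j])^2) / rho[j])
  q
}

truth_from_q <- function(q, lambda) fill_holes(q <= lambda, Inf)

# bisect lambda so that the filled-union area matches `target`
solve_lambda <- function(q, target, lambda_max) {
  lo <- 0.02; hi <- lambda_max
  if (sum(truth_from_q(q, hi)) <= target) return(hi)
  if (sum(truth_from_q(q, lo)) >= target) return(lo)
  for (i in 1:18) {
    mid <- (lo + hi) / 2
    if (sum(truth_from_q(q, mid)) <= target) lo <- mid else hi <- mid
  }
  lo  # largest tested scale with area <= target
}

# per-well compiled state: fragment layout in px, steady-state scatter
compile_layout <- function(spec) {
  rmax <- well_content_radius(spec)
  lapply(seq_len(nrow(spec$wells)), function(w) {
    ag <- spec$aggregation[w, ]
    if (ag$n_fragments < 1)
      return(list(empty = TRUE, n_debris = ag$n_debris,
                  debris = place_debris(spec, w, 0)))
    lseed <- derive_seed(spec$seed, 1000L + w)
    pl <- place_fragments(ag$n_fragments, lseed)
    # scale so the loose mass spans its initial scatter radius
    scatter0 <- max(12, min(sqrt(ag$initial_area / (pi * 0.58)), rmax - 6))
    ext <- max(sqrt(pl$px^2 + pl$py^2) + pl$u)
    g <- scatter0 / ext
    fx <- pl$px * g; fy <- pl$py * g
    rho <- pl$u * g * 0.72
    # clamp so every fragment disk stays inside the content radius with a
    # scale margin
    rad <- sqrt(fx^2 + fy^2)
    over <- rad + 1.35 * rho > rmax
    if (any(over)) {
      sc <- pmin(1, (rmax - 1.35 * rho[over]) / rad[over])
      fx[over] <- fx[over] * sc; fy[over] <- fy[over] * sc
    }
    half <- ceiling(rmax) + 4
    q <- fragment_q(fx, fy, rho, half)
    lambda_max <- min((rmax - rad) / rho)
    lam0 <- solve_lambda(q, ag$initial_area, lambda_max)
    a0 <- sum(truth_from_q(q, lam0))     # achieved initial area
    ass <- min(ag$steady_area, a0)       # area must not grow over time
    # steady-state scatter: bisect the contraction that delivers the stated
    # steady circularity at the stated steady area
    sss <- solve_steady_scatter(fx, fy, rho, half, ass,
                                ag$steady_circularity, rmax)
    list(empty = FALSE, fx = fx, fy = fy, rho = rho, half = half,
         lambda_max = lambda_max, a0 = a0, ass = ass, sss = sss,
         rate = ag$rate_per_hour,
         debris = place_debris(spec, w, scatter0))
  })
}

# circularity of the steady-state mass as a function of residual scatter s
steady_circ_at <- function(fx, fy, rho, half, area, s, rmax) {
  q <- fragment_q(fx * s, fy * s, rho, half)
  lmax <- min((rmax - s * sqrt(fx^2 + fy^2)) / rho)
  m <- truth_from_q(q, solve_lambda(q, area, lmax))
  4 * pi * sum(m) / perimeter_length(largest_component(m))^2
}

solve_steady_scatter <- function(fx, fy, rho, half, area, target, rmax) {
  lo <- 0.04; hi <- 0.85
  if (steady_circ_at(fx, fy, rho, half, area, lo, rmax) <= target) return(lo)
  if (steady_circ_at(fx, fy, rho, half, area, hi, rmax) >= target) return(hi)
  for (i in 1:7) {
    mid <- (lo + hi) / 2
    if (steady_circ_at(fx, fy, rho, half, area, mid, rmax) >= target)
      lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# fixed debris (stray single cells outside the truth mass): positions in
# well-local px, radius in px
place_debris <- function(spec, w, scatter0) {
  ag <- spec$aggregation[w, ]
  nd <- if (is.null(ag$n_debris)) 0L else ag$n_debris
  if (nd < 1) return(NULL)
  rmax <- well_content_radius(spec)
  with_seed(derive_seed(spec$seed, 5000L + w), {
    rr <- runif(nd, 2.5, 4)
    lo <- scatter0 + 9
    if (lo > rmax - max(rr) - 1) return(NULL)
    d <- runif(nd, lo, rmax - max(rr) - 1)
    a <- runif(nd, 0, 2 * pi)
    data.frame(x = d * cos(a), y = d * sin(a), r = rr)
  })
}

## ---- kinetics --------------------------------------------------------

# exponential-approach factor u(t) = exp(-k t); for an infinite rate the
# well is at steady state in every frame (the t = 0 limit is taken as 0)
kinetic_u <- function(rate_per_hour, t_min) {
  if (is.infinite(rate_per_hour)) return(0)
  exp(-rate_per_hour * t_min / 60)
}

# aggregation state of one well at time t: scatter scale and radius scale
well_state <- function(lay, t_min) {
  u <- kinetic_u(lay$rate, t_min)
  s <- lay$sss + (1 - lay$sss) * u
  target <- lay$ass + (lay$a0 - lay$ass) * u
  q <- fragment_q(lay$fx * s, lay$fy * s, lay$rho, lay$half)
  lmax <- min((well_content_radius_from_half(lay$half) -
                 s * sqrt(lay$fx^2 + lay$fy^2)) / lay$rho)
  lambda <- solve_lambda(q, target, lmax)
  list(s = s, lambda = lambda, q = q)
}

well_content_radius_from_half <- function(half) half - 4

## ---- rendering -------------------------------------------------------

# separable Gaussian blur, kernel truncated at 3 sigma
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_pass <- function(m, horizontal) {
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      d <- i - r - 1L
      s <- if (horizontal) shift_num_edge(m, 0, d) else shift_num_edge(m, d, 0)
      out <- out + k[i] * s
    }
    out
  }
  blur_pass(blur_pass(m, TRUE), FALSE)
}

# shift with replicated (clamped) edges, used by the blur
shift_num_edge <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  rs <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  cs <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[rs, cs, drop = FALSE]
}

# cumulative stage drift offsets (x, y) for a frame index (0-based)
drift_offset <- function(spec, frame_index) {
  if (spec$drift_per_frame <= 0 || frame_index == 0)
    return(c(0, 0))
  ang <- with_seed(derive_seed(spec$seed, 700001L),
                   runif(spec$n_frames, 0, 2 * pi))
  steps <- spec$drift_per_frame *
    with_seed(derive_seed(spec$seed, 700002L),
              runif(spec$n_frames, 0.5, 1))
  idx <- seq_len(frame_index)
  c(sum(steps[idx] * cos(ang[idx])), sum(steps[idx] * sin(ang[idx])))
}

#' Generate one phantom frame with its ground truth
#'
#' Renders the bright background, dark rims of sinusoidally irregular
#' thickness, and the cellular material of every well at the aggregation
#' state for this time point; applies Gaussian blur, a linear shading ramp
#' and additive Gaussian noise (clipped to `[0, 1]`). The matching truth
#' slice carries the true well centres/radii, per-well truth masks and the
#' truth features computed with [extract_features()] on those masks.
#'
#' @param spec a [phantom_spec()].
#' @param frame_index 0-based frame index, `< n_frames`.
#' @return A list with elements `frame` ([new_frame()]) and `truth` (list
#'   `wells`, `masks`, `features`).
#' @export
generate_frame <- function(spec, frame_index = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (frame_index < 0 || frame_index >= spec$n_frames)
    stop("frame_index out of range")
  t_min <- frame_index * spec$frame_interval
  sh <- spec$image_shape
  off <- drift_offset(spec, frame_index)
  img <- matrix(spec$background_level, sh[1], sh[2])
  wells <- spec$wells
  wells$cx <- wells$cx0 + off[1]
  wells$cy <- wells$cy0 + off[2]
  wells$r_inner <- spec$well_inner_radius
  wells$r_outer <- spec$well_outer_radius
  wells$fully_visible <-
    wells$cx - spec$well_outer_radius >= 0.5 &
    wells$cx + spec$well_outer_radius <= sh[2] + 0.5 &
    wells$cy - spec$well_outer_radius >= 0.5 &
    wells$cy + spec$well_outer_radius <= sh[1] + 0.5
  masks <- list()
  feats <- list()
  for (w in seq_len(nrow(wells))) {
    lay <- spec$layout[[w]]
    res <- render_well(spec, lay, w, wells$cx[w], wells$cy[w], t_min, sh)
    if (!is.null(res$sub)) {
      img[res$rows, res$cols] <-
        pmin(img[res$rows, res$cols, drop = FALSE], res$sub)
    }
    if (wells$fully_visible[w]) {
      wid <- as.character(wells$well_id[w])
      masks[[wid]] <- res$truth
      fr <- extract_features(res$truth)
      fr <- cbind(data.frame(well_id = wells$well_id[w]), fr)
      feats[[wid]] <- fr
    }
  }
  img <- gaussian_blur(img, spec$blur_sigma)
  xx <- matrix(seq_len(sh[2]) / sh[2] - 0.5, sh[1], sh[2], byrow = TRUE)
  img <- img + spec$shading_amp * xx
  if (spec$noise_sigma > 0) {
    img <- img + matrix(
      with_seed(derive_seed(spec$seed, 90000L + frame_index),
                rnorm(prod(sh), 0, spec$noise_sigma)), sh[1], sh[2])
  }
  img <- pmin(pmax(img, 0), 1)
  list(frame = new_frame(img, frame_index, t_min),
       truth = list(wells = wells, masks = masks,
                    features = do.call(rbind, feats)))
}

# render the rim and contents of one well into a local crop; returns the
# crop (as a darkness "min" layer), its frame indices, and the truth mask
render_well <- function(spec, lay, w, cx, cy, t_min, sh) {
  pad <- ceiling(spec$well_outer_radius + spec$rim_wobble +
                   spec$rim_feather + 3)
  r0 <- floor(cy) - pad; r1 <- ceiling(cy) + pad
  c0 <- floor(cx) - pad; c1 <- ceiling(cx) + pad
  if (r1 < 1 || c1 < 1 || r0 > sh[1] || c0 > sh[2])
    return(list(sub = NULL, truth = NULL))
  rr0 <- max(1L, r0); rr1 <- min(sh[1], r1)
  cc0 <- max(1L, c0); cc1 <- min(sh[2], c1)
  rows <- rr0:rr1; cols <- cc0:cc1
  yy <- matrix(rows - cy, length(rows), length(cols))
  xx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  rho <- sqrt(xx^2 + yy^2)
  th <- atan2(yy, xx)
  ph <- with_seed(derive_seed(spec$seed, 3000L + w), runif(2, 0, 2 * pi))
  sub <- matrix(spec$background_level, length(rows), length(cols))
  # rim annulus with irregular thickness
  rin <- spec$well_inner_radius + spec$rim_wobble * sin(3 * th + ph[1])
  rout <- spec$well_outer_radius + 0.5 * spec$rim_wobble * sin(5 * th + ph[2])
  f <- spec$rim_feather
  mrim <- pmin(pmax((rho - rin) / f, 0), 1) * pmin(pmax((rout - rho) / f, 0), 1)
  sub <- sub - spec$rim_darkness * mrim
  truth <- NULL
  if (!lay$empty) {
    st <- well_state(lay, t_min)
    m <- matrix(0, length(rows), length(cols))
    for (j in seq_along(lay$fx)) {
      d <- sqrt((xx - st$s * lay$fx[j])^2 + (yy - st$s * lay$fy[j])^2)
      rj <- st$lambda * lay$rho[j]
      fj <- min(spec$edge_feather, 0.6 * rj)
      m <- pmax(m, pmin(pmax((rj - d) / fj, 0), 1))
    }
    sub <- sub - spec$cell_darkness * m
    tm <- truth_mask_for(lay, st, cx, cy)
    truth <- tm
  } else {
    truth <- structure(
      list(pixels = matrix(FALSE, 1, 1),
           offset = c(as.integer(round(cy)) - 1L, as.integer(round(cx)) - 1L),
           center = c(cx, cy), empty_flag = TRUE, degenerate_otsu = FALSE),
      class = "spheromon_mask")
  }
  # debris (not part of the truth)
  if (!is.null(lay$debris)) {
    for (j in seq_len(nrow(lay$debris))) {
      d <- sqrt((xx - lay$debris$x[j])^2 + (yy - lay$debris$y[j])^2)
      rj <- lay$debris$r[j]
      md <- pmin(pmax((rj - d) / min(1.5, 0.6 * rj), 0), 1)
      sub <- pmin(sub, spec$background_level - 0.85 * spec$cell_darkness * md)
    }
  }
  list(sub = sub, rows = rows, cols = cols, truth = truth)
}

# truth mask of one well as a spheromon_mask in frame coordinates
truth_mask_for <- function(lay, st, cx, cy) {
  half <- lay$half
  gs <- seq(-half, half)
  m <- truth_from_q(st$q, st$lambda)
  # place the crop grid (well-local integer offsets) at the nearest frame
  # pixels; sub-pixel well centres shift the sampled distances accordingly
  cxr <- round(cx); cyr <- round(cy)
  if (abs(cx - cxr) > 1e-9 || abs(cy - cyr) > 1e-9) {
    n <- length(gs)
    xx <- matrix(gs + (cxr - cx), n, n, byrow = TRUE)
    yy <- matrix(gs + (cyr - cy), n, n)
    q <- matrix(Inf, n, n)
    for (j in seq_along(lay$fx))
      q <- pmin(q, sqrt((xx - st$s * lay$fx[j])^2 +
                          (yy - st$s * lay$fy[j])^2) / lay$rho[j])
    m <- truth_from_q(q, st$lambda)
  }
  structure(
    list(pixels = m, offset = c(as.integer(cyr) - half - 1L,
                                as.integer(cxr) - half - 1L),
         center = c(cx, cy), empty_flag = !any(m), degenerate_otsu = FALSE),
    class = "spheromon_mask")
}

#' Generate a phantom time-lapse
#'
#' @param spec a [phantom_spec()].
#' @return A list with `frames` (list of [new_frame()]) and `truth` (list of
#'   per-frame truth slices as in [generate_frame()]).
#' @export
generate_timelapse <- function(spec) {
  out <- lapply(seq_len(spec$n_frames) - 1L,
                function(i) generate_frame(spec, i))
  list(frames = lapply(out, `[[`, "frame"),
       truth = lapply(out, `[[`, "truth"))
}

#' Reference time-lapse preset
#'
#' The stated acquisition protocol: 193 frames at a 5-minute interval
#' (16 hours), full-size 1532 x 2048 frames with a 6 x 9 grid of wells at
#' 225-px pitch, and a slight cumulative stage drift.
#'
#' @param seed integer seed.
#' @param image_shape frame size; the default matches the reference camera.
#' @return A [phantom_spec()].
#' @export
phantom_preset_timelapse <- function(seed = 1L,
                                     image_shape = c(1532, 2048)) {
  phantom_spec(image_shape = image_shape, n_frames = 193L,
               frame_interval = 5, seed = seed, drift_per_frame = 0.4,
               size_class = "small")
}

#' Four-set validation benchmark
#'
#' Generates the synthetic counterpart of the four validation sets used for
#' quantitative assessment: initial (Set 1) and final (Set 2) small-sized
#' spheroids, initial (Set 3) and final (Set 4) large-sized spheroids,
#' each with about 60 wells (two 30-well frames). "Initial" sets are
#' rendered at the start of aggregation (loose, low-contrast,
#' multi-fragment masses with holes and notches); "final" sets at steady
#' state (compact near-circular blobs), obtained by taking the rate
#' constant to infinity.
#'
#' @param seed integer seed.
#' @param wells_per_frame,frames_per_set set size controls (default 2
#'   frames x 30 wells = 60 wells per set).
#' @return A list of four sets, each a list with `label`, `stage`, `size`,
#'   `frames` and `truth` (as in [generate_timelapse()]).
#' @export
validation_benchmark <- function(seed = 20180628L, wells_per_frame = 30L,
                                 frames_per_set = 2L) {
  shape <- c(1090, 1315)  # 5 x 6 grid of wells at 225-px pitch
  sets <- list(
    list(label = "Set 1", size = "small", stage = "initial"),
    list(label = "Set 2", size = "small", stage = "final"),
    list(label = "Set 3", size = "large", stage = "initial"),
    list(label = "Set 4", size = "large", stage = "final"))
  out <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    frames <- list(); truth <- list()
    for (f in seq_len(frames_per_set)) {
      sp <- phantom_spec(image_shape = shape, n_frames = 1L,
                         seed = derive_seed(seed, i * 100L + f),
                         size_class = s$size)
      if (nrow(sp$wells) != wells_per_frame)
        warning("unexpected well count in benchmark frame")
      if (s$stage == "final") {
        sp$aggregation$rate_per_hour <- Inf
        sp$layout <- compile_layout(sp)
      }
      g <- generate_frame(sp, 0L)
      frames[[f]] <- g$frame
      truth[[f]] <- g$truth
    }
    c(s, list(frames = frames, truth = truth))
  })
  names(out) <- vapply(out, `[[`, "", "label")
  out
}
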