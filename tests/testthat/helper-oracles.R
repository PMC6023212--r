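# Independent brute-force oracles. These re-derive every operation from its
# definition with naive algorithms (per-pixel loops, BFS), sharing no code
# with the package implementations they check.

oracle_roberts <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  at <- function(r, c) if (r >= 1 && r <= nr && c >= 1 && c <= nc) img[r, c] else 0
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    gx <- at(r, c) - at(r + 1, c + 1)
    gy <- at(r + 1, c) - at(r, c + 1)
    out[r, c] <- sqrt(gx^2 + gy^2)
  }
  out
}

oracle_erode <- function(mask, disk_r) {
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- ceiling(disk_r)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    ok <- TRUE
    for (dr in -rr:rr) for (dc in -rr:rr) {
      if (dr^2 + dc^2 > disk_r^2) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !mask[r2, c2]) ok <- FALSE
    }
    out[r, c] <- ok
  }
  out
}

oracle_dilate <- function(mask, disk_r) {
  nr <- nrow(mask); nc <- ncol(mask)
  rr <- ceiling(disk_r)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    for (dr in -rr:rr) for (dc in -rr:rr) {
      if (dr^2 + dc^2 > disk_r^2) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) out[r2, c2] <- TRUE
    }
  }
  out
}

# BFS connected-component labelling (order-free; compare as partitions)
oracle_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  nbr <- if (connectivity == 8L)
    cbind(c(-1,-1,-1,0,0,1,1,1), c(-1,0,1,-1,1,-1,0,1))
  else cbind(c(-1,1,0,0), c(0,0,-1,1))
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r, c)); lab[r, c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        r2 <- p[1] + nbr[k, 1]; c2 <- p[2] + nbr[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- cur
          queue <- c(queue, list(c(r2, c2)))
        }
      }
    }
  }
  lab
}

oracle_fill_holes <- function(mask, max_area = Inf) {
  lab <- oracle_label(!mask, 4L)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(mask), ], lab[, 1], lab[, ncol(mask)]))
  out <- mask
  for (l in seq_len(max(lab))) {
    if (l %in% border) next
    if (sum(lab == l) <= max_area) out[lab == l] <- TRUE
  }
  out
}

# bridge predicate evaluated per pixel with an explicit neighbourhood graph
oracle_bridge <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  off <- cbind(c(0,-1,-1,-1,0,1,1,1), c(-1,-1,0,1,1,1,0,-1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c]) next
    pts <- list()
    for (k in 1:8) {
      r2 <- r + off[k, 1]; c2 <- c + off[k, 2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && mask[r2, c2])
        pts <- c(pts, list(c(off[k, 1], off[k, 2])))
    }
    if (length(pts) < 2) next
    # count 8-connected groups among the foreground neighbours by BFS
    n <- length(pts)
    seen <- rep(FALSE, n); groups <- 0L
    for (i in seq_len(n)) {
      if (seen[i]) next
      groups <- groups + 1L
      q <- i; seen[i] <- TRUE
      while (length(q)) {
        a <- q[1]; q <- q[-1]
        for (b in seq_len(n)) {
          if (!seen[b] && max(abs(pts[[a]] - pts[[b]])) <= 1) {
            seen[b] <- TRUE; q <- c(q, b)
          }
        }
      }
    }
    if (groups >= 2L) out[r, c] <- TRUE
  }
  out
}

# one simultaneous diagonal-fill sweep from the definition
oracle_diagonal_sweep <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (r in seq_len(nr - 1)) for (c in seq_len(nc - 1)) {
    b <- mask[r:(r + 1), c:(c + 1)]
    if (b[1, 1] && b[2, 2] && !b[1, 2] && !b[2, 1])
      out[r, c + 1] <- out[r + 1, c] <- TRUE
    if (b[1, 2] && b[2, 1] && !b[1, 1] && !b[2, 2])
      out[r, c] <- out[r + 1, c + 1] <- TRUE
  }
  out
}

oracle_diagonal_fixpoint <- function(mask) {
  repeat {
    nxt <- oracle_diagonal_sweep(mask)
    if (identical(nxt, mask)) return(mask)
    mask <- nxt
  }
}

has_diagonal_pattern <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  for (r in seq_len(nr - 1)) for (c in seq_len(nc - 1)) {
    b <- mask[r:(r + 1), c:(c + 1)]
    if ((b[1, 1] && b[2, 2] && !b[1, 2] && !b[2, 1]) ||
        (b[1, 2] && b[2, 1] && !b[1, 1] && !b[2, 2])) return(TRUE)
  }
  FALSE
}

oracle_otsu <- function(values, bins = 256L) {
  lo <- min(values); hi <- max(values)
  if (lo == hi) return(lo)
  edges <- seq(lo, hi, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(values, edges, all.inside = TRUE), 1L), bins)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  best <- -Inf; bt <- NA
  for (k in seq_len(bins - 1L)) {
    in1 <- idx <= k
    n1 <- sum(in1); n2 <- length(values) - n1
    if (n1 == 0 || n2 == 0) next
    m1 <- sum(mids[idx[in1]]) / n1
    m2 <- sum(mids[idx[!in1]]) / n2
    sb <- (n1 / length(values)) * (n2 / length(values)) * (m1 - m2)^2
    if (sb > best + 1e-15) { best <- sb; bt <- edges[k + 1L] }
  }
  bt
}

# moments-ellipse axes straight from the pixel list via eigen()
oracle_axes <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  xs <- idx[, 2]; ys <- idx[, 1]
  cov <- stats::cov(cbind(xs, ys)) * (length(xs) - 1) / length(xs) +
    diag(2) / 12
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values)
  c(minor = 4 * sqrt(max(0, ev[1])), major = 4 * sqrt(ev[2]))
}

# independent Moore walk for the chain perimeter, written over a padded
# matrix with direction bookkeeping via complex numbers
oracle_perimeter <- function(mask) {
  if (!any(mask)) return(0)
  lab <- oracle_label(mask, 8L)
  dirs <- c(-1i, -1 - 1i, -1 + 0i, -1 + 1i, 1i, 1 + 1i, 1 + 0i, 1 - 1i)
  # dirs as complex: real = dr, imag = dc; order W NW N NE E SE S SW
  dirs <- complex(real = c(0, -1, -1, -1, 0, 1, 1, 1),
                  imaginary = c(-1, -1, 0, 1, 1, 1, 0, -1))
  total <- 0
  for (l in seq_len(max(lab))) {
    comp <- lab == l
    n <- sum(comp)
    if (n == 1L) { total <- total + 4; next }
    pad <- matrix(FALSE, nrow(comp) + 2, ncol(comp) + 2)
    pad[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)] <- comp
    idx <- which(t(pad))[1]
    start <- complex(real = (idx - 1) %/% ncol(pad) + 1,
                     imaginary = (idx - 1) %% ncol(pad) + 1)
    fg <- function(z) pad[Re(z), Im(z)]
    cur <- start; back <- 1L
    first_p <- NULL; first_d <- NULL
    len <- 0; caps <- 0; prev_d <- NULL; d_list <- c()
    repeat {
      found <- FALSE
      for (k in 1:8) {
        di <- ((back - 1 + k) %% 8) + 1
        p <- cur + dirs[di]
        if (fg(p)) { found <- TRUE; break }
      }
      if (!found) { len <- 4; break }
      if (is.null(first_p)) { first_p <- cur; first_d <- di }
      else if (cur == first_p && di == first_d) break
      d_list <- c(d_list, di)
      back <- which(dirs == (cur - p))
      cur <- p
    }
    if (length(d_list)) {
      w <- ifelse(d_list %% 2 == 1, 1, sqrt(2))
      prev <- d_list[c(length(d_list), seq_len(length(d_list) - 1))]
      caps <- sum(d_list == ((prev + 3) %% 8) + 1)
      total <- total + sum(w) + caps
    } else total <- total + 4
  }
  total
}

# random blob masks for property tests
random_mask <- function(seed, nr = 32, nc = 32, density = 0.35,
                        smooth = TRUE) {
  set.seed(seed)
  m <- matrix(runif(nr * nc) < density, nr, nc)
  if (smooth) {
    # thicken a little so masks contain blobs, holes and filaments
    m <- m | spheromon:::shift_mask(m, 0, 1) | spheromon:::shift_mask(m, 1, 0)
  }
  m
}

# shared, lazily built benchmark fixture (reused by phantom + acceptance
# tests so the expensive generation happens once per test run)
fixture_env <- new.env()

bench_fixture <- function() {
  if (is.null(fixture_env$bench))
    fixture_env$bench <- validation_benchmark(seed = 20180628L)
  fixture_env$bench
}

validation_fixture <- function() {
  if (is.null(fixture_env$val))
    fixture_env$val <- run_validation(bench_fixture())
  fixture_env$val
}
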