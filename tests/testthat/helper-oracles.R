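# Independent brute-force oracles, deliberately written with explicit loops
# and queues so they share no code path with the implementation.

# Connected-component labelling by explicit BFS flood fill.
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 8) {
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
         c(1, -1), c(1, 0), c(1, 1))
  } else {
    list(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  }
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] && lab[r, c] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(r, c))
      lab[r, c] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (o in offs) {
          rr <- p[1] + o[1]; cc <- p[2] + o[2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            queue <- c(queue, list(c(rr, cc)))
          }
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition of foreground pixels.
same_partition <- function(a, b) {
  fa <- a > 0; fb <- b > 0
  if (!identical(fa, fb)) return(FALSE)
  ia <- a[fa]; ib <- b[fb]
  identical(as.integer(match(ia, unique(ia))),
            as.integer(match(ib, unique(ib))))
}

# Pixel-edge perimeter by explicit per-pixel edge counting.
oracle_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  total <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c]) {
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]) {
          total <- total + 1L
        }
      }
    }
  }
  total
}

# Mean over masked pixels by explicit loop.
oracle_masked_mean <- function(px, mask) {
  s <- 0; n <- 0L
  for (r in seq_len(nrow(px))) for (c in seq_len(ncol(px))) {
    if (mask[r, c]) { s <- s + px[r, c]; n <- n + 1L }
  }
  s / n
}

# AUC via the midpoint rule on the linear interpolant (exact for a
# piecewise-linear function, so it equals the trapezoid area analytically).
oracle_auc <- function(values, days) {
  f <- stats::approxfun(days, values)
  mids <- (utils::head(days, -1) + utils::tail(days, -1)) / 2
  sum(diff(days) * f(mids))
}

# Branch points via a pixel adjacency graph: merged nodes of degree >= 3.
oracle_branch_points <- function(S) {
  idx <- which(S)
  if (length(idx) == 0) return(0L)
  nr <- nrow(S)
  pts <- cbind(((idx - 1) %% nr) + 1, ((idx - 1) %/% nr) + 1)
  D <- as.matrix(stats::dist(pts, method = "maximum"))
  g <- igraph::graph_from_adjacency_matrix(D == 1, mode = "undirected")
  deg <- igraph::degree(g)
  hi <- which(deg >= 3)
  if (length(hi) == 0) return(0L)
  igraph::count_components(igraph::induced_subgraph(g, hi))
}

# Z-sum mean intensity by explicit triple loop.
oracle_zsum_mean <- function(ros, mask) {
  nz <- dim(ros)[1]; nr <- dim(ros)[2]; nc <- dim(ros)[3]
  s <- 0; n <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c]) {
      for (z in seq_len(nz)) s <- s + ros[z, r, c]
      n <- n + 1L
    }
  }
  s / n
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Thick ring mask used for rotation-stability checks.
ring_mask <- function(angle_off = 0, size = 80, radius = 25) {
  m <- matrix(FALSE, size, size)
  t <- seq(0, 2 * pi, length.out = 600)
  ctr <- size / 2
  rr <- round(ctr + radius * sin(t + angle_off))
  cc <- round(ctr + radius * cos(t + angle_off))
  for (dr in -1:1) for (dc in -1:1) {
    m[cbind(pmax(1, pmin(size, rr + dr)), pmax(1, pmin(size, cc + dc)))] <- TRUE
  }
  m
}

# Random blob mask with tunable density.
random_mask <- function(seed, nr = 20, nc = 20, density = 0.4) {
  set.seed(seed)
  matrix(stats::runif(nr * nc) < density, nr, nc)
}

micro_pipeline_config <- function(dir, seed = 11) {
  run_config(
    out_dir = dir, seed = seed,
    synthetic = list(n_wells_per_condition = 2, n_plates = 2,
                     base = list(image_shape = c(96, 96), n_days = 4,
                                 n_somata_initial = 10,
                                 neurite_growth_rate = 5, noise_sd = 0.01)),
    coherency = list(reach = 15, n_sectors = 8, min_cover = 0.02, sigma = 2),
    log_level = "quiet")
}
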