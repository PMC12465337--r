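#' Specify a synthetic culture time-course
#'
#' Parameters of the synthetic image generator that emulates a developing
#' neuronal monolayer under daily live-cell imaging: somata that drift into
#' clusters (and merge when their discs touch), neurites that elongate day by
#' day and fasciculate into aligned bundles, photobleaching of the
#' fluorophore, and an optional abrupt death event that drops the whole-frame
#' intensity.
#'
#' Somata are rendered as Gaussian-profile discs (radial sigma 2R/3, support
#' truncated at the true radius R) and neurites as anti-aliased quadratic
#' Bezier curves about 2-3 px wide. Neurite bend amplitude scales with
#' `1 - fasciculation_strength`, so full fasciculation produces straight,
#' parallel bundles while zero fasciculation produces curved neurites with
#' isotropic orientations.
#'
#' @param seed Integer RNG seed; the same seed and spec give a bit-identical
#'   image sequence.
#' @param image_shape Integer vector (rows, cols), each at least 64.
#' @param n_days Number of daily frames (at least 1).
#' @param n_somata_initial Number of somata seeded on day 1.
#' @param soma_radius_mean,soma_radius_sd Soma disc radius distribution (px).
#' @param cluster_attraction Per-day attraction rate toward cluster
#'   centroids, in \[0, 1\]; 0 freezes all positions.
#' @param n_neurites_per_soma Neurites emitted per soma.
#' @param neurite_growth_rate Neurite elongation in px/day.
#' @param fasciculation_strength In \[0, 1\]: 0 gives isotropic neurite
#'   orientations, 1 gives fully aligned straight bundles.
#' @param bleach_rate Fractional intensity loss per day, in \[0, 1).
#' @param death_day Optional day index at which an abrupt death event occurs.
#' @param death_drop Fractional intensity drop at the death event, in (0, 1].
#' @param noise_sd Additive Gaussian noise sd on the unit intensity scale.
#' @param bit_depth Output bit depth, 16 (integers in \[0, 65535\]) or 32
#'   (floats in \[0, 1\]); the 32-bit variant exercises the bit-conversion
#'   path.
#' @return A `culture_spec` list.
#' @export
culture_spec <- function(seed = 1L, image_shape = c(192L, 192L), n_days = 10L,
                         n_somata_initial = 25L, soma_radius_mean = 5,
                         soma_radius_sd = 1, cluster_attraction = 0.15,
                         n_neurites_per_soma = 3L, neurite_growth_rate = 6,
                         fasciculation_strength = 0.3, bleach_rate = 0.05,
                         death_day = NULL, death_drop = 0.3, noise_sd = 0.01,
                         bit_depth = 16L) {
  check_scalar(seed, "seed", integer = TRUE)
  if (!is.numeric(image_shape) || length(image_shape) != 2L ||
      any(image_shape < 64)) {
    abort_param("image_shape", "must be two dimensions, each >= 64")
  }
  check_scalar(n_days, "n_days", lower = 1, integer = TRUE)
  check_scalar(n_somata_initial, "n_somata_initial", lower = 1, integer = TRUE)
  check_scalar(soma_radius_mean, "soma_radius_mean", lower = 2)
  check_scalar(soma_radius_sd, "soma_radius_sd", lower = 0)
  check_scalar(cluster_attraction, "cluster_attraction", lower = 0, upper = 1)
  check_scalar(n_neurites_per_soma, "n_neurites_per_soma", lower = 0,
               integer = TRUE)
  check_scalar(neurite_growth_rate, "neurite_growth_rate", lower = 0)
  check_scalar(fasciculation_strength, "fasciculation_strength",
               lower = 0, upper = 1)
  if (!is.numeric(bleach_rate) || length(bleach_rate) != 1L ||
      bleach_rate < 0 || bleach_rate >= 1) {
    abort_param("bleach_rate", "must be in [0, 1)")
  }
  check_scalar(death_day, "death_day", lower = 2, integer = TRUE,
               allow_null = TRUE)
  if (!is.null(death_day) && death_day > n_days) {
    abort_param("death_day", "must not exceed n_days")
  }
  if (!is.numeric(death_drop) || length(death_drop) != 1L ||
      death_drop <= 0 || death_drop > 1) {
    abort_param("death_drop", "must be in (0, 1]")
  }
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (!bit_depth %in% c(16, 32)) abort_param("bit_depth", "must be 16 or 32")
  structure(list(
    seed = as.integer(seed), image_shape = as.integer(image_shape),
    n_days = as.integer(n_days),
    n_somata_initial = as.integer(n_somata_initial),
    soma_radius_mean = soma_radius_mean, soma_radius_sd = soma_radius_sd,
    cluster_attraction = cluster_attraction,
    n_neurites_per_soma = as.integer(n_neurites_per_soma),
    neurite_growth_rate = neurite_growth_rate,
    fasciculation_strength = fasciculation_strength,
    bleach_rate = bleach_rate, death_day = death_day,
    death_drop = death_drop, noise_sd = noise_sd,
    bit_depth = as.integer(bit_depth)
  ), class = "culture_spec")
}

# Rasterise one soma disc (Gaussian radial profile, support r <= R) onto
# intensity/mask canvases by max-compositing. Centres are integer so the
# pixel footprint is translation-invariant (keeps summed perimeter stable).
stamp_soma <- function(canvas, mask, cr, cc, radius) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  rad <- ceiling(radius)
  rows <- (cr - rad):(cr + rad)
  cols <- (cc - rad):(cc + rad)
  ok_r <- rows >= 1 & rows <= nr
  ok_c <- cols >= 1 & cols <= nc
  rows <- rows[ok_r]; cols <- cols[ok_c]
  if (length(rows) == 0 || length(cols) == 0) {
    return(list(canvas = canvas, mask = mask))
  }
  d2 <- outer((rows - cr)^2, (cols - cc)^2, `+`)
  sig <- (2 * radius / 3)^2
  prof <- exp(-d2 / (2 * sig))
  inside <- d2 <= radius^2
  prof[!inside] <- 0
  canvas[rows, cols] <- pmax(canvas[rows, cols], prof)
  mask[rows, cols] <- mask[rows, cols] | inside
  list(canvas = canvas, mask = mask)
}

# Sample a quadratic Bezier curve: start point, initial heading theta,
# terminal heading theta + bend, chord length len. Returns sample points and
# tangent angles.
bezier_samples <- function(p0, theta, bend, len, step = 0.5) {
  u0 <- c(sin(theta), cos(theta))            # (dr, dc)
  u1 <- c(sin(theta + bend), cos(theta + bend))
  P1 <- p0 + 0.5 * len * u0
  P2 <- p0 + 0.5 * len * (u0 + u1)
  n <- max(2L, ceiling(2 * len / step))
  t <- seq(0, 1, length.out = n)
  b <- function(i) (1 - t)^2 * p0[i] + 2 * t * (1 - t) * P1[i] + t^2 * P2[i]
  db <- function(i) 2 * (1 - t) * (P1[i] - p0[i]) + 2 * t * (P2[i] - P1[i])
  list(r = b(1), c = b(2), angle = atan2(db(1), db(2)) %% pi)
}

# Max-composite a set of curve samples onto canvases with an anti-aliased
# Gaussian cross-profile (half-width ~1.5 px). Orientation of each painted
# pixel is that of its strongest contribution.
stamp_curves <- function(shape, samples) {
  nr <- shape[1]; nc <- shape[2]
  canvas <- matrix(0, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  orient <- matrix(NA_real_, nr, nc)
  if (nrow(samples) == 0) {
    return(list(canvas = canvas, mask = mask, orient = orient))
  }
  off <- expand.grid(dr = -2:2, dc = -2:2)
  ns <- nrow(samples)
  sr <- rep(samples$r, times = nrow(off))
  sc <- rep(samples$c, times = nrow(off))
  ang <- rep(samples$angle, times = nrow(off))
  ir <- floor(sr + rep(off$dr, each = ns) + 0.5)
  ic <- floor(sc + rep(off$dc, each = ns) + 0.5)
  dr <- ir - sr
  dc <- ic - sc
  d2 <- dr^2 + dc^2
  keep <- ir >= 1 & ir <= nr & ic >= 1 & ic <= nc & d2 <= 4
  ir <- ir[keep]; ic <- ic[keep]; d2 <- d2[keep]; ang <- ang[keep]
  val <- exp(-d2 / (2 * 0.9^2))
  idx <- (ic - 1L) * nr + ir
  ord <- order(val)                    # later (larger) assignments win
  canvas[idx[ord]] <- val[ord]
  orient[idx[ord]] <- ang[ord]
  inside <- d2 <= 1.5^2
  mask[idx[inside]] <- TRUE
  list(canvas = canvas, mask = mask, orient = orient)
}

#' Generate a synthetic culture image time-course with ground truth
#'
#' Produces one frame per day together with per-day ground-truth soma and
#' neurite masks, labelled soma objects (area, perimeter, centroid), the
#' per-pixel neurite orientation field (radians in \[0, pi)), and the true
#' foreground intensity amplitude. With `bleach_rate` b and no death event,
#' the true amplitude on day d is exactly `A0 * (1 - b)^(d - 1)`; a death
#' event at day k multiplies all frames from day k on by `1 - death_drop`.
#'
#' Somata drift each day toward fixed cluster centroids at rate
#' `cluster_attraction`; discs that come into contact merge into a single
#' connected soma object, so the object count never increases over days.
#'
#' @param spec A [culture_spec()].
#' @return A `culture_timecourse`: list with `images` (list of
#'   [field_image()], one per day), `truth` (per-day ground truth), and
#'   `spec`.
#' @export
generate_timecourse <- function(spec) {
  stopifnot(inherits(spec, "culture_spec"))
  set.seed(spec$seed)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  n <- spec$n_somata_initial
  margin <- ceiling(spec$soma_radius_mean * 2)
  pos0 <- cbind(r = runif(n, margin, nr - margin),
                c = runif(n, margin, nc - margin))
  radii <- pmax(2.5, stats::rnorm(n, spec$soma_radius_mean,
                                  spec$soma_radius_sd))
  k <- max(1L, min(n, as.integer(ceiling(n / 6))))
  if (k > 1L) {
    km <- stats::kmeans(pos0, centers = k, nstart = 1)
    clus <- km$cluster
    centers <- km$centers
  } else {
    clus <- rep(1L, n)
    centers <- matrix(colMeans(pos0), 1, 2)
  }
  # One global bundle direction; per-cluster and per-neurite deviations
  # shrink with fasciculation strength, so f = 1 gives a fully aligned,
  # straight field and f = 0 an isotropic, curved one.
  global_angle <- runif(1, 0, pi)
  cluster_dev <- runif(k, -pi / 2, pi / 2)

  f <- spec$fasciculation_strength
  nn <- spec$n_neurites_per_soma
  neur <- NULL
  if (nn > 0) {
    neur <- tidyr::expand_grid(soma = seq_len(n), j = seq_len(nn))
    neur$u <- runif(nrow(neur), -pi / 2, pi / 2)
    neur$side <- sample(c(0, pi), nrow(neur), replace = TRUE)
    neur$bend0 <- runif(nrow(neur), -0.6, 0.6)
    neur$theta <- (global_angle +
                     (1 - f) * (cluster_dev[clus[neur$soma]] + neur$u)) %% pi
  }

  A0 <- 0.8; bg <- 0.02
  images <- vector("list", spec$n_days)
  truth_days <- vector("list", spec$n_days)
  max_len <- 0.45 * min(nr, nc)

  for (d in seq_len(spec$n_days)) {
    lam <- (1 - spec$cluster_attraction)^(d - 1)
    pos <- centers[clus, , drop = FALSE] +
      lam * (pos0 - centers[clus, , drop = FALSE])
    pos_i <- round(pos)

    soma_canvas <- matrix(0, nr, nc)
    soma_mask <- matrix(FALSE, nr, nc)
    for (i in seq_len(n)) {
      st <- stamp_soma(soma_canvas, soma_mask, pos_i[i, 1], pos_i[i, 2],
                       radii[i])
      soma_canvas <- st$canvas; soma_mask <- st$mask
    }

    if (!is.null(neur)) {
      len <- min(max_len, spec$neurite_growth_rate * d)
      samp <- purrr::pmap_dfr(neur, function(soma, j, u, side, bend0, theta) {
        dir_angle <- theta + side
        p0 <- pos_i[soma, ] + radii[soma] *
          c(sin(dir_angle), cos(dir_angle)) * 0.8
        s <- bezier_samples(p0, dir_angle, bend0 * (1 - f), len)
        tibble::tibble(r = s$r, c = s$c, angle = s$angle)
      })
      nstamp <- stamp_curves(c(nr, nc), samp)
    } else {
      nstamp <- stamp_curves(c(nr, nc), tibble::tibble(r = double(),
                                                       c = double(),
                                                       angle = double()))
    }
    neurite_mask <- nstamp$mask & !soma_mask
    orient <- nstamp$orient
    orient[!neurite_mask] <- NA_real_

    A_d <- A0 * (1 - spec$bleach_rate)^(d - 1)
    if (!is.null(spec$death_day) && d >= spec$death_day) {
      A_d <- A_d * (1 - spec$death_drop)
    }
    profile <- pmax(soma_canvas, 0.7 * nstamp$canvas)
    px <- profile * A_d + bg
    if (spec$noise_sd > 0) {
      px <- px + stats::rnorm(nr * nc, 0, spec$noise_sd)
    }
    px <- pmin(pmax(px, 0), 1)
    if (spec$bit_depth == 16L) px <- round(px * 65535)

    images[[d]] <- field_image(px, bit_depth = spec$bit_depth,
                               condition = "synthetic", well = "W01",
                               day = d, fov = 1L)
    objs <- label_somata(new_segmentation_masks(soma_mask, neurite_mask,
                                                "internal"))
    truth_days[[d]] <- list(
      soma_mask = soma_mask, neurite_mask = neurite_mask,
      orientation = orient, objects = objs,
      soma_centers = pos_i, true_mean_intensity = A_d
    )
  }
  structure(list(images = images,
                 truth = structure(truth_days, class = "culture_truth"),
                 spec = spec),
            class = "culture_timecourse")
}

#' Circular variance of an orientation field
#'
#' Axial circular variance `1 - |mean(exp(2i * theta))|` for orientations in
#' \[0, pi); 0 for perfectly aligned fields, 1 for isotropic ones. `NA`
#' values (pixels off the neurite mask) are dropped.
#'
#' @param theta Numeric vector or matrix of orientations in radians.
#' @return Circular variance in \[0, 1\].
#' @export
circular_variance <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (length(theta) == 0) return(NA_real_)
  1 - Mod(mean(exp(2i * theta)))
}

#' Write a synthetic time-course to disk
#'
#' Lays images out as `plate/<condition>/<day>/<fov>.tif` with a sidecar
#' `manifest.csv` (columns plate, well, condition, day, fov, path), the
#' ground-truth masks as 8-bit TIFFs under `truth/`, and the generator
#' parameters as `params.csv`.
#'
#' @param tc A `culture_timecourse`.
#' @param root Output directory.
#' @param plate,well Identifiers recorded in the manifest.
#' @return `root`, invisibly.
#' @export
write_timecourse <- function(tc, root, plate = "P1", well = "W01") {
  stopifnot(inherits(tc, "culture_timecourse"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(tc$images, function(img) {
    rel <- file.path(plate, img$condition, sprintf("day%02d", img$day),
                     sprintf("fov%02d.tif", img$fov))
    write_field_image(img, file.path(root, rel))
    tibble::tibble(plate = plate, well = well, condition = img$condition,
                   day = img$day, fov = img$fov, path = rel)
  })
  readr::write_csv(rows, file.path(root, "manifest.csv"))
  tdir <- file.path(root, "truth")
  dir.create(tdir, showWarnings = FALSE)
  for (d in seq_along(tc$truth)) {
    tiff::writeTIFF(tc$truth[[d]]$soma_mask * 1,
                    file.path(tdir, sprintf("soma_day%02d.tif", d)),
                    bits.per.sample = 8L)
    tiff::writeTIFF(tc$truth[[d]]$neurite_mask * 1,
                    file.path(tdir, sprintf("neurite_day%02d.tif", d)),
                    bits.per.sample = 8L)
  }
  sp <- tc$spec
  sp$death_day <- sp$death_day %||% NA_integer_
  params <- tibble::tibble(parameter = names(sp),
                           value = vapply(sp, function(v)
                             paste(format(v), collapse = "x"), character(1)))
  readr::write_csv(params, file.path(root, "params.csv"))
  invisible(root)
}

#' Generate a synthetic factorial AUC dataset
#'
#' Draws per-well AUC values from the linear model used for the factorial
#' analysis: three main effects (media, laminin, seeding density), their
#' three two-way interactions, additive plate offsets, and Gaussian noise.
#' Factors use treatment coding with reference levels NB / mouse / low (the
#' indicator is 1 for BPI / human / high).
#'
#' @param effects Named list of coefficients: `intercept`, `media`,
#'   `laminin`, `density`, `media_laminin`, `media_density`,
#'   `laminin_density`. Missing entries default to 0 (intercept 10).
#' @param n_wells_per_condition Replicate wells per condition (at least 2).
#' @param plate_effects Numeric vector of per-plate additive offsets; wells
#'   are assigned to plates round-robin within condition. At least 2 plates
#'   are required when any offset is nonzero.
#' @param noise_sd Residual standard deviation.
#' @param seed RNG seed.
#' @return A tibble with columns `well`, `plate`, `media`, `laminin`,
#'   `density`, `condition`, `auc`.
#' @export
generate_factorial_dataset <- function(effects = list(),
                                       n_wells_per_condition = 7,
                                       plate_effects = c(0, 0, 0),
                                       noise_sd = 1, seed = 1L) {
  check_scalar(n_wells_per_condition, "n_wells_per_condition", lower = 2,
               integer = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (any(plate_effects != 0) && length(plate_effects) < 2) {
    abort_param("plate_effects",
                "at least 2 plates are required when plate offsets are nonzero")
  }
  b <- utils::modifyList(
    list(intercept = 10, media = 0, laminin = 0, density = 0,
         media_laminin = 0, media_density = 0, laminin_density = 0),
    effects)
  set.seed(seed)
  design <- tidyr::expand_grid(
    media = factor(c("NB", "BPI"), levels = c("NB", "BPI")),
    laminin = factor(c("mouse", "human"), levels = c("mouse", "human")),
    density = factor(c("low", "high"), levels = c("low", "high")),
    rep = seq_len(n_wells_per_condition)
  )
  n_plates <- length(plate_effects)
  design <- design |>
    dplyr::group_by(.data$media, .data$laminin, .data$density) |>
    dplyr::mutate(plate = sprintf("P%d", ((.data$rep - 1L) %% n_plates) + 1L)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      condition = paste(.data$media, .data$laminin, .data$density, sep = "_"),
      well = sprintf("%s_W%02d", .data$condition, .data$rep)
    )
  x1 <- as.integer(design$media == "BPI")
  x2 <- as.integer(design$laminin == "human")
  x3 <- as.integer(design$density == "high")
  mu <- b$intercept + b$media * x1 + b$laminin * x2 + b$density * x3 +
    b$media_laminin * x1 * x2 + b$media_density * x1 * x3 +
    b$laminin_density * x2 * x3 +
    plate_effects[as.integer(sub("P", "", design$plate))]
  design$auc <- mu + stats::rnorm(nrow(design), 0, noise_sd)
  dplyr::select(design, "well", "plate", "media", "laminin", "density",
                "condition", "auc")
}
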