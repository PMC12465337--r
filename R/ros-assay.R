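#' Construct a ROS imaging stack
#'
#' Pairs a 3-D oxidative-stress probe channel (z, row, col) with the 2-D
#' nuclei mask derived from the nuclei counterstain channel. The nuclei
#' mask is defined on the 2-D image footprint and applied to every z slice.
#'
#' @param ros 3-D numeric array (z, row, col) of probe intensities.
#' @param nuclei_mask Logical 2-D matrix matching the stack footprint.
#' @param nuclei_count Number of nuclei in the field (>= 0).
#' @param group Experimental group label (e.g. `"experimental_BPI"`,
#'   `"experimental_NB"`, `"positive_control"`, `"negative_control"`).
#' @return A `ros_stack`.
#' @export
ros_stack <- function(ros, nuclei_mask, nuclei_count,
                      group = "experimental_NB") {
  if (!is.array(ros) || length(dim(ros)) != 3L) {
    abort_param("ros", "must be a 3-D array (z, row, col)")
  }
  nuclei_mask <- as_logical_mask(nuclei_mask, "nuclei_mask")
  if (!identical(dim(nuclei_mask), dim(ros)[2:3])) {
    abort_param("nuclei_mask", "must match the stack footprint")
  }
  check_scalar(nuclei_count, "nuclei_count", lower = 0, integer = TRUE)
  structure(list(ros = ros, nuclei_mask = nuclei_mask,
                 nuclei_count = as.integer(nuclei_count),
                 group = group),
            class = "ros_stack")
}

#' Z-sum mean intensity within the nuclei mask
#'
#' Sums probe intensity along z per pixel, restricts to pixels inside the
#' nuclei mask, and returns their mean — the per-image ROS reading before
#' normalisation.
#'
#' @param stack A `ros_stack`.
#' @return Mean of per-pixel z-sums over nuclei pixels; `NA` with a warning
#'   when the nuclei mask is empty.
#' @export
zsum_mean_intensity <- function(stack) {
  stopifnot(inherits(stack, "ros_stack"))
  if (!any(stack$nuclei_mask)) {
    warning("empty nuclei mask: intensity undefined")
    return(NA_real_)
  }
  zsum <- apply(stack$ros, c(2, 3), sum)
  mean(zsum[stack$nuclei_mask])
}

#' Normalize a ROS intensity and apply background correction
#'
#' Divides the per-image intensity by the nuclei count (accounting for cell
#' density) and subtracts the normalized mean intensity of the negative
#' control (background correction).
#'
#' @param intensity Per-image z-sum mean intensity.
#' @param nuclei_count Nuclei in the field (> 0).
#' @param negative_control_mean Mean *normalized* intensity of the negative
#'   control group.
#' @return Corrected intensity; `NA` with a warning for zero nuclei.
#' @export
normalize_and_correct <- function(intensity, nuclei_count,
                                  negative_control_mean) {
  if (is.na(nuclei_count) || nuclei_count == 0) {
    warning("zero nuclei count: normalized intensity undefined")
    return(NA_real_)
  }
  intensity / nuclei_count - negative_control_mean
}

#' Count nuclei by blob detection
#'
#' Laplacian-of-Gaussian blob detection at a fixed physical spot size
#' (default XY diameter 5.83 um converted by the pixel size): the image is
#' smoothed at `sigma = diameter_px / (2 * sqrt(2))`, the negated discrete
#' Laplacian response is computed, and strict local maxima above a fraction
#' of the global maximum response are counted. The response threshold is
#' relative, so counts are invariant to global intensity scaling. If a
#' ground-truth count is supplied it is returned directly.
#'
#' @param nuclei_image 2-D numeric matrix (projected nuclei channel).
#' @param diameter_um Expected nucleus diameter, micrometres.
#' @param pixel_size Pixel size in micrometres (default 1.25, the confocal
#'   setting used for ROS stacks).
#' @param rel_threshold Fraction of the maximum response a blob must reach.
#' @param truth Optional known count (returned as-is).
#' @return Integer nucleus count.
#' @export
count_nuclei <- function(nuclei_image, diameter_um = 5.83, pixel_size = 1.25,
                         rel_threshold = 0.15, truth = NULL) {
  if (!is.null(truth)) return(as.integer(truth))
  stopifnot(is.matrix(nuclei_image))
  if (max(nuclei_image) <= min(nuclei_image)) return(0L)
  d_px <- diameter_um / pixel_size
  sigma <- d_px / (2 * sqrt(2))
  sm <- gblur_mat(nuclei_image, sigma)
  lap <- shift_mat(sm, 1, 0) + shift_mat(sm, -1, 0) +
    shift_mat(sm, 0, 1) + shift_mat(sm, 0, -1) - 4 * sm
  resp <- -lap
  resp[resp < 0] <- 0
  # suppress zero-padding artefacts at the image border
  resp[c(1, 2, nrow(resp) - 1, nrow(resp)), ] <- 0
  resp[, c(1, 2, ncol(resp) - 1, ncol(resp))] <- 0
  mx <- max(resp)
  if (mx <= 0) return(0L)
  # strict local maxima within a neighbourhood about one blob radius wide
  win <- max(3L, 2L * floor(d_px / 4) + 1L)
  dil <- as.matrix(EBImage::imageData(EBImage::dilate(
    EBImage::Image(resp), EBImage::makeBrush(win, "box"))))
  peaks <- resp >= dil - 1e-12 & resp >= rel_threshold * mx
  # merge adjacent plateau peaks
  max(label_components(peaks, connectivity = 8))
}

#' Simulate a field of nuclei
#'
#' Draws `n` non-overlapping Gaussian-profile nuclei at the stated physical
#' diameter and returns the image plus ground truth.
#'
#' @param n Number of nuclei.
#' @param shape Image shape (rows, cols).
#' @param diameter_um,pixel_size Physical nucleus diameter and pixel size.
#' @param amplitude Peak intensity per nucleus.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return List with `image`, `centers` (n x 2), and `count`.
#' @export
simulate_nuclei_field <- function(n, shape = c(128L, 128L),
                                  diameter_um = 5.83, pixel_size = 1.25,
                                  amplitude = 1, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  r_px <- diameter_um / pixel_size / 2
  min_gap <- 4 * r_px
  centers <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(centers) < n && tries < 20000) {
    cand <- c(runif(1, 2 * r_px, shape[1] - 2 * r_px),
              runif(1, 2 * r_px, shape[2] - 2 * r_px))
    ok <- nrow(centers) == 0 ||
      all(sqrt((centers[, 1] - cand[1])^2 +
                 (centers[, 2] - cand[2])^2) >= min_gap)
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1
  }
  if (nrow(centers) < n) {
    stop("could not place ", n, " non-overlapping nuclei in this field",
         call. = FALSE)
  }
  img <- matrix(0, shape[1], shape[2])
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  sig <- r_px / 1.5
  for (i in seq_len(n)) {
    d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
    img <- pmax(img, amplitude * exp(-d2 / (2 * sig^2)))
  }
  if (noise_sd > 0) {
    img <- pmax(img + matrix(stats::rnorm(length(img), 0, noise_sd),
                             shape[1], shape[2]), 0)
  }
  list(image = img, centers = centers, count = n)
}

#' Simulate a ROS assay experiment
#'
#' Generates per-FOV `ros_stack`s for the four assay groups with injected
#' additive group offsets on the per-nucleus signal, then computes the full
#' quantification chain (z-sum mean, nuclei-count normalisation, negative
#' control background correction).
#'
#' @param group_offsets Named numeric vector of per-nucleus signal offsets
#'   for groups `experimental_BPI`, `experimental_NB`, `positive_control`;
#'   the negative control sits at `baseline`.
#' @param baseline Per-nucleus baseline signal.
#' @param n_fov FOVs per group per plate.
#' @param n_plates Plates (independent experiments).
#' @param n_z Z slices per stack.
#' @param shape Stack footprint.
#' @param noise_sd Per-voxel Gaussian noise sd.
#' @param seed RNG seed.
#' @return A tibble `plate`, `fov`, `group`, `raw_mean`, `nuclei_count`,
#'   `normalized`, `corrected`.
#' @export
simulate_ros_experiment <- function(group_offsets = c(experimental_BPI = 0,
                                                      experimental_NB = 2,
                                                      positive_control = 4),
                                    baseline = 3, n_fov = 4, n_plates = 3,
                                    n_z = 5, shape = c(96L, 96L),
                                    noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  groups <- c(names(group_offsets), "negative_control")
  offsets <- c(group_offsets, negative_control = 0)
  rows <- tidyr::expand_grid(plate = sprintf("P%d", seq_len(n_plates)),
                             group = groups, fov = seq_len(n_fov))
  res <- purrr::pmap_dfr(rows, function(plate, group, fov) {
    n_nuc <- sample(15:25, 1)
    fld <- simulate_nuclei_field(n_nuc, shape = shape,
                                 seed = sample.int(2^30, 1))
    mask <- fld$image > 0.3
    # total probe signal scales with cell number, so dividing the z-sum
    # mean by the nuclei count recovers the per-nucleus offset
    per_slice <- (baseline + offsets[[group]]) * n_nuc / n_z
    ros <- array(stats::rnorm(n_z * prod(shape), 0, noise_sd),
                 dim = c(n_z, shape))
    for (z in seq_len(n_z)) {
      ros[z, , ] <- pmax(0, ros[z, , ] + per_slice * mask)
    }
    st <- ros_stack(ros, mask, n_nuc, group)
    tibble::tibble(plate = plate, fov = fov, group = group,
                   raw_mean = zsum_mean_intensity(st),
                   nuclei_count = n_nuc)
  })
  neg_mean <- mean(res$raw_mean[res$group == "negative_control"] /
                     res$nuclei_count[res$group == "negative_control"])
  res$normalized <- res$raw_mean / res$nuclei_count
  res$corrected <- purrr::map2_dbl(res$raw_mean, res$nuclei_count,
                                   normalize_and_correct,
                                   negative_control_mean = neg_mean)
  res
}

#' Mixed-model comparison of ROS groups
#'
#' Fits the standard linear mixed model for the assay — condition as fixed
#' effect, plate as random intercept, FOV replicates as observations nested
#' within plates — and reports Benjamini-Hochberg-corrected pairwise group
#' contrasts of corrected intensity.
#'
#' @param ros_table Output of [simulate_ros_experiment()] or a tibble with
#'   `corrected`, `group`, `plate`.
#' @param groups Which groups to compare pairwise (default: the two
#'   experimental groups and the positive control).
#' @return A tibble of pairwise contrasts: `contrast`, `estimate`,
#'   `statistic`, `p.value`, `p.adj`.
#' @export
fit_ros_model <- function(ros_table,
                          groups = c("experimental_BPI", "experimental_NB",
                                     "positive_control")) {
  d <- ros_table[ros_table$group %in% groups, ]
  d$group <- factor(d$group, levels = groups)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    sub <- d[d$group %in% pr, ]
    sub$group <- droplevels(sub$group)
    fit <- lme4::lmer(corrected ~ group + (1 | plate), data = sub,
                      REML = TRUE)
    cf <- summary(fit)$coefficients
    tibble::tibble(contrast = paste(pr[2], "-", pr[1]),
                   estimate = cf[2, "Estimate"],
                   statistic = cf[2, "t value"],
                   p.value = 2 * stats::pnorm(-abs(cf[2, "t value"])))
  })
  res$p.adj <- benjamini_hochberg(res$p.value)
  res
}
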