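#' Baseline reference for aggregation metrics
#'
#' The Disaggregation Index and Cluster Density Factor are anchored to the
#' first imaging day of a well's series: `s0` is the average soma object
#' area at the initial timepoint (user-settable; defaults to the observed
#' day-1 mean area so the day-1 DI is exactly 1) and `m0` is the number of
#' individual somata at the initial timepoint. The reference is fixed per
#' well for the whole series.
#'
#' @param s0 Average soma area at baseline, pixels (> 0).
#' @param m0 Soma count at baseline (>= 1).
#' @return A `baseline_reference`.
#' @export
baseline_reference <- function(s0, m0) {
  check_scalar(s0, "s0", lower = .Machine$double.eps)
  check_scalar(m0, "m0", lower = 1)
  structure(list(s0 = s0, m0 = m0), class = "baseline_reference")
}

#' Baseline from the first-day soma objects
#'
#' Convenience constructor: `s0 = a_0 / m_0` and `m0` from the labelled
#' day-1 objects, so DI at day 1 self-normalizes to exactly 1.
#'
#' @param objects Day-1 `soma_objects`.
#' @return A `baseline_reference`.
#' @export
baseline_from_objects <- function(objects) {
  stopifnot(inherits(objects, "soma_objects"))
  if (objects$count == 0) {
    stop("cannot form a baseline from an empty soma mask", call. = FALSE)
  }
  baseline_reference(sum(objects$objects$area) / objects$count,
                     objects$count)
}

#' Disaggregation Index
#'
#' `DI = s0 * m_n / a_n`, where `m_n` is the number of soma objects
#' (individual cells and fused clusters alike) and `a_n` their total area at
#' timepoint n. High DI indicates small, uniformly spread somata (young or
#' finely clustered cultures); low DI indicates organised aggregation into
#' large clusters. When `s0 = a_0 / m_0`, DI at the initial timepoint is
#' exactly 1.
#'
#' @param objects A `soma_objects` for the current timepoint.
#' @param baseline A `baseline_reference` (only `s0` is used).
#' @return Dimensionless DI, or `NA` with a warning when the total soma
#'   area is zero.
#' @export
disaggregation_index <- function(objects, baseline) {
  stopifnot(inherits(objects, "soma_objects"),
            inherits(baseline, "baseline_reference"))
  a_n <- sum(objects$objects$area)
  if (a_n == 0) {
    warning("total soma area is zero: DI undefined")
    return(NA_real_)
  }
  baseline$s0 * objects$count / a_n
}

#' Cluster Density Factor
#'
#' `CDF = m0 / p_n`, where `m0` is the number of individual somata at the
#' initial timepoint and `p_n` the summed perimeter of all soma objects at
#' timepoint n (pixel-edge convention, see [label_somata()]). High CDF means
#' many somata condensed into compact aggregates with little total
#' perimeter — the hallmark of mature network formation; low CDF means
#' loosely clustered or dissociated cultures.
#'
#' @param objects A `soma_objects` for the current timepoint.
#' @param baseline A `baseline_reference` (only `m0` is used).
#' @return CDF in 1/pixels, or `NA` with a warning when the summed
#'   perimeter is zero.
#' @export
cluster_density_factor <- function(objects, baseline) {
  stopifnot(inherits(objects, "soma_objects"),
            inherits(baseline, "baseline_reference"))
  p_n <- sum(objects$objects$perimeter)
  if (p_n == 0) {
    warning("summed soma perimeter is zero: CDF undefined")
    return(NA_real_)
  }
  baseline$m0 / p_n
}

# Smoothed structure-tensor component fields of an intensity matrix.
# Gradients by central differences (outermost 1-px border left zero).
structure_tensor_fields <- function(px, sigma = 2) {
  gx <- (shift_mat(px, 0, -1) - shift_mat(px, 0, 1)) / 2  # d/dcol
  gy <- (shift_mat(px, -1, 0) - shift_mat(px, 1, 0)) / 2  # d/drow
  # zero the border where the central difference is invalid
  gx[, c(1, ncol(px))] <- 0; gx[c(1, nrow(px)), ] <- 0
  gy[, c(1, ncol(px))] <- 0; gy[c(1, nrow(px)), ] <- 0
  list(Jxx = gblur_mat(gx * gx, sigma),
       Jyy = gblur_mat(gy * gy, sigma),
       Jxy = gblur_mat(gx * gy, sigma))
}

coherency_from_tensor <- function(jxx, jyy, jxy) {
  tr <- jxx + jyy
  if (!is.finite(tr) || tr <= .Machine$double.eps) return(0)
  min(1, max(0, sqrt((jxx - jyy)^2 + 4 * jxy^2) / tr))
}

#' Structure-tensor orientation coherency of a window
#'
#' Eigenvalue contrast `(lambda1 - lambda2) / (lambda1 + lambda2)` of the
#' Gaussian-smoothed structure tensor averaged over the window: 1 when all
#' local gradients share one orientation (perfectly aligned fibres), 0 for
#' isotropic texture. A gradient-free (constant) window is defined to have
#' coherency 0.
#'
#' @param window Numeric intensity matrix larger than 3x3.
#' @param sigma Tensor smoothing sigma in px (default 2).
#' @return Coherency in \[0, 1\].
#' @export
structure_tensor_coherency <- function(window, sigma = 2) {
  if (!is.matrix(window) || nrow(window) <= 3 || ncol(window) <= 3) {
    abort_param("window", "must be a matrix larger than 3x3")
  }
  f <- structure_tensor_fields(window, sigma)
  interior <- matrix(FALSE, nrow(window), ncol(window))
  interior[2:(nrow(window) - 1), 2:(ncol(window) - 1)] <- TRUE
  coherency_from_tensor(mean(f$Jxx[interior]), mean(f$Jyy[interior]),
                        mean(f$Jxy[interior]))
}

#' Region-based neurite coherency around soma objects
#'
#' Evaluates orientation coherency of the neurites emanating from each soma
#' object: an annular region (the object dilated by `reach`, minus the
#' object) is divided into `n_sectors` angular sectors about the object
#' centroid; sectors whose neurite coverage reaches `min_cover` contribute
#' the coherency of the smoothed structure tensor averaged over their
#' neurite pixels. Sector values are averaged per object with equal weight,
#' and object values are averaged over all objects with at least one valid
#' sector to give the image-level coherency.
#'
#' @param image A `field_image`.
#' @param objects `soma_objects` for the image.
#' @param neurite_mask Logical neurite mask (or `segmentation_masks`).
#' @param reach Annulus reach in px beyond the object boundary (default
#'   30 px, about 18.6 um at 0.62 um/px).
#' @param n_sectors Number of angular sectors (default 8).
#' @param min_cover Minimum fraction of sector-annulus pixels that must be
#'   neurite for the sector to count (default 0.02).
#' @param sigma Tensor smoothing sigma in px.
#' @return A `coherency_result`: `per_object` tibble (`label`, `coherency`,
#'   `n_sectors_used`), `image_coherency`, `n_objects_used`. When no object
#'   has a valid sector the image value is `NA` with a warning.
#' @export
region_coherency <- function(image, objects, neurite_mask, reach = 30,
                             n_sectors = 8, min_cover = 0.02, sigma = 2) {
  stopifnot(inherits(image, "field_image"), inherits(objects, "soma_objects"))
  if (inherits(neurite_mask, "segmentation_masks")) {
    neurite_mask <- neurite_mask$neurite
  }
  neurite_mask <- as_logical_mask(neurite_mask)
  check_scalar(reach, "reach", lower = 1)
  check_scalar(n_sectors, "n_sectors", lower = 1, integer = TRUE)
  check_scalar(min_cover, "min_cover", lower = 0, upper = 1)

  px <- image$pixels
  rng <- range(px)
  if (rng[2] > rng[1]) px <- (px - rng[1]) / (rng[2] - rng[1])
  tf <- structure_tensor_fields(px, sigma)
  nr <- nrow(px); nc <- ncol(px)
  row_i <- matrix(seq_len(nr), nr, nc)
  col_i <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  per_object <- purrr::map_dfr(seq_len(objects$count), function(l) {
    obj <- objects$labels == l
    dm <- as.matrix(EBImage::imageData(EBImage::distmap(
      EBImage::Image((!obj) * 1))))
    annulus <- dm > 0 & dm <= reach
    cr <- objects$objects$centroid_row[l]
    cc <- objects$objects$centroid_col[l]
    ang <- atan2(row_i - cr, col_i - cc)          # (-pi, pi]
    sector <- pmin(n_sectors,
                   1L + floor((ang + pi) / (2 * pi) * n_sectors))
    vals <- purrr::map_dbl(seq_len(n_sectors), function(s) {
      sel <- annulus & sector == s
      n_sel <- sum(sel)
      if (n_sel == 0) return(NA_real_)
      nb <- sel & neurite_mask
      if (sum(nb) / n_sel < min_cover || !any(nb)) return(NA_real_)
      coherency_from_tensor(mean(tf$Jxx[nb]), mean(tf$Jyy[nb]),
                            mean(tf$Jxy[nb]))
    })
    used <- sum(!is.na(vals))
    tibble::tibble(label = l,
                   coherency = if (used > 0) mean(vals, na.rm = TRUE)
                               else NA_real_,
                   n_sectors_used = used)
  })
  valid <- per_object$n_sectors_used > 0
  if (!any(valid)) {
    warning("no soma object has a neurite-covered sector: coherency undefined")
    img_val <- NA_real_
  } else {
    img_val <- mean(per_object$coherency[valid])
  }
  structure(list(per_object = per_object, image_coherency = img_val,
                 n_objects_used = sum(valid)),
            class = "coherency_result")
}

#' @export
print.coherency_result <- function(x, ...) {
  cat(sprintf("<coherency_result> image coherency %.3f over %d objects\n",
              x$image_coherency, x$n_objects_used))
  invisible(x)
}

#' Select representative fields of view for coherency analysis
#'
#' Picks a uniformly spaced 3x3 spatial grid of FOV positions from the
#' mosaic tiling a well, kept consistent across days, so the coherency
#' metric stays computationally tractable on large screens. The selected
#' position along an axis of length n is `floor((i - 0.5) * n / 3) + 1` for
#' i = 1, 2, 3 (the centres of thirds). Mosaics with 9 or fewer FOVs are
#' used in full (with a note).
#'
#' @param n_rows,n_cols Mosaic grid dimensions.
#' @return A tibble with columns `row`, `col` and row-major `fov` index.
#' @export
select_coherency_fovs <- function(n_rows, n_cols) {
  check_scalar(n_rows, "n_rows", lower = 1, integer = TRUE)
  check_scalar(n_cols, "n_cols", lower = 1, integer = TRUE)
  pick <- function(n, k = 3L) {
    if (n <= k) return(seq_len(n))
    unique(floor((seq_len(k) - 0.5) * n / k) + 1L)
  }
  if (n_rows * n_cols < 9) {
    message("fewer than 9 FOVs in mosaic: using all ", n_rows * n_cols)
  }
  tidyr::expand_grid(row = pick(n_rows), col = pick(n_cols)) |>
    dplyr::mutate(fov = (.data$row - 1L) * n_cols + .data$col)
}
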