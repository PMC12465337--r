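new_segmentation_masks <- function(soma, neurite, source) {
  structure(list(soma = soma, neurite = neurite, source = source),
            class = "segmentation_masks")
}

#' @export
print.segmentation_masks <- function(x, ...) {
  cat(sprintf("<segmentation_masks> %d x %d (%s): %d soma px, %d neurite px\n",
              nrow(x$soma), ncol(x$soma), x$source, sum(x$soma),
              sum(x$neurite)))
  invisible(x)
}

#' Segment soma and neurite masks from a field image
#'
#' Deterministic classical segmentation: Gaussian smoothing, Otsu
#' thresholding of the foreground, then a width-based split — morphological
#' opening with a disc structuring element retains compact, wide structures
#' (somata) while the foreground removed by the opening (thin, elongated
#' structures) becomes the neurite class. Small speckle components are
#' dropped from the neurite mask. An externally produced mask pair can be
#' supplied instead via [ingest_masks()].
#'
#' The width criterion alone cannot separate somata from thick neurite
#' bundles that stay attached to them, so the opened foreground is further
#' restricted to pixels lying within `core_reach` of a bright core — a
#' pixel whose smoothed intensity reaches `core_frac` of the image maximum.
#' Somata are the brightest compact structures in these images, so cores
#' mark soma centres and the restriction trims bundle annexes from the soma
#' class.
#'
#' @param image A `field_image` (preprocessed; any intensity scale).
#' @param soma_radius Expected soma radius in px; the opening disc has
#'   diameter about `soma_radius + 2` so structures thinner than a soma
#'   fall into the neurite class.
#' @param blur_sigma Gaussian smoothing sigma in px.
#' @param core_frac Fraction of the maximum smoothed intensity that defines
#'   a soma core.
#' @param core_reach Soma pixels must lie within this distance (px) of a
#'   core; default `0.8 * soma_radius`.
#' @param min_speck_px Neurite components smaller than this are discarded.
#' @return A `segmentation_masks` object (`soma`, `neurite` logical
#'   matrices, disjoint by construction).
#' @export
segment_culture <- function(image, soma_radius = 5, blur_sigma = 1,
                            core_frac = 0.8, core_reach = 0.8 * soma_radius,
                            min_speck_px = 8) {
  stopifnot(inherits(image, "field_image"))
  px <- image$pixels
  rng <- range(px)
  if (rng[1] == rng[2]) {
    warning("empty foreground: constant image")
    empty <- matrix(FALSE, nrow(px), ncol(px))
    return(new_segmentation_masks(empty, empty, "internal"))
  }
  u <- (px - rng[1]) / (rng[2] - rng[1])
  sm <- gblur_mat(u, blur_sigma)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  fg <- sm > thr
  if (!any(fg)) {
    warning("empty foreground after thresholding")
    return(new_segmentation_masks(fg, fg, "internal"))
  }
  size <- 2L * floor((soma_radius + 2) / 2) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  soma <- as.matrix(EBImage::imageData(
    EBImage::opening(EBImage::Image(fg * 1), brush))) > 0.5
  core <- sm >= core_frac * max(sm)
  if (any(core) && any(soma)) {
    dcore <- as.matrix(EBImage::imageData(EBImage::distmap(
      EBImage::Image((!core) * 1))))
    soma <- soma & dcore <= core_reach
  } else {
    soma[] <- FALSE
  }
  neurite <- fg & !soma
  if (any(neurite) && min_speck_px > 0) {
    lab <- label_components(neurite)
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= min_speck_px)
    neurite <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  }
  new_segmentation_masks(soma, neurite, "internal")
}

#' Ingest externally produced soma/neurite masks
#'
#' Supports masks exported from an externally trained pixel classifier.
#' Masks are binarised (`> 0` is foreground) and pixels claimed by both
#' classes are resolved in favour of the soma class.
#'
#' @param soma_path,neurite_path TIFF mask files (any bit depth; nonzero =
#'   foreground), or logical/numeric matrices.
#' @param image The `field_image` the masks belong to (shape check).
#' @return A `segmentation_masks` with `source = "external"`.
#' @export
ingest_masks <- function(soma_path, neurite_path, image) {
  stopifnot(inherits(image, "field_image"))
  load_mask <- function(x) {
    if (is.character(x)) x <- tiff::readTIFF(x)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    x > 0
  }
  soma <- load_mask(soma_path)
  neurite <- load_mask(neurite_path)
  shp <- dim(image$pixels)
  for (m in list(soma, neurite)) {
    if (!identical(dim(m), shp)) {
      stop(sprintf("mask shape (%s) does not match image shape (%s)",
                   paste(dim(m), collapse = "x"),
                   paste(shp, collapse = "x")), call. = FALSE)
    }
  }
  neurite <- neurite & !soma  # overlap resolved soma-priority
  new_segmentation_masks(soma, neurite, "external")
}

#' Label connected components of a binary mask
#'
#' Components under 8-connectivity (default) or 4-connectivity, labelled
#' 1..k in raster order of their first pixel. Implemented as iterative
#' minimum-label propagation, which is exact for any mask.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- as_logical_mask(mask)
  if (!connectivity %in% c(4, 8)) {
    abort_param("connectivity", "must be 4 or 8")
  }
  lab <- matrix(Inf, nrow(mask), ncol(mask))
  lab[mask] <- which(mask)
  offs <- if (connectivity == 8) NEIGH8 else NEIGH8[c(1, 3, 5, 7), ]
  repeat {
    nb <- lab
    for (i in seq_len(nrow(offs))) {
      nb <- pmin(nb, shift_mat(lab, offs[i, 1], offs[i, 2], fill = Inf))
    }
    nb[!mask] <- Inf
    if (identical(nb, lab)) break
    lab <- nb
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (any(mask)) {
    ids <- lab[mask]
    out[mask] <- as.integer(match(ids, sort(unique(ids))))
  }
  out
}

# Per-pixel count of exposed pixel edges (4-neighbour background or image
# border) — the pixel-edge-walk perimeter convention.
exposed_edges <- function(mask) {
  mask <- as_logical_mask(mask)
  e <- matrix(0L, nrow(mask), ncol(mask))
  for (i in c(1, 3, 5, 7)) {
    nb <- shift_mat(mask, NEIGH8[i, 1], NEIGH8[i, 2], fill = FALSE)
    e <- e + (mask & !nb)
  }
  e
}

#' Extract labelled soma objects
#'
#' Connected soma components under 8-connectivity with per-object area
#' (pixel count), perimeter (count of exposed pixel edges; a consistent
#' pixel-edge-walk convention rather than a Crofton estimate), and centroid.
#' Objects touching the image border are retained. These are the `m_n`,
#' `a_n` and `p_n` ingredients of the Disaggregation Index and Cluster
#' Density Factor.
#'
#' @param masks A `segmentation_masks` object or a logical soma mask.
#' @return A `soma_objects` object: `labels` matrix, `objects` tibble
#'   (`label`, `area`, `perimeter`, `centroid_row`, `centroid_col`), and
#'   `count`.
#' @export
label_somata <- function(masks) {
  soma <- if (inherits(masks, "segmentation_masks")) masks$soma else
    as_logical_mask(masks)
  lab <- label_components(soma, connectivity = 8)
  k <- max(lab)
  if (k == 0) {
    objects <- tibble::tibble(label = integer(), area = integer(),
                              perimeter = integer(),
                              centroid_row = double(),
                              centroid_col = double())
  } else {
    idx <- which(lab > 0)
    l <- lab[idx]
    rows <- ((idx - 1L) %% nrow(lab)) + 1L
    cols <- ((idx - 1L) %/% nrow(lab)) + 1L
    per <- exposed_edges(soma)[idx]
    objects <- tibble::tibble(
      label = seq_len(k),
      area = as.integer(tabulate(l, k)),
      perimeter = as.integer(rowsum(per, l)[, 1]),
      centroid_row = as.vector(rowsum(as.double(rows), l) / tabulate(l, k)),
      centroid_col = as.vector(rowsum(as.double(cols), l) / tabulate(l, k))
    )
  }
  structure(list(labels = lab, objects = objects, count = k),
            class = "soma_objects")
}

#' @export
print.soma_objects <- function(x, ...) {
  cat(sprintf("<soma_objects> %d objects, total area %d px\n", x$count,
              sum(x$objects$area)))
  invisible(x)
}

#' Mean fluorescence over the segmented cell area
#'
#' Mean pixel intensity over the union of the soma and neurite masks —
#' the per-image fluorescence reading used for bleaching and death-event
#' analysis. Pixels outside the masks never contribute.
#'
#' @param image A `field_image`.
#' @param masks A `segmentation_masks` registered to the image.
#' @return Mean intensity; 0 with a warning when the union is empty.
#' @export
mean_fluorescence <- function(image, masks) {
  stopifnot(inherits(image, "field_image"),
            inherits(masks, "segmentation_masks"))
  sel <- masks$soma | masks$neurite
  if (!any(sel)) {
    warning("empty mask union: mean fluorescence reported as 0")
    return(0)
  }
  mean(image$pixels[sel])
}
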