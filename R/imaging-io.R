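#' Create a field image
#'
#' A `field_image` is one single-channel 2-D fluorescence image together with
#' its acquisition metadata (plate, condition, well, imaging day, field-of-view
#' index, pixel size). Intensities are stored as a numeric matrix in
#' (row, col) orientation. 16-bit images hold integer values in
#' \[0, 65535\]; 32-bit images hold floating-point values in \[0, 1\].
#'
#' @param pixels Numeric matrix of non-negative finite intensities.
#' @param bit_depth Either 16 or 32.
#' @param pixel_size Pixel edge length in micrometres (default 0.62).
#' @param plate,condition,well Character identifiers.
#' @param day Integer imaging day.
#' @param fov Integer field-of-view index (1-based).
#' @return A `field_image` object.
#' @export
field_image <- function(pixels, bit_depth = 16, pixel_size = 0.62,
                        plate = NA_character_, condition = NA_character_,
                        well = NA_character_, day = NA_integer_,
                        fov = NA_integer_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort_param("pixels", "must be a numeric matrix")
  }
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    abort_param("pixels", "must be finite and non-negative")
  }
  if (!bit_depth %in% c(16, 32)) abort_param("bit_depth", "must be 16 or 32")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         pixel_size = pixel_size, plate = as.character(plate),
         condition = as.character(condition), well = as.character(well),
         day = as.integer(day), fov = as.integer(fov)),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf(
    "<field_image> %d x %d px, %d-bit, pixel %.2f um\n  plate=%s condition=%s well=%s day=%s fov=%s\n",
    nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_size,
    x$plate, x$condition, x$well, x$day, x$fov))
  invisible(x)
}

#' Convert a 32-bit image to 16-bit
#'
#' Linearly maps the image's value range onto \[0, 65535\] and rounds
#' half-up, mirroring the usual 32-bit to 16-bit conversion step applied
#' before segmentation. A constant-valued image maps to all zeros (this is
#' documented behaviour, not an error).
#'
#' @param image A `field_image` with `bit_depth = 32`.
#' @return A `field_image` with `bit_depth = 16`.
#' @export
to_16bit <- function(image) {
  stopifnot(inherits(image, "field_image"))
  if (image$bit_depth != 32L) abort_param("image", "bit_depth must be 32")
  px <- image$pixels
  rng <- range(px)
  if (rng[1] == rng[2]) {
    out <- matrix(0, nrow(px), ncol(px))
  } else {
    scaled <- (px - rng[1]) / (rng[2] - rng[1]) * 65535
    out <- floor(scaled + 0.5)  # round half-up
  }
  image$pixels <- out
  image$bit_depth <- 16L
  image
}

#' Rescale an image to its min-max intensity range
#'
#' Maps the minimum intensity to 0 and the maximum to the top of the chosen
#' output scale, preserving the rank order of all pixels. If the image is
#' constant the result is all zeros and a warning is issued.
#'
#' @param image A `field_image`.
#' @param scale `"unit"` (default; output in \[0, 1\]) or `"full"`
#'   (output in \[0, 65535\]).
#' @return A rescaled `field_image` (bit depth unchanged for `"unit"` output
#'   interpretation; values become fractional).
#' @export
rescale_minmax <- function(image, scale = c("unit", "full")) {
  stopifnot(inherits(image, "field_image"))
  scale <- match.arg(scale)
  top <- if (scale == "unit") 1 else 65535
  px <- image$pixels
  rng <- range(px)
  if (rng[1] == rng[2]) {
    warning("constant-valued image: rescaled to all zeros")
    image$pixels <- matrix(0, nrow(px), ncol(px))
  } else {
    image$pixels <- (px - rng[1]) / (rng[2] - rng[1]) * top
  }
  image
}

#' Write a field image as single-plane TIFF
#'
#' 16-bit images are written as 16-bit integer TIFF; 32-bit images as 32-bit
#' float TIFF (values must already lie in \[0, 1\]). Round-trip through
#' [read_field_image()] preserves pixel values exactly.
#'
#' @param image A `field_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_image <- function(image, path) {
  stopifnot(inherits(image, "field_image"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (image$bit_depth == 16L) {
    tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L)
  } else {
    if (any(image$pixels > 1)) {
      abort_param("image", "32-bit images must have values in [0, 1] for TIFF output")
    }
    tiff::writeTIFF(image$pixels, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a single-plane TIFF as a field image
#'
#' @param path TIFF file path.
#' @param bit_depth 16 or 32; governs the intensity scale of the returned
#'   image (16-bit: integers in \[0, 65535\]; 32-bit: floats in \[0, 1\]).
#' @inheritParams field_image
#' @return A `field_image`.
#' @export
read_field_image <- function(path, bit_depth = 16, pixel_size = 0.62,
                             plate = NA, condition = NA, well = NA,
                             day = NA, fov = NA) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # plane extraction only
  if (bit_depth == 16) px <- round(px * 65535)
  field_image(px, bit_depth = bit_depth, pixel_size = pixel_size,
              plate = plate, condition = condition, well = well,
              day = day, fov = fov)
}

#' Read an imaging dataset from disk
#'
#' Reads a directory of single-plane TIFFs indexed by a sidecar manifest CSV
#' (columns `plate, well, condition, day, fov, path`; paths relative to
#' `root`). Every image is tagged with design metadata from the platemap;
#' wells absent from the platemap raise an error naming the well. Missing
#' (well, day) combinations relative to the full grid are recorded as gaps.
#' Unreadable files are skipped with a warning.
#'
#' @param root Dataset root directory containing `manifest.csv`.
#' @param platemap A data frame with columns `well`, `plate`, `condition`
#'   (see [read_platemap()]), or `NULL` to trust the manifest columns.
#' @param load_images If `TRUE` (default) attach a list-column of
#'   `field_image` objects.
#' @return A tibble with one row per image and attribute `"gaps"` listing
#'   missing well/day combinations.
#' @export
read_dataset <- function(root, platemap = NULL, load_images = TRUE) {
  manifest_path <- file.path(root, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.csv found under ", root, call. = FALSE)
  }
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  if (!is.null(platemap)) {
    unmapped <- setdiff(unique(man$well), platemap$well)
    if (length(unmapped) > 0) {
      stop("well(s) not present in platemap: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    man <- man |>
      dplyr::select(-dplyr::any_of(c("plate", "condition"))) |>
      dplyr::left_join(
        dplyr::select(platemap, "well", "plate", "condition"), by = "well")
  }
  grid <- tidyr::expand_grid(well = unique(man$well), day = unique(man$day))
  gaps <- dplyr::anti_join(grid, man, by = c("well", "day"))
  if (load_images) {
    man$image <- purrr::pmap(man, function(plate, well, condition, day, fov,
                                           path, ...) {
      fp <- file.path(root, path)
      tryCatch(
        read_field_image(fp, plate = plate, condition = condition,
                         well = well, day = day, fov = fov),
        error = function(e) {
          warning("skipping unreadable image ", fp, ": ",
                  conditionMessage(e))
          NULL
        })
    })
    man <- man[!vapply(man$image, is.null, logical(1)), ]
  }
  out <- tibble::as_tibble(man)
  attr(out, "gaps") <- tibble::as_tibble(gaps)
  out
}

#' Read a platemap configuration
#'
#' YAML mapping each well id to its plate and condition, e.g.
#' `W01: {plate: P1, condition: BPI_mouse_high}`.
#'
#' @param path YAML file path.
#' @return A tibble with columns `well`, `plate`, `condition`.
#' @export
read_platemap <- function(path) {
  if (!file.exists(path)) stop("platemap not found: ", path, call. = FALSE)
  pm <- yaml::read_yaml(path)
  purrr::imap_dfr(pm, function(v, well) {
    tibble::tibble(well = well, plate = as.character(v$plate),
                   condition = as.character(v$condition))
  })
}

#' Enumerate a longitudinal acquisition plan
#'
#' Expands the full (condition, well, day, field-of-view) grid of a
#' longitudinal screen into one row per image to be acquired. With the
#' defaults used here — 64 contiguous fields of view tiling each well, one
#' scan per day over 33 days, 7 replicate wells for each of 8 conditions —
#' the plan contains 14,784 images per condition and 118,272 in total.
#'
#' @param n_conditions Number of experimental conditions.
#' @param wells_per_condition Replicate wells per condition.
#' @param n_days Number of daily scans.
#' @param n_fov Fields of view per well per scan.
#' @return A tibble with columns `condition`, `well`, `day`, `fov`.
#' @export
plan_acquisition <- function(n_conditions = 8, wells_per_condition = 7,
                             n_days = 33, n_fov = 64) {
  for (f in c("n_conditions", "wells_per_condition", "n_days", "n_fov")) {
    check_scalar(get(f), f, lower = 1, integer = TRUE)
  }
  tidyr::expand_grid(
    condition = sprintf("C%02d", seq_len(n_conditions)),
    well_rep = seq_len(wells_per_condition),
    day = seq_len(n_days),
    fov = seq_len(n_fov)
  ) |>
    dplyr::mutate(well = paste0(.data$condition, "_W", .data$well_rep)) |>
    dplyr::select("condition", "well", "day", "fov")
}

#' Count planned or indexed images
#'
#' @param plan A tibble with a `condition` column, one row per image
#'   (e.g. from [plan_acquisition()] or [read_dataset()]).
#' @return A tibble with per-condition counts and attribute `"total"`;
#'   `summary` rows give `n_images` per condition.
#' @export
count_images <- function(plan) {
  per <- dplyr::count(plan, .data$condition, name = "n_images")
  attr(per, "total") <- nrow(plan)
  per
}

#' Light exposure per well per scan
#'
#' Total non-overlapping fluorescence excitation time a well receives in one
#' scan: number of captures times acquisition time. 64 captures at 300 ms
#' give 19.2 s of light exposure per well per scan.
#'
#' @param n_captures Fields of view captured per well per scan.
#' @param exposure_ms Acquisition time per capture, in milliseconds.
#' @return Exposure in seconds.
#' @export
light_exposure <- function(n_captures = 64, exposure_ms = 300) {
  check_scalar(n_captures, "n_captures", lower = 1, integer = TRUE)
  check_scalar(exposure_ms, "exposure_ms", lower = 0)
  n_captures * exposure_ms / 1000
}
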