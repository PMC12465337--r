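#' Build a run configuration
#'
#' A run is driven either by an input directory of TIFFs plus a platemap
#' (`input_root`, `platemap`) or by a synthetic specification
#' (`synthetic`). All randomness flows from `seed`; per-well generator
#' seeds are derived from it deterministically. The configuration is
#' serialisable and is copied verbatim into the output directory of every
#' run.
#'
#' @param out_dir Output directory for the result bundle.
#' @param seed Master RNG seed.
#' @param input_root,platemap Paths for a disk-based run (`platemap` is a
#'   YAML well map, see [read_platemap()]).
#' @param synthetic List for a generator-based run:
#'   `n_wells_per_condition`, `n_plates`, and `base` (arguments for
#'   [culture_spec()]); optional `conditions` (character vector of
#'   condition names to keep; default all 8) and `death` (named list of
#'   condition -> death day).
#' @param soma_radius,blur_sigma Segmentation parameters.
#' @param coherency List of region-coherency parameters: `reach`,
#'   `n_sectors`, `min_cover`, `sigma`.
#' @param s0 Optional user-set baseline mean soma area (otherwise the
#'   observed day-1 value per well).
#' @param death_threshold Fractional intensity drop defining death.
#' @param include_death_day Keep the death-day observation in AUCs.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, input_root = NULL,
                       platemap = NULL, synthetic = NULL,
                       soma_radius = 5, blur_sigma = 1,
                       coherency = list(reach = 30, n_sectors = 8,
                                        min_cover = 0.02, sigma = 2),
                       s0 = NULL, death_threshold = 0.10,
                       include_death_day = FALSE, log_level = "info") {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              input_root = input_root, platemap = platemap,
              synthetic = synthetic, soma_radius = soma_radius,
              blur_sigma = blur_sigma, coherency = coherency, s0 = s0,
              death_threshold = death_threshold,
              include_death_day = include_death_day, log_level = log_level)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML config path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

write_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
}

pipeline_log <- function(state, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  if (!identical(state$level, "quiet")) message(msg)
  cat(msg, "\n", file = state$con, append = TRUE)
}

# Map design factor levels to generator parameters. BPI media promotes
# fasciculation and clustering, human laminin slows outgrowth slightly,
# high density seeds more somata — the qualitative structure of the
# factorial screen, not any condition-specific trajectory.
condition_spec <- function(base, media, laminin, density, seed,
                           death_day = NULL) {
  args <- base
  args$seed <- seed
  args$fasciculation_strength <- min(1, (args$fasciculation_strength %||% 0.3) +
                                       0.3 * (media == "BPI"))
  args$cluster_attraction <- min(1, (args$cluster_attraction %||% 0.15) +
                                   0.1 * (media == "BPI"))
  args$neurite_growth_rate <- (args$neurite_growth_rate %||% 6) *
    (1 - 0.15 * (laminin == "human"))
  args$n_somata_initial <- ceiling((args$n_somata_initial %||% 25) *
                                     (1 + 0.6 * (density == "high")))
  args$death_day <- death_day
  do.call(culture_spec, args)
}

full_factorial_design <- function(n_wells_per_condition, n_plates,
                                  conditions = NULL) {
  design <- tidyr::expand_grid(
    media = c("NB", "BPI"), laminin = c("mouse", "human"),
    density = c("low", "high"), rep = seq_len(n_wells_per_condition)) |>
    dplyr::mutate(
      condition = paste(.data$media, .data$laminin, .data$density, sep = "_"),
      plate = sprintf("P%d", ((.data$rep - 1L) %% n_plates) + 1L),
      well = sprintf("%s_W%02d", .data$condition, .data$rep))
  if (!is.null(conditions)) {
    design <- dplyr::filter(design, .data$condition %in% conditions)
  }
  design
}

#' Per-image structural metrics
#'
#' Runs preprocessing, segmentation, soma labelling, skeletonisation and
#' all five structural metrics plus mean fluorescence on one field image.
#'
#' @param image A `field_image`.
#' @param baseline A `baseline_reference` for DI/CDF (fixed per well).
#' @param masks Optional pre-computed `segmentation_masks` (otherwise
#'   [segment_culture()] is run).
#' @param soma_radius,blur_sigma Segmentation parameters.
#' @param coherency Region-coherency parameter list (see [run_config()]).
#' @return A one-row tibble of metric values in long-ready wide form.
#' @export
image_metrics <- function(image, baseline, masks = NULL, soma_radius = 5,
                          blur_sigma = 1,
                          coherency = list(reach = 30, n_sectors = 8,
                                           min_cover = 0.02, sigma = 2)) {
  pre <- rescale_minmax(image)
  if (is.null(masks)) {
    masks <- segment_culture(pre, soma_radius = soma_radius,
                             blur_sigma = blur_sigma)
  }
  objs <- label_somata(masks)
  skel <- skeletonize_neurites(masks)
  coh <- if (objs$count > 0 && any(masks$neurite)) {
    suppressWarnings(region_coherency(
      pre, objs, masks$neurite, reach = coherency$reach %||% 30,
      n_sectors = coherency$n_sectors %||% 8,
      min_cover = coherency$min_cover %||% 0.02,
      sigma = coherency$sigma %||% 2)$image_coherency)
  } else NA_real_
  tibble::tibble(
    plate = image$plate, condition = image$condition, well = image$well,
    day = image$day, fov = image$fov,
    neurite_length = as.double(skel$length_px),
    branch_points = suppressWarnings(normalized_branch_points(skel)),
    di = suppressWarnings(disaggregation_index(objs, baseline)),
    cdf = suppressWarnings(cluster_density_factor(objs, baseline)),
    coherency = coh,
    mean_fluorescence = suppressWarnings(mean_fluorescence(image, masks)),
    n_objects = objs$count)
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end workflow — acquire or simulate images, preprocess,
#' segment, compute per-image morphometrics and network metrics, assemble
#' per-well trajectories with death-event detection, summarise AUCs, fit the
#' factorial interaction model per metric (when the design supports it), and
#' compute the network score — and writes all tables, the run config, and a
#' log to the output directory. Two runs with the same configuration and
#' seed produce bit-identical CSV outputs.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return A `result_bundle`: list of tibbles `metrics`, `trajectories`,
#'   `auc`, `model_terms`, `network_score`, plus `design`, `config`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(level = config$log_level,
                con = file.path(config$out_dir, "run.log"))
  cat("", file = state$con)  # truncate
  write_run_config(config, file.path(config$out_dir, "config.yaml"))

  stage <- "acquire"
  bundle <- tryCatch({
    metrics <- if (!is.null(config$input_root)) {
      pipeline_log(state, "stage acquire: reading ", config$input_root)
      pm <- read_platemap(config$platemap)
      ds <- read_dataset(config$input_root, pm)
      design <- dplyr::distinct(ds, .data$well, .data$plate, .data$condition)
      stage <- "metrics"
      purrr::map_dfr(split(ds, ds$well), function(wd) {
        wd <- dplyr::arrange(wd, .data$day, .data$fov)
        first <- rescale_minmax(wd$image[[1]])
        m0 <- segment_culture(first, config$soma_radius, config$blur_sigma)
        o0 <- label_somata(m0)
        base <- if (!is.null(config$s0)) {
          baseline_reference(config$s0, max(1, o0$count))
        } else baseline_from_objects(o0)
        purrr::map_dfr(wd$image, image_metrics, baseline = base,
                       soma_radius = config$soma_radius,
                       blur_sigma = config$blur_sigma,
                       coherency = config$coherency)
      })
    } else if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      design <- full_factorial_design(syn$n_wells_per_condition %||% 2,
                                      syn$n_plates %||% 2, syn$conditions)
      pipeline_log(state, "stage simulate: ", nrow(design), " wells")
      stage <- "metrics"
      purrr::pmap_dfr(design, function(media, laminin, density, rep,
                                       condition, plate, well) {
        dd <- (syn$death %||% list())[[condition]]
        sp <- condition_spec(syn$base %||% list(), media, laminin, density,
                             seed = derive_seed(config$seed,
                                                match(well, design$well)),
                             death_day = dd)
        tc <- generate_timecourse(sp)
        pipeline_log(state, "  well ", well)
        first <- rescale_minmax(tc$images[[1]])
        m0 <- segment_culture(first, config$soma_radius, config$blur_sigma)
        o0 <- label_somata(m0)
        base <- if (!is.null(config$s0)) {
          baseline_reference(config$s0, max(1, o0$count))
        } else baseline_from_objects(o0)
        purrr::map_dfr(tc$images, function(img) {
          img$plate <- plate; img$condition <- condition; img$well <- well
          image_metrics(img, base, soma_radius = config$soma_radius,
                        blur_sigma = config$blur_sigma,
                        coherency = config$coherency)
        })
      })
    } else {
      stop("config must provide either input_root or synthetic", call. = FALSE)
    }

    stage <- "trajectories"
    pipeline_log(state, "stage trajectories")
    long <- tidyr::pivot_longer(
      metrics, cols = c("neurite_length", "branch_points", "di", "cdf",
                        "coherency", "mean_fluorescence"),
      names_to = "metric", values_to = "value")
    traj <- build_trajectories(long, death_threshold = config$death_threshold)
    auc <- summarise_auc(traj, include_death_day = config$include_death_day)

    stage <- "stats"
    design <- dplyr::distinct(metrics, .data$well, .data$plate,
                              .data$condition) |>
      tidyr::separate_wider_delim("condition", "_",
                                  names = c("media", "laminin", "density"),
                                  cols_remove = FALSE)
    auc_design <- dplyr::left_join(auc, design, by = c("well", "condition"))
    model_terms <- NULL
    can_fit <- dplyr::n_distinct(design$plate) >= 2 &&
      dplyr::n_distinct(design$condition) == 8
    if (can_fit) {
      pipeline_log(state, "stage stats: factorial model per metric")
      model_terms <- purrr::map_dfr(
        setdiff(unique(auc_design$metric), "mean_fluorescence"),
        function(m) {
          d <- dplyr::filter(auc_design, .data$metric == m, !is.na(.data$auc))
          ft <- tryCatch(fit_interaction_model(d), error = function(e) NULL)
          if (is.null(ft)) return(NULL)
          dplyr::mutate(tidy(ft), metric = m, .before = 1)
        })
    } else {
      pipeline_log(state, "stage stats: skipped (needs 8 conditions, 2+ plates)")
    }

    cond_means <- auc_design |>
      dplyr::filter(.data$metric %in% c("cdf", "coherency")) |>
      dplyr::group_by(.data$condition, .data$metric) |>
      dplyr::summarise(mean_auc = mean(.data$auc, na.rm = TRUE),
                       .groups = "drop")
    net <- if (dplyr::n_distinct(cond_means$condition) >= 2) {
      network_score(cond_means)
    } else NULL

    stage <- "report"
    pipeline_log(state, "stage write")
    readr::write_csv(metrics, file.path(config$out_dir, "metrics.csv"))
    readr::write_csv(traj, file.path(config$out_dir, "trajectories.csv"))
    readr::write_csv(auc_design, file.path(config$out_dir, "auc.csv"))
    if (!is.null(model_terms)) {
      readr::write_csv(model_terms,
                       file.path(config$out_dir, "model_terms.csv"))
    }
    if (!is.null(net)) {
      readr::write_csv(net, file.path(config$out_dir, "network_score.csv"))
    }
    structure(list(metrics = metrics, trajectories = traj, auc = auc_design,
                   model_terms = model_terms, network_score = net,
                   design = design, config = config,
                   out_dir = config$out_dir),
              class = "result_bundle")
  }, error = function(e) {
    pipeline_log(state, "FAILED at stage ", stage, ": ", conditionMessage(e))
    stop(sprintf("pipeline failed at stage `%s`: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  pipeline_log(state, "done")
  bundle
}

#' Generate figures and summary tables from a result bundle
#'
#' Writes one trajectory figure per metric (death events marked with black
#' squares), a per-factor AUC boxplot figure, and the network-score table.
#'
#' @param bundle A `result_bundle` from [run_pipeline()].
#' @param dir Output directory (default: the bundle's `report/` subdir).
#' @return Invisibly, a character vector of files written.
#' @export
make_report <- function(bundle, dir = file.path(bundle$out_dir, "report")) {
  stopifnot(inherits(bundle, "result_bundle"))
  if (is.null(bundle$trajectories) || nrow(bundle$trajectories) == 0) {
    stop("empty result bundle", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (m in unique(bundle$trajectories$metric)) {
    p <- autoplot.metric_trajectories(bundle$trajectories, metric = m)
    f <- file.path(dir, paste0("trajectory_", m, ".png"))
    ggplot2::ggsave(f, p, width = 7, height = 4.5, dpi = 120)
    files <- c(files, f)
  }
  aucp <- plot_auc_by_factor(bundle$auc)
  f <- file.path(dir, "auc_by_factor.png")
  ggplot2::ggsave(f, aucp, width = 9, height = 6, dpi = 120)
  files <- c(files, f)
  if (!is.null(bundle$network_score)) {
    f <- file.path(dir, "network_score.csv")
    readr::write_csv(bundle$network_score, f)
    files <- c(files, f)
  }
  invisible(files)
}
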