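#' Fit the factorial interaction model for a metric's AUCs
#'
#' Ordinary least squares of per-well AUC on the three culture factors
#' (media, laminin, seeding density), their three two-way interactions, and
#' plate as a categorical nuisance covariate:
#' `auc ~ media + laminin + density + media:laminin + media:density +
#' laminin:density + plate`. Factors use treatment coding with reference
#' levels NB / mouse / low, so each coefficient is the effect of switching
#' to BPI / human / high. Benjamini-Hochberg adjusted p-values are reported
#' across all six effect terms.
#'
#' @param auc_table Tibble with columns `auc`, `media`, `laminin`,
#'   `density`, `plate` (e.g. a [summarise_auc()] result joined to its
#'   design, or [generate_factorial_dataset()] output).
#' @return A `factorial_fit`: the underlying `lm` plus tidy term and plate
#'   tables. Access terms with [tidy()] and fit summaries with [glance()].
#' @export
fit_interaction_model <- function(auc_table) {
  needed <- c("auc", "media", "laminin", "density", "plate")
  missing_cols <- setdiff(needed, names(auc_table))
  if (length(missing_cols) > 0) {
    abort_param("auc_table", paste("missing columns:",
                                   paste(missing_cols, collapse = ", ")))
  }
  d <- auc_table
  d$media <- factor(d$media, levels = c("NB", "BPI"))
  d$laminin <- factor(d$laminin, levels = c("mouse", "human"))
  d$density <- factor(d$density, levels = c("low", "high"))
  d$plate <- factor(d$plate)
  if (nlevels(d$plate) < 2) {
    abort_param("auc_table", "at least 2 plates are required")
  }
  combos <- dplyr::distinct(d, .data$media, .data$laminin, .data$density)
  if (nrow(combos) < 8) {
    abort_param("auc_table", "all 8 factor combinations must be represented")
  }
  fit <- stats::lm(auc ~ media + laminin + density + media:laminin +
                     media:density + laminin:density + plate, data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  terms_tbl <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
  effect_terms <- c("mediaBPI", "lamininhuman", "densityhigh",
                    "mediaBPI:lamininhuman", "mediaBPI:densityhigh",
                    "lamininhuman:densityhigh")
  is_effect <- terms_tbl$term %in% effect_terms
  terms_tbl$p.adj <- NA_real_
  terms_tbl$p.adj[is_effect] <- benjamini_hochberg(terms_tbl$p.value[is_effect])
  structure(list(fit = fit,
                 terms = terms_tbl[!grepl("^plate", terms_tbl$term), ],
                 plate_effects = terms_tbl[grepl("^plate", terms_tbl$term),
                                           c("term", "estimate")]),
            class = "factorial_fit")
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat("<factorial_fit> effect terms:\n")
  print(x$terms)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_interaction_model
#' @param x A `factorial_fit`.
#' @param ... Unused.
#' @export
tidy.factorial_fit <- function(x, ...) x$terms

#' @rdname fit_interaction_model
#' @export
glance.factorial_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r.squared = sm$r.squared,
                 adj.r.squared = sm$adj.r.squared,
                 sigma = sm$sigma,
                 df.residual = x$fit$df.residual,
                 nobs = stats::nobs(x$fit))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement (delegates to [stats::p.adjust()] after validation).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (!is.numeric(pvalues) ||
      any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))) {
    abort_param("pvalues", "must be numeric values in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Rank-based network score per condition
#'
#' Ranks each condition's mean AUC for the two network metrics (Cluster
#' Density Factor and neurite coherency; rank 1 = lowest, ties share the
#' mean rank), sums the two ranks per condition, and reports the summed
#' rank as the overall network score — higher score, more mature network
#' formation. Conditions missing a mean for either metric are excluded with
#' a message.
#'
#' @param condition_means Tibble with columns `condition`, `metric`,
#'   `mean_auc`, containing one row per condition for each of two metrics
#'   (by convention `"cdf"` and `"coherency"`).
#' @return A tibble `condition`, one `rank_<metric>` column per metric,
#'   `summed_rank`, `score`, sorted by descending score.
#' @export
network_score <- function(condition_means) {
  needed <- c("condition", "metric", "mean_auc")
  missing_cols <- setdiff(needed, names(condition_means))
  if (length(missing_cols) > 0) {
    abort_param("condition_means", paste("missing columns:",
                                         paste(missing_cols, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(condition_means, names_from = "metric",
                             values_from = "mean_auc")
  metrics <- setdiff(names(wide), "condition")
  incomplete <- !stats::complete.cases(wide[metrics])
  if (any(incomplete)) {
    message("excluding condition(s) with missing means: ",
            paste(wide$condition[incomplete], collapse = ", "))
    wide <- wide[!incomplete, ]
  }
  for (m in metrics) {
    wide[[paste0("rank_", m)]] <- rank(wide[[m]], ties.method = "average")
  }
  rank_cols <- paste0("rank_", metrics)
  wide$summed_rank <- rowSums(wide[rank_cols])
  wide$score <- wide$summed_rank
  dplyr::arrange(
    dplyr::select(wide, "condition", dplyr::all_of(rank_cols),
                  "summed_rank", "score"),
    dplyr::desc(.data$score))
}
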