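test_that("noise-free factorial data is fitted exactly", {
  d0 <- generate_factorial_dataset(list(intercept = 10), noise_sd = 0,
                                   plate_effects = c(0, 0), seed = 2)
  ft <- fit_interaction_model(d0)
  est <- tidy(ft)
  expect_equal(est$estimate[est$term == "(Intercept)"], 10)
  expect_equal(max(abs(est$estimate[est$term != "(Intercept)"])), 0,
               tolerance = 1e-10)

  d1 <- generate_factorial_dataset(list(media = 5), noise_sd = 0,
                                   plate_effects = c(0, 0), seed = 2)
  est1 <- tidy(fit_interaction_model(d1))
  expect_equal(est1$estimate[est1$term == "mediaBPI"], 5, tolerance = 1e-10)
})

test_that("plate offsets are absorbed by the nuisance covariate", {
  d <- generate_factorial_dataset(list(media = 3), noise_sd = 0,
                                  plate_effects = c(0, 4, -2),
                                  n_wells_per_condition = 6, seed = 5)
  ft <- fit_interaction_model(d)
  est <- tidy(ft)
  expect_equal(est$estimate[est$term == "mediaBPI"], 3, tolerance = 1e-10)
  expect_equal(sort(ft$plate_effects$estimate), c(-2, 4), tolerance = 1e-10)
})

test_that("the model demands 2 plates and a full factorial", {
  d <- generate_factorial_dataset(noise_sd = 1, plate_effects = c(0, 0))
  d$plate <- "P1"
  expect_error(fit_interaction_model(d), "plate")
  d2 <- generate_factorial_dataset(noise_sd = 1, plate_effects = c(0, 0))
  expect_error(fit_interaction_model(d2[d2$media == "NB", ]), "combinations")
})

test_that("tidy and glance expose the fit the broom way", {
  d <- generate_factorial_dataset(list(media = 1), noise_sd = 0.5,
                                  plate_effects = c(0, 0), seed = 9)
  ft <- fit_interaction_model(d)
  tt <- tidy(ft)
  expect_true(all(c("term", "estimate", "statistic", "p.value", "p.adj")
                  %in% names(tt)))
  expect_equal(nrow(tt), 7)  # intercept + 3 main + 3 interactions
  effect_rows <- !is.na(tt$p.adj)
  expect_equal(sum(effect_rows), 6)
  expect_true(all(tt$p.adj[effect_rows] >= tt$p.value[effect_rows]))
  g <- glance(ft)
  expect_equal(g$nobs, nrow(d))
  expect_true(g$r.squared >= 0 && g$r.squared <= 1)
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  # step-up: p_(i) * m / i, cumulative minimum from the largest p down
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.04), 0.04)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))

  set.seed(3)
  p <- runif(20)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  hand <- numeric(m)
  hand[o] <- cummin(p[o] * m / rank(p)[o])
  hand <- pmin(hand, 1)
  expect_equal(benjamini_hochberg(p), hand)
  # monotone: adjusted >= raw and order-preserving
  expect_true(all(hand >= p))
  expect_equal(order(hand[order(p)]), seq_len(m))
  # idempotent on fully tied adjustments
  expect_equal(benjamini_hochberg(rep(0.03, 3)), rep(0.03, 3))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "pvalues")
})

test_that("network scores sum per-metric ranks with shared ties", {
  cm <- tidyr::expand_grid(condition = LETTERS[1:8],
                           metric = c("cdf", "coherency"))
  cm$mean_auc <- c(rbind(1:8, c(5, 6, 7, 8, 1, 2, 3, 4)))
  ns <- network_score(cm)
  expect_equal(ns$score[ns$condition == "H"], 8 + 4)
  # best-on-both extremal case
  cm2 <- cm
  cm2$mean_auc <- c(rbind(1:8, 1:8))
  ns2 <- network_score(cm2)
  expect_equal(ns2$score[1], 16)
  expect_equal(ns2$condition[1], "H")
  # ties share the mean rank and produce tied scores
  cm3 <- cm
  cm3$mean_auc <- rep(1, 16)
  ns3 <- network_score(cm3)
  expect_true(all(ns3$score == 2 * mean(1:8)))
})

test_that("network ranks agree with an independent sorting oracle", {
  for (s in 1:10) {
    set.seed(s)
    cm <- tidyr::expand_grid(condition = LETTERS[1:8],
                             metric = c("cdf", "coherency"))
    cm$mean_auc <- runif(16)
    ns <- network_score(cm)
    for (m in c("cdf", "coherency")) {
      vals <- cm$mean_auc[cm$metric == m]
      names(vals) <- cm$condition[cm$metric == m]
      sorted <- names(sort(vals))
      oracle_rank <- match(ns$condition, sorted)
      expect_equal(ns[[paste0("rank_", m)]], oracle_rank)
    }
  }
})

test_that("network score is invariant to monotone transforms of the means", {
  set.seed(5)
  cm <- tidyr::expand_grid(condition = LETTERS[1:8],
                           metric = c("cdf", "coherency"))
  cm$mean_auc <- runif(16)
  ns1 <- network_score(cm)
  cm2 <- cm
  cm2$mean_auc <- exp(3 * cm2$mean_auc)
  expect_equal(network_score(cm2), ns1)
})

test_that("conditions missing a metric mean are excluded with a message", {
  cm <- tidyr::expand_grid(condition = LETTERS[1:8],
                           metric = c("cdf", "coherency"))
  set.seed(2)
  cm$mean_auc <- runif(16)
  cm$mean_auc[cm$condition == "C" & cm$metric == "cdf"] <- NA
  expect_message(ns <- network_score(cm), "C")
  expect_equal(nrow(ns), 7)
  expect_false("C" %in% ns$condition)
})
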