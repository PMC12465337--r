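test_that("spec validation names the offending field", {
  expect_error(culture_spec(cluster_attraction = 2), "cluster_attraction")
  expect_error(culture_spec(image_shape = c(32, 128)), "image_shape")
  expect_error(culture_spec(bleach_rate = 1), "bleach_rate")
  expect_error(culture_spec(death_drop = 0), "death_drop")
  expect_error(culture_spec(n_days = 0), "n_days")
  expect_error(culture_spec(death_day = 99, n_days = 5), "death_day")
})

test_that("same seed and spec give a bit-identical time-course", {
  sp <- culture_spec(seed = 21, n_days = 3, image_shape = c(96, 96))
  expect_identical(generate_timecourse(sp), generate_timecourse(sp))
})

test_that("zero attraction freezes soma positions", {
  tc <- generate_timecourse(culture_spec(seed = 5, n_days = 3,
                                         cluster_attraction = 0,
                                         image_shape = c(96, 96)))
  expect_identical(tc$truth[[1]]$soma_centers, tc$truth[[3]]$soma_centers)
})

test_that("true mean intensity follows the closed-form bleaching decay", {
  tc <- generate_timecourse(culture_spec(seed = 3, n_days = 4,
                                         bleach_rate = 0.1, noise_sd = 0,
                                         image_shape = c(96, 96)))
  tm <- vapply(tc$truth, `[[`, numeric(1), "true_mean_intensity")
  expect_equal(tm[-1] / tm[-4], rep(0.9, 3), tolerance = 1e-12)
})

test_that("death event drops the intensity scale by death_drop", {
  tc <- generate_timecourse(culture_spec(seed = 4, n_days = 5, death_day = 3,
                                         death_drop = 0.4, bleach_rate = 0.05,
                                         image_shape = c(96, 96)))
  tm <- vapply(tc$truth, `[[`, numeric(1), "true_mean_intensity")
  expect_equal(tm[3] / tm[2], 0.95 * (1 - 0.4), tolerance = 1e-12)
  expect_equal(tm[5] / tm[4], 0.95, tolerance = 1e-12)  # no second drop
})

test_that("full fasciculation aligns the orientation field", {
  tc <- generate_timecourse(culture_spec(seed = 7, n_days = 3,
                                         fasciculation_strength = 1,
                                         image_shape = c(128, 128)))
  expect_lt(circular_variance(tc$truth[[3]]$orientation), 0.01)
})

test_that("orientation circular variance decreases with fasciculation", {
  cvs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    tc <- generate_timecourse(culture_spec(seed = 7, n_days = 2,
                                           fasciculation_strength = f,
                                           image_shape = c(128, 128)))
    circular_variance(tc$truth[[2]]$orientation)
  }, numeric(1))
  expect_true(all(diff(cvs) <= 0))
})

test_that("orientation values lie in [0, pi) and masks are disjoint", {
  tc <- generate_timecourse(culture_spec(seed = 13, n_days = 3,
                                         image_shape = c(96, 96)))
  for (t in tc$truth) {
    th <- t$orientation[!is.na(t$orientation)]
    expect_true(all(th >= 0 & th < pi))
    expect_false(any(t$soma_mask & t$neurite_mask))
    expect_identical(!is.na(t$orientation), t$neurite_mask)
  }
})

test_that("aggregation only merges: counts and perimeters never increase", {
  for (s in c(1, 2, 3)) {
    tc <- generate_timecourse(culture_spec(seed = s, n_days = 6,
                                           cluster_attraction = 0.25,
                                           image_shape = c(128, 128)))
    cnt <- vapply(tc$truth, function(t) t$objects$count, integer(1))
    per <- vapply(tc$truth, function(t) sum(t$objects$objects$perimeter),
                  numeric(1))
    expect_true(all(diff(cnt) <= 0))
    expect_true(all(diff(per) <= 0))
  }
})

test_that("a written time-course reads back with correct metadata and pixels", {
  tc <- generate_timecourse(culture_spec(seed = 2, n_days = 2,
                                         image_shape = c(64, 64)))
  root <- withr::local_tempdir()
  write_timecourse(tc, root, plate = "P7", well = "W03")
  ds <- read_dataset(root)
  expect_equal(nrow(ds), 2)
  expect_setequal(ds$day, 1:2)
  expect_equal(unique(ds$plate), "P7")
  expect_identical(ds$image[[which(ds$day == 2)]]$pixels,
                   tc$images[[2]]$pixels)
})

test_that("factorial dataset reproduces the linear model exactly without noise", {
  d0 <- generate_factorial_dataset(list(intercept = 7), noise_sd = 0,
                                   plate_effects = c(0, 0))
  expect_true(all(d0$auc == 7))
  d1 <- generate_factorial_dataset(list(media = 5), noise_sd = 0,
                                   plate_effects = c(0, 0))
  expect_equal(mean(d1$auc[d1$media == "BPI"]) -
                 mean(d1$auc[d1$media == "NB"]), 5)
  expect_error(generate_factorial_dataset(plate_effects = 3), "plate")
  expect_error(generate_factorial_dataset(n_wells_per_condition = 1),
               "n_wells_per_condition")
})

test_that("fitted coefficients recover the generating betas within 3 SE", {
  d <- generate_factorial_dataset(list(media = 2, laminin = -1, density = 0.5),
                                  n_wells_per_condition = 50, noise_sd = 1,
                                  plate_effects = c(0.5, -0.5), seed = 17)
  tt <- tidy(fit_interaction_model(d))
  truth <- c(mediaBPI = 2, lamininhuman = -1, densityhigh = 0.5)
  for (term in names(truth)) {
    row <- tt[tt$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$std.error)
  }
})
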