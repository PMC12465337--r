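make_objects <- function(mask) label_somata(mask)

test_that("DI follows its definition and drops when objects merge", {
  one <- matrix(FALSE, 12, 12); one[2:6, 2:3] <- TRUE  # area 10
  expect_equal(disaggregation_index(make_objects(one),
                                    baseline_reference(10, 1)), 1)

  four <- matrix(FALSE, 30, 30)
  for (ctr in list(c(3, 3), c(3, 20), c(20, 3), c(20, 20))) {
    four[ctr[1] + 0:1, ctr[2] + 0:4] <- TRUE  # 4 objects of area 10
  }
  b <- baseline_reference(10, 4)
  expect_equal(disaggregation_index(make_objects(four), b), 1)

  merged <- matrix(FALSE, 30, 30); merged[2:5, 2:11] <- TRUE  # one, area 40
  expect_equal(disaggregation_index(make_objects(merged), b), 0.25)
})

test_that("DI self-normalizes to exactly 1 with the day-1 baseline", {
  for (s in c(2, 9)) {
    tc <- generate_timecourse(culture_spec(seed = s, n_days = 2,
                                           image_shape = c(96, 96)))
    o1 <- tc$truth[[1]]$objects
    expect_equal(disaggregation_index(o1, baseline_from_objects(o1)), 1)
  }
})

test_that("CDF follows its definition and rises when somata fuse", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE  # 10x10, perimeter 40
  expect_equal(cluster_density_factor(make_objects(sq),
                                      baseline_reference(1, 1)), 1 / 40)

  apart <- matrix(FALSE, 20, 40)
  apart[6:15, 3:12] <- TRUE; apart[6:15, 25:34] <- TRUE  # two 10x10
  fused <- matrix(FALSE, 20, 40); fused[6:15, 3:22] <- TRUE  # 10x20
  b <- baseline_reference(1, 2)
  expect_equal(cluster_density_factor(make_objects(apart), b), 2 / 80)
  expect_equal(cluster_density_factor(make_objects(fused), b), 2 / 60)
})

test_that("DI and CDF are invariant to object order and report NA when empty", {
  m <- random_mask(55, 25, 25, 0.3)
  b <- baseline_reference(5, 3)
  di1 <- disaggregation_index(make_objects(m), b)
  cdf1 <- cluster_density_factor(make_objects(m), b)
  flipped <- m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  expect_equal(disaggregation_index(make_objects(flipped), b), di1)
  expect_equal(cluster_density_factor(make_objects(flipped), b), cdf1)

  none <- make_objects(matrix(FALSE, 8, 8))
  expect_warning(v1 <- disaggregation_index(none, b))
  expect_warning(v2 <- cluster_density_factor(none, b))
  expect_true(is.na(v1) && is.na(v2))
})

test_that("DI decreases on aggregating cultures (ground-truth masks)", {
  tc <- generate_timecourse(culture_spec(seed = 2, n_days = 6,
                                         cluster_attraction = 0.25,
                                         image_shape = c(128, 128)))
  base <- baseline_from_objects(tc$truth[[1]]$objects)
  di <- vapply(tc$truth, function(t) disaggregation_index(t$objects, base),
               numeric(1))
  expect_equal(di[1], 1)
  expect_lt(di[6], 0.6 * di[1])
  # non-increasing within tolerance: upticks from merge geometry stay small
  # relative to the trajectory's dynamic range
  expect_true(all(diff(di) <= 0.1 * (max(di) - min(di))))
})

test_that("window coherency hits its aligned, degenerate and isotropic limits", {
  stripes <- matrix(rep(c(0, 0, 1, 1), 8), 32, 32, byrow = TRUE)
  expect_gt(structure_tensor_coherency(stripes), 0.95)

  expect_equal(structure_tensor_coherency(matrix(5, 16, 16)), 0)

  set.seed(1)
  iso <- matrix(0, 64, 64)
  for (i in 1:60) {
    r0 <- runif(1, 5, 59); c0 <- runif(1, 5, 59); a <- runif(1, 0, pi)
    t <- seq(-4, 4, by = 0.5)
    rr <- round(r0 + t * sin(a)); cc <- round(c0 + t * cos(a))
    ok <- rr >= 1 & rr <= 64 & cc >= 1 & cc <= 64
    iso[cbind(rr[ok], cc[ok])] <- 1
  }
  expect_lt(structure_tensor_coherency(iso), 0.2)
  expect_error(structure_tensor_coherency(matrix(1, 3, 3)), "window")
})

test_that("coherency is invariant to global intensity scaling", {
  set.seed(12)
  w <- matrix(runif(900), 30, 30)
  expect_equal(structure_tensor_coherency(w * 50),
               structure_tensor_coherency(w), tolerance = 1e-9)
})

test_that("radial straight neurites give near-perfect region coherency", {
  canvas <- matrix(0, 96, 96); mask <- matrix(FALSE, 96, 96)
  st <- neurocult:::stamp_soma(canvas, mask, 48, 48, 6)
  px <- st$canvas
  neur <- matrix(FALSE, 96, 96)
  for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
    for (t in 7:40) {
      r <- 48 + d[1] * t; c <- 48 + d[2] * t
      neur[r, c + (-1:1) * abs(d[1])] <- TRUE
      neur[r + (-1:1) * abs(d[2]), c] <- TRUE
      px[neur] <- pmax(px[neur], 0.7)
    }
  }
  img <- field_image(px + 0.02, bit_depth = 32)
  objs <- label_somata(st$mask)
  rc <- region_coherency(img, objs, neur, reach = 25)
  expect_gt(rc$image_coherency, 0.9)
  expect_equal(rc$n_objects_used, 1)
  expect_true(all(rc$per_object$coherency >= 0 & rc$per_object$coherency <= 1))
})

test_that("region coherency is missing when no neurites exist", {
  canvas <- matrix(0, 64, 64); mask <- matrix(FALSE, 64, 64)
  st <- neurocult:::stamp_soma(canvas, mask, 32, 32, 5)
  img <- field_image(st$canvas + 0.02, bit_depth = 32)
  objs <- label_somata(st$mask)
  expect_warning(rc <- region_coherency(img, objs, matrix(FALSE, 64, 64)))
  expect_true(is.na(rc$image_coherency))
  expect_equal(rc$n_objects_used, 0)
})

test_that("image coherency rises with fasciculation strength", {
  fs <- c(0.1, 0.5, 0.9)
  coh <- vapply(fs, function(f) {
    tc <- generate_timecourse(culture_spec(seed = 11, n_days = 4,
                                           fasciculation_strength = f))
    tr <- tc$truth[[4]]
    suppressWarnings(region_coherency(
      rescale_minmax(tc$images[[4]]), label_somata(tr$soma_mask),
      tr$neurite_mask, reach = 20)$image_coherency)
  }, numeric(1))
  expect_true(all(diff(coh) > 0))
})

test_that("coherency FOV subsetting picks the uniform 3x3 grid", {
  sel <- select_coherency_fovs(8, 8)
  expect_equal(nrow(sel), 9)
  expect_equal(unique(sel$row), c(2, 5, 7))  # centres of thirds, 1-based
  expect_equal(unique(sel$col), c(2, 5, 7))

  full <- select_coherency_fovs(3, 3)
  expect_equal(nrow(full), 9)
  expect_equal(full$fov, 1:9)

  expect_message(deg <- select_coherency_fovs(2, 2), "fewer than 9")
  expect_equal(nrow(deg), 4)
})
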