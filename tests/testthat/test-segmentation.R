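test_that("labelling matches the flood-fill oracle on random masks", {
  for (s in 1:25) {
    m <- random_mask(s, 15, 15, density = 0.45)
    expect_true(same_partition(label_components(m, 8), oracle_label(m, 8)))
    expect_true(same_partition(label_components(m, 4), oracle_label(m, 4)))
  }
})

test_that("diagonally touching squares are one object under 8-connectivity", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE
  m[4:5, 4:5] <- TRUE
  expect_equal(label_somata(m)$count, 1)
  expect_equal(max(label_components(m, connectivity = 4)), 2)
})

test_that("soma objects report exact areas, perimeters and centroids", {
  m <- matrix(FALSE, 20, 20)
  m[2:6, 2:6] <- TRUE     # 5x5 square
  m[10:14, 10:14] <- TRUE # disjoint 5x5 square
  so <- label_somata(m)
  expect_equal(so$count, 2)
  expect_equal(sort(so$objects$area), c(25L, 25L))
  expect_equal(so$objects$perimeter, c(20L, 20L))
  expect_equal(so$objects$centroid_row[1], 4)
  expect_equal(sum(so$objects$area), sum(m))
})

test_that("per-object perimeters agree with the boundary-walk oracle", {
  for (s in 26:40) {
    m <- random_mask(s, 18, 18, density = 0.35)
    so <- label_somata(m)
    expect_equal(sum(so$objects$perimeter), oracle_perimeter(m))
    for (l in seq_len(so$count)) {
      expect_equal(so$objects$perimeter[l], oracle_perimeter(so$labels == l))
    }
  }
})

test_that("segmentation recovers synthetic ground truth at Dice thresholds", {
  for (s in c(2, 4)) {
    for (f in c(0.2, 0.8)) {
      tc <- generate_timecourse(culture_spec(seed = s, n_days = 3,
                                             fasciculation_strength = f))
      img <- rescale_minmax(tc$images[[3]])
      tr <- tc$truth[[3]]
      m <- segment_culture(img)
      expect_gt(dice_coef(m$soma, tr$soma_mask), 0.9)
      expect_gt(dice_coef(m$neurite, tr$neurite_mask), 0.8)
      expect_false(any(m$soma & m$neurite))
    }
  }
})

test_that("degenerate images yield empty masks with a warning", {
  expect_warning(m <- segment_culture(field_image(matrix(5, 64, 64))),
                 "constant")
  expect_false(any(m$soma) || any(m$neurite))
})

test_that("disc-only images have an empty neurite mask", {
  canvas <- matrix(0, 96, 96)
  mask <- matrix(FALSE, 96, 96)
  for (ctr in list(c(20, 20), c(50, 70), c(75, 35))) {
    st <- neurocult:::stamp_soma(canvas, mask, ctr[1], ctr[2], 6)
    canvas <- st$canvas; mask <- st$mask
  }
  img <- field_image(canvas + 0.02, bit_depth = 32)
  m <- segment_culture(rescale_minmax(img), soma_radius = 6)
  expect_equal(sum(m$neurite), 0)
  expect_gt(dice_coef(m$soma, mask), 0.9)
})

test_that("external masks are binarised with soma priority and shape-checked", {
  img <- field_image(matrix(0, 8, 8))
  soma <- matrix(0, 8, 8); soma[2:4, 2:4] <- 128
  neur <- matrix(0, 8, 8); neur[4:6, 4] <- 255   # overlaps soma at (4,4)
  m <- ingest_masks(soma, neur, img)
  expect_identical(m$soma, soma > 0)
  expect_true(m$soma[4, 4] && !m$neurite[4, 4])  # soma priority
  expect_equal(sum(m$neurite), 2)
  expect_equal(m$source, "external")
  expect_error(ingest_masks(matrix(0, 4, 4), neur, img), "4x4.*8x8")
})

test_that("external mask TIFFs round-trip through ingest_masks", {
  img <- field_image(matrix(0, 8, 8))
  soma <- matrix(FALSE, 8, 8); soma[2:3, 2:3] <- TRUE
  neur <- matrix(FALSE, 8, 8); neur[6, 2:7] <- TRUE
  sp <- withr::local_tempfile(fileext = ".tif")
  np <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(soma * 1, sp, bits.per.sample = 8L)
  tiff::writeTIFF(neur * 1, np, bits.per.sample = 8L)
  m <- ingest_masks(sp, np, img)
  expect_identical(m$soma, soma)
  expect_identical(m$neurite, neur)
})

test_that("mean fluorescence matches a loop oracle and ignores unmasked pixels", {
  set.seed(3)
  px <- matrix(runif(400, 0, 100), 20, 20)
  soma <- random_mask(41, 20, 20, 0.2)
  neur <- random_mask(42, 20, 20, 0.2) & !soma
  img <- field_image(px)
  m <- neurocult:::new_segmentation_masks(soma, neur, "external")
  expect_equal(mean_fluorescence(img, m), oracle_masked_mean(px, soma | neur))

  px2 <- px
  px2[!(soma | neur)] <- 9999  # outside-mask intensities are irrelevant
  expect_equal(mean_fluorescence(field_image(px2), m),
               mean_fluorescence(img, m))

  uniform <- field_image(matrix(7, 20, 20))
  expect_equal(mean_fluorescence(uniform, m), 7)
  empty <- neurocult:::new_segmentation_masks(matrix(FALSE, 20, 20),
                                              matrix(FALSE, 20, 20),
                                              "external")
  expect_warning(v <- mean_fluorescence(img, empty), "empty")
  expect_equal(v, 0)
})
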