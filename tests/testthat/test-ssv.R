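test_that("euclidean distance and cosine similarity match closed forms", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(1, 2, 3), c(4, 6, 3)), 5)  # sqrt(9+16+0)
  expect_error(euclidean_distance(1:3, 1:2), "dimension error")

  expect_equal(cosine_similarity(c(2, 1), c(2, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(2, 4), c(1, 2)), 1)  # scale invariance
  expect_true(is.na(cosine_similarity(c(0, 0), c(1, 2))))
  expect_error(cosine_similarity(1:3, 1:2), "dimension error")
})

test_that("distance normalization maps scene extremes to 0 and 1", {
  d <- matrix(c(0, 5, 10, NA), 2, 2)
  nd <- normalize_distance(d)
  expect_equal(nd$d_min, 0)
  expect_equal(nd$d_max, 10)
  expect_equal(nd$d_norm[1:3], c(0, 0.5, 1))
  expect_true(is.na(nd$d_norm[4]))

  const <- matrix(3, 2, 2)
  expect_equal(normalize_distance(const)$d_norm, matrix(0, 2, 2))
  expect_error(normalize_distance(matrix(NA_real_, 2, 2)), "empty-image")
})

test_that("standard curve is the mean rice feature vector, invalid points dropped", {
  g <- raster_grid(2, 2, px = 10)
  img <- make_image(list(a = matrix(c(1, 3, 9, 9), 2, 2),
                         b = matrix(c(3, 5, 9, 9), 2, 2)), g)
  # pixel centres: (5,15)=r1c1 value a=1,b=3 ; (5,5)=r2c1 a=3,b=5
  pts <- sample_point_set(c(5, 5), c(15, 5), c("rice", "rice"))
  cv <- build_standard_curve(img, pts)
  expect_equal(unname(cv$values), c(2, 4))
  expect_equal(cv$sample_count, 2)

  one <- build_standard_curve(img, sample_point_set(5, 15, "rice"))
  expect_equal(unname(one$values), c(1, 3))

  # point on an invalid (nodata) pixel is excluded with a message
  img$values$a[1, 1] <- NA
  expect_message(cv2 <- build_standard_curve(img, pts), "dropped")
  expect_equal(unname(cv2$values), c(3, 5))
  img$values$a[2, 1] <- NA
  expect_error(suppressMessages(build_standard_curve(img, pts)), "calibration error")
  expect_error(build_standard_curve(img, sample_point_set(5, 5, "water")),
               "calibration error")
})

test_that("min-max scaling maps bands to [0,1], flags degenerate bands, and transforms the curve identically", {
  g <- raster_grid(1, 3, px = 10)
  img <- make_image(list(vh = matrix(c(-20, -15, -10), 1, 3),
                         flat = matrix(7, 1, 3)), g)
  sc <- scale_features(img, "minmax")
  expect_equal(as.vector(sc$image$values$vh), c(0, 0.5, 1))
  expect_equal(as.vector(sc$image$values$flat), c(0, 0, 0))
  expect_true(sc$record$degenerate[2])

  cv <- structure(list(stage = "sowing", features = c("vh", "flat"),
                       values = c(vh = -15, flat = 7), n = 2L, sample_count = 1L),
                  class = "standard_curve")
  cvs <- apply_scaling(cv, sc$record)
  expect_equal(unname(cvs$values), c(0.5, 0))

  sc_none <- scale_features(img, "none")
  expect_identical(sc_none$image$values, img$values)
})

test_that("the 3-pixel toy SSV image matches hand computation", {
  # pixels (1,0), (0.6,0.8), (1,1) vs curve (1,0), scaling none:
  # d  = (0, sqrt(0.8), 1); d_min = 0, d_max = 1 -> d_norm = (0, 0.894427, 1)
  # cs = (1, 0.6, 1/sqrt(2))
  # ssv = (1, 0.6 - sqrt(0.8), 1/sqrt(2) - 1)
  g <- raster_grid(1, 3, px = 10)
  img <- make_image(list(f1 = matrix(c(1, 0.6, 1), 1, 3),
                         f2 = matrix(c(0, 0.8, 1), 1, 3)), g)
  cv <- structure(list(stage = "sowing", features = c("f1", "f2"),
                       values = c(f1 = 1, f2 = 0), n = 2L, sample_count = 1L),
                  class = "standard_curve")
  s <- ssv_image(img, cv, scaling = "none")
  expect_equal(as.vector(s$d), c(0, sqrt(0.8), 1), tolerance = 1e-9)
  expect_equal(s$d_min, 0)
  expect_equal(s$d_max, 1)
  expect_equal(as.vector(s$d_norm), c(0, sqrt(0.8), 1), tolerance = 1e-9)
  expect_equal(as.vector(s$cs), c(1, 0.6, 1 / sqrt(2)), tolerance = 1e-9)
  expect_equal(as.vector(s$ssv), c(1, 0.6 - sqrt(0.8), 1 / sqrt(2) - 1),
               tolerance = 1e-9)
  # the pixel identical to the curve attains cs = 1, d_norm = 0, ssv = 1
  expect_equal(s$ssv[1, 1], 1)
})

test_that("production SSV equals the naive per-pixel oracle on random scenes", {
  for (seed in c(1, 2)) {
    img <- random_image(16, 16, 8, seed)
    img$values$f1[3, 4] <- NA  # nodata propagates
    cv <- random_curve(img, seed)
    for (mode in c("minmax", "none")) {
      got <- ssv_image(img, cv, scaling = mode)
      want <- ssv_oracle(img, cv, scaling = mode)
      expect_equal(got$ssv, want$ssv, tolerance = 1e-12)
      expect_equal(got$cs, want$cs, tolerance = 1e-12)
      expect_equal(got$d, want$d, tolerance = 1e-12)
      expect_true(is.na(got$ssv[3, 4]))
    }
  }
})

test_that("ssv = cs - d_norm with the documented bounds and rank behaviour", {
  img <- random_image(20, 20, 10, 5)
  cv <- random_curve(img, 5)
  s <- ssv_image(img, cv, scaling = "minmax")
  ok <- !is.na(s$ssv)
  expect_equal(s$ssv[ok], (s$cs - s$d_norm)[ok])
  expect_true(all(s$ssv[ok] <= 1 + 1e-12))
  expect_true(all(s$ssv[ok] >= -1 - 1e-12))  # minmax: all features non-negative
  expect_true(all(s$d[ok] >= 0))
  expect_true(all(s$d_norm[ok] >= 0 & s$d_norm[ok] <= 1))
  expect_true(all(abs(s$cs[ok]) <= 1))
  expect_lte(s$d_min, s$d_max)

  # rank property: with equal cs, ssv strictly decreases in d. Build pixels
  # colinear with the curve (cs = 1) at increasing distances.
  g <- raster_grid(1, 4, px = 10)
  img2 <- make_image(list(f1 = matrix(c(1, 2, 3, 4), 1, 4),
                          f2 = matrix(c(2, 4, 6, 8), 1, 4)), g)
  cv2 <- structure(list(stage = "sowing", features = c("f1", "f2"),
                        values = c(f1 = 1, f2 = 2), n = 2L, sample_count = 1L),
                   class = "standard_curve")
  s2 <- ssv_image(img2, cv2, scaling = "none")
  expect_equal(as.vector(s2$cs), rep(1, 4), tolerance = 1e-12)
  expect_true(all(diff(as.vector(s2$ssv)) < 0))
})

test_that("rice pixels outscore every non-rice class at every stage on the synthetic scene", {
  sc <- small_scene()
  cal <- crop_calendar()
  masks <- lapply(sc$optical$values, function(v) cloud_score(v)$mask)
  terrain <- list(elevation = sc$dem, slope = sc$slope)
  pts <- sample_points(sc, c(rice = 25), "training", seed = 5)
  for (st in rice_stages()) {
    img <- build_stage_feature_image(
      st, mean_composite(sc$optical, st, cal, masks),
      mean_composite(sc$sar, st, cal), terrain, sc$grid, "combined")
    s <- ssv_image(img, build_standard_curve(img, pts), "minmax")
    rice_med <- stats::median(s$ssv[sc$truth == 1], na.rm = TRUE)
    for (cl in c("water", "built-up", "natural-vegetation", "dry-land")) {
      sel <- sc$classes == cl & sc$truth == 0
      expect_gt(rice_med, stats::median(s$ssv[sel], na.rm = TRUE),
                label = paste("rice median SSV at", st, "vs", cl))
    }
  }
})

test_that("ssv images survive a write/read round trip", {
  img <- random_image(6, 6, 4, 9)
  s <- ssv_image(img, random_curve(img, 9), "minmax")
  f <- file.path(tempdir(), "ssv_test.json")
  write_ssv(s, f)
  r <- read_raster(f)
  expect_identical(r$values$ssv, s$ssv)
  expect_equal(r$metadata$d_max, s$d_max)
})
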