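test_that("dates map to half-open stage windows", {
  cal <- crop_calendar()
  expect_equal(assign_stage(100, cal), "sowing")          # DOY 100 in [60,110)
  expect_equal(assign_stage(110, cal), "transplanting")   # boundary -> later stage
  expect_equal(assign_stage(130, cal), "growing")         # transplanting/growing boundary
  expect_equal(assign_stage(230, cal), "maturity")
  expect_true(is.na(assign_stage(300, cal)))              # fallow: outside all windows
  expect_true(is.na(assign_stage(10, cal)))
  # Date input: 2020-04-09 is DOY 100 (leap year)
  expect_equal(assign_stage(as.Date("2020-04-09"), cal), "sowing")
  expect_error(crop_calendar(data.frame(stage = rice_stages(),
                                        start = c(60, 100, 130, 230),
                                        end = c(110, 130, 230, 270))),
               "non-overlapping")
})

test_that("mean composite averages valid unmasked dates only", {
  g <- tiny_grid(2, 2)
  mk <- function(v) list(vh = matrix(v, 2, 2), vv = matrix(v - 5, 2, 2))
  st <- temporal_stack(as.Date(c("2020-06-10", "2020-06-22")), c("vh", "vv"),
                       list(mk(10), mk(20)), "sar-db", g)
  cal <- crop_calendar()
  comp <- mean_composite(st, "growing", cal)
  expect_equal(comp$vh, matrix(15, 2, 2))

  # idempotence: two identical dates -> composite equals either date
  st2 <- temporal_stack(as.Date(c("2020-06-10", "2020-06-22")), c("vh", "vv"),
                        list(mk(10), mk(10)), "sar-db", g)
  expect_equal(mean_composite(st2, "growing", cal)$vh, matrix(10, 2, 2))

  # masked date excluded pixel-wise
  masks <- list(matrix(FALSE, 2, 2), matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  compm <- mean_composite(st, "growing", cal, masks)
  expect_equal(compm$vh[1, 1], 10)   # cloudy 20 dropped
  expect_equal(compm$vh[2, 2], 15)

  # zero valid dates at a pixel -> nodata
  masks2 <- list(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2),
                 matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_true(is.na(mean_composite(st, "growing", cal, masks2)$vh[1, 1]))

  # stage with zero acquisitions is a coverage error
  expect_error(mean_composite(st, "sowing", cal), "stage-coverage error")
})

test_that("mean composite is linear and date-order invariant", {
  g <- tiny_grid(3, 3)
  set.seed(11)
  vals <- lapply(1:3, function(i) list(vh = matrix(rnorm(9, -18, 2), 3, 3)))
  dates <- as.Date(c("2020-06-10", "2020-07-04", "2020-07-28"))
  cal <- crop_calendar()
  st <- temporal_stack(dates, "vh", vals, "sar-db", g)
  comp <- mean_composite(st, "growing", cal)$vh

  st_scaled <- temporal_stack(dates, "vh",
                              lapply(vals, function(v) list(vh = 3 * v$vh)),
                              "sar-db", g)
  expect_equal(mean_composite(st_scaled, "growing", cal)$vh, 3 * comp)

  # permuting which value sits on which (same-stage) date changes nothing
  st_perm <- temporal_stack(dates, "vh", vals[c(3, 1, 2)], "sar-db", g)
  expect_equal(mean_composite(st_perm, "growing", cal)$vh, comp)
})

test_that("indices are computed on composited reflectance, not per-date", {
  # asymmetric values where mean-of-indices != index-of-means
  g <- tiny_grid(1, 1)
  d1 <- list(nir = matrix(0.8), red = matrix(0.1))
  d2 <- list(nir = matrix(0.2), red = matrix(0.1))
  ndvi_of_means <- (0.5 - 0.1) / (0.5 + 0.1)
  mean_of_ndvis <- mean(c((0.8 - 0.1) / 0.9, (0.2 - 0.1) / 0.3))
  expect_false(isTRUE(all.equal(ndvi_of_means, mean_of_ndvis)))

  full <- function(nir) {
    b <- const_bands(list(blue = .03, green = .06, red = .1, rededge1 = .1,
                          rededge2 = .3, rededge3 = .35, nir = nir,
                          narrownir = .5, swir1 = .2, swir2 = .1), 1, 1)
    b
  }
  st <- temporal_stack(as.Date(c("2020-06-10", "2020-06-22")), optical_bands(),
                       list(full(0.8), full(0.2)), "optical-reflectance", g)
  comp <- mean_composite(st, "growing", crop_calendar())
  img <- build_stage_feature_image("growing", optical = comp,
                                   sar = list(vh = matrix(-15), vv = matrix(-10)),
                                   terrain = list(elevation = matrix(300),
                                                  slope = matrix(0)),
                                   grid = g, mode = "combined")
  expect_equal(img$values$ndvi[1, 1], ndvi_of_means)
})

test_that("stage feature images stack the declared features in fixed order", {
  sc <- small_scene()
  cal <- crop_calendar()
  terrain <- list(elevation = sc$dem, slope = sc$slope)
  opt <- mean_composite(sc$optical, "growing", cal)
  sar <- mean_composite(sc$sar, "growing", cal)

  img <- build_stage_feature_image("growing", opt, sar, terrain, sc$grid, "combined")
  expect_length(img$features, 20)  # 10 bands + 6 indices + 2 SAR + 2 terrain
  expect_equal(img$features, feature_names("combined"))

  img_sar <- build_stage_feature_image("growing", sar = sar, terrain = terrain,
                                       grid = sc$grid, mode = "sar-only")
  expect_equal(img_sar$features, c("vh", "vv", "elevation", "slope"))

  img_opt <- build_stage_feature_image("growing", optical = opt, terrain = terrain,
                                       grid = sc$grid, mode = "optical-only")
  expect_length(img_opt$features, 18)

  expect_error(build_stage_feature_image("growing", optical = opt["blue"],
                                         sar = sar, terrain = terrain,
                                         grid = sc$grid, mode = "combined"),
               "schema error")
})

test_that("a pixel cloud-masked on every stage date is invalid in that stage", {
  sc <- small_scene()
  cal <- crop_calendar()
  masks <- lapply(sc$optical$values, function(v) matrix(FALSE, sc$grid$nrow, sc$grid$ncol))
  sow <- which(assign_stage(sc$optical$dates, cal) == "sowing")
  for (i in sow) masks[[i]][5, 5] <- TRUE
  comp <- mean_composite(sc$optical, "sowing", cal, masks)
  img <- build_stage_feature_image("sowing", comp,
                                   mean_composite(sc$sar, "sowing", cal),
                                   list(elevation = sc$dem, slope = sc$slope),
                                   sc$grid, "combined")
  expect_false(valid_mask(img)[5, 5])
  expect_true(valid_mask(img)[6, 6])
})
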