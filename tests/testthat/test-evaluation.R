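test_that("confusion matrix tabulates predicted vs reference binary labels", {
  g <- raster_grid(2, 5, px = 10)
  pred <- structure(list(values = matrix(c(rep(1, 5), rep(0, 5)), 2, 5, byrow = TRUE),
                         grid = g), class = "rice_map")
  # 5 points on predicted-rice row, 5 on predicted-non-rice row
  x <- seq(5, 45, by = 10)
  pts <- sample_point_set(c(x, x), c(rep(15, 5), rep(5, 5)),
                          c(rep("rice", 5), rep(c("water", "dry-land"), length.out = 5)),
                          role = "validation")
  cm <- confusion(pred, pts)
  expect_equal(unclass(cm), matrix(c(5L, 0L, 0L, 5L), 2, 2,
               dimnames = list(predicted = c("rice", "non-rice"),
                               reference = c("rice", "non-rice"))),
               ignore_attr = "class")

  # all-rice prediction on 5 rice + 5 non-rice points -> (5,5;0,0)
  pred$values[] <- 1
  cm2 <- confusion(pred, pts)
  expect_equal(as.vector(unclass(cm2)), c(5, 0, 5, 0))

  # samples on nodata pixels are dropped with a message
  pred$values[1, 1] <- NA
  expect_message(cm3 <- confusion(pred, pts), "dropped")
  expect_equal(sum(unclass(cm3)), 9)
  pred$values[] <- NA
  expect_error(suppressMessages(confusion(pred, pts)), "evaluation error")
})

test_that("metrics reproduce the published accuracy table from its printed counts", {
  # Dianjiang: predicted rice (61 rice, 3 non-rice), predicted non-rice (4, 118)
  dj <- metrics(confusion_matrix(matrix(c(61, 4, 3, 118), 2, 2)))
  expect_equal(dj$rounded$ua_rice, 0.95)
  expect_equal(dj$rounded$pa_rice, 0.94)
  expect_equal(dj$rounded$oa, 0.96)
  expect_equal(dj$rounded$kappa, 0.92)
  expect_equal(dj$oa, 179 / 186)
  expect_equal(dj$kappa, (186 * 179 - (64 * 65 + 122 * 121)) /
                           (186^2 - (64 * 65 + 122 * 121)))

  # Zhongxian: (34,3;6,37); printed OA is 0.88 although 71/80 = 0.8875,
  # so OA/kappa are compared at printed precision (one unit in the 2nd decimal)
  zx <- metrics(confusion_matrix(matrix(c(34, 6, 3, 37), 2, 2)))
  expect_equal(zx$rounded$ua_rice, 0.92)
  expect_equal(zx$rounded$pa_rice, 0.85)
  expect_equal(zx$oa, 0.8875)
  expect_lt(abs(zx$oa - 0.88), 0.01)
  expect_equal(zx$kappa, 0.775)
  expect_equal(zx$rounded$kappa, 0.78)
})

test_that("kappa hits its boundary cases and zero marginals are not-applicable", {
  perfect <- metrics(confusion_matrix(matrix(c(7, 0, 0, 13), 2, 2)))
  expect_equal(perfect$oa, 1)
  expect_equal(perfect$kappa, 1)

  # rows proportional to column marginals -> chance agreement, kappa 0
  chance <- metrics(confusion_matrix(matrix(c(8, 8, 2, 2), 2, 2)))
  expect_equal(chance$kappa, 0)

  nr <- metrics(confusion_matrix(matrix(c(0, 5, 0, 15), 2, 2)))
  expect_true(is.na(nr$ua_rice))   # no predicted rice
  expect_equal(nr$pa_rice, 0)
  nc <- metrics(confusion_matrix(matrix(c(0, 0, 5, 15), 2, 2)))
  expect_true(is.na(nc$pa_rice))   # no reference rice
  expect_error(metrics(confusion_matrix(matrix(0, 2, 2))), "evaluation error")
})

test_that("patch labelling respects connectivity and ordering invariance", {
  m <- matrix(0, 5, 5)
  m[1, 1] <- 1; m[2, 2] <- 1   # diagonal pair
  m[5, 4:5] <- 1               # horizontal pair
  lab8 <- label_patches(m == 1, 8)
  lab4 <- label_patches(m == 1, 4)
  expect_equal(max(lab8), 2)   # diagonal merges under 8-connectivity
  expect_equal(max(lab4), 3)
  expect_equal(sum(lab8 > 0), 4)
  # labelling order does not affect patch membership sizes
  expect_setequal(tabulate(lab8[lab8 > 0]), c(2, 2))
})

test_that("patch-size recognition counts omissions per area bin", {
  truth <- matrix(0, 10, 10)
  truth[2:4, 2:4] <- 1          # 9 px = 900 m2
  truth[8, 8] <- 1              # 1 px = 100 m2
  pred <- structure(list(values = truth, grid = raster_grid(10, 10, px = 10)),
                    class = "rice_map")

  perfect <- patch_recognition_by_size(truth, pred, c(0, 400, 800))
  occupied <- perfect$n_pixels > 0
  expect_equal(perfect$proportion[occupied], c(1, 1))

  empty_pred <- pred; empty_pred$values[] <- 0
  none <- patch_recognition_by_size(truth, empty_pred, c(0, 400, 800))
  expect_equal(none$proportion[occupied], c(0, 0))

  # 8 of 9 pixels of the 900 m2 patch predicted -> 8/9 in the [800, Inf) bin
  part <- pred; part$values[2, 2] <- 0
  pr <- patch_recognition_by_size(truth, part, c(0, 400, 800))
  expect_equal(pr$proportion[pr$bin == "[800,Inf)"], 8 / 9)
  expect_equal(pr$n_patches[pr$bin == "[0,400)"], 1L)

  # proportions stay in [0,1]
  expect_true(all(pr$proportion >= 0 & pr$proportion <= 1, na.rm = TRUE))
  expect_error(patch_recognition_by_size(truth * 0, pred), "evaluation error")

  # pixel- vs patch-weighted differ when bins mix patch sizes
  truth2 <- matrix(0, 10, 10); truth2[1, 1:8] <- 1; truth2[3, 1:9] <- 1
  pred2 <- structure(list(values = truth2 * 0, grid = raster_grid(10, 10, px = 10)),
                     class = "rice_map")
  pred2$values[1, 1:8] <- 1     # first patch fully found, second missed
  px_w <- patch_recognition_by_size(truth2, pred2, c(0, 10000))
  pa_w <- patch_recognition_by_size(truth2, pred2, c(0, 10000), weighting = "patch")
  expect_equal(px_w$proportion[1], 8 / 17)
  expect_equal(pa_w$proportion[1], 0.5)
})

test_that("slope-binned recognition is a direct count ratio with NA for empty bins", {
  truth <- matrix(0, 6, 6); truth[, 1:3] <- 1
  slope <- matrix(rep(c(0, 1, 3, 8, 12, 15), each = 6), 6, 6)
  pred <- structure(list(values = truth, grid = raster_grid(6, 6, px = 10)),
                    class = "rice_map")
  r <- recognition_by_slope(truth, pred, slope, c(0, 2, 6, 10))
  expect_equal(r$proportion[r$bin == "[0,2)"], 1)     # flat, perfect
  expect_equal(r$proportion[r$bin == "[2,6)"], 1)
  expect_true(is.na(r$proportion[r$bin == "[10,Inf)"]))  # no rice that steep

  # brute-force oracle on a random hillside scene
  set.seed(30)
  truth2 <- matrix(rbinom(36, 1, 0.4), 6, 6)
  predv <- ifelse(matrix(runif(36), 6, 6) < 0.7, truth2, 0)
  slope2 <- matrix(runif(36, 0, 14), 6, 6)
  got <- recognition_by_slope(truth2, list(values = predv), slope2, c(0, 2, 6, 10))
  edges <- c(0, 2, 6, 10, Inf)
  for (k in 1:4) {
    sel <- truth2 == 1 & slope2 >= edges[k] & slope2 < edges[k + 1]
    want <- if (!any(sel)) NA_real_ else sum(predv[sel] == 1) / sum(sel)
    expect_equal(got$proportion[k], want)
  }
})
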