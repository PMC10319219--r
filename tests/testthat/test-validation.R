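test_that("accuracy metrics reproduce the reference worked example", {
  cm <- confusion_counts(tp = 380, fp = 2, fn = 33, tn = 585)
  m <- accuracy_metrics(cm)
  expect_equal(round(m$oa, 2), 96.50)
  expect_equal(round(m$ua_flooded, 2), 99.48)
  expect_equal(round(m$pa_flooded, 2), 92.01)
  expect_equal(round(m$ua_nonflooded, 2), 94.66)
  expect_equal(round(m$pa_nonflooded, 2), 99.66)
  # harmonic-mean F1 of the same counts
  p <- 380 / 382; r <- 380 / 413
  expect_equal(m$f1, 2 * p * r / (p + r))
})

test_that("accuracy metrics handle perfect, degenerate and random cases", {
  perfect <- confusion_counts(tp = 10, fp = 0, fn = 0, tn = 20)
  mp <- accuracy_metrics(perfect)
  expect_equal(mp$oa, 100)
  expect_equal(mp$f1, 1)

  inverted <- confusion_counts(tp = 0, fp = 20, fn = 10, tn = 0)
  expect_equal(accuracy_metrics(inverted)$oa, 0)

  none_pred <- accuracy_metrics(confusion_counts(0, 0, 5, 5))
  expect_true(is.na(none_pred$ua_flooded))
  expect_error(accuracy_metrics(confusion_counts(0, 0, 0, 0)), "empty")
  expect_error(confusion_counts(-1, 0, 0, 2), "non-negative")

  set.seed(91)
  for (i in 1:5) {
    n <- sample(5:50, 4)
    cm <- confusion_counts(n[1], n[2], n[3], n[4])
    m <- accuracy_metrics(cm)
    expect_equal(m$oa, 100 * (n[1] + n[4]) / sum(n))
    expect_equal(m$ua_flooded, 100 * n[1] / (n[1] + n[2]))
    expect_equal(m$pa_flooded, 100 * n[1] / (n[1] + n[3]))
    expect_equal(m$ua_nonflooded, 100 * n[4] / (n[4] + n[3]))
    expect_equal(m$pa_nonflooded, 100 * n[4] / (n[4] + n[2]))
  }
})

test_that("confusion counts agree with a brute-force point loop", {
  pred <- rand_binary_map(95, nr = 20, nc = 20, px = 10)
  pred$values[1, 1] <- NA
  set.seed(96)
  smp <- tibble::tibble(
    x = runif(200, 0, 200), y = runif(200, 0, 200),
    label = sample(c("flooded", "non_flooded"), 200, replace = TRUE),
    split = sample(c("train", "val"), 200, replace = TRUE))
  cm <- suppressWarnings(confusion(pred, smp, split = "val"))
  # loop oracle
  tp <- fp <- fn <- tn <- 0
  for (i in which(smp$split == "val")) {
    col <- floor(smp$x[i] / 10) + 1; row <- 20 - floor(smp$y[i] / 10)
    v <- pred$values[row, col]
    if (is.na(v)) next
    fl <- smp$label[i] == "flooded"
    if (v == 1 && fl) tp <- tp + 1
    if (v == 1 && !fl) fp <- fp + 1
    if (v == 0 && fl) fn <- fn + 1
    if (v == 0 && !fl) tn <- tn + 1
  }
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(tp, fp, fn, tn))

  # perfect and inverted predictions
  truth_map <- rand_binary_map(97, nr = 20, nc = 20)
  pts <- tibble::tibble(
    x = rep(seq(5, 195, by = 10), 20),
    y = rep(seq(195, 5, by = -10), each = 20))
  pts$label <- ifelse(as.vector(t(truth_map$values)) == 1,
                      "flooded", "non_flooded")
  cm_perf <- confusion(truth_map, pts)
  expect_equal(cm_perf$fp + cm_perf$fn, 0)
  inv <- raster_grid(1 - truth_map$values, pixel_size = 10)
  cm_inv <- confusion(inv, pts)
  expect_equal(cm_inv$tp + cm_inv$tn, 0)
})

test_that("threshold calibration separates classes and is deterministic", {
  set.seed(101)
  n <- 300
  idxvals <- c(runif(n / 2, -9, -5.5), runif(n / 2, -0.9, 0))
  r <- raster_grid(matrix(idxvals, nrow = 15), pixel_size = 10)
  pts <- tibble::tibble(
    x = rep(seq(5, by = 10, length.out = 20), each = 15),
    y = rep(seq(145, by = -10, length.out = 15), times = 20))
  pts$label <- ifelse(as.vector(r$values) < -3, "flooded", "non_flooded")

  th <- calibrate_threshold(r, pts, seed = 7)
  expect_gt(th$T, -5.5)
  expect_lt(th$T, -0.9)
  expect_equal(th$oa, 100)
  th2 <- calibrate_threshold(r, pts, seed = 7)
  expect_identical(th$T, th2$T)
  expect_false(identical(th$T, calibrate_threshold(r, pts, seed = 8)$T))

  # within 1 OA point of the exhaustive optimum on the validation set
  vals <- extract_values(r, pts)
  lab <- pts$label == "flooded"
  cand <- sort(unique(vals))
  cand <- c(cand - 1e-9, cand + 1e-9)
  best_oa <- max(vapply(cand, function(T)
    mean((vals < T) == lab) * 100, numeric(1)))
  expect_gte(th$oa, best_oa - 1)

  one_class <- pts; one_class$label <- "flooded"
  expect_error(calibrate_threshold(r, one_class), "both flooded")

  const <- raster_grid(matrix(-2, 15, 20), pixel_size = 10)
  expect_warning(thc <- calibrate_threshold(const, pts), "degenerate")
  expect_equal(thc$T, -2)
})

test_that("optical indices match their closed forms", {
  mk <- function(v) raster_grid(matrix(v, 2, 2))
  oi <- optical_indices(red = mk(1000), blue = mk(500), nir = mk(4000),
                        swir1 = mk(2000))
  expect_equal(oi$ndvi$values[1, 1], 3000 / 5000)
  expect_equal(oi$evi$values[1, 1], 7500 / 16250)
  expect_equal(oi$lswi$values[1, 1], 2000 / 6000)

  # NIR == RED -> NDVI 0 ; zero denominator -> nodata
  oi2 <- optical_indices(red = mk(2000), blue = mk(500), nir = mk(2000),
                         swir1 = mk(-2000))
  expect_equal(oi2$ndvi$values[1, 1], 0)
  expect_true(is.na(oi2$lswi$values[1, 1]))

  # 0-1 reflectance scale switch
  oi3 <- optical_indices(red = mk(0.1), blue = mk(0.05), nir = mk(0.4),
                         swir1 = mk(0.2), scale = 1)
  expect_equal(oi3$evi$values[1, 1], 2.5 * 0.3 / (0.4 + 0.6 - 0.375 + 1))
})

test_that("the optical water rule uses strict inequalities", {
  mk <- function(v) raster_grid(matrix(v, 1, 1))
  expect_equal(optical_flood(mk(0.3), mk(0.1), mk(0.2))$values[1, 1], 1)
  expect_equal(optical_flood(mk(0.05), mk(0.1), mk(0.2))$values[1, 1], 0)
  expect_equal(optical_flood(mk(0.1), mk(0.1), mk(0.2))$values[1, 1], 0)
  expect_equal(optical_flood(mk(0.3), mk(0.2), mk(0.2))$values[1, 1], 0)

  set.seed(103)
  nd <- rand_raster(104, lo = -0.2, hi = 0.8)
  ev <- rand_raster(105, lo = -0.2, hi = 0.6)
  ls <- rand_raster(106, lo = -0.3, hi = 0.6)
  expect_equal(optical_flood(nd, ev, ls)$values,
               (ls$values > ev$values & nd$values > 0.1) + 0)
})

test_that("cross-map agreement reports zonal areas and R-squared", {
  m <- rand_binary_map(111, nr = 24, nc = 24)
  zones <- grid_zones(m, 3, 3)
  self <- crossmap_agreement(m, m, zones)
  expect_equal(self$r_squared, 1)

  empty <- raster_grid(matrix(0, 24, 24))
  deg <- crossmap_agreement(m, empty, zones)
  expect_true(is.na(deg$r_squared))
  expect_match(deg$flag, "undefined")

  m2 <- rand_binary_map(112, nr = 24, nc = 24)
  res <- crossmap_agreement(m, m2, zones)
  a <- res$table$area_a_km2; b <- res$table$area_b_km2
  r2_oracle <- cor(a, b)^2
  expect_equal(res$r_squared, r2_oracle)
  expect_error(crossmap_agreement(m, m2, zones[1, ]), "two zones")
})
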