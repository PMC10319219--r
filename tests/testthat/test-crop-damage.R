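test_that("flooded-cropland overlay accounts area by crop type", {
  flood <- raster_grid(matrix(c(rep(1, 50), rep(0, 50)), 10, 10))
  crops <- raster_grid(matrix(0, 10, 10))
  res <- flooded_cropland(flood, crops)
  expect_equal(sum(res$areas$area_km2), 0)

  rice <- raster_grid(matrix(1, 10, 10))
  res2 <- flooded_cropland(flood, rice)
  expect_equal(res2$rice_share_percent, 100)
  expect_equal(res2$areas$area_km2[res2$areas$crop == "rice"],
               area_km2(flood, 1))

  set.seed(121)
  fl <- rand_binary_map(122, nr = 15, nc = 15)
  cr <- raster_grid(matrix(sample(0:2, 225, replace = TRUE), 15, 15))
  res3 <- flooded_cropland(fl, cr)
  expect_equal(res3$areas$area_km2[1],
               sum(fl$values == 1 & cr$values == 1) * 100 / 1e6)
  expect_equal(res3$areas$area_km2[2],
               sum(fl$values == 1 & cr$values == 2) * 100 / 1e6)
  expect_equal(sum(res3$mask$values), sum(fl$values == 1 & cr$values > 0))

  bad <- raster_grid(matrix(7, 10, 10))
  expect_error(flooded_cropland(flood, bad), "codes")
})

test_that("VI difference and mVCI/DVDI match their closed forms", {
  a <- raster_grid(matrix(0.3, 3, 3)); b <- raster_grid(matrix(0.7, 3, 3))
  expect_equal(vi_difference(a, b)$values, matrix(-0.4, 3, 3))
  expect_true(all(vi_difference(a, a)$values == 0))
  ra <- rand_raster(131, lo = -1, hi = 1)
  rb <- rand_raster(132, lo = -1, hi = 1)
  expect_equal(vi_difference(ra, rb)$values, ra$values - rb$values)

  mk <- function(v) raster_grid(matrix(v, 2, 2))
  expect_equal(mvci(mk(0.5), mk(0.6), mk(0.8))$values[1, 1], -0.5)
  expect_equal(mvci(mk(0.8), mk(0.6), mk(0.8))$values[1, 1], 1)
  expect_true(is.na(mvci(mk(0.5), mk(0.6), mk(0.6))$values[1, 1]))
  expect_equal(dvdi(mk(0.2), mk(0.5))$values[1, 1], -0.3)

  # undamaged pixel on a noise-free synthetic scene: DVDI approximately 0
  cfg <- small_config(seed = 14, vi = list(vi_sd = 0, hist_sd = 0))
  sc <- generate_scene(cfg)
  clim <- vi_climatology(sc$vi$hist)
  dv <- dvdi(mvci(sc$vi$ndvi_a, clim$med, clim$max),
             mvci(sc$vi$ndvi_pre, clim$med, clim$max))
  calm <- sc$truth$intensity$values == 0 & sc$truth$water_mask$values == 0
  expect_true(all(abs(dv$values[calm]) < 1e-9))
})

test_that("geometrical intervals have constant-ratio widths and balance classes", {
  set.seed(141)
  u <- raster_grid(matrix(runif(2500), 50, 50))
  cls <- geometric_interval_reclass(u)
  br <- attr(cls, "breaks")
  w <- diff(br)
  ratios <- w[-1] / w[-length(w)]
  expect_lt(max(abs(ratios - ratios[1])) / ratios[1], 1e-9)
  # uniform data -> ratio near 1, near-equal widths
  expect_lt(abs(log(attr(cls, "ratio"))), 0.1)
  expect_lt(max(w) / min(w), 1.4)
  expect_setequal(sort(unique(as.vector(cls$values))), 0:3)

  # skewed data still yields a constant-ratio progression
  sk <- raster_grid(matrix(-rexp(2500, 3), 50, 50))
  cls_sk <- geometric_interval_reclass(sk)
  wsk <- diff(attr(cls_sk, "breaks"))
  rsk <- wsk[-1] / wsk[-length(wsk)]
  expect_lt(max(abs(rsk - rsk[1])) / rsk[1], 1e-9)
  # breaks reproduce under a fixed input
  cls_sk2 <- geometric_interval_reclass(sk)
  expect_identical(attr(cls_sk, "breaks"), attr(cls_sk2, "breaks"))

  expect_warning(cc <- geometric_interval_reclass(
    raster_grid(matrix(5, 4, 4))), "class 0")
  expect_true(all(cc$values == 0))

  # orientation: the most negative interval gets the top class
  neg <- raster_grid(matrix(c(-0.45, -0.30, -0.15, -0.001), 2, 2))
  cls_neg <- geometric_interval_reclass(neg)
  expect_equal(cls_neg$values[1, 1], 3)
  expect_equal(cls_neg$values[2, 2], 0)
  # zero_floor forces non-declines to class 0
  mix <- raster_grid(matrix(c(-0.4, -0.2, 0, 0.2), 2, 2))
  cls_mix <- geometric_interval_reclass(mix, zero_floor = TRUE)
  expect_equal(cls_mix$values[1, 2], 0)
  expect_equal(cls_mix$values[2, 2], 0)
  expect_gt(cls_mix$values[1, 1], 0)
})

test_that("severity degree combines components and partitions the domain", {
  mk <- function(v) raster_grid(matrix(v, 2, 2))
  sev <- severity_degree(mk(3), mk(3), mk(3), mk(3))
  expect_true(all(sev$degree$values == 3))
  expect_true(all(sev$classes$values == 3))

  sev2 <- severity_degree(mk(0), mk(0), mk(0), mk(1))
  expect_true(all(sev2$degree$values == 0.25))
  expect_true(all(sev2$classes$values == 1))

  sev3 <- severity_degree(mk(1), mk(2), mk(1), mk(2))
  expect_true(all(sev3$degree$values == 1.5))
  expect_true(all(sev3$classes$values == 2))

  # intensity 0 pixels are excluded from the domain
  int <- raster_grid(matrix(c(0, 1, 2, 3), 2, 2))
  sev4 <- severity_degree(mk(2), mk(2), mk(2), int)
  expect_true(is.na(sev4$degree$values[1, 1]))
  expect_false(anyNA(sev4$degree$values[-1]))
  # boundary degrees map to (0,1] (1,2] (2,3]
  expect_equal(sev4$classes$values[2, 1], ceiling((2 + 2 + 2 + 1) / 4))
})

test_that("damage report areas and integer shares are consistent", {
  # construct a class map with exact pixel counts at 1 km pixels
  counts <- c(slight = 637, moderate = 1054, severe = 558)
  vals <- rep(c(1, 2, 3, NA), c(637, 1054, 558, 2304 - 2249))
  m <- raster_grid(matrix(vals, 48, 48), pixel_size = 1000)
  crops <- raster_grid(matrix(1, 48, 48), pixel_size = 1000)
  rep1 <- damage_report(m, crops, grid_zones(m, 1, 1))
  expect_equal(rep1$summary$area_km2, c(637, 1054, 558))
  expect_equal(rep1$summary$share_percent, c(28, 47, 25))
  expect_equal(sum(rep1$by_zone$area_km2), 2249)

  # single-class map -> 100/0/0
  u <- raster_grid(matrix(2, 6, 6), pixel_size = 1000)
  rep2 <- damage_report(u, raster_grid(matrix(1, 6, 6), pixel_size = 1000),
                        grid_zones(u, 1, 1))
  expect_equal(rep2$summary$share_percent,
               c(0, 100, 0))

  # random map vs brute-force tally by class and crop
  set.seed(151)
  dm <- raster_grid(matrix(sample(c(NA, 1, 2, 3), 400, replace = TRUE),
                           20, 20))
  cr <- raster_grid(matrix(sample(1:2, 400, replace = TRUE), 20, 20))
  rep3 <- damage_report(dm, cr, grid_zones(dm, 1, 1))
  for (cl in 1:3) for (code in 1:2) {
    lbl <- c("slight", "moderate", "severe")[cl]
    crop <- c("rice", "other")[code]
    expect_equal(
      rep3$by_zone$area_km2[rep3$by_zone$class == lbl &
                              rep3$by_zone$crop == crop],
      sum(dm$values == cl & cr$values == code, na.rm = TRUE) * 100 / 1e6)
  }
})

test_that("mean severity is non-decreasing in truth intensity on scenes", {
  res <- run_flood_pipeline(small_config(seed = 17))
  deg <- res$damage$degree$values
  tint <- res$scene$truth$intensity$values
  means <- sapply(1:3, function(k) mean(deg[tint == k], na.rm = TRUE))
  expect_true(all(diff(means) >= 0))
  # severity degree lies in (0, 3] and classes partition its domain
  dom <- !is.na(deg)
  expect_true(all(deg[dom] > 0 & deg[dom] <= 3))
  cls <- res$damage$classes$values
  expect_true(all(!is.na(cls[dom])))
  expect_true(all(cls[dom] %in% 1:3))
})

test_that("noise-free top-intensity cropland is classed severe", {
  cfg <- small_config(seed = 18, looks = Inf, sigma_db = 0,
                      vi = list(vi_sd = 0, hist_sd = 0))
  res <- run_flood_pipeline(cfg)
  cls <- res$damage$classes$values
  tint <- res$scene$truth$intensity$values
  crop <- res$scene$truth$cropland$values
  top <- tint == 3 & crop > 0
  expect_true(any(top))
  expect_true(all(cls[top] == 3))
})
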