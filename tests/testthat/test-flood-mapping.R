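test_that("CDAT difference is min(F) - min(R), linear in offsets", {
  ref <- const_stack(c(-10, -12))
  fl <- const_stack(c(-20, -15), start = as.Date("2020-07-01"))
  d <- cdat_difference(temporal_min(fl), temporal_min(ref))
  expect_true(all(d$values == -8))
  expect_identical(attr(d, "algorithm"), "CDAT")

  # identical stacks -> D == 0
  d0 <- cdat_difference(temporal_min(ref), temporal_min(ref))
  expect_true(all(d0$values == 0))

  # elementwise oracle + shift invariance on random composites
  a <- rand_raster(41, nr = 12, nc = 12)
  b <- rand_raster(42, nr = 12, nc = 12)
  expect_equal(cdat_difference(a, b)$values, a$values - b$values)
  ac <- raster_grid(a$values + 5, pixel_size = 10)
  bc <- raster_grid(b$values + 5, pixel_size = 10)
  expect_equal(cdat_difference(ac, bc)$values,
               cdat_difference(a, b)$values, tolerance = 1e-12)

  mean_ref <- temporal_mean(ref)
  expect_error(cdat_difference(temporal_min(fl), mean_ref), "min-composite")
})

test_that("NDFI matches worked values and is monotone in the minimum", {
  # reference constant -10 dB; flood never darker than reference -> NDFI 0
  ref <- const_stack(c(-10, -10))
  fl_same <- const_stack(c(-10, -8), start = as.Date("2020-07-01"))
  expect_true(all(abs(ndfi(ref, fl_same)$values) < 1e-12))

  # mean(R) = -10, min = -20 -> -1/3 ; min = -30 -> -0.5
  fl20 <- const_stack(c(-20), start = as.Date("2020-07-01"))
  fl30 <- const_stack(c(-30), start = as.Date("2020-07-01"))
  expect_equal(ndfi(ref, fl20)$values[1, 1], -1 / 3)
  expect_equal(ndfi(ref, fl30)$values[1, 1], -0.5)

  # monotone: mean(R) fixed and negative, NDFI non-increasing as min drops
  mins <- seq(-10, -35, by = -1)
  vals <- sapply(mins, function(m) (-10 - m) / (-10 + m))
  expect_true(all(diff(vals) <= 0))

  expect_error(ndfi(ref, structure(list(rasters = list(), dates = NULL),
                                   class = "fs_stack")),
               "at least one")
})

test_that("adaptive threshold implements mean - Kc * sd over valid pixels", {
  r <- raster_grid(matrix(c(-2, -1, 0, 1, 2, NA), 2, 3))
  th <- adaptive_threshold(r, Kc = 1.5, std_kind = "population")
  expect_equal(th$T, -1.5 * sqrt(2), tolerance = 1e-12)
  expect_equal(adaptive_threshold(r, Kc = 0)$T, 0)

  const <- raster_grid(matrix(-4, 3, 3))
  expect_equal(adaptive_threshold(const)$T, -4)

  th_s <- adaptive_threshold(r, Kc = 1.5, std_kind = "sample")
  expect_equal(th_s$T, mean(-2:2) - 1.5 * sd(-2:2), tolerance = 1e-12)

  allna <- raster_grid(matrix(NA_real_, 2, 2))
  expect_error(adaptive_threshold(allna), "at least 2 valid")
})

test_that("terrain filter keeps slopes up to the cutoff, inclusive", {
  flat <- raster_grid(matrix(0, 10, 10), pixel_size = 1)
  expect_true(all(terrain_filter(flat)$values == 1))

  # ramp rising 0.1 m per meter: slope atan(0.1) = 5.71 deg -> ineligible
  ramp <- raster_grid(outer(rep(1, 10), 1:10) * 0.1, pixel_size = 1)
  elig <- terrain_filter(ramp, 5)
  expect_true(all(elig$values[3:8, 3:8] == 0))
  expect_equal(slope_deg(ramp)$values[5, 5], atan(0.1) * 180 / pi,
               tolerance = 1e-9)

  # ramp at exactly 5 degrees stays eligible (inclusive cutoff)
  ramp5 <- raster_grid(outer(rep(1, 10), 1:10) * tan(5 * pi / 180),
                       pixel_size = 1)
  expect_true(all(terrain_filter(ramp5, 5)$values[3:8, 3:8] == 1))

  expect_error(terrain_filter(flat, -1), ">= 0")
})

test_that("background and seasonal filters apply their boundary rules", {
  d <- raster_grid(matrix(c(0, -5, 1e-9, NA), 2, 2))
  attr(d, "algorithm") <- "CDAT"
  bg <- background_filter(d)
  expect_equal(bg$values[1, 1], 0)   # exact zero excluded
  expect_equal(bg$values[2, 1], 1)
  expect_equal(bg$values[1, 2], 0)   # within epsilon of zero
  expect_true(is.na(bg$values[2, 2]))

  nd <- raster_grid(matrix(0, 2, 2))
  attr(nd, "algorithm") <- "NDFI"
  expect_error(background_filter(nd), "difference image")

  mf <- raster_grid(matrix(c(-18.9, -19.1, -19, -40), 2, 2))
  seas <- seasonal_filter(mf, -19)
  expect_equal(as.vector(seas$values), c(0, 1, 0, 1))
  expect_true(all(seasonal_filter(mf, -Inf)$values == 0))

  # random D vs elementwise oracle
  rd <- rand_raster(51, nr = 10, nc = 10, lo = -3, hi = 3)
  attr(rd, "algorithm") <- "CDAT"
  expect_equal(background_filter(rd)$values,
               (abs(rd$values) > 1e-6) + 0)
})

test_that("classification is strict and masks intersect order-free", {
  idx <- raster_grid(matrix(c(-3.242, -4, -1, NA), 2, 2))
  m <- classify_flood(idx, fixed_threshold(-3.242))
  expect_equal(m$values[1, 1], 0)  # at the threshold -> non-flooded
  expect_equal(m$values[2, 1], 1)  # -4 < -3.242 -> flooded
  expect_equal(m$values[1, 2], 0)
  expect_true(is.na(m$values[2, 2]))

  # random inputs vs boolean oracle with masks, order-independent
  idx2 <- rand_raster(61, nr = 14, nc = 14, lo = -10, hi = 0)
  m1 <- rand_binary_map(62, nr = 14, nc = 14, p = 0.7)
  m2 <- rand_binary_map(63, nr = 14, nc = 14, p = 0.7)
  a <- classify_flood(idx2, -5, m1, m2)
  b <- classify_flood(idx2, -5, m2, m1)
  expect_identical(a$values, b$values)
  oracle <- (idx2$values < -5 & m1$values == 1 & m2$values == 1) + 0
  expect_equal(a$values, oracle)
})

test_that("synergy map is the logical AND with nodata propagation", {
  a <- raster_grid(matrix(c(1, 1, 0, NA), 2, 2))
  b <- raster_grid(matrix(c(1, 0, 1, 1), 2, 2))
  s <- synergy_map(a, b)
  expect_equal(as.vector(s$values)[1:3], c(1, 0, 0))
  expect_true(is.na(s$values[2, 2]))

  for (seed in 1:3) {
    ma <- rand_binary_map(seed * 7, nr = 20, nc = 20)
    mb <- rand_binary_map(seed * 7 + 1, nr = 20, nc = 20)
    sy <- synergy_map(ma, mb)
    expect_lte(area_km2(sy, 1), min(area_km2(ma, 1), area_km2(mb, 1)))
    expect_equal(sy$values, (ma$values == 1 & mb$values == 1) + 0)
  }
})

test_that("permanent water never enters the flood map", {
  # water stays at -20 dB in both periods: D = 0 -> background filter
  ref <- const_stack(c(-20, -20))
  fl <- const_stack(c(-20, -20), start = as.Date("2020-07-01"))
  d <- cdat_difference(temporal_min(fl), temporal_min(ref))
  bg <- background_filter(d)
  flooded <- classify_flood(d, fixed_threshold(-3), bg)
  expect_true(all(flooded$values == 0))
})

test_that("speckle-free scenes are recovered exactly outside confounders and hills", {
  cfg <- small_config(seed = 9, looks = Inf, sigma_db = 0)
  res <- run_flood_pipeline(cfg)
  tr <- res$scene$truth
  excl <- tr$confounder_mask$values == 1 | tr$hill_mask$values == 1
  for (k in 1:3)
    expect_equal(sum(res$stage_maps[[k]]$values[!excl] !=
                       tr$stage_masks[[k]]$values[!excl]), 0)
})
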