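test_that("ASCII grid round-trip preserves values and nodata exactly", {
  tmp <- withr::local_tempdir()
  # integer / categorical raster: bit-exact
  m <- matrix(sample.int(6, 100, replace = TRUE), 10, 10)
  m[c(4, 17, 60)] <- NA
  r <- make_raster(m, categorical = TRUE)
  path <- file.path(tmp, "lc.asc")
  write_raster(r, path)
  back <- read_raster(path, categorical = TRUE)
  expect_identical(back$values, r$values)
  expect_equal(sum(is.na(raster_values(back))), 3)
  expect_equal(back$cell_size, 30)
  expect_equal(back$crs, "test")
  # continuous raster: doubles survive the %.17g round trip
  set.seed(3)
  rc <- make_raster(matrix(rnorm(100), 10, 10))
  write_raster(rc, file.path(tmp, "c.asc"))
  expect_identical(read_raster(file.path(tmp, "c.asc"))$values, rc$values)
})

test_that("nodata sentinel cells come back as an invalid mask", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "s.asc")
  writeLines(c("NCOLS 3", "NROWS 3", "XLLCORNER 0", "YLLCORNER 0",
               "CELLSIZE 30", "NODATA_VALUE -9999",
               "1 2 -9999", "4 -9999 6", "-9999 8 9"), path)
  r <- read_raster(path, crs = "test")
  expect_equal(sum(is.na(raster_values(r))), 3)
  expect_equal(raster_values(r)[1, 1], 1)
})

test_that("unreadable or CRS-less rasters fail with the file named", {
  tmp <- withr::local_tempdir()
  txt <- file.path(tmp, "notraster.txt")
  writeLines("this is not a raster", txt)
  expect_error(read_raster(txt), "notraster")
  nocrs <- file.path(tmp, "nocrs.asc")
  writeLines(c("NCOLS 2", "NROWS 1", "XLLCORNER 0", "YLLCORNER 0",
               "CELLSIZE 30", "NODATA_VALUE -9999", "1 2"), nocrs)
  expect_error(read_raster(nocrs), "CRS")
  expect_error(read_raster(file.path(tmp, "absent.asc")), "not found")
})

test_that("dominant aggregation takes the block mode with deterministic ties", {
  # classes: forest 1, park 2, water 6
  f <- make_raster(matrix(c(1, 1, 2, 6), 2, 2), categorical = TRUE)
  expect_equal(raster_values(aggregate_dominant(f, 2))[1, 1], 1L)
  tie <- make_raster(matrix(c(2, 2, 1, 1), 2, 2), categorical = TRUE)
  expect_equal(raster_values(aggregate_dominant(tie, 2))[1, 1], 1L)
  allna <- make_raster(matrix(NA_integer_, 2, 2), categorical = TRUE)
  expect_true(is.na(raster_values(aggregate_dominant(allna, 2))[1, 1]))
  expect_error(aggregate_dominant(make_raster(matrix(runif(4), 2, 2)), 2),
               "categorical")
})

test_that("dominant aggregation output is always a class present in the block", {
  set.seed(42)
  for (rep in 1:10) {
    m <- matrix(sample.int(5, 144, replace = TRUE), 12, 12)
    m[sample(144, 20)] <- NA
    fine <- make_raster(m, categorical = TRUE)
    coarse <- aggregate_dominant(fine, 3)
    for (bi in 1:4) for (bj in 1:4) {
      blk <- m[(3 * bi - 2):(3 * bi), (3 * bj - 2):(3 * bj)]
      cc <- raster_values(coarse)[bi, bj]
      if (all(is.na(blk))) expect_true(is.na(cc))
      else expect_true(cc %in% blk)
    }
  }
})

test_that("dominant aggregation pads non-divisible grids with nodata", {
  m <- matrix(1L, 5, 5)
  coarse <- aggregate_dominant(make_raster(m, categorical = TRUE), 2)
  expect_equal(dim(coarse), c(3L, 3L))
  expect_equal(raster_values(coarse)[3, 3], 1L)  # 1-cell corner still modal
})

test_that("bilinear resampling preserves constants and interpolates centres", {
  coarse <- make_raster(matrix(5, 4, 4), cell_size = 30)
  target <- make_raster(matrix(0, 12, 12), cell_size = 10)
  expect_true(all(raster_values(resample_bilinear(coarse, target)) == 5))
  # 2x2 coarse [0,1;1,2] sampled at its exact centre -> mean of corners
  c2 <- make_raster(matrix(c(0, 1, 1, 2), 2, 2), cell_size = 30)
  centre <- make_raster(matrix(0, 1, 1), cell_size = 60)
  expect_equal(raster_values(resample_bilinear(c2, centre))[1, 1], 1.0)
  expect_error(
    resample_bilinear(make_raster(matrix(1L, 2, 2), categorical = TRUE), centre),
    "continuous")
})

test_that("bilinear resampling is exact for linear ramps inside the support", {
  cs <- 30
  cx <- (1:6 - 0.5) * cs
  cy <- (6:1 - 0.5) * cs
  ramp <- outer(cy, cx, function(y, x) 2 * x + 3 * y)
  coarse <- make_raster(ramp, cell_size = cs)
  target <- make_raster(matrix(0, 12, 12), cell_size = 15)
  out <- raster_values(resample_bilinear(coarse, target))
  tx <- (1:12 - 0.5) * 15
  ty <- (12:1 - 0.5) * 15
  want <- outer(ty, tx, function(y, x) 2 * x + 3 * y)
  inner <- 2:11  # outer target ring lies beyond the coarse centre hull (clamped)
  expect_equal(out[inner, inner], want[inner, inner], tolerance = 1e-12)
  # and never outside the coarse range anywhere
  expect_true(all(out >= min(ramp) - 1e-9 & out <= max(ramp) + 1e-9))
})

test_that("bilinear output stays within the coarse value range", {
  set.seed(9)
  coarse <- make_raster(matrix(runif(25, -3, 7), 5, 5), cell_size = 30)
  target <- make_raster(matrix(0, 25, 25), cell_size = 6)
  out <- raster_values(resample_bilinear(coarse, target))
  expect_true(all(out >= min(coarse$values) & out <= max(coarse$values)))
})

test_that("stacking intersects component validity masks", {
  s1 <- make_stack(na_cells = list(c(3, 7)))
  expect_equal(s1$n, 23)
  s2 <- make_stack(na_cells = list(c(3, 7), c(10, 11, 12)))
  expect_equal(s2$n, 20)
  r_small <- make_raster(matrix(1, 4, 4))
  r5 <- make_raster(matrix(1, 5, 5))
  expect_error(stack_components(r5, r5, r5, r_small), "soil_potential")
})
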