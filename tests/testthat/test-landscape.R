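test_that("patch labeling respects connectivity", {
  m <- matrix(2L, 3, 3)
  m[1, 1] <- 1L; m[2, 2] <- 1L          # two diagonal forest cells
  lc <- make_raster(m, categorical = TRUE)
  p8 <- label_patches(lc, connectivity = 8)
  expect_equal(sum(p8$patches$class == 1), 1)
  p4 <- label_patches(lc, connectivity = 4)
  expect_equal(sum(p4$patches$class == 1), 2)
  solid <- label_patches(make_raster(matrix(1L, 5, 5), categorical = TRUE))
  expect_equal(nrow(solid$patches), 1)
  expect_equal(solid$patches$n_cells, 25)
  expect_equal(solid$patches$area_ha, 25 * 900 / 1e4)
  expect_error(label_patches(make_raster(matrix(runif(9), 3, 3))), "categorical")
})

test_that("a two-class checkerboard under rook connectivity is all singletons", {
  m <- matrix(rep_len(c(1L, 2L), 25), 5, 5)
  p <- label_patches(make_raster(m, categorical = TRUE), connectivity = 4)
  expect_equal(nrow(p$patches), 25)
  expect_true(all(p$patches$n_cells == 1))
})

test_that("per-class patch areas sum to class cell counts times cell area", {
  set.seed(77)
  m <- matrix(sample.int(3, 400, replace = TRUE), 20, 20)
  lc <- make_raster(m, categorical = TRUE)
  p <- label_patches(lc)
  for (cc in 1:3) {
    expect_equal(sum(p$patches$area_m2[p$patches$class == cc]),
                 sum(m == cc) * 900)
  }
})

test_that("edge detection at one cell depth matches the toy geometry", {
  p <- label_patches(make_raster(matrix(1L, 5, 5), categorical = TRUE))
  p <- detect_edges(p, 30)
  expect_equal(sum(p$edge), 16)
  expect_equal(sum(!p$edge), 9)
  # 2-cell-wide strip: every cell is edge
  strip <- label_patches(make_raster(matrix(1L, 2, 6), categorical = TRUE))
  strip <- detect_edges(strip, 30)
  expect_true(all(strip$edge))
  # single-cell patch is its own edge
  m <- matrix(2L, 3, 3); m[2, 2] <- 1L
  single <- detect_edges(label_patches(make_raster(m, categorical = TRUE)), 30)
  expect_true(single$edge[2, 2])
  expect_warning(detect_edges(p, 10), "cell size")
})

test_that("edge detection equals the brute-force centre-distance oracle", {
  set.seed(55)
  for (rep in 1:15) {
    nr <- sample(4:20, 1); nc <- sample(4:20, 1)
    m <- matrix(sample.int(3, nr * nc, replace = TRUE), nr, nc)
    m[sample(nr * nc, round(0.1 * nr * nc))] <- NA
    lc <- make_raster(m, categorical = TRUE)
    d <- sample(c(30, 45, 60, 90), 1)
    p <- detect_edges(label_patches(lc), d)
    expect_identical(p$edge, edge_oracle(m, 30, d))
  }
})

test_that("edge and interior partition every patch", {
  set.seed(66)
  m <- matrix(sample.int(4, 900, replace = TRUE), 30, 30)
  lc <- make_raster(m, categorical = TRUE)
  p <- detect_edges(label_patches(lc), 30)
  in_patch <- !is.na(p$labels)
  expect_false(any(p$edge & !in_patch))   # edge flags only inside patches
  expect_equal(sum(p$edge) + sum(in_patch & !p$edge), sum(in_patch))
  # every patch has at least one edge cell
  for (pid in p$patches$patch) {
    expect_true(any(p$edge[!is.na(p$labels) & p$labels == pid]))
  }
})

test_that("adjacency classification follows the out-of-class neighbourhood", {
  # forest column, road column, park column
  m <- cbind(rep(1L, 3), rep(5L, 3), rep(2L, 3))
  p <- detect_edges(label_patches(make_raster(m, categorical = TRUE)), 30)
  p <- classify_adjacency(p, impervious_classes = 5L, green_classes = c(1L, 2L))
  expect_true(all(p$adjacency[, 1] == "impervious"))  # forest touches only road
  expect_true(all(p$adjacency[, 3] == "impervious"))
  expect_true(all(p$adjacency[, 2] == "green"))       # road touches both greens
  mixed <- cbind(rep(5L, 3), rep(1L, 3), rep(2L, 3))
  pm <- detect_edges(label_patches(make_raster(mixed, categorical = TRUE)), 30)
  pm <- classify_adjacency(pm, impervious_classes = 5L, green_classes = c(1L, 2L))
  expect_true(all(pm$adjacency[, 2] == "mixed"))      # forest touches road and park
  expect_error(classify_adjacency(p, impervious_classes = integer(0),
                                  green_classes = 1L), "non-empty")
})

test_that("zonal statistics aggregate valid cells per zone", {
  v <- matrix(c(1, 2, 3, 10, 20, NA), 2, 3)
  z <- matrix(c(1L, 1L, 1L, 2L, 2L, 3L), 2, 3)
  zs <- zonal_stats(make_raster(v), make_raster(z, categorical = TRUE))
  expect_equal(zs$mean[zs$zone == 1], 2)
  expect_equal(zs$sd[zs$zone == 1], 1)
  expect_equal(zs$n[zs$zone == 1], 3)
  expect_false(3 %in% zs$zone)                   # fully-nodata zone omitted
  expect_equal(zs$n[zs$zone == 2], 2)
  single <- zonal_stats(matrix(c(7, NA), 1, 2), matrix(c(1L, 1L), 1, 2))
  expect_equal(single$sd, 0)
  expect_false(single$sd_defined)
})

test_that("edge-interior comparison recovers constructed contrasts", {
  # one 6x6 forest patch in an impervious frame; interior at 0.50, edge 0.35
  m <- matrix(5L, 8, 8)
  m[2:7, 2:7] <- 1L
  lc <- make_raster(m, categorical = TRUE)
  p <- detect_edges(label_patches(lc), 30)
  v <- matrix(NA_real_, 8, 8)
  v[m == 1L & p$edge] <- 0.35
  v[m == 1L & !p$edge] <- 0.50
  set.seed(2); v <- v + matrix(rnorm(64, 0, 1e-6), 8, 8)  # avoid zero variance
  cmp <- compare_edge_interior(v, p, classes = 1L)
  expect_equal(cmp$pct_lower, 30, tolerance = 1e-2)
  expect_lt(cmp$p_value, 1e-6)
  # identical distributions: near-zero difference, large p
  v2 <- matrix(rnorm(64, 0.5, 0.05), 8, 8); v2[m != 1L] <- NA
  cmp2 <- compare_edge_interior(v2, p, classes = 1L)
  expect_lt(abs(cmp2$pct_lower), 15)
  expect_gt(cmp2$p_value, 0.001)
  # insufficient group sizes are skipped with a notice
  tiny <- detect_edges(label_patches(make_raster(matrix(1L, 2, 2),
                                                 categorical = TRUE)), 30)
  expect_message(out <- compare_edge_interior(matrix(1:4 / 4, 2, 2), tiny),
                 "skipped")
  expect_equal(nrow(out), 0)
})

test_that("patch size correlation behaves at the extremes", {
  # patches of growing size in an impervious matrix, value = linear in log area
  m <- matrix(5L, 12, 40)
  sizes <- list(2:2, 4:6, 9:13, 18:25, 30:39)
  for (k in seq_along(sizes)) m[2:(1 + k), sizes[[k]]] <- 2L
  lc <- make_raster(m, categorical = TRUE)
  p <- label_patches(lc, connectivity = 4)
  areas <- p$patches$area_ha[p$patches$class == 2]
  v <- matrix(NA_real_, 12, 40)
  for (pid in p$patches$patch[p$patches$class == 2]) {
    a <- p$patches$area_ha[p$patches$patch == pid]
    v[!is.na(p$labels) & p$labels == pid] <- 0.1 + 0.2 * log(a)
  }
  res <- patch_size_correlation(v, p, 2L)
  expect_equal(res$r, 1, tolerance = 1e-9)
  # shuffled values: |r| small on average (single seeded draw, generous band)
  set.seed(99)
  vals <- runif(5)
  v2 <- v
  for (k in seq_along(sizes)) {
    pid <- p$patches$patch[p$patches$class == 2][k]
    v2[!is.na(p$labels) & p$labels == pid] <- vals[k]
  }
  res2 <- patch_size_correlation(v2, p, 2L)
  expect_lt(abs(res2$r), 0.9)
  expect_error(patch_size_correlation(v, p, 5L), ">= 3")
})
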