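test_that("min-max normalization rescales columns to [0, 1]", {
  n <- normalize_minmax(cbind(a = c(2, 4, 6), b = c(-1, 0, 3)))
  expect_equal(unname(n$values[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(n$values[, "b"]), c(0, 0.25, 1))
  expect_false(any(n$degenerate))
  expect_error(normalize_minmax(matrix(1, 1, 2)), "at least 2")
})

test_that("a constant component is flagged degenerate and normalized to 0", {
  expect_warning(n <- normalize_minmax(cbind(a = c(1, 2, 3), b = c(5, 5, 5))),
                 "degenerate")
  expect_true(n$degenerate[["b"]])
  expect_equal(unname(n$values[, "b"]), c(0, 0, 0))
})

test_that("entropy weights match independent brute force on random matrices", {
  set.seed(101)
  for (rep in 1:50) {
    raw <- matrix(runif(20, -5, 15), 5, 4)
    norm <- normalize_minmax(raw)
    w <- entropy_weights(norm)
    oracle <- entropy_weights_bruteforce(minmax_bruteforce(raw))
    expect_equal(unname(w$weights), oracle, tolerance = 1e-10)
    expect_equal(sum(w$weights), 1, tolerance = 1e-12)
    expect_true(all(w$weights >= 0))
    expect_true(all(w$entropy >= 0 & w$entropy <= 1 + 1e-12))
  }
})

test_that("worked two-component example reproduces hand-derived weights", {
  n <- structure(list(values = cbind(A = c(0, 0.5, 1), B = c(1, 0, 1)),
                      degenerate = c(A = FALSE, B = FALSE)),
                 class = "normalized_matrix")
  w <- entropy_weights(n)
  expect_equal(unname(w$weights), c(0.5326, 0.4674), tolerance = 1e-3)
  expect_equal(w$k, 1 / log(3))
})

test_that("uniform positive components get zero weight; all-uniform errors", {
  expect_warning(n <- normalize_minmax(cbind(a = c(1, 5, 9), b = c(4, 4, 4))))
  w <- entropy_weights(n)
  expect_equal(unname(w$weights[["b"]]), 0)
  expect_warning(nd <- normalize_minmax(cbind(a = c(2, 2, 2), b = c(4, 4, 4))))
  expect_error(entropy_weights(nd), "uniform")
})

test_that("weights are invariant to grid (row) permutation", {
  set.seed(7)
  raw <- matrix(runif(40), 10, 4)
  w1 <- entropy_weights(normalize_minmax(raw))
  w2 <- entropy_weights(normalize_minmax(raw[sample(10), ]))
  expect_equal(w1$weights, w2$weights, tolerance = 1e-12)
})

test_that("an interior mean-preserving contraction lowers a column's weight", {
  set.seed(23)
  for (rep in 1:20) {
    A <- sort(runif(6))
    B <- A
    # contract an interior pair toward each other, preserving mean, min, max
    delta <- 0.3 * (B[4] - B[3])
    B[3] <- B[3] + delta
    B[4] <- B[4] - delta
    w <- entropy_weights(normalize_minmax(cbind(A = A, B = B)))
    expect_lte(w$weights[["B"]], w$weights[["A"]] + 1e-12)
  }
})

test_that("the composite index is the weighted dot product, bounded in [0, 1]", {
  n <- structure(list(values = rbind(c(0.5, 1.0), c(0, 0), c(1, 1)),
                      degenerate = c(FALSE, FALSE)),
                 class = "normalized_matrix")
  w <- structure(list(weights = c(0.6, 0.4), components = c("a", "b")),
                 class = "weight_vector")
  u <- compute_ugci(n, w)
  expect_equal(u, c(0.7, 0, 1))
  one_hot <- structure(list(weights = c(1, 0), components = c("a", "b")),
                       class = "weight_vector")
  expect_equal(compute_ugci(n, one_hot), n$values[, 1])
  bad <- structure(list(weights = c(1, 0, 0), components = letters[1:3]),
                   class = "weight_vector")
  expect_error(compute_ugci(n, bad), "mismatch")
})

test_that("the index is invariant to positive affine transforms of raw components", {
  set.seed(5)
  raw <- matrix(runif(60, 0, 50), 15, 4)
  u1 <- compute_ugci(normalize_minmax(raw), entropy_weights(normalize_minmax(raw)))
  raw2 <- raw
  raw2[, 2] <- 3.7 * raw2[, 2] + 12   # scale and offset one component
  raw2[, 4] <- 0.01 * raw2[, 4] - 5
  u2 <- compute_ugci(normalize_minmax(raw2), entropy_weights(normalize_minmax(raw2)))
  expect_equal(u1, u2, tolerance = 1e-12)
})

test_that("quartile classification partitions values into four levels", {
  res <- classify_quartiles(1:8)
  expect_equal(unname(as.vector(res$counts)), c(2, 2, 2, 2))
  expect_equal(as.character(res$levels[1]), "extremely_low")
  expect_equal(as.character(res$levels[8]), "high")
  expect_error(classify_quartiles(1:3), "at least 4")
  expect_error(classify_quartiles(rep(0.3, 10)), "not distinct")
})

test_that("published-style thresholds assign boundary values lower-inclusive", {
  thr <- c(0.14, 0.26, 0.49)
  res <- classify_quartiles(c(0.13, 0.14, 0.25, 0.26, 0.48, 0.49, 0.9), thr)
  expect_equal(as.character(res$levels),
               c("extremely_low", "low", "low", "moderate", "moderate",
                 "high", "high"))
})

test_that("level counts stay within 1 of n/4 for distinct values", {
  set.seed(31)
  for (n in c(10, 37, 100, 1001)) {
    res <- classify_quartiles(runif(n))
    expect_true(all(abs(as.vector(res$counts) - n / 4) <= 1))
  }
})

test_that("top-component selection keeps the largest weights, ties canonical", {
  w <- structure(list(weights = c(0.35, 0.30, 0.27, 0.08),
                      components = ugci_components()),
                 class = "weight_vector")
  expect_equal(select_top_components(w),
               c("vegetation_c", "soil_c", "net_uptake"))
  tied <- structure(list(weights = rep(0.25, 4), components = ugci_components()),
                    class = "weight_vector")
  expect_equal(select_top_components(tied), ugci_components()[1:3])
  expect_equal(select_top_components(w, 4), ugci_components())
  expect_error(select_top_components(w, 5), "cannot select")
})
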