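# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. These deliberately re-derive results from first
# principles (loops, all-pairs distances) rather than reusing package code.

# Entropy weights evaluated by naive loops on an already-normalized matrix.
entropy_weights_bruteforce <- function(Xn) {
  n <- nrow(Xn); m <- ncol(Xn)
  E <- numeric(m)
  for (j in seq_len(m)) {
    s <- sum(Xn[, j])
    acc <- 0
    for (i in seq_len(n)) {
      p <- Xn[i, j] / s
      if (p > 0) acc <- acc + p * log(p)
    }
    E[j] <- -acc / log(n)
  }
  u <- 1 - E
  u / sum(u)
}

# Column-wise min-max normalization by naive loops.
minmax_bruteforce <- function(X) {
  out <- X
  for (j in seq_len(ncol(X))) {
    out[, j] <- (X[, j] - min(X[, j])) / (max(X[, j]) - min(X[, j]))
  }
  out
}

# Edge flags by all-pairs centre distance; cells beyond the raster boundary
# count as nodata neighbours.
edge_oracle <- function(cls, cell_size, distance_m) {
  nr <- nrow(cls); nc <- ncol(cls)
  r <- ceiling(distance_m / cell_size) + 1L
  is_edge_cell <- function(i, j) {
    for (di in -r:r) for (dj in -r:r) {
      if (di == 0 && dj == 0) next
      if (sqrt((di * cell_size)^2 + (dj * cell_size)^2) > distance_m + 1e-9) next
      ii <- i + di; jj <- j + dj
      other <- if (ii < 1 || ii > nr || jj < 1 || jj > nc) NA else cls[ii, jj]
      if (is.na(other) || other != cls[i, j]) return(TRUE)
    }
    FALSE
  }
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!is.na(cls[i, j])) out[i, j] <- is_edge_cell(i, j)
  }
  out
}

# Small continuous raster with optional nodata cells.
make_raster <- function(values, cell_size = 30, categorical = FALSE) {
  grid_raster(values, cell_size = cell_size, crs = "test", categorical = categorical)
}

# A tiny aligned four-component stack from one base matrix (scaled copies so
# every component varies).
make_stack <- function(base = matrix(seq_len(25), 5, 5), na_cells = list()) {
  mats <- list(base, base * 2 + 1, base / 3, 100 - base)
  for (k in seq_along(na_cells)) {
    for (cell in na_cells[[k]] %||% integer(0)) mats[[k]][cell] <- NA
  }
  stack_components(make_raster(mats[[1]]), make_raster(mats[[2]]),
                   make_raster(mats[[3]]), make_raster(mats[[4]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fast small synthetic landscape for pipeline tests.
small_config <- function(out_dir, seed = 11L, nrow = 60, ncol = 60,
                         edge_deficit = 0.7) {
  cfg <- default_config()
  cfg$out_dir <- out_dir
  cfg$seed <- as.integer(seed)
  cfg$landscape$nrow <- nrow
  cfg$landscape$ncol <- ncol
  cfg$landscape$edge_deficit <- edge_deficit
  cfg
}
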