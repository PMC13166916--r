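#' Aggregate a categorical raster by dominant class
#'
#' Coarsens a fine categorical raster by an integer factor, assigning each
#' coarse cell the modal (dominant) class among its `factor` x `factor` fine
#' cells. Nodata fine cells are ignored; a coarse cell whose block is entirely
#' nodata is nodata. Ties are broken deterministically in favour of the
#' smallest class code. Dimensions not divisible by `factor` are padded with
#' nodata on the south/east sides before blocking.
#'
#' @param fine a categorical [grid_raster] (e.g. a 1 m land-cover map).
#' @param factor integer >= 1; the linear coarsening factor (30 turns a 1 m
#'   map into the 30 m analysis grid).
#' @return A categorical [grid_raster] on the coarse geometry.
#' @export
aggregate_dominant <- function(fine, factor) {
  stopifnot(is_grid_raster(fine))
  if (!fine$categorical) stop("aggregate_dominant() requires a categorical raster")
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("`factor` must be an integer >= 1")
  m <- fine$values
  nr <- nrow(m); nc <- ncol(m)
  nrp <- ceiling(nr / factor) * factor
  ncp <- ceiling(nc / factor) * factor
  if (nrp != nr || ncp != nc) {
    mp <- matrix(NA_integer_, nrp, ncp)
    mp[seq_len(nr), seq_len(nc)] <- m
    m <- mp
  }
  nbr <- nrp %/% factor; nbc <- ncp %/% factor
  bi <- (row(m) - 1L) %/% factor
  bj <- (col(m) - 1L) %/% factor
  block <- bi * nbc + bj + 1L
  modal_min <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    u <- sort(unique(v))
    u[which.max(tabulate(match(v, u)))]
  }
  # split() orders numeric keys numerically, and `block` is the row-major
  # coarse index, so the result fills the coarse matrix by row
  agg <- vapply(split(as.vector(m), as.vector(block)), modal_min, integer(1))
  out <- matrix(agg, nbr, nbc, byrow = TRUE)
  # padding extends south/east, so the coarse grid keeps the fine upper-left
  # corner: yll shifts down by the padded rows
  grid_raster(out, cell_size = fine$cell_size * factor,
              xll = fine$xll,
              yll = fine$yll - (nrp - nr) * fine$cell_size,
              crs = fine$crs, nodata = fine$nodata, categorical = TRUE)
}

#' Resample a continuous raster to a finer grid by bilinear interpolation
#'
#' Interpolates `coarse` at the cell centres of `target`'s geometry. Values
#' are bilinear combinations of the four surrounding coarse cell centres, so
#' the output never leaves the value range of the input and linear fields are
#' reproduced exactly. Target centres outside the coarse centre lattice are
#' clamped to its edge (nearest-valid extrapolation). If any of the four
#' surrounding coarse cells is nodata the nearest valid one of the four is
#' used; if all four are nodata the output cell is nodata.
#'
#' @param coarse a continuous [grid_raster] (e.g. a 250 m flux or 1 km soil map).
#' @param target a [grid_raster] supplying the output geometry (e.g. the 30 m
#'   analysis grid); its values are ignored.
#' @return A continuous [grid_raster] on `target`'s geometry.
#' @export
resample_bilinear <- function(coarse, target) {
  stopifnot(is_grid_raster(coarse), is_grid_raster(target))
  if (coarse$categorical) stop("resample_bilinear() requires a continuous raster")
  V <- coarse$values
  nrc <- nrow(V); ncc <- ncol(V)
  xs <- cell_centers_x(target)
  ys <- cell_centers_y(target)
  # fractional (row, col) position of each target centre in coarse index space
  fc <- (xs - coarse$xll) / coarse$cell_size + 0.5
  fr <- nrc + 0.5 - (ys - coarse$yll) / coarse$cell_size
  fc <- pmin(pmax(fc, 1), ncc)
  fr <- pmin(pmax(fr, 1), nrc)
  j0 <- if (ncc > 1) pmin(floor(fc), ncc - 1) else rep(1, length(fc))
  i0 <- if (nrc > 1) pmin(floor(fr), nrc - 1) else rep(1, length(fr))
  wx <- fc - j0
  wy <- fr - i0
  nrt <- nrow(target$values); nct <- ncol(target$values)
  I0 <- matrix(rep(i0, nct), nrt, nct)
  J0 <- matrix(rep(j0, each = nrt), nrt, nct)
  WX <- matrix(rep(wx, each = nrt), nrt, nct)
  WY <- matrix(rep(wy, nct), nrt, nct)
  I1 <- pmin(I0 + 1, nrc); J1 <- pmin(J0 + 1, ncc)
  v00 <- V[cbind(as.vector(I0), as.vector(J0))]
  v01 <- V[cbind(as.vector(I0), as.vector(J1))]
  v10 <- V[cbind(as.vector(I1), as.vector(J0))]
  v11 <- V[cbind(as.vector(I1), as.vector(J1))]
  w00 <- as.vector((1 - WY) * (1 - WX)); w01 <- as.vector((1 - WY) * WX)
  w10 <- as.vector(WY * (1 - WX));       w11 <- as.vector(WY * WX)
  out <- v00 * w00 + v01 * w01 + v10 * w10 + v11 * w11
  bad <- is.na(out)
  if (any(bad)) {
    corner_v <- cbind(v00, v01, v10, v11)[bad, , drop = FALSE]
    corner_w <- cbind(w00, w01, w10, w11)[bad, , drop = FALSE]
    corner_w[is.na(corner_v)] <- -Inf
    pick <- max.col(corner_w, ties.method = "first")
    repl <- corner_v[cbind(seq_len(nrow(corner_v)), pick)]
    out[bad] <- repl  # still NA where all four corners are nodata
  }
  # guard the convexity invariant against floating-point drift
  out <- pmin(pmax(out, min(V, na.rm = TRUE)), max(V, na.rm = TRUE))
  grid_raster(matrix(out, nrt, nct),
              cell_size = target$cell_size, xll = target$xll, yll = target$yll,
              crs = target$crs, nodata = coarse$nodata, categorical = FALSE)
}
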