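#' Min-max normalize the component matrix
#'
#' Rescales each component over all valid grid cells to \[0, 1\]:
#' \deqn{X'_{ij} = \frac{X_{ij} - X_{j,min}}{X_{j,max} - X_{j,min}}}
#' so every non-degenerate component attains an exact 0 and an exact 1. A
#' spatially constant (degenerate) component carries no information for the
#' index: it is flagged, its normalized values are set to 0, and a warning is
#' issued; [entropy_weights()] then assigns it zero weight.
#'
#' @param x a `component_stack` (see [stack_components()]) or a plain numeric
#'   matrix with grid cells in rows and components in columns.
#' @return A `normalized_matrix`: list with `values` (n x m matrix in
#'   \[0, 1\]), `min`/`max` per component, `degenerate` flags, and — when `x`
#'   is a stack — the cell index mapping and grid geometry needed to rebuild
#'   rasters.
#' @export
normalize_minmax <- function(x) {
  if (inherits(x, "component_stack")) {
    X <- stack_matrix(x)
    idx <- attr(X, "idx"); dims <- attr(X, "dims")
    geometry <- list(cell_size = x$cell_size, xll = x$xll, yll = x$yll,
                     crs = x$crs)
  } else if (is.matrix(x) && is.numeric(x)) {
    X <- x
    if (is.null(colnames(X))) colnames(X) <- paste0("component_", seq_len(ncol(X)))
    idx <- NULL; dims <- NULL; geometry <- NULL
  } else {
    stop("`x` must be a component_stack or a numeric matrix")
  }
  n <- nrow(X)
  if (is.null(n) || n < 2)
    stop("min-max normalization needs at least 2 valid grid cells")
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  rng <- maxs - mins
  degenerate <- rng == 0
  if (any(degenerate))
    warning(sprintf("degenerate (spatially constant) component(s): %s; normalized to 0",
                    paste(colnames(X)[degenerate], collapse = ", ")))
  Xn <- sweep(sweep(X, 2, mins, "-"), 2, ifelse(degenerate, 1, rng), "/")
  Xn[, degenerate] <- 0
  attributes(Xn) <- attributes(Xn)[c("dim", "dimnames")]
  structure(
    list(values = Xn, min = mins, max = maxs, degenerate = degenerate,
         components = colnames(Xn), idx = idx, dims = dims,
         geometry = geometry),
    class = "normalized_matrix"
  )
}

#' Entropy-based component weights
#'
#' Objective weights for the composite index from the spatial information
#' content of each component. Each cell's share of a component is
#' \eqn{P_{ij} = X'_{ij} / \sum_i X'_{ij}}; the normalized Shannon entropy is
#' \eqn{E_j = -\frac{1}{\ln n} \sum_i P_{ij} \ln P_{ij}} (with
#' \eqn{0 \ln 0 := 0}), and the weight is the renormalized information
#' utility \eqn{W_j = (1 - E_j) / \sum_j (1 - E_j)}. A component that varies
#' more across space has lower entropy of shares and hence more weight;
#' a spatially uniform component has \eqn{E_j = 1} and weight 0.
#'
#' @param norm a `normalized_matrix` from [normalize_minmax()].
#' @return A `weight_vector`: list with `weights` (summing to 1), `entropy`,
#'   `utility` (1 - E), the share matrix `P`, the constant `k = 1/ln(n)`, and
#'   the degenerate flags.
#' @export
entropy_weights <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  X <- norm$values
  n <- nrow(X)
  if (n < 2) stop("entropy weighting needs at least 2 grid cells")
  colsum <- colSums(X)
  degenerate <- norm$degenerate | colsum == 0
  P <- sweep(X, 2, ifelse(colsum == 0, 1, colsum), "/")
  plnp <- P * log(P)
  plnp[P == 0] <- 0             # 0 * ln 0 := 0
  E <- -colSums(plnp) / log(n)
  E[degenerate] <- 1
  utility <- 1 - E
  if (sum(utility) <= 0)
    stop("all components are spatially uniform: entropy weights are undefined")
  W <- utility / sum(utility)
  structure(
    list(weights = W, entropy = E, utility = utility, P = P, k = 1 / log(n),
         degenerate = degenerate, components = colnames(X)),
    class = "weight_vector"
  )
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector>\n")
  print(round(rbind(entropy = x$entropy, weight = x$weights), 4))
  invisible(x)
}

#' Compute the composite index
#'
#' Linear weighted aggregation of the normalized components:
#' \eqn{UGCI_i = \sum_j X'_{ij} W_j}. With weights summing to 1 and
#' normalized values in \[0, 1\], the index is bounded in \[0, 1\]; lower
#' values indicate poorer combined carbon condition.
#'
#' @param norm a `normalized_matrix`.
#' @param w a `weight_vector` over the same components.
#' @return Numeric vector of per-grid index values.
#' @export
compute_ugci <- function(norm, w) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(w, "weight_vector"))
  if (ncol(norm$values) != length(w$weights))
    stop(sprintf("component count mismatch: %d normalized components, %d weights",
                 ncol(norm$values), length(w$weights)))
  as.vector(norm$values %*% w$weights)
}

#' Classify index values into quartile management levels
#'
#' Splits the valid index values into four management levels at the 25th,
#' 50th and 75th percentiles (linear interpolation between order statistics):
#' `extremely_low` \[min, Q1), `low` \[Q1, Q2), `moderate` \[Q2, Q3), and
#' `high` \[Q3, max\]. Threshold values are lower-inclusive for the upper
#' level, matching the ">= Q3" reading of the top class. Externally supplied
#' thresholds (e.g. from an earlier run) can be passed to reproduce a fixed
#' classification.
#'
#' @param values numeric vector of index values (>= 4 required when
#'   thresholds are estimated).
#' @param thresholds optional numeric length-3 vector (Q1, Q2, Q3), strictly
#'   increasing.
#' @return An `index_result`: list with `ugci`, `thresholds`, `levels` (an
#'   ordered factor), and the per-level `counts`.
#' @export
classify_quartiles <- function(values, thresholds = NULL) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("`values` must not contain NA")
  if (is.null(thresholds)) {
    if (length(values) < 4)
      stop("quartile classification needs at least 4 values")
    thresholds <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
    if (any(diff(thresholds) <= 0))
      stop("quartile thresholds are not distinct (index values too uniform); supply `thresholds` explicitly")
  } else {
    if (length(thresholds) != 3 || any(diff(thresholds) <= 0))
      stop("`thresholds` must be 3 strictly increasing values (Q1, Q2, Q3)")
  }
  lev <- c("extremely_low", "low", "moderate", "high")
  idx <- 1L + (values >= thresholds[1]) + (values >= thresholds[2]) +
    (values >= thresholds[3])
  levels <- factor(lev[idx], levels = lev, ordered = TRUE)
  structure(
    list(ugci = values, thresholds = thresholds, levels = levels,
         counts = table(levels)),
    class = "index_result"
  )
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf("<index_result> n = %d, thresholds = %s\n", length(x$ugci),
              paste(signif(x$thresholds, 3), collapse = " / ")))
  print(x$counts)
  invisible(x)
}

#' Select the highest-weight components
#'
#' Returns the `count` components with the largest weights, in descending
#' weight order; ties are broken by the canonical component order. The
#' prescription workflow keeps the top three for the ternary decomposition
#' and drops the least informative component.
#'
#' @param w a `weight_vector`.
#' @param count number of components to keep (default 3).
#' @return Character vector of component names, length `count`.
#' @export
select_top_components <- function(w, count = 3) {
  stopifnot(inherits(w, "weight_vector"))
  m <- length(w$weights)
  if (count > m)
    stop(sprintf("cannot select %d of %d components", count, m))
  ord <- order(-w$weights, seq_len(m))
  w$components[ord[seq_len(count)]]
}

#' Rebuild a raster from per-valid-cell index values
#'
#' Maps a vector aligned with the valid cells of a normalized matrix (one
#' value per row, e.g. the output of [compute_ugci()]) back onto the source
#' grid geometry.
#'
#' @param values numeric (or integer-coded) vector, one value per valid cell.
#' @param norm the `normalized_matrix` the values are aligned with; must have
#'   been built from a `component_stack`.
#' @param categorical logical, passed through to [grid_raster()].
#' @return A [grid_raster].
#' @export
values_to_raster <- function(values, norm, categorical = FALSE) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (is.null(norm$idx))
    stop("`norm` was built from a plain matrix; no grid geometry to rebuild")
  if (length(values) != nrow(norm$values))
    stop("`values` length does not match the number of valid cells")
  g <- norm$geometry
  template <- list(cell_size = g$cell_size, xll = g$xll, yll = g$yll, crs = g$crs)
  vector_to_raster(as.numeric(values), norm$idx, norm$dims, template,
                   categorical = categorical)
}
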