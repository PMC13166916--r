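#' Canonical component names
#'
#' The four carbon components of the index, in canonical order: vegetation
#' carbon storage (tC/ha), soil carbon storage (tC/ha), net carbon uptake
#' (tC/ha/yr), and soil carbon storage potential (% silt+clay). This order is
#' the tie-break order wherever components are ranked.
#' @export
ugci_components <- function() {
  c("vegetation_c", "soil_c", "net_uptake", "soil_potential")
}

#' Assemble the four component rasters into a co-registered stack
#'
#' Validates that the four rasters share one geometry and builds the shared
#' validity mask: a cell is valid only where all four components are valid
#' (any nodata component invalidates the cell for the whole analysis).
#'
#' @param vegetation_c vegetation carbon storage raster, tC/ha.
#' @param soil_c soil carbon storage raster, tC/ha.
#' @param net_uptake net ecosystem productivity raster, tC/ha/yr.
#' @param soil_potential silt+clay content raster, percent.
#' @return A `component_stack`: list of the four rasters, the logical validity
#'   `mask`, and `n`, the number of valid grid cells.
#' @export
stack_components <- function(vegetation_c, soil_c, net_uptake, soil_potential) {
  comps <- list(vegetation_c = vegetation_c, soil_c = soil_c,
                net_uptake = net_uptake, soil_potential = soil_potential)
  for (nm in names(comps)) {
    if (!is_grid_raster(comps[[nm]]))
      stop(sprintf("component '%s' is not a grid_raster", nm))
    if (comps[[nm]]$categorical)
      stop(sprintf("component '%s' must be continuous", nm))
  }
  ref <- comps[[1]]
  for (nm in names(comps)[-1]) {
    if (!same_geometry(ref, comps[[nm]]))
      stop(sprintf("geometry mismatch: component '%s' does not match 'vegetation_c'", nm))
  }
  mask <- Reduce(`&`, lapply(comps, function(r) !is.na(r$values)))
  structure(
    list(components = comps, mask = mask, n = sum(mask),
         cell_size = ref$cell_size, xll = ref$xll, yll = ref$yll, crs = ref$crs),
    class = "component_stack"
  )
}

#' @export
print.component_stack <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<component_stack> %d x %d cells @ %g m, %d valid (%.1f%%)\n",
              d[1], d[2], x$cell_size, x$n, 100 * x$n / prod(d)))
  invisible(x)
}

# n-valid x 4 matrix of raw component values, rows in row-major cell order.
# Attributes carry the mapping back to the grid.
stack_matrix <- function(stack) {
  stopifnot(inherits(stack, "component_stack"))
  maskv <- as.vector(t(stack$mask))        # row-major order
  idx <- which(maskv)
  X <- vapply(stack$components,
              function(r) as.vector(t(r$values))[idx], numeric(length(idx)))
  colnames(X) <- names(stack$components)
  attr(X, "idx") <- idx
  attr(X, "dims") <- dim(stack$mask)
  X
}

# Rebuild a grid_raster from a vector of per-valid-cell values (row-major idx).
vector_to_raster <- function(v, idx, dims, template, categorical = FALSE) {
  full <- rep(NA_real_, prod(dims))
  full[idx] <- v
  m <- matrix(full, nrow = dims[1], ncol = dims[2], byrow = TRUE)
  grid_raster(m, cell_size = template$cell_size, xll = template$xll,
              yll = template$yll, crs = template$crs,
              nodata = if (is_grid_raster(template)) template$nodata else -9999,
              categorical = categorical)
}
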